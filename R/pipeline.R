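#' Channel statistics over a sample subset
#'
#' Per-channel mean and standard deviation computed on a subset of samples
#' (e.g. only those belonging to training-split trials), for use as frozen
#' statistics in [zscore_standardize()].
#'
#' @param rec A `seeg_recording`.
#' @param sample_idx Integer or logical sample index; default all samples.
#' @return A tibble with `name`, `mean`, `sd`.
#' @export
compute_channel_stats <- function(rec, sample_idx = NULL) {
  x <- if (is.null(sample_idx)) rec$signal else rec$signal[, sample_idx, drop = FALSE]
  tibble::tibble(name = rec$channels$name,
                 mean = rowMeans(x),
                 sd = apply(x, 1, stats::sd))
}

# Sample index (raw-rate) of all trials belonging to the given sentences.
samples_in_sentences <- function(schedule, sentence_ids, fs, n_total) {
  bd <- trial_boundaries(schedule)
  bd <- bd[bd$sentence_id %in% sentence_ids, ]
  idx <- logical(n_total)
  for (i in seq_len(nrow(bd))) {
    i0 <- floor(bd$trial_onset[i] * fs) + 1L
    i1 <- min(floor(bd$trial_offset[i] * fs), n_total)
    if (i0 <= i1) idx[i0:i1] <- TRUE
  }
  which(idx)
}

#' Prepare the split-independent pipeline inputs
#'
#' Channel selection and offline filtering do not depend on the sentence
#' split, so when the pipeline is repeated over many split seeds they can
#' be computed once and passed to [run_decoding_pipeline()] via its
#' `prepared` argument.
#'
#' @inheritParams run_decoding_pipeline
#' @return A list of class `prepared_inputs` with `selection`, the filtered
#'   selected-channel recording, and the preprocessing config.
#' @export
prepare_decoding_inputs <- function(rec, schedule,
                                    preproc = preproc_config(),
                                    select = TRUE) {
  selection <- select_channels(rec, schedule)
  keep <- if (select) selection$name[selection$selected]
          else selection$name[!(selection$reason %in% c("white_matter", "visual_region"))]
  if (length(keep) == 0)
    stop("no channels survive selection", call. = FALSE)
  rec_sel <- restrict_channels(rec, keep)
  filtered <- filter_signal(rec_sel, preproc, causal = FALSE)
  structure(list(selection = selection, filtered = filtered,
                 preproc = preproc),
            class = "prepared_inputs")
}

#' Run the discretized decoding pipeline for one split seed
#'
#' The full offline chain on a raw recording: speech-responsive channel
#' selection (paired band-power t-tests with BH correction plus anatomical
#' exclusions), filtering (broadband or high-gamma), z-scoring with
#' statistics frozen on the training-split samples, decimation,
#' segmentation, class balancing, sentence-level splitting with a leakage
#' guard, CNN training with early stopping, and held-out discretized
#' accuracy.
#'
#' A fraction of the *training* sentences is carved out as the
#' early-stopping validation set, so the held-out evaluation sentences are
#' never used for model selection.
#'
#' @param rec A raw `seeg_recording`.
#' @param schedule Its `trial_schedule`.
#' @param split_seed Seed for the sentence split (also seeds training and
#'   balancing via derived sub-seeds).
#' @param preproc A [preproc_config()].
#' @param train A [train_config()]; its `seed` is overridden by a sub-seed
#'   of `split_seed` so one seed reproduces the whole run.
#' @param eval_fraction Fraction of sentences held out for evaluation.
#' @param val_fraction Fraction of training sentences used for early
#'   stopping.
#' @param select Run channel selection (otherwise all non-excluded channels
#'   are used).
#' @param prepared Optional [prepare_decoding_inputs()] result, to reuse the
#'   split-independent selection and filtering across seeds.
#' @return A list of class `decoding_result`: `model`, `selection`, `split`,
#'   `accuracy` (one-row tibble), `zscore_stats`, `eval_segments` counts and
#'   the preprocessing config.
#' @export
run_decoding_pipeline <- function(rec, schedule, split_seed = 1L,
                                  preproc = preproc_config(),
                                  train = train_config(),
                                  eval_fraction = 0.2,
                                  val_fraction = 0.15,
                                  select = TRUE,
                                  prepared = NULL) {
  fs <- rec$sampling_rate

  if (is.null(prepared))
    prepared <- prepare_decoding_inputs(rec, schedule, preproc, select)
  selection <- prepared$selection
  filtered <- prepared$filtered
  preproc <- prepared$preproc

  # sentence-level split, with the leakage guard on every run
  split <- sentence_level_split(unique(schedule$sentence_id),
                                eval_fraction = eval_fraction,
                                seed = split_seed)
  assert_no_leakage(split)

  # z-score statistics frozen on training-split samples
  train_idx <- samples_in_sentences(schedule, split$train_sentence_ids,
                                    fs, n_samples(filtered))
  zstats <- compute_channel_stats(filtered, train_idx)
  standardized <- zscore_standardize(filtered, stats = zstats)
  ds <- downsample_recording(standardized, preproc$target_rate)

  segs <- label_and_segment(ds, schedule, preproc)
  in_train <- segs$info$sentence_id %in% split$train_sentence_ids

  # early-stopping validation sentences carved from the training split
  tr_sent <- split$train_sentence_ids
  n_val <- max(1L, round(val_fraction * length(tr_sent)))
  val_sent <- with_seed(derive_seed(split_seed, "valsplit"),
                        sort(tr_sent[sample.int(length(tr_sent), n_val)]))
  seg_train <- subset_segments(segs, in_train &
                                 !(segs$info$sentence_id %in% val_sent))
  seg_val <- subset_segments(segs, segs$info$sentence_id %in% val_sent)
  seg_eval <- subset_segments(segs, !in_train)

  seg_train <- balance_segments(seg_train, derive_seed(split_seed, "bal_train"))
  seg_val <- balance_segments(seg_val, derive_seed(split_seed, "bal_val"))
  seg_eval <- balance_segments(seg_eval, derive_seed(split_seed, "bal_eval"))

  train$seed <- derive_seed(split_seed, "train")
  model <- build_model(n_channels(ds), T = dim(segs$x)[2],
                       seed = derive_seed(split_seed, "init"))
  model <- train_cnn(model, seg_train, seg_val, train)
  model$channel_names <- ds$channels$name
  model$zscore_stats <- attr(standardized, "zscore_stats")

  acc <- discretized_accuracy(model, seg_eval)
  acc$split_seed <- split_seed
  acc$mode <- preproc$signal_mode

  structure(list(model = model, selection = selection, split = split,
                 accuracy = acc, zscore_stats = model$zscore_stats,
                 preproc = preproc,
                 n_train = dim(seg_train$x)[3],
                 n_val = dim(seg_val$x)[3],
                 n_eval = dim(seg_eval$x)[3]),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s mode | %d channels | eval accuracy %.3f (n=%d, seed %d)\n",
              x$accuracy$mode, x$model$C, x$accuracy$accuracy,
              x$accuracy$n_segments, x$accuracy$split_seed))
  invisible(x)
}

#' Continuous (streaming) evaluation of a trained pipeline
#'
#' Re-preprocesses the raw recording with strictly causal filters, applies
#' the frozen training z-score statistics, decimates, and runs
#' [continuous_decode()] over the held-out sentences of the result's split.
#'
#' @param result A `decoding_result` from [run_decoding_pipeline()].
#' @param rec The same raw `seeg_recording` the pipeline was run on.
#' @param schedule Its `trial_schedule`.
#' @param window,step Sliding-window length and step (s).
#' @return Per-trial accuracy tibble from [continuous_decode()].
#' @export
run_continuous_evaluation <- function(result, rec, schedule,
                                      window = 0.100, step = 0.005) {
  rec_sel <- restrict_channels(rec, result$model$channel_names)
  filtered <- filter_signal(rec_sel, result$preproc, causal = TRUE)
  standardized <- zscore_standardize(filtered, stats = result$zscore_stats)
  ds <- downsample_recording(standardized, result$preproc$target_rate)
  bd <- trial_boundaries(schedule)
  eval_trials <- bd$trial_id[bd$sentence_id %in% result$split$eval_sentence_ids]
  continuous_decode(result$model, ds, schedule, trial_ids = eval_trials,
                    window = window, step = step)
}
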