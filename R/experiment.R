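#' Experiment configuration
#'
#' One nested configuration object driving the whole pipeline, from
#' synthetic-data generation to saliency. All defaults reproduce the
#' package's reference settings: the 100-sentence x 3-repetition reading
#' paradigm, the standard preprocessing chain, the fixed CNN architecture
#' and its Adam/cosine training recipe, 80/20 sentence-level splitting, the
#' 100 ms / 5 ms continuous-decoding protocol, and the classical
#' speech-region exclusion list. Round-trips losslessly through YAML.
#'
#' @param paradigm A [paradigm_config()].
#' @param n_channels,fraction_informative,snr Channel-montage settings for
#'   the generator.
#' @param noise A [noise_params()].
#' @param preprocessing A [preproc_config()].
#' @param training A [train_config()].
#' @param eval_fraction Held-out sentence fraction.
#' @param n_seeds Number of split seeds.
#' @param continuous_window,continuous_step Continuous decoding window and
#'   step (s).
#' @param run_continuous,run_ablation,run_saliency Stage switches.
#' @param ablation An [ablation_spec()] (used when `run_ablation`).
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param output_dir Optional directory for reports.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(paradigm = paradigm_config(),
                              n_channels = 40L,
                              fraction_informative = 0.3,
                              snr = 1,
                              noise = noise_params(),
                              preprocessing = preproc_config(),
                              training = train_config(),
                              eval_fraction = 0.2,
                              n_seeds = 20L,
                              continuous_window = 0.100,
                              continuous_step = 0.005,
                              run_continuous = TRUE,
                              run_ablation = FALSE,
                              run_saliency = TRUE,
                              ablation = ablation_spec("region_exclusion"),
                              seed = 1L,
                              output_dir = NULL) {
  if (eval_fraction <= 0 || eval_fraction >= 1)
    stop("eval_fraction must be in (0, 1)", call. = FALSE)
  if (n_seeds < 1) stop("n_seeds must be >= 1", call. = FALSE)
  structure(list(paradigm = paradigm, n_channels = as.integer(n_channels),
                 fraction_informative = fraction_informative, snr = snr,
                 noise = noise, preprocessing = preprocessing,
                 training = training, eval_fraction = eval_fraction,
                 n_seeds = as.integer(n_seeds),
                 continuous_window = continuous_window,
                 continuous_step = continuous_step,
                 run_continuous = run_continuous,
                 run_ablation = run_ablation,
                 run_saliency = run_saliency,
                 ablation = ablation, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Write / read an experiment configuration as YAML
#'
#' @param config An [experiment_config()].
#' @param path YAML file path.
#' @return `write_experiment_config` invisibly returns `path`;
#'   `read_experiment_config` returns the `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  plain <- rapply(unclass(config), identity, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  experiment_config(
    paradigm = do.call(paradigm_config, raw$paradigm),
    n_channels = raw$n_channels,
    fraction_informative = raw$fraction_informative,
    snr = raw$snr,
    noise = do.call(noise_params, raw$noise),
    preprocessing = do.call(preproc_config, raw$preprocessing),
    training = do.call(train_config, raw$training[setdiff(names(raw$training), "loss")]),
    eval_fraction = raw$eval_fraction,
    n_seeds = raw$n_seeds,
    continuous_window = raw$continuous_window,
    continuous_step = raw$continuous_step,
    run_continuous = raw$run_continuous,
    run_ablation = raw$run_ablation,
    run_saliency = raw$run_saliency,
    ablation = do.call(ablation_spec, raw$ablation),
    seed = raw$seed,
    output_dir = raw$output_dir)
}

#' Run a full experiment
#'
#' Generate -> preprocess -> select channels -> split -> train -> evaluate
#' (discretized and optionally continuous) -> optional ablation -> optional
#' saliency, repeated over `n_seeds` sentence splits. Every randomized stage
#' draws a sub-seed derived from the global seed, so the whole report is
#' reproducible from `config$seed`. When `output_dir` is set, the summary
#' (JSON) and per-stage tables (TSV) are written there.
#'
#' @param config An [experiment_config()].
#' @return A list of class `experiment_report`: `discretized` (per-seed
#'   accuracy tibble), `continuous` (per-trial tibble or NULL), `ablation`
#'   (tibble or NULL), `saliency` (a `saliency_report` or NULL), `selection`
#'   (channel tibble), `config`, plus generation metadata.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  schedule <- generate_schedule(config$paradigm,
                                seed = derive_seed(config$seed, "schedule"))
  specs <- generate_channel_specs(config$n_channels,
                                  config$fraction_informative,
                                  seed = derive_seed(config$seed, "channels"),
                                  snr = config$snr)
  rec <- synthesize_recording(schedule, specs, config$noise,
                              seed = derive_seed(config$seed, "signal"),
                              sampling_rate = config$paradigm$sampling_rate)

  seeds <- seq_len(config$n_seeds)
  runs <- vector("list", length(seeds))
  continuous <- list()
  prepared <- prepare_decoding_inputs(rec, schedule, config$preprocessing)
  for (i in seq_along(seeds)) {
    res <- run_decoding_pipeline(rec, schedule, split_seed = seeds[i],
                                 preproc = config$preprocessing,
                                 train = config$training,
                                 eval_fraction = config$eval_fraction,
                                 prepared = prepared)
    runs[[i]] <- res
    if (config$run_continuous) {
      ct <- run_continuous_evaluation(res, rec, schedule,
                                      window = config$continuous_window,
                                      step = config$continuous_step)
      ct$split_seed <- seeds[i]
      continuous[[i]] <- ct
    }
  }
  discretized <- purrr::map_dfr(runs, "accuracy")
  continuous_tbl <- if (config$run_continuous) dplyr::bind_rows(continuous)
                    else NULL

  ablation_tbl <- if (config$run_ablation)
    run_ablation(rec, schedule, config$ablation,
                 seeds = seq_len(config$ablation$n_seeds),
                 preproc = config$preprocessing, train = config$training,
                 eval_fraction = config$eval_fraction)
  else NULL

  saliency <- NULL
  if (config$run_saliency) {
    # saliency on the last run's evaluation segments, dropout off
    res <- runs[[length(runs)]]
    eval_segs <- pipeline_eval_segments(res, rec, schedule, config)
    saliency <- compute_saliency(
      res$model, eval_segs,
      channels = specs[match(res$model$channel_names, specs$name), ])
  }

  report <- structure(list(
    discretized = discretized,
    continuous = continuous_tbl,
    ablation = ablation_tbl,
    saliency = saliency,
    selection = runs[[1]]$selection,
    n_trials = length(unique(schedule$trial_id)),
    config = config), class = "experiment_report")

  if (!is.null(config$output_dir)) write_experiment_report(report)
  report
}

# Rebuild the (balanced) evaluation segments of a finished pipeline run.
pipeline_eval_segments <- function(res, rec, schedule, config) {
  rec_sel <- restrict_channels(rec, res$model$channel_names)
  filtered <- filter_signal(rec_sel, config$preprocessing, causal = FALSE)
  standardized <- zscore_standardize(filtered, stats = res$zscore_stats)
  ds <- downsample_recording(standardized, config$preprocessing$target_rate)
  segs <- label_and_segment(ds, schedule, config$preprocessing)
  seg_eval <- subset_segments(
    segs, segs$info$sentence_id %in% res$split$eval_sentence_ids)
  balance_segments(seg_eval,
                   derive_seed(res$accuracy$split_seed, "bal_eval"))
}

write_experiment_report <- function(report) {
  dir <- report$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(report$discretized),
                     file.path(dir, "discretized_accuracy.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$continuous))
    utils::write.table(as.data.frame(report$continuous),
                       file.path(dir, "continuous_accuracy.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$ablation))
    utils::write.table(as.data.frame(report$ablation),
                       file.path(dir, "ablation.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$saliency)) {
    utils::write.table(as.data.frame(report$saliency$channel),
                       file.path(dir, "saliency_channels.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(report$saliency$region),
                       file.path(dir, "saliency_regions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_selection_report(report$selection, file.path(dir, "channel_selection.tsv"))
  summary <- list(
    seed = report$config$seed,
    n_trials = report$n_trials,
    n_selected_channels = sum(report$selection$selected),
    discretized_mean_accuracy = mean(report$discretized$accuracy),
    discretized_sd_accuracy = stats::sd(report$discretized$accuracy),
    continuous_mean_accuracy = if (!is.null(report$continuous))
      mean(report$continuous$accuracy) else NULL)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d trials, %d seeds | discretized %.3f +/- %.3f\n",
              x$n_trials, nrow(x$discretized),
              mean(x$discretized$accuracy), stats::sd(x$discretized$accuracy)))
  if (!is.null(x$continuous))
    cat(sprintf("  continuous (per-sentence mean): %.3f\n",
                mean(x$continuous$accuracy)))
  invisible(x)
}
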