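suppressMessages({
  library(dplyr)
  library(tibble)
})

# Shared fixtures, built once per test session and cached. Sizes are kept
# small: the paradigm structure, not the cohort scale, is what unit tests
# exercise.

# internal utilities exercised directly by the suite
with_seed <- speechstate:::with_seed

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small paradigm: 8 sentences x 2 repetitions, ~10 channels.
tiny_config <- function() paradigm_config(n_sentences = 8, n_repetitions = 2)

tiny_dataset <- function() {
  fixture("tiny_dataset", function() {
    sched <- generate_schedule(tiny_config(), seed = 101)
    specs <- generate_channel_specs(10, fraction_informative = 0.4,
                                    seed = 102, snr = 2)
    rec <- synthesize_recording(sched, specs, seed = 103)
    list(schedule = sched, specs = specs, rec = rec)
  })
}

# Downsampled, standardized, segmented version of the tiny dataset.
tiny_segments <- function() {
  fixture("tiny_segments", function() {
    d <- tiny_dataset()
    cfg <- preproc_config()
    rec <- filter_signal(d$rec, cfg)
    rec <- zscore_standardize(rec)
    rec <- downsample_recording(rec, cfg$target_rate)
    label_and_segment(rec, d$schedule, cfg)
  })
}

# One trained pipeline on the tiny dataset (few epochs; high SNR converges
# fast). Reused by prediction, saliency and continuous-decoding tests.
tiny_result <- function() {
  fixture("tiny_result", function() {
    d <- tiny_dataset()
    run_decoding_pipeline(d$rec, d$schedule, split_seed = 1,
                          train = train_config(epochs = 6),
                          eval_fraction = 0.25)
  })
}

# Offline-preprocessed evaluation segments matching a pipeline result's
# channel subset and frozen statistics.
pipeline_segments_for <- function(res, d) {
  rec_sel <- restrict_channels(d$rec, res$model$channel_names)
  filtered <- filter_signal(rec_sel, res$preproc)
  standardized <- zscore_standardize(filtered, stats = res$zscore_stats)
  ds <- downsample_recording(standardized, res$preproc$target_rate)
  segs <- label_and_segment(ds, d$schedule, res$preproc)
  subset_segments(segs, segs$info$sentence_id %in% res$split$eval_sentence_ids)
}

# Random labeled segments for pure model-mechanics tests (no signal).
random_segments <- function(C = 4, T = 50, n = 64, seed = 1) {
  with_seed(seed, {
    structure(list(
      x = array(rnorm(C * T * n), c(C, T, n)),
      info = tibble::tibble(segment_id = seq_len(n),
                            trial_id = rep(1L, n),
                            sentence_id = rep(1L, n),
                            repetition = rep(1L, n),
                            label = rep(c(0L, 1L), length.out = n),
                            window_start = seq_len(n) * 0.1)),
      class = "segment_set")
  })
}
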