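#' Ablation experiment specification
#'
#' Exactly one of three kinds:
#' * `random_dropout`: remove a fraction of the available channels uniformly
#'   at random (redrawn per seed) before training, emulating electrode
#'   malfunction; fractions of interest are 0, 0.1, 0.3 and 0.5.
#' * `region_exclusion`: remove every channel in the classical
#'   speech-related regions ([speech_regions()] by default).
#' * `region_restricted`: keep only channels of one anatomical domain
#'   (`cortical` or `subcortical`), or `all`.
#'
#' @param kind Ablation kind.
#' @param dropout_fraction Fraction of channels removed (random_dropout).
#' @param excluded_regions Region codes to remove (region_exclusion).
#' @param restriction Domain kept (region_restricted).
#' @param n_seeds Number of split/dropout seeds.
#' @return A list of class `ablation_spec`.
#' @export
ablation_spec <- function(kind = c("random_dropout", "region_exclusion",
                                   "region_restricted"),
                          dropout_fraction = 0,
                          excluded_regions = speech_regions(),
                          restriction = c("all", "cortical", "subcortical"),
                          n_seeds = 20L) {
  kind <- match.arg(kind)
  restriction <- match.arg(restriction)
  if (dropout_fraction < 0 || dropout_fraction >= 1)
    stop("dropout_fraction must be in [0, 1)", call. = FALSE)
  structure(list(kind = kind, dropout_fraction = dropout_fraction,
                 excluded_regions = excluded_regions,
                 restriction = restriction, n_seeds = as.integer(n_seeds)),
            class = "ablation_spec")
}

# Channel subset retained under an ablation spec, for one seed.
ablated_channels <- function(channels, spec, seed) {
  switch(spec$kind,
    random_dropout = {
      n <- nrow(channels)
      n_drop <- round(spec$dropout_fraction * n)
      if (n_drop == 0) return(channels$name)
      drop <- with_seed(derive_seed(seed, "chdrop"),
                        sample.int(n, n_drop))
      channels$name[-drop]
    },
    region_exclusion = channels$name[!(channels$region %in% spec$excluded_regions)],
    region_restricted = {
      if (spec$restriction == "all") channels$name
      else channels$name[channels$domain == spec$restriction]
    })
}

#' Run a channel-ablation experiment
#'
#' Applies the ablation to the recording's channel set, then retrains the
#' full pipeline from scratch once per seed (the same seeds are used across
#' conditions, so comparisons are paired on the sentence split).
#'
#' @param rec A raw `seeg_recording`.
#' @param schedule Its `trial_schedule`.
#' @param spec An [ablation_spec()].
#' @param seeds Integer vector of split seeds (defaults to
#'   `1:spec$n_seeds`).
#' @param preproc,train,eval_fraction Passed to [run_decoding_pipeline()].
#' @param select Run channel selection inside the pipeline.
#' @return A tibble with one row per seed: `kind`, `condition`, `seed`,
#'   `n_channels_in`, `accuracy`, `n_segments`.
#' @export
run_ablation <- function(rec, schedule, spec, seeds = seq_len(spec$n_seeds),
                         preproc = preproc_config(), train = train_config(),
                         eval_fraction = 0.2, select = TRUE) {
  condition <- switch(spec$kind,
    random_dropout = sprintf("dropout_%g", spec$dropout_fraction),
    region_exclusion = "speech_regions_excluded",
    region_restricted = spec$restriction)
  # the retained channel set is seed-independent except for random dropout,
  # so selection + filtering can be shared across seeds in the other kinds
  shared <- NULL
  if (spec$kind != "random_dropout" || spec$dropout_fraction == 0) {
    keep0 <- ablated_channels(rec$channels, spec, seeds[1])
    if (length(keep0) == 0) stop("ablation removed all channels", call. = FALSE)
    shared <- prepare_decoding_inputs(restrict_channels(rec, keep0), schedule,
                                      preproc, select)
  }
  purrr::map_dfr(seeds, function(s) {
    keep <- ablated_channels(rec$channels, spec, s)
    if (length(keep) == 0)
      stop("ablation removed all channels", call. = FALSE)
    rec_ab <- restrict_channels(rec, keep)
    res <- run_decoding_pipeline(rec_ab, schedule, split_seed = s,
                                 preproc = preproc, train = train,
                                 eval_fraction = eval_fraction,
                                 select = select, prepared = shared)
    tibble::tibble(kind = spec$kind, condition = condition, seed = s,
                   n_channels_in = length(keep),
                   accuracy = res$accuracy$accuracy,
                   n_segments = res$accuracy$n_segments)
  })
}
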