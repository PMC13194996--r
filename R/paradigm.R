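#' Sentence-reading paradigm configuration
#'
#' Parameters of the three-phase trial paradigm emulated by the synthetic
#' generator: a preparation phase (fixation), a reading phase during which the
#' sentence is spoken aloud, and an inter-trial rest phase. Defaults follow
#' the recording protocol the analysis is built around: 100 sentences read
#' three times each, preparation 1.5--2.0 s, reading completed within 10 s,
#' rest 2--3 s, at a 2,000 Hz sampling rate.
#'
#' @param n_sentences Number of unique sentences.
#' @param n_repetitions Repetitions of each sentence.
#' @param prep_duration_range Preparation-phase duration range (s).
#' @param speech_max_duration Maximum allowed reading-phase duration (s);
#'   syllables that would overrun it are truncated away.
#' @param rest_duration_range Inter-trial rest duration range (s).
#' @param syllables_per_sentence_range Range of syllable counts per sentence
#'   (drawn once per sentence, shared across its repetitions).
#' @param syllable_duration_range Range of single-syllable durations (s).
#' @param pause_probability Probability of an intra-sentence pause between
#'   two consecutive syllables.
#' @param pause_duration_range Intra-sentence pause duration range (s).
#' @param speech_onset_latency_range Delay between the end of the preparation
#'   phase and the first syllable onset (s); this span belongs to the rest
#'   state because it precedes the first syllable.
#' @param sampling_rate Sampling rate of the synthesized recording (Hz).
#'
#' @return An object of class `paradigm_config`.
#' @export
#' @examples
#' cfg <- paradigm_config(n_sentences = 5, n_repetitions = 2)
#' generate_schedule(cfg, seed = 1)
paradigm_config <- function(n_sentences = 100,
                            n_repetitions = 3,
                            prep_duration_range = c(1.5, 2.0),
                            speech_max_duration = 10,
                            rest_duration_range = c(2.0, 3.0),
                            syllables_per_sentence_range = c(8L, 14L),
                            syllable_duration_range = c(0.20, 0.35),
                            pause_probability = 0.3,
                            pause_duration_range = c(0.2, 0.6),
                            speech_onset_latency_range = c(0.1, 0.3),
                            sampling_rate = 2000) {
  cfg <- list(
    n_sentences = as.integer(n_sentences),
    n_repetitions = as.integer(n_repetitions),
    prep_duration_range = prep_duration_range,
    speech_max_duration = speech_max_duration,
    rest_duration_range = rest_duration_range,
    syllables_per_sentence_range = as.integer(syllables_per_sentence_range),
    syllable_duration_range = syllable_duration_range,
    pause_probability = pause_probability,
    pause_duration_range = pause_duration_range,
    speech_onset_latency_range = speech_onset_latency_range,
    sampling_rate = sampling_rate
  )
  validate_paradigm_config(cfg)
  structure(cfg, class = "paradigm_config")
}

validate_paradigm_config <- function(cfg) {
  if (cfg$n_sentences < 1L || cfg$n_repetitions < 1L)
    stop("n_sentences and n_repetitions must be positive", call. = FALSE)
  ranges <- cfg[c("prep_duration_range", "rest_duration_range",
                  "syllable_duration_range", "pause_duration_range",
                  "speech_onset_latency_range")]
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || any(r < 0) || r[1] > r[2])
      stop(nm, " must be a non-negative, non-inverted pair", call. = FALSE)
  }
  r <- cfg$syllables_per_sentence_range
  if (length(r) != 2L || r[1] < 1L || r[1] > r[2])
    stop("syllables_per_sentence_range must be a positive, ordered pair",
         call. = FALSE)
  if (cfg$speech_max_duration <= 0 || cfg$sampling_rate <= 0)
    stop("speech_max_duration and sampling_rate must be positive",
         call. = FALSE)
  if (cfg$pause_probability < 0 || cfg$pause_probability > 1)
    stop("pause_probability must be in [0, 1]", call. = FALSE)
  invisible(cfg)
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Generate a trial schedule for the reading paradigm
#'
#' Lays `n_sentences * n_repetitions` trials end-to-end on a global timeline.
#' Each trial contributes a preparation interval, one interval per syllable
#' (with optional intra-sentence pauses between syllables), and a trailing
#' rest interval. Trial order is a seeded random permutation of all
#' sentence-repetition pairs. Deterministic for a fixed seed.
#'
#' @param config A [paradigm_config()].
#' @param seed Integer seed.
#'
#' @return A tibble of class `trial_schedule` with one row per interval and
#'   columns `trial_id`, `sentence_id`, `repetition`, `phase`
#'   (`"prep"`, `"syllable"` or `"rest"`), `syllable_index` (NA outside
#'   syllables), `onset` and `offset` in seconds on the global timeline.
#' @export
generate_schedule <- function(config = paradigm_config(), seed = 1L) {
  validate_paradigm_config(config)
  with_seed(seed, generate_schedule_impl(config))
}

generate_schedule_impl <- function(config) {
  n_tr <- config$n_sentences * config$n_repetitions
  syll_counts <- sample(
    seq.int(config$syllables_per_sentence_range[1],
            config$syllables_per_sentence_range[2]),
    config$n_sentences, replace = TRUE)

  order_tbl <- tidyr::expand_grid(
    sentence_id = seq_len(config$n_sentences),
    repetition = seq_len(config$n_repetitions))
  order_tbl <- order_tbl[sample.int(n_tr), ]

  rows <- vector("list", n_tr)
  t0 <- 0
  for (i in seq_len(n_tr)) {
    sid <- order_tbl$sentence_id[i]
    rep_i <- order_tbl$repetition[i]
    n_syll <- syll_counts[sid]

    prep_dur <- runif_range(1, config$prep_duration_range)
    latency <- runif_range(1, config$speech_onset_latency_range)
    durs <- runif_range(n_syll, config$syllable_duration_range)
    pauses <- ifelse(
      stats::runif(n_syll - 1) < config$pause_probability,
      runif_range(n_syll - 1, config$pause_duration_range), 0)

    onsets <- numeric(n_syll)
    offsets <- numeric(n_syll)
    cursor <- t0 + prep_dur + latency
    reading_end <- t0 + prep_dur + config$speech_max_duration
    kept <- 0L
    for (s in seq_len(n_syll)) {
      if (cursor + durs[s] > reading_end && kept >= 1L) break
      onsets[s] <- cursor
      offsets[s] <- min(cursor + durs[s], reading_end)
      kept <- s
      cursor <- offsets[s] + if (s < n_syll) pauses[s] else 0
    }
    n_syll <- kept
    onsets <- onsets[seq_len(n_syll)]
    offsets <- offsets[seq_len(n_syll)]

    rest_dur <- runif_range(1, config$rest_duration_range)
    rest_on <- offsets[n_syll]
    rest_off <- rest_on + rest_dur

    rows[[i]] <- tibble::tibble(
      trial_id = i,
      sentence_id = sid,
      repetition = rep_i,
      phase = c("prep", rep("syllable", n_syll), "rest"),
      syllable_index = c(NA_integer_, seq_len(n_syll), NA_integer_),
      onset = c(t0, onsets, rest_on),
      offset = c(t0 + prep_dur, offsets, rest_off)
    )
    t0 <- rest_off
  }

  out <- dplyr::bind_rows(rows)
  class(out) <- c("trial_schedule", class(out))
  out
}

#' Total scheduled duration in seconds
#' @param schedule A `trial_schedule`.
#' @return Scalar seconds (end of the last interval).
#' @export
schedule_duration <- function(schedule) max(schedule$offset)

#' Per-trial speech boundaries
#'
#' First syllable onset and last syllable offset of every trial; the speech
#' state spans exactly this interval (pauses between syllables included),
#' everything else is rest.
#'
#' @param schedule A `trial_schedule`.
#' @return Tibble with `trial_id`, `sentence_id`, `repetition`,
#'   `trial_onset`, `speech_onset`, `speech_offset`, `trial_offset`.
#' @export
trial_boundaries <- function(schedule) {
  schedule |>
    dplyr::group_by(.data$trial_id, .data$sentence_id, .data$repetition) |>
    dplyr::summarise(
      trial_onset = min(.data$onset),
      speech_onset = suppressWarnings(min(.data$onset[.data$phase == "syllable"])),
      speech_offset = suppressWarnings(max(.data$offset[.data$phase == "syllable"])),
      trial_offset = max(.data$offset),
      .groups = "drop")
}

#' Ground-truth binary state vector
#'
#' Samples the rest/speech labeling rule on a regular grid: speech (1) from
#' the first syllable onset through the last syllable offset of each trial,
#' rest (0) elsewhere (preparation, pre-onset latency, and inter-trial rest).
#'
#' @param schedule A `trial_schedule`.
#' @param sampling_rate Grid rate (Hz).
#' @param n_samples Optional total sample count (defaults to covering the
#'   whole schedule).
#' @return Integer vector of 0/1 states, one per sample.
#' @export
state_vector <- function(schedule, sampling_rate, n_samples = NULL) {
  if (is.null(n_samples))
    n_samples <- ceiling(schedule_duration(schedule) * sampling_rate)
  state <- integer(n_samples)
  bd <- trial_boundaries(schedule)
  for (i in seq_len(nrow(bd))) {
    i0 <- floor(bd$speech_onset[i] * sampling_rate) + 1L
    i1 <- min(ceiling(bd$speech_offset[i] * sampling_rate), n_samples)
    if (i0 <= i1) state[i0:i1] <- 1L
  }
  state
}

# Evaluate `code` under a local RNG seed, restoring the caller's RNG state.
# Every randomized operation in the package routes its seed through here, so
# nothing perturbs (or depends on) the global random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage sub-seed derived from a global seed, kept within
# the 32-bit integer range.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
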