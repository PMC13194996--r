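#' Preprocessing configuration
#'
#' Filtering, standardization, decimation and segmentation settings for the
#' speech-state pipeline. Defaults: 200 Hz anti-alias low-pass for broadband
#' mode (or a 75--150 Hz band-pass for high-gamma mode), powerline notches at
#' 50/100/150/200 Hz (Q = 30 biquads), decimation from the raw rate to
#' 500 Hz, and non-overlapping 100 ms windows (50 samples at 500 Hz).
#'
#' @param broadband_cutoff Low-pass cutoff for broadband mode (Hz).
#' @param hga_band High-gamma band edges for hga mode (Hz).
#' @param notch_freqs Notch bank frequencies (Hz).
#' @param notch_q Notch quality factor.
#' @param target_rate Post-decimation sampling rate (Hz).
#' @param window_length Segment length (s).
#' @param signal_mode `"broadband"` or `"hga"`.
#' @param filter_order Butterworth order for low-/band-pass filters.
#' @return A list of class `preproc_config`.
#' @export
preproc_config <- function(broadband_cutoff = 200,
                           hga_band = c(75, 150),
                           notch_freqs = c(50, 100, 150, 200),
                           notch_q = 30,
                           target_rate = 500,
                           window_length = 0.100,
                           signal_mode = c("broadband", "hga"),
                           filter_order = 4) {
  signal_mode <- match.arg(signal_mode)
  structure(list(broadband_cutoff = broadband_cutoff, hga_band = hga_band,
                 notch_freqs = notch_freqs, notch_q = notch_q,
                 target_rate = target_rate, window_length = window_length,
                 signal_mode = signal_mode, filter_order = filter_order),
            class = "preproc_config")
}

# RBJ cookbook notch biquad at f0 with quality factor Q.
design_notch <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

apply_filter <- function(x, filt, causal) {
  if (causal) as.numeric(iir_filter_cpp(filt$b, filt$a, x))
  else as.numeric(filtfilt_cpp(filt$b, filt$a, x))
}

#' Filter a recording (band-limiting plus notch bank)
#'
#' Broadband mode applies the anti-alias low-pass; hga mode applies the
#' high-gamma band-pass. Both are followed by the powerline notch bank.
#' Offline (default) filtering is zero-phase (forward-backward); the causal
#' variant filters forward only, so the continuous-decoding path never reads
#' future samples.
#'
#' @param rec A `seeg_recording`.
#' @param cfg A [preproc_config()].
#' @param causal Use strictly causal (forward-only) filtering.
#' @return The filtered recording (same shape and rate).
#' @export
filter_signal <- function(rec, cfg = preproc_config(), causal = FALSE) {
  fs <- rec$sampling_rate
  nyq <- fs / 2
  band <- if (cfg$signal_mode == "hga") cfg$hga_band else cfg$broadband_cutoff
  if (any(band >= nyq))
    stop("filter band edge at or above Nyquist (", nyq, " Hz)", call. = FALSE)
  if (any(cfg$notch_freqs >= nyq))
    stop("notch frequency at or above Nyquist", call. = FALSE)

  main <- if (cfg$signal_mode == "hga")
    signal::butter(cfg$filter_order, cfg$hga_band / nyq, type = "pass")
  else
    signal::butter(cfg$filter_order, cfg$broadband_cutoff / nyq, type = "low")
  notches <- lapply(cfg$notch_freqs, design_notch, fs = fs, Q = cfg$notch_q)

  out <- rec
  for (c in seq_len(n_channels(rec))) {
    x <- apply_filter(rec$signal[c, ], main, causal)
    for (nf in notches) x <- apply_filter(x, nf, causal)
    out$signal[c, ] <- x
  }
  out
}

#' Z-score standardization per channel
#'
#' Standardizes each channel to zero mean and unit variance. Statistics can
#' be computed from the recording itself (`stats = NULL`) or supplied — e.g.
#' frozen training-split statistics applied to evaluation or streaming data,
#' which prevents information leaking from evaluation data into the scaling.
#' Channels with (numerically) zero variance are flagged and removed rather
#' than silently passed through.
#'
#' @param rec A `seeg_recording`.
#' @param stats Optional tibble with columns `name`, `mean`, `sd` (from a
#'   previous call's `zscore_stats` attribute).
#' @return The standardized recording. Attribute `zscore_stats` holds the
#'   per-channel statistics; attribute `excluded_channels` names any
#'   zero-variance channels that were dropped.
#' @export
zscore_standardize <- function(rec, stats = NULL) {
  if (is.null(stats)) {
    m <- rowMeans(rec$signal)
    s <- apply(rec$signal, 1, stats::sd)
    stats <- tibble::tibble(name = rec$channels$name, mean = m, sd = s)
  } else {
    idx <- match(rec$channels$name, stats$name)
    if (anyNA(idx)) stop("provided stats missing channels", call. = FALSE)
    stats <- stats[idx, ]
  }
  degenerate <- stats$sd <= .Machine$double.eps * 100
  out <- rec
  if (any(degenerate)) {
    warning(sprintf("excluding %d zero-variance channel(s): %s",
                    sum(degenerate),
                    paste(stats$name[degenerate], collapse = ", ")),
            call. = FALSE)
    out$signal <- out$signal[!degenerate, , drop = FALSE]
    out$channels <- out$channels[!degenerate, ]
    stats_kept <- stats[!degenerate, ]
  } else stats_kept <- stats
  out$signal <- (out$signal - stats_kept$mean) / stats_kept$sd
  attr(out, "zscore_stats") <- stats_kept
  attr(out, "excluded_channels") <- stats$name[degenerate]
  out
}

#' Decimate a recording to a lower sampling rate
#'
#' Plain decimation by the integer factor `sampling_rate / target_rate`
#' (every k-th sample kept), intended to follow the anti-alias low-pass of
#' [filter_signal()]. Annotations are in seconds and need no adjustment.
#'
#' @param rec A `seeg_recording`.
#' @param target_rate Target rate (Hz); must divide the current rate.
#' @return The decimated recording.
#' @export
downsample_recording <- function(rec, target_rate = 500) {
  factor <- rec$sampling_rate / target_rate
  if (factor != round(factor))
    stop("target rate must divide the raw sampling rate", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(rec)
  keep <- seq(1L, n_samples(rec), by = factor)
  out <- rec
  out$signal <- rec$signal[, keep, drop = FALSE]
  out$sampling_rate <- target_rate
  if (!is.null(rec$audio)) out$audio <- rec$audio[keep]
  if (!is.null(rec$state)) out$state <- rec$state[keep]
  for (a in c("zscore_stats", "excluded_channels"))
    attr(out, a) <- attr(rec, a)
  out
}

#' Slice a recording into labeled fixed-length segments
#'
#' Per trial, lays non-overlapping windows of `cfg$window_length` across the
#' trial span. A window is labeled rest (0) if it ends strictly before the
#' trial's first syllable onset, speech (1) if it lies entirely within
#' \[first syllable onset, last syllable offset\] (intra-sentence pauses are
#' inside this span, hence speech), and rest again if it starts at or after
#' the last syllable offset. Windows straddling either boundary are dropped.
#' Trials without syllables are skipped with a warning.
#'
#' @param rec A downsampled `seeg_recording`.
#' @param schedule The `trial_schedule` of the recording.
#' @param cfg A [preproc_config()].
#' @return A `segment_set`: list with `x`, a `(C, T, n)` array of segment
#'   data, and `info`, a tibble (`segment_id`, `trial_id`, `sentence_id`,
#'   `repetition`, `label`, `window_start`). Attribute `n_dropped` counts
#'   boundary-straddling windows.
#' @export
label_and_segment <- function(rec, schedule, cfg = preproc_config()) {
  fs <- rec$sampling_rate
  T_len <- round(cfg$window_length * fs)
  C <- n_channels(rec)
  bd <- trial_boundaries(schedule)
  no_syll <- !is.finite(bd$speech_onset)
  if (any(no_syll)) {
    warning(sprintf("skipping %d trial(s) without syllables", sum(no_syll)),
            call. = FALSE)
    bd <- bd[!no_syll, ]
  }

  xs <- list()
  infos <- list()
  n_dropped <- 0L
  for (i in seq_len(nrow(bd))) {
    start0 <- floor(bd$trial_onset[i] * fs)        # 0-based sample
    end0 <- floor(bd$trial_offset[i] * fs)
    on0 <- bd$speech_onset[i] * fs
    off0 <- bd$speech_offset[i] * fs
    n_win <- (min(end0, ncol(rec$signal)) - start0) %/% T_len
    if (n_win < 1) next
    w0 <- start0 + (seq_len(n_win) - 1L) * T_len   # 0-based window starts
    w1 <- w0 + T_len                               # exclusive ends
    label <- dplyr::case_when(
      w1 <= on0 ~ 0L,
      w0 >= on0 & w1 <= off0 ~ 1L,
      w0 >= off0 ~ 0L,
      TRUE ~ NA_integer_
    )
    n_dropped <- n_dropped + sum(is.na(label))
    keep <- which(!is.na(label))
    if (length(keep) == 0) next
    arr <- array(0, dim = c(C, T_len, length(keep)))
    for (j in seq_along(keep))
      arr[, , j] <- rec$signal[, (w0[keep[j]] + 1L):(w0[keep[j]] + T_len),
                               drop = FALSE]
    xs[[length(xs) + 1L]] <- arr
    infos[[length(infos) + 1L]] <- tibble::tibble(
      trial_id = bd$trial_id[i],
      sentence_id = bd$sentence_id[i],
      repetition = bd$repetition[i],
      label = label[keep],
      window_start = w0[keep] / fs)
  }
  if (length(xs) == 0) stop("no segments produced", call. = FALSE)
  info <- dplyr::bind_rows(infos)
  info$segment_id <- seq_len(nrow(info))
  info <- dplyr::relocate(info, "segment_id")
  x <- array(0, dim = c(C, T_len, nrow(info)))
  pos <- 0L
  for (a in xs) {
    nb <- dim(a)[3]
    x[, , pos + seq_len(nb)] <- a
    pos <- pos + nb
  }
  structure(list(x = x, info = info),
            class = "segment_set", n_dropped = n_dropped)
}

#' @export
print.segment_set <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<segment_set> %d segments of (%d channels x %d samples); %d rest / %d speech\n",
              d[3], d[1], d[2], sum(x$info$label == 0), sum(x$info$label == 1)))
  invisible(x)
}

#' Subset a segment set
#' @param segs A `segment_set`.
#' @param idx Integer or logical index over segments.
#' @return The subset `segment_set`.
#' @export
subset_segments <- function(segs, idx) {
  if (is.logical(idx)) idx <- which(idx)
  info <- segs$info[idx, ]
  info$segment_id <- seq_len(nrow(info))
  structure(list(x = segs$x[, , idx, drop = FALSE], info = info),
            class = "segment_set", n_dropped = attr(segs, "n_dropped"))
}

#' Balance rest/speech classes by subsampling the majority class
#'
#' Random (seeded) subsampling of the majority class so both classes have
#' equal counts, making the 50% chance baseline exact.
#'
#' @param segs A `segment_set`.
#' @param seed Integer seed.
#' @return A balanced `segment_set`.
#' @export
balance_segments <- function(segs, seed = 1L) {
  lab <- segs$info$label
  n0 <- sum(lab == 0); n1 <- sum(lab == 1)
  if (n0 == 0 || n1 == 0) stop("both classes required to balance", call. = FALSE)
  n_keep <- min(n0, n1)
  with_seed(seed, {
    keep0 <- which(lab == 0)
    keep1 <- which(lab == 1)
    if (n0 > n_keep) keep0 <- sort(keep0[sample.int(n0, n_keep)])
    if (n1 > n_keep) keep1 <- sort(keep1[sample.int(n1, n_keep)])
    subset_segments(segs, sort(c(keep0, keep1)))
  })
}

#' Select a channel subset of a recording or segment set
#' @param x A `seeg_recording` or `segment_set`.
#' @param idx Integer/logical index or channel names.
#' @return Object of the same class with only the chosen channels.
#' @export
restrict_channels <- function(x, idx) {
  if (inherits(x, "seeg_recording")) {
    if (is.character(idx)) idx <- match(idx, x$channels$name)
    x$signal <- x$signal[idx, , drop = FALSE]
    x$channels <- x$channels[idx, ]
    return(x)
  }
  if (inherits(x, "segment_set")) {
    x$x <- x$x[idx, , , drop = FALSE]
    return(x)
  }
  stop("unsupported object", call. = FALSE)
}
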