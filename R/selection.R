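#' Welch power spectral density
#'
#' One-sided PSD estimate by Welch's method: the signal is cut into
#' Hann-tapered windows with the given overlap, periodograms are averaged,
#' and the density is scaled so that its integral over frequency equals the
#' variance of a zero-mean input (Parseval-consistent).
#'
#' @param x Numeric signal vector.
#' @param sampling_rate Sampling rate (Hz).
#' @param window_length Welch window length (s); default 1 s gives a
#'   1 Hz-resolution grid, ample for a 4--150 Hz band.
#' @param overlap Fractional overlap between windows.
#' @return A tibble with columns `frequency` (Hz) and `psd` (power per Hz).
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 5, by = 1 / 500))
#' psd <- welch_psd(x, 500)
#' psd$frequency[which.max(psd$psd)]
welch_psd <- function(x, sampling_rate, window_length = 1, overlap = 0.5) {
  nwin <- round(window_length * sampling_rate)
  n <- length(x)
  if (nwin > n) stop("Welch window longer than the signal", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)", call. = FALSE)
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, n - nwin + 1L, by = step)
  w <- signal::hanning(nwin)
  scale <- sampling_rate * sum(w^2)
  nfreq <- nwin %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)]
    X <- stats::fft(seg * w)[seq_len(nfreq)]
    acc <- acc + (Mod(X)^2) / scale
  }
  psd <- acc / length(starts)
  # fold two-sided density into one-sided (DC and Nyquist not doubled)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nwin %% 2 == 0) dbl[nfreq] <- 1
  tibble::tibble(frequency = (seq_len(nfreq) - 1) * sampling_rate / nwin,
                 psd = psd * dbl)
}

# Mean PSD over [band[1], band[2]] Hz inclusive.
mean_band_power <- function(x, fs, band, window_length = 1) {
  wl <- min(window_length, length(x) / fs)
  p <- welch_psd(x, fs, window_length = wl)
  sel <- p$frequency >= band[1] & p$frequency <= band[2]
  mean(p$psd[sel])
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up BH procedure. A thin wrapper over [stats::p.adjust()] that also
#' returns rejection flags at the given level.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level.
#' @return A tibble with `p`, `p_adj` and logical `rejected`.
#' @export
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05))
fdr_bh <- function(p_values, alpha = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p_adj <- stats::p.adjust(p_values, method = "BH")
  # step-up rule rejects at equality: p_(i) <= i * alpha / m
  tibble::tibble(p = p_values, p_adj = p_adj, rejected = p_adj <= alpha)
}

#' Speech-responsiveness test per channel
#'
#' For each channel, contrasts mean 4--150 Hz band power after speech onset
#' with the immediately preceding silence, one paired observation per trial,
#' via a two-sided paired t-test. The silence interval is matched in
#' duration to the speech interval, capped at the available pre-onset span.
#' P-values are BH-adjusted across channels.
#'
#' @param rec A `seeg_recording` at its raw rate (unfiltered or broadband).
#' @param schedule The `trial_schedule` of the recording.
#' @param band Frequency band for the power contrast (Hz).
#' @param alpha FDR level for the selected flag.
#' @return A `channel_selection` tibble: `name`, `region`, `domain`,
#'   `tissue`, `mean_speech_power`, `mean_silence_power`, `t`, `p`, `p_adj`,
#'   `selected`, `reason`.
#' @export
speech_responsiveness_test <- function(rec, schedule, band = c(4, 150),
                                       alpha = 0.05) {
  fs <- rec$sampling_rate
  bd <- trial_boundaries(schedule)
  bd <- bd[is.finite(bd$speech_onset), ]
  if (nrow(bd) < 2) stop("need at least 2 trials for the paired test",
                         call. = FALSE)
  C <- n_channels(rec)
  n_tr <- nrow(bd)
  speech_pw <- matrix(NA_real_, n_tr, C)
  silence_pw <- matrix(NA_real_, n_tr, C)
  n_total <- n_samples(rec)
  for (i in seq_len(n_tr)) {
    sp0 <- floor(bd$speech_onset[i] * fs) + 1L
    sp1 <- min(ceiling(bd$speech_offset[i] * fs), n_total)
    dur <- sp1 - sp0 + 1L
    sil1 <- sp0 - 1L
    sil0 <- max(floor(bd$trial_onset[i] * fs) + 1L, sil1 - dur + 1L)
    if (sil1 - sil0 + 1L < fs / 2 || dur < fs / 2) next
    for (c in seq_len(C)) {
      speech_pw[i, c] <- mean_band_power(rec$signal[c, sp0:sp1], fs, band)
      silence_pw[i, c] <- mean_band_power(rec$signal[c, sil0:sil1], fs, band)
    }
  }
  ok <- stats::complete.cases(speech_pw) & stats::complete.cases(silence_pw)
  speech_pw <- speech_pw[ok, , drop = FALSE]
  silence_pw <- silence_pw[ok, , drop = FALSE]
  if (nrow(speech_pw) < 2) stop("fewer than 2 usable trials", call. = FALSE)

  tt <- purrr::map(seq_len(C), function(c) {
    d <- speech_pw[, c] - silence_pw[, c]
    if (stats::sd(d) == 0)  # degenerate: all paired differences equal
      return(list(t = NA_real_, p = 1))
    ht <- stats::t.test(d)
    list(t = unname(ht$statistic), p = ht$p.value)
  })
  res <- tibble::tibble(
    name = rec$channels$name,
    region = rec$channels$region,
    domain = rec$channels$domain,
    tissue = rec$channels$tissue,
    mean_speech_power = colMeans(speech_pw),
    mean_silence_power = colMeans(silence_pw),
    t = purrr::map_dbl(tt, "t"),
    p = purrr::map_dbl(tt, "p"))
  bh <- fdr_bh(res$p, alpha)
  res$p_adj <- bh$p_adj
  res$selected <- bh$rejected
  res$reason <- ifelse(res$selected, "none", "not_significant")
  class(res) <- c("channel_selection", class(res))
  res
}

#' Apply anatomical exclusion rules to a channel-selection result
#'
#' White-matter contacts and channels in visual areas (occipital lobe) are
#' excluded regardless of statistical significance; their significance
#' fields are left untouched but `selected` is forced to `FALSE` with the
#' reason recorded.
#'
#' @param result A `channel_selection` tibble.
#' @param specs The channel spec tibble aligned with `result` (defaults to
#'   the metadata already carried by `result`).
#' @return The updated `channel_selection` tibble.
#' @export
apply_exclusions <- function(result, specs = NULL) {
  if (!is.null(specs)) {
    if (nrow(specs) != nrow(result) || !all(specs$name == result$name))
      stop("channel specs do not match the selection result", call. = FALSE)
    result$region <- specs$region
    result$tissue <- specs$tissue
  }
  wm <- result$tissue == "white" | result$region == "WhiteMatter"
  vis <- result$region == "Occipital"
  result$reason[wm] <- "white_matter"
  result$reason[vis & !wm] <- "visual_region"
  result$selected <- result$selected & !wm & !vis
  result
}

#' Full channel-selection pipeline
#'
#' [speech_responsiveness_test()] followed by [apply_exclusions()].
#'
#' @inheritParams speech_responsiveness_test
#' @return A `channel_selection` tibble.
#' @export
select_channels <- function(rec, schedule, band = c(4, 150), alpha = 0.05) {
  apply_exclusions(speech_responsiveness_test(rec, schedule, band, alpha))
}

#' Audio-neural independence check
#'
#' Pearson correlation between the audio envelope and every neural channel
#' over randomly placed epochs, reported as the maximum absolute correlation
#' per channel; channels above the threshold are flagged as possible audio
#' contamination.
#'
#' @param rec A `seeg_recording`.
#' @param audio Audio envelope on the same timeline (defaults to
#'   `rec$audio`).
#' @param epoch_length Epoch length (s); the protocol's default is 10 min,
#'   shorter epochs are used on shorter recordings.
#' @param n_epochs Number of random epochs.
#' @param seed Integer seed for epoch placement.
#' @param threshold Absolute-correlation flag threshold.
#' @return A tibble with `name`, `max_abs_r`, `pass`.
#' @export
audio_neural_independence_check <- function(rec, audio = rec$audio,
                                            epoch_length = 600,
                                            n_epochs = 10, seed = 1L,
                                            threshold = 0.1) {
  n <- n_samples(rec)
  fs <- rec$sampling_rate
  ne <- round(epoch_length * fs)
  if (ne > n) stop("epoch longer than the recording", call. = FALSE)
  if (length(audio) != n) stop("audio and neural timelines differ", call. = FALSE)
  with_seed(seed, {
    starts <- sample.int(n - ne + 1L, n_epochs, replace = n_epochs > n - ne + 1L)
    r <- matrix(0, n_epochs, n_channels(rec))
    for (e in seq_len(n_epochs)) {
      idx <- starts[e]:(starts[e] + ne - 1L)
      a <- audio[idx]
      if (stats::sd(a) == 0) next
      for (c in seq_len(n_channels(rec)))
        r[e, c] <- stats::cor(a, rec$signal[c, idx])
    }
    tibble::tibble(name = rec$channels$name,
                   max_abs_r = apply(abs(r), 2, max),
                   pass = apply(abs(r), 2, max) < threshold)
  })
}
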