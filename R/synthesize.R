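#' Noise and effect parameters for the synthetic recording
#'
#' The generator's signal model, per channel:
#' `x(t) = background + powerline + gate(t) * snr * (w_lf * lf(t) + w_hga * hga(t))`
#' where the background is `1/f^alpha` Gaussian noise of unit standard
#' deviation (spectrally shaped in the frequency domain), the powerline term
#' is a bank of mains harmonics with random phase, `lf` and `hga` are
#' unit-sd band-limited Gaussian noises in the low-frequency and high-gamma
#' bands, and `gate` rises from 0 to 1 at speech onset (and back at offset)
#' over a raised-cosine ramp so that state transitions are not step
#' discontinuities. Only channels flagged informative receive the gated term.
#'
#' @param alpha Spectral slope of the `1/f^alpha` background (power ~
#'   `f^-alpha`).
#' @param line_freqs Powerline harmonic frequencies (Hz).
#' @param line_amplitude Amplitude of each harmonic (relative to the unit-sd
#'   background).
#' @param lf_band Low-frequency modulation band (Hz).
#' @param hga_band High-gamma band (Hz).
#' @param lf_weight,hga_weight Relative weights of the two gated components.
#' @param ramp_duration Raised-cosine on/off ramp of the state gate (s).
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(alpha = 1.0,
                         line_freqs = c(50, 100, 150, 200),
                         line_amplitude = 0.15,
                         lf_band = c(2, 30),
                         hga_band = c(75, 150),
                         lf_weight = 0.6,
                         hga_weight = 0.8,
                         ramp_duration = 0.05) {
  structure(list(alpha = alpha, line_freqs = line_freqs,
                 line_amplitude = line_amplitude, lf_band = lf_band,
                 hga_band = hga_band, lf_weight = lf_weight,
                 hga_weight = hga_weight, ramp_duration = ramp_duration),
            class = "noise_params")
}

# Unit-sd 1/f^alpha Gaussian noise via frequency-domain shaping. The FFT is
# taken at the next highly composite length (mixed-radix FFTs degrade badly
# on lengths with large prime factors) and truncated.
pink_noise <- function(n, alpha, fs) {
  w <- stats::rnorm(n)
  if (alpha == 0) return(w)
  m <- stats::nextn(n, c(2, 3, 5))
  W <- stats::fft(c(w, numeric(m - n)))
  k <- 0:(m - 1)
  freq <- pmin(k, m - k) * fs / m
  shape <- ifelse(freq == 0, 0, freq^(-alpha / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x)
}

# Unit-sd band-limited Gaussian noise (4th-order Butterworth band-pass).
band_noise <- function(n, band, fs) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- as.numeric(filtfilt_cpp(bf$b, bf$a, stats::rnorm(n)))
  x / stats::sd(x)
}

# Smooth 0/1 state gate: raised-cosine smoothing of the binary state vector.
state_gate <- function(state, fs, ramp_duration) {
  w <- max(1L, round(ramp_duration * fs))
  if (w <= 1L) return(as.numeric(state))
  kern <- signal::hanning(w)
  kern <- kern / sum(kern)
  as.numeric(stats::filter(c(rep(state[1], w), state, rep(state[length(state)], w)),
                           kern, sides = 2))[(w + 1):(w + length(state))]
}

#' Synthesize a multichannel recording for a trial schedule
#'
#' Builds the signal model described in [noise_params()] channel by channel,
#' together with a synthetic audio envelope (raised-cosine bump per syllable)
#' and the ground-truth per-sample state vector. Fully reproducible for a
#' fixed seed.
#'
#' @param schedule A [generate_schedule()] result.
#' @param specs A [generate_channel_specs()] tibble.
#' @param noise A [noise_params()] list.
#' @param seed Integer seed.
#' @param sampling_rate Sampling rate (Hz).
#'
#' @return An object of class `seeg_recording`: a list with `signal`
#'   (channels x samples matrix), `sampling_rate`, `channels` (the spec
#'   tibble), `audio` (envelope vector), `state` (ground-truth 0/1 vector)
#'   and `seed`.
#' @export
#' @examples
#' sched <- generate_schedule(paradigm_config(n_sentences = 2,
#'                                            n_repetitions = 1), seed = 1)
#' specs <- generate_channel_specs(4, 0.5, seed = 1, snr = 2)
#' rec <- synthesize_recording(sched, specs, seed = 1)
#' rec
synthesize_recording <- function(schedule, specs, noise = noise_params(),
                                 seed = 1L, sampling_rate = 2000) {
  if (nrow(schedule) == 0 || nrow(specs) == 0)
    stop("schedule and channel specs must be non-empty", call. = FALSE)
  fs <- sampling_rate
  n <- ceiling(schedule_duration(schedule) * fs)
  C <- nrow(specs)
  state <- state_vector(schedule, fs, n)

  with_seed(seed, {
    gate <- state_gate(state, fs, noise$ramp_duration)
    tvec <- (seq_len(n) - 1) / fs
    signal_mat <- matrix(0, nrow = C, ncol = n)
    for (c in seq_len(C)) {
      x <- pink_noise(n, noise$alpha, fs)
      for (f0 in noise$line_freqs)
        x <- x + noise$line_amplitude *
          sin(2 * pi * f0 * tvec + stats::runif(1, 0, 2 * pi))
      if (specs$informative[c] && specs$snr[c] > 0) {
        lf <- band_noise(n, noise$lf_band, fs)
        hga <- band_noise(n, noise$hga_band, fs)
        x <- x + gate * specs$snr[c] *
          (noise$lf_weight * lf + noise$hga_weight * hga)
      }
      signal_mat[c, ] <- x
    }

    audio <- numeric(n)
    syll <- schedule[schedule$phase == "syllable", ]
    for (i in seq_len(nrow(syll))) {
      i0 <- floor(syll$onset[i] * fs) + 1L
      i1 <- min(ceiling(syll$offset[i] * fs), n)
      if (i1 > i0) audio[i0:i1] <- audio[i0:i1] +
          signal::hanning(i1 - i0 + 1L)
    }

    new_recording(signal_mat, fs, specs, audio = audio, state = state,
                  seed = as.integer(seed))
  })
}

#' Construct a recording object
#'
#' Low-level constructor wrapping a channels x samples signal matrix with
#' its sampling rate and channel metadata (and optional audio envelope and
#' ground-truth state), e.g. for data imported from other containers.
#'
#' @param signal Numeric matrix, channels x samples.
#' @param sampling_rate Sampling rate (Hz).
#' @param channels Channel metadata tibble (at least a `name` column; the
#'   generator's [generate_channel_specs()] format is the convention).
#' @param audio Optional audio envelope (length = samples).
#' @param state Optional ground-truth 0/1 state vector (length = samples).
#' @param seed Seed recorded as provenance, if any.
#' @return A `seeg_recording`.
#' @export
new_recording <- function(signal, sampling_rate, channels, audio = NULL,
                          state = NULL, seed = NA_integer_) {
  stopifnot(nrow(signal) == nrow(channels))
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 channels = channels, audio = audio, state = state,
                 seed = seed),
            class = "seeg_recording")
}

#' @export
print.seeg_recording <- function(x, ...) {
  cat(sprintf("<seeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              ncol(x$signal) / x$sampling_rate))
  cat(sprintf("  informative channels: %d | regions: %s\n",
              sum(x$channels$informative),
              paste(utils::head(sort(unique(x$channels$region)), 8),
                    collapse = ", ")))
  invisible(x)
}

#' Number of channels / samples of a recording
#' @param rec A `seeg_recording`.
#' @return Integer count.
#' @export
n_channels <- function(rec) nrow(rec$signal)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$signal)
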