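# Independent oracles used across tests. These deliberately avoid the
# package's own implementation paths.

# Literal Benjamini-Hochberg step-up rule: reject H_(1..k) where k is the
# largest i with p_(i) <= i * alpha / m; adjusted p by the textbook
# backward-minimum recursion.
bh_stepup_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  crit <- seq_len(m) * alpha / m
  k <- suppressWarnings(max(which(ps <= crit)))
  reject_sorted <- rep(FALSE, m)
  if (is.finite(k)) reject_sorted[seq_len(k)] <- TRUE
  adj_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  reject <- adj <- numeric(m)
  reject[o] <- reject_sorted
  adj[o] <- adj_sorted
  list(rejected = as.logical(reject), p_adj = adj)
}

# Band-power envelope oracle: band-pass by direct FFT masking, then the
# analytic-signal (Hilbert) magnitude.
hilbert_band_envelope <- function(x, fs, band) {
  n0 <- length(x)
  n <- stats::nextn(n0, c(2, 3, 5))   # keep the FFT on a composite length
  x <- c(x, numeric(n - n0))
  X <- stats::fft(x)
  freq <- pmin(0:(n - 1), n - (0:(n - 1))) * fs / n
  X[freq < band[1] | freq > band[2]] <- 0
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else h[2:((n + 1) / 2)] <- 2
  Mod(stats::fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
}

# Plain rectangular-window periodogram (two-sided power, not density).
periodogram_power <- function(x) {
  n <- length(x)
  Mod(stats::fft(x))^2 / n^2
}

# Log-log PSD slope of a signal via Welch estimate over a frequency band.
fit_psd_slope <- function(x, fs, fmin = 2, fmax = 150) {
  p <- welch_psd(x, fs, window_length = 2)
  sel <- p$frequency >= fmin & p$frequency <= fmax
  stats::coef(stats::lm(log10(p$psd[sel]) ~ log10(p$frequency[sel])))[2]
}

# Force a model to predict a constant class regardless of input.
constant_predictor <- function(model, class = 1L) {
  model$params$w4 <- rep(0, length(model$params$w4))
  model$params$b4 <- if (class == 1L) 25 else -25
  model$trained <- TRUE
  model
}

# Butterworth magnitude response at frequency f (Hz) for a signal::butter
# filter designed at rate fs, evaluated from its transfer coefficients.
butter_gain <- function(filt, f, fs) {
  w <- 2 * pi * f / fs
  z <- exp(1i * w)
  num <- sum(filt$b * z^(-(seq_along(filt$b) - 1)))
  den <- sum(filt$a * z^(-(seq_along(filt$a) - 1)))
  Mod(num / den)
}
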