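make_tone_recording <- function(freqs, fs = 2000, dur = 4, amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  sig <- do.call(rbind, lapply(freqs, function(f) amp * sin(2 * pi * f * t)))
  specs <- generate_channel_specs(length(freqs), 0, seed = 1)
  new_recording(sig, fs, specs)
}

rms <- function(x) sqrt(mean(x^2))

test_that("broadband low-pass rejects out-of-band tones and keeps in-band ones", {
  rec <- make_tone_recording(c(300, 10))
  out <- filter_signal(rec, preproc_config())
  edge <- 400:(n_samples(rec) - 400)  # ignore filter edge transients
  expect_lt(rms(out$signal[1, edge]), 0.05 * rms(rec$signal[1, edge]))
  expect_gt(rms(out$signal[2, edge]), 0.95 * rms(rec$signal[2, edge]))
})

test_that("the notch bank removes powerline tones", {
  for (f0 in c(50, 100, 150, 200)) {
    rec <- make_tone_recording(f0)
    out <- filter_signal(rec, preproc_config())
    edge <- 400:(n_samples(rec) - 400)
    expect_lt(rms(out$signal[1, edge]), 0.05 * rms(rec$signal[1, edge]))
  }
})

test_that("high-gamma mode passes 100 Hz nearly unattenuated", {
  rec <- make_tone_recording(100)
  cfg <- preproc_config(signal_mode = "hga", notch_freqs = c(50, 150, 200))
  out <- filter_signal(rec, cfg)
  edge <- 400:(n_samples(rec) - 400)
  measured <- rms(out$signal[1, edge]) / rms(rec$signal[1, edge])
  expect_gt(measured, 0.90)
  # cross-check against the designed band-pass frequency response
  bf <- signal::butter(4, c(75, 150) / 1000, type = "pass")
  gain <- butter_gain(bf, 100, 2000)^2  # forward-backward doubles the order
  expect_lt(abs(measured - gain), 0.05)
})

test_that("filtering is linear", {
  d <- tiny_dataset()
  rec <- restrict_channels(d$rec, 1:2)
  rec$signal <- rec$signal[, 1:20000, drop = FALSE]
  a <- filter_signal(rec, preproc_config())
  scaled <- rec
  scaled$signal <- 3.7 * rec$signal
  b <- filter_signal(scaled, preproc_config())
  expect_lt(max(abs(b$signal - 3.7 * a$signal)) / max(abs(a$signal)), 1e-9)
})

test_that("band edges above Nyquist are rejected", {
  rec <- make_tone_recording(10, fs = 300)
  expect_error(filter_signal(rec, preproc_config()), "Nyquist")
})

test_that("z-scoring standardizes and flags degenerate channels", {
  with_seed(1, {
    sig <- rbind(stats::rnorm(100000, mean = 5, sd = 3), rep(2, 100000))
    specs <- generate_channel_specs(2, 0, seed = 1)
    rec <- new_recording(sig, 2000, specs)
    expect_warning(out <- zscore_standardize(rec), "zero-variance")
    expect_equal(attr(out, "excluded_channels"), specs$name[2])
    expect_equal(n_channels(out), 1L)
    expect_lt(abs(mean(out$signal[1, ])), 0.01)
    expect_true(stats::sd(out$signal[1, ]) > 0.99 &&
                  stats::sd(out$signal[1, ]) < 1.01)
  })
})

test_that("provided unit stats leave standard data untouched", {
  with_seed(2, {
    sig <- matrix(stats::rnorm(2000), nrow = 1)
    specs <- generate_channel_specs(1, 0, seed = 1)
    rec <- new_recording(sig, 2000, specs)
    st <- tibble::tibble(name = specs$name, mean = 0, sd = 1)
    out <- zscore_standardize(rec, stats = st)
    expect_identical(out$signal, sig)
  })
})

test_that("decimation quarters the sample count from 2 kHz to 500 Hz", {
  d <- tiny_dataset()
  ds <- downsample_recording(d$rec, 500)
  expect_equal(n_samples(ds), ceiling(n_samples(d$rec) / 4))
  expect_equal(ds$sampling_rate, 500)
  expect_identical(downsample_recording(d$rec, 2000)$signal, d$rec$signal)
  expect_error(downsample_recording(d$rec, 600), "divide")
})

test_that("a 10 Hz tone survives decimation with its amplitude intact", {
  rec <- make_tone_recording(10, dur = 8)
  out <- downsample_recording(filter_signal(rec, preproc_config()), 500)
  edge <- 200:(n_samples(out) - 200)
  # oracle: direct subsampling of the analytic tone
  t_ds <- (seq(1, 16000, by = 4) - 1) / 2000
  oracle <- sin(2 * pi * 10 * t_ds)
  expect_gt(rms(out$signal[1, edge]), 0.99 * rms(oracle[edge]))
})

test_that("segmentation yields 50-sample windows with the labeling rule", {
  segs <- tiny_segments()
  expect_equal(dim(segs$x)[2], 50L)
  expect_true(all(segs$info$label %in% c(0L, 1L)))
  d <- tiny_dataset()
  bd <- trial_boundaries(d$schedule)
  # windows entirely inside the speech span are labeled speech
  for (i in sample(nrow(segs$info), 50)) {
    row <- segs$info[i, ]
    b <- bd[bd$trial_id == row$trial_id, ]
    w0 <- row$window_start
    w1 <- w0 + 0.1
    if (row$label == 1L) {
      expect_gte(w1, b$speech_onset - 0.1)
      expect_lte(w0, b$speech_offset + 0.1)
    }
  }
})

test_that("a trial with 2 s before speech onset yields 20 rest windows", {
  # hand-built single-trial schedule: prep 1.6 s + 0.4 s latency, one
  # 1 s syllable, 2 s rest
  sched <- tibble::tibble(
    trial_id = 1L, sentence_id = 1L, repetition = 1L,
    phase = c("prep", "syllable", "rest"),
    syllable_index = c(NA, 1L, NA),
    onset = c(0, 2.0, 3.0),
    offset = c(1.6, 3.0, 5.0))
  class(sched) <- c("trial_schedule", class(sched))
  sig <- matrix(stats::rnorm(2 * 5.0 * 500), nrow = 2)
  rec <- new_recording(sig, 500, generate_channel_specs(2, 0, seed = 1))
  segs <- label_and_segment(rec, sched, preproc_config())
  expect_equal(sum(segs$info$label == 0L & segs$info$window_start < 2), 20L)
  expect_equal(sum(segs$info$label == 1L), 10L)
})

test_that("windows spanning an intra-sentence pause are labeled speech", {
  sched <- tibble::tibble(
    trial_id = 1L, sentence_id = 1L, repetition = 1L,
    phase = c("prep", "syllable", "syllable", "rest"),
    syllable_index = c(NA, 1L, 2L, NA),
    onset = c(0, 1.0, 1.9, 2.4),    # 0.4 s pause from 1.5 to 1.9
    offset = c(0.9, 1.5, 2.4, 4.4))
  class(sched) <- c("trial_schedule", class(sched))
  sig <- matrix(stats::rnorm(4.4 * 500), nrow = 1)
  rec <- new_recording(sig, 500, generate_channel_specs(1, 0, seed = 1))
  segs <- label_and_segment(rec, sched, preproc_config())
  pause_windows <- segs$info[segs$info$window_start >= 1.5 &
                               segs$info$window_start + 0.1 <= 1.9, ]
  expect_gt(nrow(pause_windows), 0)
  expect_true(all(pause_windows$label == 1L))
})

test_that("segment counts are conserved across labels and drops", {
  d <- tiny_dataset()
  segs <- tiny_segments()
  bd <- trial_boundaries(d$schedule)
  fs <- 500
  whole_windows <- sum(vapply(seq_len(nrow(bd)), function(i) {
    (floor(bd$trial_offset[i] * fs) - floor(bd$trial_onset[i] * fs)) %/% 50
  }, numeric(1)))
  expect_equal(nrow(segs$info) + attr(segs, "n_dropped"), whole_windows)
})

test_that("a trial without syllables is skipped with a warning", {
  sched <- tibble::tibble(
    trial_id = c(1L, 1L, 1L, 2L, 2L),
    sentence_id = c(1L, 1L, 1L, 2L, 2L),
    repetition = 1L,
    phase = c("prep", "syllable", "rest", "prep", "rest"),
    syllable_index = c(NA, 1L, NA, NA, NA),
    onset = c(0, 2, 3, 5, 7),
    offset = c(1.6, 3, 5, 6.6, 9))
  class(sched) <- c("trial_schedule", class(sched))
  sig <- matrix(stats::rnorm(9 * 500), nrow = 1)
  rec <- new_recording(sig, 500, generate_channel_specs(1, 0, seed = 1))
  expect_warning(segs <- label_and_segment(rec, sched, preproc_config()),
                 "without syllables")
  expect_true(all(segs$info$trial_id == 1L))
})

test_that("balancing equalizes classes by subsampling the majority", {
  segs <- tiny_segments()
  bal <- balance_segments(segs, seed = 3)
  expect_equal(sum(bal$info$label == 0), sum(bal$info$label == 1))
  expect_equal(dim(bal$x)[3], nrow(bal$info))
  # deterministic per seed
  bal2 <- balance_segments(segs, seed = 3)
  expect_identical(bal$info$window_start, bal2$info$window_start)
})
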