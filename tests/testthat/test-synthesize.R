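test_that("sample count covers the whole schedule at the sampling rate", {
  d <- tiny_dataset()
  expect_equal(n_samples(d$rec),
               ceiling(schedule_duration(d$schedule) * 2000))
  expect_equal(n_channels(d$rec), nrow(d$specs))
  expect_equal(length(d$rec$audio), n_samples(d$rec))
  expect_equal(length(d$rec$state), n_samples(d$rec))
})

test_that("synthesis is reproducible per seed and differs across seeds", {
  sched <- generate_schedule(paradigm_config(n_sentences = 2, n_repetitions = 1),
                             seed = 1)
  specs <- generate_channel_specs(3, 0.34, seed = 1, snr = 1)
  a <- synthesize_recording(sched, specs, seed = 5)
  b <- synthesize_recording(sched, specs, seed = 5)
  c <- synthesize_recording(sched, specs, seed = 6)
  expect_identical(a$signal, b$signal)
  expect_false(isTRUE(all.equal(a$signal, c$signal)))
})

test_that("an informative channel's high-gamma envelope rises during speech", {
  # oracle: direct FFT band-pass + analytic-signal magnitude
  sched <- generate_schedule(paradigm_config(n_sentences = 4, n_repetitions = 2),
                             seed = 31)
  specs <- generate_channel_specs(2, 0.5, seed = 32, snr = 3)
  rec <- synthesize_recording(sched, specs, seed = 33)
  inf <- which(rec$channels$informative)[1]
  noninf <- which(!rec$channels$informative)[1]
  st <- rec$state == 1L
  env_inf <- hilbert_band_envelope(rec$signal[inf, ], 2000, c(75, 150))
  expect_gt(mean(env_inf[st]), mean(env_inf[!st]))
  env_non <- hilbert_band_envelope(rec$signal[noninf, ], 2000, c(75, 150))
  ratio_inf <- mean(env_inf[st]) / mean(env_inf[!st])
  ratio_non <- mean(env_non[st]) / mean(env_non[!st])
  expect_gt(ratio_inf, ratio_non + 0.2)
})

test_that("zero-snr channels show no state-dependent band power", {
  sched <- generate_schedule(paradigm_config(n_sentences = 3, n_repetitions = 2),
                             seed = 41)
  flagged <- 0L
  n_runs <- 10L
  for (s in seq_len(n_runs)) {
    specs <- generate_channel_specs(2, 0, seed = s)
    rec <- synthesize_recording(sched, specs, seed = 100 + s)
    st <- rec$state == 1L
    env <- hilbert_band_envelope(rec$signal[1, ], 2000, c(75, 150))
    # compare per-trial means so samples are roughly independent units
    bd <- trial_boundaries(sched)
    sp <- sil <- numeric(nrow(bd))
    for (i in seq_len(nrow(bd))) {
      s0 <- floor(bd$speech_onset[i] * 2000) + 1
      s1 <- floor(bd$speech_offset[i] * 2000)
      r0 <- floor(bd$trial_onset[i] * 2000) + 1
      sp[i] <- mean(env[s0:s1]^2)
      sil[i] <- mean(env[r0:(s0 - 1)]^2)
    }
    if (stats::t.test(sp, sil, paired = TRUE)$p.value < 0.05)
      flagged <- flagged + 1L
  }
  expect_lte(flagged, 2L)  # ~ alpha-level false positives only
})

test_that("background spectral slope tracks the configured 1/f exponent", {
  n <- 2000 * 60
  for (alpha in c(0.5, 1, 1.5)) {
    x <- with_seed(9, speechstate:::pink_noise(n, alpha, 2000))
    slope <- fit_psd_slope(x, 2000, fmin = 2, fmax = 150)
    expect_lt(abs(-alpha - slope), 0.5)
  }
})

test_that("state-detectability grows with snr (Cohen's d monotone)", {
  sched <- generate_schedule(paradigm_config(n_sentences = 3, n_repetitions = 2),
                             seed = 51)
  bd <- trial_boundaries(sched)
  mean_d <- vapply(c(0, 0.5, 1, 2), function(snr) {
    ds <- vapply(1:5, function(s) {
      specs <- generate_channel_specs(1, 1, seed = s, snr = snr,
                                      region_pool = c("Tha", "STG"))
      if (snr == 0) specs$informative <- FALSE
      rec <- synthesize_recording(sched, specs, seed = 200 + s)
      env <- hilbert_band_envelope(rec$signal[1, ], 2000, c(75, 150))
      sp <- sil <- numeric(nrow(bd))
      for (i in seq_len(nrow(bd))) {
        s0 <- floor(bd$speech_onset[i] * 2000) + 1
        s1 <- floor(bd$speech_offset[i] * 2000)
        r0 <- floor(bd$trial_onset[i] * 2000) + 1
        sp[i] <- mean(env[s0:s1]^2)
        sil[i] <- mean(env[r0:(s0 - 1)]^2)
      }
      d <- sp - sil
      mean(d) / stats::sd(d)
    }, numeric(1))
    mean(ds)
  }, numeric(1))
  expect_true(all(diff(mean_d) > -0.05))  # non-decreasing up to noise
  expect_gt(mean_d[4], mean_d[1] + 1)
})

test_that("audio envelope is aligned with syllable intervals", {
  d <- tiny_dataset()
  syl <- d$schedule[d$schedule$phase == "syllable", ]
  mid <- round((syl$onset[1] + syl$offset[1]) / 2 * 2000)
  expect_gt(d$rec$audio[mid], 0.5)
  bd <- trial_boundaries(d$schedule)
  pre <- floor(bd$trial_onset[1] * 2000) + 10L  # inside prep phase
  expect_equal(d$rec$audio[pre], 0)
})

test_that("empty schedule or specs are rejected", {
  d <- tiny_dataset()
  expect_error(synthesize_recording(d$schedule[0, ], d$specs), "non-empty")
  expect_error(synthesize_recording(d$schedule, d$specs[0, ]), "non-empty")
})
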