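test_that("Welch PSD is Parseval-consistent for white noise", {
  x <- with_seed(1, stats::rnorm(500 * 30))
  p <- welch_psd(x, 500)
  total <- sum(p$psd) * (p$frequency[2] - p$frequency[1])
  expect_lt(abs(total - stats::var(x)) / stats::var(x), 0.05)
  # flat: no band holds disproportionate density
  lo <- mean(p$psd[p$frequency > 10 & p$frequency < 100])
  hi <- mean(p$psd[p$frequency > 150 & p$frequency < 240])
  expect_lt(abs(lo / hi - 1), 0.2)
})

test_that("Welch PSD localizes tones and preserves their power ratio", {
  t <- seq(0, 20, by = 1 / 500)
  x <- sin(2 * pi * 10 * t)
  p <- welch_psd(x, 500)
  expect_equal(p$frequency[which.max(p$psd)], 10)
  x2 <- sin(2 * pi * 10 * t) + sin(2 * pi * 100 * t)
  p2 <- welch_psd(x2, 500)
  pk <- function(f) sum(p2$psd[abs(p2$frequency - f) <= 1])
  expect_lt(abs(pk(10) / pk(100) - 1), 0.1)
  # oracle: rectangular periodogram peak ratio on the same signal
  pg <- periodogram_power(x2)
  freqs <- (seq_along(pg) - 1) * 500 / length(pg)
  pgk <- function(f) sum(pg[abs(freqs - f) <= 1])
  expect_lt(abs(pgk(10) / pgk(100) - 1), 0.1)
})

test_that("welch_psd rejects windows longer than the signal", {
  expect_error(welch_psd(stats::rnorm(100), 500, window_length = 1), "longer")
})

test_that("BH-FDR agrees with the literal step-up rule on random vectors", {
  with_seed(42, {
    for (rep in 1:200) {
      m <- sample(1:5, 1)
      p <- round(stats::runif(m), 3)
      mine <- fdr_bh(p, alpha = 0.05)
      oracle <- bh_stepup_oracle(p, alpha = 0.05)
      expect_equal(mine$rejected, oracle$rejected)
      expect_equal(mine$p_adj, oracle$p_adj, tolerance = 1e-12)
    }
  })
})

test_that("BH-FDR matches hand-worked examples", {
  # p_(i) <= i * 0.05 / 5 holds at i = 5 (0.05 <= 0.05): all rejected
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05), alpha = 0.05)
  expect_true(all(r$rejected))
  expect_false(any(fdr_bh(rep(1, 6))$rejected))
  expect_true(fdr_bh(0.04)$rejected)        # m = 1 reduces to the raw level
  expect_error(fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("adjusted p-values are monotone in raw p-values", {
  p <- with_seed(7, stats::runif(50))
  r <- fdr_bh(p)
  o <- order(p)
  expect_true(all(diff(r$p_adj[o]) >= -1e-12))
})

test_that("responsiveness test finds informative channels and spares null ones", {
  d <- tiny_dataset()
  res <- speech_responsiveness_test(d$rec, d$schedule)
  inf <- d$specs$informative
  expect_true(all(res$p_adj[inf] < 0.05))
  expect_gt(min(res$t[inf]), 0)  # speech power above silence power
  expect_true(all(res$mean_speech_power[inf] > res$mean_silence_power[inf]))
})

test_that("under the global null the selection rate stays near alpha", {
  sched <- generate_schedule(paradigm_config(n_sentences = 6, n_repetitions = 2),
                             seed = 61)
  selected <- total <- 0
  for (s in 1:6) {
    specs <- generate_channel_specs(12, 0, seed = s)
    rec <- synthesize_recording(sched, specs, seed = 300 + s)
    res <- speech_responsiveness_test(rec, sched)
    selected <- selected + sum(res$selected)
    total <- total + nrow(res)
  }
  # BH at 5% across 72 null channels: a handful of false selections at most
  expect_lte(selected / total, 0.10)
})

test_that("degenerate all-zero paired differences give p = 1", {
  sched <- tibble::tibble(
    trial_id = 1:3, sentence_id = 1:3, repetition = 1L,
    phase = "syllable", syllable_index = 1L,
    onset = c(2, 8, 14), offset = c(4, 10, 16))
  prep <- tibble::tibble(
    trial_id = 1:3, sentence_id = 1:3, repetition = 1L,
    phase = "prep", syllable_index = NA_integer_,
    onset = c(0, 6, 12), offset = c(1.9, 7.9, 13.9))
  rest <- tibble::tibble(
    trial_id = 1:3, sentence_id = 1:3, repetition = 1L,
    phase = "rest", syllable_index = NA_integer_,
    onset = c(4, 10, 16), offset = c(6, 12, 18))
  sched <- dplyr::arrange(dplyr::bind_rows(sched, prep, rest), onset)
  class(sched) <- c("trial_schedule", class(sched))
  # constant signal: zero in-band power in every interval, so all paired
  # differences are exactly zero
  sig <- matrix(1, nrow = 1, ncol = 18 * 2000)
  rec <- new_recording(sig, 2000, generate_channel_specs(1, 0, seed = 1))
  res <- speech_responsiveness_test(rec, sched)
  expect_equal(res$p, 1)
  expect_false(res$selected)
})

test_that("anatomical exclusions override significance", {
  res <- tibble::tibble(
    name = c("a", "b", "c", "d"),
    region = c("Occipital", "WhiteMatter", "Tha", "STG"),
    domain = c("cortical", "none", "subcortical", "cortical"),
    tissue = c("gray", "white", "gray", "gray"),
    mean_speech_power = 1, mean_silence_power = 0.5,
    t = 5, p = 1e-4, p_adj = 1e-4,
    selected = TRUE, reason = "none")
  class(res) <- c("channel_selection", class(res))
  out <- apply_exclusions(res)
  expect_false(out$selected[1])
  expect_equal(out$reason[1], "visual_region")
  expect_false(out$selected[2])
  expect_equal(out$reason[2], "white_matter")
  expect_true(all(out$selected[3:4]))
  expect_equal(out$p_adj, res$p_adj)  # significance untouched
  # identity when nothing to exclude
  expect_identical(apply_exclusions(res[3:4, ]), res[3:4, ])
})

test_that("selection is equivariant under channel permutation", {
  d <- tiny_dataset()
  perm <- with_seed(5, sample(n_channels(d$rec)))
  rec_p <- restrict_channels(d$rec, perm)
  a <- select_channels(d$rec, d$schedule)
  b <- select_channels(rec_p, d$schedule)
  expect_equal(b$name, a$name[perm])
  expect_equal(b$t, a$t[perm], tolerance = 1e-12)
  expect_equal(b$selected, a$selected[perm])
})

test_that("fewer than two trials is an error", {
  d <- tiny_dataset()
  one <- d$schedule[d$schedule$trial_id == 1, ]
  class(one) <- class(d$schedule)
  expect_error(speech_responsiveness_test(d$rec, one), "2 trials")
})
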