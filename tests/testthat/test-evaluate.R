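# causal preprocessing chain reused by continuous tests
prepared_continuous_recording <- function(res, d) {
  rec_sel <- restrict_channels(d$rec, res$model$channel_names)
  filtered <- filter_signal(rec_sel, res$preproc, causal = TRUE)
  standardized <- zscore_standardize(filtered, stats = res$zscore_stats)
  downsample_recording(standardized, res$preproc$target_rate)
}

test_that("sentence split holds out 20% with no repetition leakage", {
  sp <- sentence_level_split(1:100, 0.2, seed = 1)
  expect_length(sp$eval_sentence_ids, 20L)
  expect_length(sp$train_sentence_ids, 80L)
  expect_length(intersect(sp$train_sentence_ids, sp$eval_sentence_ids), 0L)
  expect_setequal(c(sp$train_sentence_ids, sp$eval_sentence_ids), 1:100)
  expect_silent(assert_no_leakage(sp))
})

test_that("distinct seeds give (almost surely) distinct evaluation sets", {
  sets <- lapply(1:20, function(s)
    sentence_level_split(1:100, 0.2, seed = s)$eval_sentence_ids)
  expect_gte(length(unique(lapply(sets, sort))), 19L)
})

test_that("the leakage guard trips on overlap and missing coverage", {
  sp <- sentence_level_split(1:20, 0.2, seed = 2)
  bad <- sp
  bad$train_sentence_ids <- c(bad$train_sentence_ids, bad$eval_sentence_ids[1])
  expect_error(assert_no_leakage(bad), "leakage")
  info <- tibble::tibble(sentence_id = c(1:20, 99L))
  expect_error(assert_no_leakage(sp, info), "missing")
  expect_error(sentence_level_split(1:4, 0.2), "at least 5")
  expect_error(sentence_level_split(1:20, 0), "\\(0, 1\\)")
})

test_that("discretized accuracy scores perfect and random predictors correctly", {
  segs <- random_segments(C = 2, n = 10000, seed = 5)
  m <- build_model(2)
  oracle <- constant_predictor(m, 1L)
  only_speech <- subset_segments(segs, segs$info$label == 1L)
  expect_equal(discretized_accuracy(oracle, only_speech)$accuracy, 1.0)
  # an untrained net on unstructured random inputs behaves like a coin flip
  acc <- discretized_accuracy(build_model(2, seed = 8), segs)$accuracy
  expect_gt(acc, 0.47)
  expect_lt(acc, 0.53)
  expect_error(discretized_accuracy(m, subset_segments(segs, integer(0))),
               "empty")
})

test_that("continuous windows advance on the 5 ms grid with 95% overlap", {
  res <- tiny_result()
  d <- tiny_dataset()
  ct <- run_continuous_evaluation(res, d$rec, d$schedule)
  bd <- trial_boundaries(d$schedule)
  eval_bd <- bd[bd$sentence_id %in% res$split$eval_sentence_ids, ]
  expect_setequal(ct$trial_id, eval_bd$trial_id)
  # ~ (trial span - window) / step windows per trial
  spans <- eval_bd$trial_offset - eval_bd$trial_onset
  expected <- floor((spans - 0.1) / 0.005) + 1
  expect_true(all(abs(ct$n_windows - expected) <= 2))
  # 5 ms step against 100 ms windows: adjacent windows share 95% of their span
  expect_equal((0.1 - 0.005) / 0.1, 0.95)
})

test_that("continuous decoding of a constant-state stretch with an oracle is perfect", {
  res <- tiny_result()
  d <- tiny_dataset()
  always_speech <- constant_predictor(res$model, 1L)
  ct <- continuous_decode(always_speech,
                          prepared_continuous_recording(res, d),
                          d$schedule,
                          trial_ids = trial_boundaries(d$schedule)$trial_id[1])
  # accuracy equals the fraction of windows whose final point is speech
  expect_gt(ct$accuracy, 0)
  rec <- prepared_continuous_recording(res, d)
  bd <- trial_boundaries(d$schedule)[1, ]
  fs <- rec$sampling_rate
  i0 <- round(seq(bd$trial_onset, bd$trial_offset - 0.1, by = 0.005) * fs) + 1L
  i0 <- i0[i0 + 49 <= n_samples(rec)]
  truth <- rec$state[i0 + 49L]
  expect_equal(ct$accuracy, mean(truth == 1L))
})

test_that("continuous decoding never reads past a window's final sample", {
  res <- tiny_result()
  d <- tiny_dataset()
  rec <- prepared_continuous_recording(res, d)
  bd <- trial_boundaries(d$schedule)[1, ]
  fs <- rec$sampling_rate
  # tripwire: poison everything after the trial's midpoint with NaN, then
  # decode only the first half; predictions must stay finite and identical
  cut <- floor((bd$trial_onset + bd$trial_offset) / 2 * fs)
  poisoned <- rec
  poisoned$signal[, (cut + 1):n_samples(rec)] <- NaN
  half_sched <- d$schedule[d$schedule$trial_id == 1, ]
  half_sched$offset <- pmin(half_sched$offset, cut / fs)
  half_sched <- half_sched[half_sched$onset < cut / fs, ]
  class(half_sched) <- class(d$schedule)
  a <- continuous_decode(res$model, poisoned, half_sched, trial_ids = 1L)
  b <- continuous_decode(res$model, rec, half_sched, trial_ids = 1L)
  expect_false(anyNA(a$accuracy))
  expect_equal(a$accuracy, b$accuracy)
})

test_that("one-way ANOVA wrapper holds its type-I error under the null", {
  with_seed(99, {
    rejections <- vapply(1:50, function(r) {
      d <- tibble::tibble(value = stats::rnorm(60),
                          group = rep(c("a", "b", "c"), each = 20))
      tidy(compare_conditions(d, "one_way"))$p_value[1] < 0.05
    }, logical(1))
    expect_lte(mean(rejections), 0.14)  # 50 draws at alpha 0.05
  })
})

test_that("one-way ANOVA detects well-separated groups with all Tukey pairs", {
  with_seed(7, {
    d <- tibble::tibble(value = c(stats::rnorm(20, 0.6, 0.05),
                                  stats::rnorm(20, 0.7, 0.05),
                                  stats::rnorm(20, 0.8, 0.05)),
                        group = rep(c("a", "b", "c"), each = 20))
    cc <- compare_conditions(d, "one_way")
    expect_lt(cc$omnibus$p_value, 0.001)
    expect_true(all(cc$pairwise$p_value < 0.05))
  })
})

test_that("two-way ANOVA reports main effects and Bonferroni simple effects", {
  with_seed(8, {
    d <- tidyr::expand_grid(group = c("raw", "hga"),
                            factor2 = c("all", "cortical", "subcortical"),
                            rep = 1:10)
    d$value <- stats::rnorm(nrow(d), 0.7 + 0.1 * (d$group == "raw"), 0.05)
    cc <- compare_conditions(d, "two_way")
    expect_setequal(cc$omnibus$term, c("group", "factor2", "group:factor2"))
    expect_lt(cc$omnibus$p_value[cc$omnibus$term == "group"], 0.001)
    expect_equal(nrow(cc$pairwise), 3L)
    expect_error(compare_conditions(d[1:5, ], "two_way"), "per cell")
  })
})

test_that("degenerate zero-variance comparisons return p = 1 by convention", {
  d <- tibble::tibble(value = rep(0.5, 10))
  expect_equal(tidy(compare_conditions(d, "vs_chance", mu = 0.5))$p_value, 1)
  d2 <- tibble::tibble(value = rep(0.7, 10), group = rep(c("x", "y"), 5))
  expect_equal(tidy(compare_conditions(d2, "two_group"))$p_value, 1)
})

test_that("one-sample comparison flags above-chance accuracy", {
  with_seed(10, {
    d <- tibble::tibble(value = stats::rnorm(20, 0.8, 0.05))
    cc <- compare_conditions(d, "vs_chance", mu = 0.5)
    expect_lt(cc$omnibus$p_value, 0.001)
    expect_gt(cc$omnibus$statistic, 0)
  })
})
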