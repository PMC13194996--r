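test_that("temporal length trace through the network matches the design", {
  # T=50: stem ceil(50/4)=13, pools floor: 13->6->3->1
  expect_equal(as.integer(speechstate:::cnn_length_trace(50L)), c(13L, 6L, 3L, 1L))
  expect_error(build_model(4, T = 20L), "too short")
  expect_silent(build_model(4, T = 29L))
})

test_that("parameter count matches the closed-form formula", {
  for (C in c(1L, 12L, 40L)) {
    m <- build_model(C)
    expected <- (15 * C * 32 + 32) + (7 * 32 * 64 + 64) +
      (5 * 64 * 128 + 128) + (5 * 128 * 256 + 256) + (256 + 1)
    expect_equal(n_parameters(m), expected)
  }
})

test_that("an untrained model sits at chance on balanced data", {
  accs <- vapply(1:20, function(s) {
    m <- build_model(4, seed = s)
    segs <- random_segments(C = 4, n = 200, seed = 1000 + s)
    pred <- predict(m, segs)
    mean(pred$pred_label == segs$info$label)
  }, numeric(1))
  expect_gt(mean(accs), 0.45)
  expect_lt(mean(accs), 0.55)
})

test_that("a single-channel model builds and runs forward", {
  m <- build_model(1)
  segs <- random_segments(C = 1, n = 8)
  pred <- predict(m, segs)
  expect_equal(nrow(pred), 8L)
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
})

test_that("evaluation-mode prediction is deterministic and batch-invariant", {
  m <- tiny_result()$model
  segs <- random_segments(C = m$C, n = 100, seed = 9)
  p1 <- predict(m, segs)$prob
  p2 <- predict(m, segs)$prob
  expect_identical(p1, p2)
  # duplicating a segment duplicates its prediction exactly
  dup <- subset_segments(segs, c(1:100, 1))
  pd <- predict(m, dup)$prob
  expect_identical(pd[101], pd[1])
  # batch partitioning must not matter
  one_by_one <- vapply(1:20, function(i)
    predict(m, segs$x[, , i, drop = FALSE])$prob, numeric(1))
  expect_lt(max(abs(one_by_one - p1[1:20])), 1e-6)
})

test_that("prediction rejects mismatched channel counts", {
  m <- build_model(4)
  expect_error(predict(m, random_segments(C = 5, n = 4)), "shape")
})

test_that("the recorded learning rate follows the cosine schedule", {
  res <- tiny_result()
  h <- tidy(res$model)
  E <- res$model$train_config$epochs
  lr0 <- res$model$train_config$lr
  expect_equal(h$lr, cosine_lr(h$epoch - 1, E, lr0), tolerance = 1e-12)
  expect_equal(cosine_lr(0, 80), 0.001)
  expect_equal(cosine_lr(40, 80), 0.0005)
})

test_that("training improves the loss and stops early on plateaus", {
  res <- tiny_result()
  h <- tidy(res$model)
  expect_lt(h$train_loss[res$model$best_epoch], h$train_loss[1])
  expect_lte(nrow(h), res$model$train_config$epochs)
  expect_true(res$model$trained)
})

test_that("training with the same seed reproduces the result", {
  segs <- tiny_segments()
  tr <- balance_segments(subset_segments(segs, segs$info$sentence_id <= 5), 1)
  va <- balance_segments(subset_segments(segs, segs$info$sentence_id > 5), 1)
  cfg <- train_config(epochs = 2, seed = 77)
  m1 <- train_cnn(build_model(dim(segs$x)[1], seed = 3), tr, va, cfg)
  m2 <- train_cnn(build_model(dim(segs$x)[1], seed = 3), tr, va, cfg)
  expect_identical(tidy(m1)$val_accuracy, tidy(m2)$val_accuracy)
  expect_identical(m1$params$W0, m2$params$W0)
})

test_that("single-class splits are rejected", {
  segs <- random_segments(n = 20)
  all1 <- subset_segments(segs, segs$info$label == 1)
  expect_error(train_cnn(build_model(4), all1, segs, train_config(epochs = 1)),
               "both classes")
})

test_that("label shuffling destroys decodability", {
  d <- tiny_dataset()
  segs <- tiny_segments()
  accs <- vapply(1:4, function(s) {
    with_seed(500 + s, {
      shuffled <- segs
      shuffled$info$label <- sample(shuffled$info$label)
      tr_ids <- 1:6
      tr <- balance_segments(subset_segments(
        shuffled, shuffled$info$sentence_id %in% tr_ids), s)
      ev <- balance_segments(subset_segments(
        shuffled, !(shuffled$info$sentence_id %in% tr_ids)), s)
      m <- train_cnn(build_model(dim(segs$x)[1], seed = s), tr, ev,
                     train_config(epochs = 3, seed = s))
      discretized_accuracy(m, ev)$accuracy
    })
  }, numeric(1))
  expect_gt(mean(accs), 0.40)
  expect_lt(mean(accs), 0.60)
})

test_that("tidy and glance summarize a fitted model", {
  res <- tiny_result()
  g <- glance(res$model)
  expect_equal(g$n_channels, res$model$C)
  expect_equal(g$epochs_run, nrow(tidy(res$model)))
  expect_true(g$val_accuracy > 0.8)  # high-SNR fixture learns
})
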