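#' Model architecture configuration
#'
#' The compact 1-D CNN used for speech-state classification: a convolutional
#' stem (kernel 15, stride 4, 32 output channels), three blocks of
#' same-padded stride-1 convolution (kernels 7/5/5, output channels
#' 64/128/256) each followed by a kernel-2/stride-2 max-pool and dropout,
#' then global average pooling over time and a linear map to a single logit
#' read through a sigmoid. The architecture is fixed; this object records it
#' and the dropout rate.
#'
#' @param dropout_rate Dropout probability after each block's max-pool.
#' @return A list of class `model_config`.
#' @export
model_config <- function(dropout_rate = 0.1) {
  structure(list(
    stem = list(kernel = 15L, stride = 4L, out = 32L),
    blocks = list(list(kernel = 7L, out = 64L, pool_stride = 2L),
                  list(kernel = 5L, out = 128L, pool_stride = 2L),
                  list(kernel = 5L, out = 256L, pool_stride = 2L)),
    head = "global_average_pool + linear(1)",
    dropout_rate = dropout_rate,
    activation = "relu"
  ), class = "model_config")
}

#' Training configuration
#'
#' Optimization recipe for the classifier: Adam (lr 0.001, beta1 0.9,
#' beta2 0.999) with weight decay 0.005, batch size 48, cosine decay of the
#' learning rate over the epoch budget, dropout 0.1, binary cross-entropy
#' loss, and early stopping after 5 epochs without validation-loss
#' improvement, over at most 80 epochs.
#'
#' @param epochs Epoch budget.
#' @param lr Base learning rate.
#' @param beta1,beta2 Adam momentum parameters.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param batch_size Mini-batch size.
#' @param lr_schedule `"cosine"` or `"constant"`.
#' @param dropout Dropout rate during training.
#' @param early_stopping_patience Epochs of validation non-improvement
#'   tolerated before stopping.
#' @param seed Integer seed for shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 80L, lr = 0.001, beta1 = 0.9,
                         beta2 = 0.999, weight_decay = 0.005,
                         batch_size = 48L, lr_schedule = c("cosine", "constant"),
                         dropout = 0.1, early_stopping_patience = 5L,
                         seed = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  if (early_stopping_patience < 1L) stop("patience must be >= 1", call. = FALSE)
  structure(list(epochs = as.integer(epochs), lr = lr, beta1 = beta1,
                 beta2 = beta2, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 lr_schedule = lr_schedule, dropout = dropout,
                 early_stopping_patience = as.integer(early_stopping_patience),
                 loss = "binary_cross_entropy", seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine learning-rate schedule
#'
#' `lr(e) = 0.5 * lr0 * (1 + cos(pi * e / E))` with `e` counted from 0, so
#' the first epoch trains at the base rate.
#'
#' @param epoch 0-based epoch index.
#' @param total_epochs Epoch budget `E`.
#' @param base_lr Base learning rate.
#' @return Learning rate for that epoch.
#' @export
cosine_lr <- function(epoch, total_epochs, base_lr = 0.001) {
  0.5 * base_lr * (1 + cos(pi * epoch / total_epochs))
}

#' Build an (untrained) speech-state CNN
#'
#' Initializes the network of [model_config()] for `C` input channels with
#' seeded He-normal weights.
#'
#' @param C Input channel count.
#' @param cfg A [model_config()].
#' @param T Segment length in samples (50 for 100 ms at 500 Hz); checked
#'   against the pooling cascade.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `speech_cnn`.
#' @export
build_model <- function(C, cfg = model_config(), T = 50L, seed = 1L) {
  if (C < 1) stop("need at least one channel", call. = FALSE)
  trace <- cnn_length_trace(as.integer(T))
  if (trace[4] < 1)
    stop("segment length ", T, " too short for the pooling cascade",
         call. = FALSE)
  structure(list(
    params = cnn_init_params(as.integer(C), as.integer(seed)),
    model_config = cfg,
    C = as.integer(C), T = as.integer(T),
    channel_names = NULL,
    trained = FALSE,
    history = NULL,
    train_config = NULL,
    zscore_stats = NULL
  ), class = "speech_cnn")
}

#' Number of trainable parameters
#' @param model A `speech_cnn`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

segs_to_xy <- function(segs) {
  list(x = segs$x, y = as.numeric(segs$info$label))
}

#' Train the speech-state CNN
#'
#' Mini-batch Adam with cosine learning-rate decay and early stopping on
#' validation loss; the best-validation checkpoint is returned. Both splits
#' must contain both classes. Deterministic for a fixed seed under
#' single-threaded BLAS.
#'
#' @param model A `speech_cnn` from [build_model()].
#' @param train_segments,val_segments `segment_set`s (already balanced if
#'   balanced training is desired).
#' @param cfg A [train_config()].
#' @return The trained `speech_cnn`, with a `history` tibble (per-epoch
#'   learning rate, train/validation loss and accuracy).
#' @export
train_cnn <- function(model, train_segments, val_segments,
                      cfg = train_config()) {
  tr <- segs_to_xy(train_segments)
  va <- segs_to_xy(val_segments)
  for (y in list(tr$y, va$y))
    if (length(unique(y)) < 2)
      stop("both classes required in each split", call. = FALSE)
  if (dim(tr$x)[1] != model$C)
    stop("segment channel count does not match the model", call. = FALSE)

  fit <- cnn_train(model$params, tr$x, tr$y, va$x, va$y,
                   epochs = cfg$epochs, lr0 = cfg$lr, beta1 = cfg$beta1,
                   beta2 = cfg$beta2, eps = 1e-8,
                   weight_decay = cfg$weight_decay,
                   batch_size = cfg$batch_size, dropout = cfg$dropout,
                   patience = cfg$early_stopping_patience, seed = cfg$seed,
                   cosine = cfg$lr_schedule == "cosine")
  model$params <- fit$params
  h <- fit$history
  colnames(h) <- c("epoch", "lr", "train_loss", "train_accuracy",
                   "val_loss", "val_accuracy")
  model$history <- tibble::as_tibble(as.data.frame(h))
  model$best_epoch <- fit$best_epoch
  model$trained <- TRUE
  model$train_config <- cfg
  model
}

#' Predict speech-state probabilities for segments
#'
#' Evaluation-mode forward pass (dropout off); deterministic and invariant
#' to batch partitioning.
#'
#' @param object A `speech_cnn`.
#' @param segments A `segment_set` or a `(C, T, n)` array.
#' @param ... Unused.
#' @return A tibble with `prob` (probability of speech) and `pred_label`
#'   (1 iff `prob >= 0.5`).
#' @export
predict.speech_cnn <- function(object, segments, ...) {
  x <- if (inherits(segments, "segment_set")) segments$x else segments
  if (length(dim(x)) != 3 || dim(x)[1] != object$C)
    stop("segment shape does not match the model: expected (",
         object$C, ", T, n)", call. = FALSE)
  prob <- as.numeric(cnn_forward_prob(object$params, x))
  tibble::tibble(prob = prob, pred_label = as.integer(prob >= 0.5))
}

#' @export
print.speech_cnn <- function(x, ...) {
  cat(sprintf("<speech_cnn> C=%d, T=%d, %d parameters, %s\n",
              x$C, x$T, n_parameters(x),
              if (x$trained) sprintf("trained (best epoch %d)", x$best_epoch)
              else "untrained"))
  invisible(x)
}

#' Tidy the training history of a fitted CNN
#' @param x A trained `speech_cnn`.
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @export
tidy.speech_cnn <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history", call. = FALSE)
  x$history
}

#' One-row summary of a fitted CNN
#' @param x A `speech_cnn`.
#' @param ... Unused.
#' @return A one-row tibble: channels, parameters, epochs run, best epoch,
#'   best validation loss/accuracy.
#' @export
glance.speech_cnn <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_channels = x$C,
    n_parameters = n_parameters(x),
    epochs_run = if (is.null(h)) 0L else nrow(h),
    best_epoch = if (is.null(h)) NA_integer_ else x$best_epoch,
    val_loss = if (is.null(h)) NA_real_ else h$val_loss[h$epoch == x$best_epoch],
    val_accuracy = if (is.null(h)) NA_real_ else h$val_accuracy[h$epoch == x$best_epoch])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
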