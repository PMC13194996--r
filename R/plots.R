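#' Plot regional saliency contributions
#'
#' Bar plot of normalized regional contributions (mean over the region's
#' channels, +/- sd), ranked in descending order.
#'
#' @param report A `saliency_report`.
#' @return A ggplot object.
#' @export
plot_saliency <- function(report) {
  d <- report$region
  d$region <- stats::reorder(d$region, -d$mean_contribution)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region,
                                  y = .data$mean_contribution)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$mean_contribution - .data$sd_contribution),
                   ymax = .data$mean_contribution + .data$sd_contribution),
      width = 0.3) +
    ggplot2::labs(x = NULL, y = "normalized contribution",
                  title = "Regional saliency contributions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_saliency
#' @param object A `saliency_report`.
#' @param ... Unused.
#' @export
autoplot.saliency_report <- function(object, ...) plot_saliency(object)

#' Plot a training history
#'
#' Train/validation loss and accuracy per epoch of a fitted classifier.
#'
#' @param model A trained `speech_cnn`.
#' @return A ggplot object.
#' @export
plot_training_history <- function(model) {
  h <- tidy(model)
  d <- tidyr::pivot_longer(h, c("train_loss", "val_loss", "train_accuracy",
                                "val_accuracy"),
                           names_to = "metric", values_to = "value")
  d$split <- ifelse(grepl("^train", d$metric), "train", "validation")
  d$what <- ifelse(grepl("loss$", d$metric), "loss", "accuracy")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_training_history
#' @param object A trained `speech_cnn`.
#' @param ... Unused.
#' @export
autoplot.speech_cnn <- function(object, ...) plot_training_history(object)

#' Plot accuracies across conditions
#'
#' Mean +/- sd accuracy per condition with the individual observations
#' overlaid, against the 50% chance baseline.
#'
#' @param data A data frame with columns `condition` and `accuracy` (e.g.
#'   bound rows of evaluation or ablation results).
#' @return A ggplot object.
#' @export
plot_condition_accuracy <- function(data) {
  summ <- data |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean = mean(.data$accuracy),
                     sd = stats::sd(.data$accuracy), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey80") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::geom_jitter(data = data,
                         ggplot2::aes(x = .data$condition, y = .data$accuracy),
                         width = 0.08, alpha = 0.5, size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = NULL, y = "accuracy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
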