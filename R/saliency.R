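#' Gradient-saliency channel and region contributions
#'
#' For every labeled segment, the gradient of its binary cross-entropy loss
#' with respect to the input is computed by backpropagation (dropout
#' disabled). The per-channel saliency is the time-average of the absolute
#' gradient, averaged across segments:
#' `zeta(c) = mean_segments( (1/T) * sum_t |dL/dx[t, c]| )`.
#' Saliencies are min-max normalized to \[0, 1\] across channels and
#' aggregated per anatomical region as the unweighted mean over the region's
#' channels; regions are ranked by descending mean contribution.
#'
#' @param model A trained `speech_cnn`.
#' @param segments A labeled `segment_set` (normally the evaluation split,
#'   both classes).
#' @param channels Optional channel metadata tibble (`name`, `region`)
#'   aligned with the model's channels; defaults to the names stored on the
#'   model with no regions.
#' @param classes Which segment classes enter the average: `"both"`
#'   (default), `"speech"` or `"rest"`.
#' @return A list of class `saliency_report` with tibbles `channel`
#'   (`name`, `region`, `zeta`, `zeta_norm`) and `region`
#'   (`region`, `mean_contribution`, `sd_contribution`, `n_channels`,
#'   `rank`).
#' @export
compute_saliency <- function(model, segments, channels = NULL,
                             classes = c("both", "speech", "rest")) {
  classes <- match.arg(classes)
  if (is.null(segments$info$label) || anyNA(segments$info$label))
    stop("saliency requires labeled segments", call. = FALSE)
  keep <- switch(classes,
                 both = rep(TRUE, nrow(segments$info)),
                 speech = segments$info$label == 1,
                 rest = segments$info$label == 0)
  segs <- subset_segments(segments, keep)
  g <- cnn_input_grad(model$params, segs$x, as.numeric(segs$info$label))
  # time-average of |gradient| per channel, then across segments
  zeta <- apply(abs(g), 1, mean)
  rng <- range(zeta)
  zeta_norm <- if (diff(rng) > 0) (zeta - rng[1]) / diff(rng)
               else rep(0, length(zeta))

  nm <- if (!is.null(channels)) channels$name
        else if (!is.null(model$channel_names)) model$channel_names
        else sprintf("ch%03d", seq_along(zeta))
  region <- if (!is.null(channels)) channels$region else rep(NA_character_, length(zeta))
  channel_tbl <- tibble::tibble(name = nm, region = region,
                                zeta = zeta, zeta_norm = zeta_norm)

  region_tbl <- channel_tbl |>
    dplyr::filter(!is.na(.data$region)) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(mean_contribution = mean(.data$zeta_norm),
                     sd_contribution = stats::sd(.data$zeta_norm),
                     n_channels = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_contribution)) |>
    dplyr::mutate(rank = dplyr::row_number())

  structure(list(channel = channel_tbl, region = region_tbl),
            class = "saliency_report")
}

#' @export
print.saliency_report <- function(x, ...) {
  cat("<saliency_report>", nrow(x$channel), "channels\n")
  if (nrow(x$region) > 0) {
    cat("top regions:\n")
    print(utils::head(x$region, 5))
  }
  invisible(x)
}

#' @export
tidy.saliency_report <- function(x, ...) x$channel

#' @export
glance.saliency_report <- function(x, ...) {
  tibble::tibble(n_channels = nrow(x$channel),
                 n_regions = nrow(x$region),
                 top_region = if (nrow(x$region) > 0) x$region$region[1]
                              else NA_character_)
}
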