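#' Generate per-channel anatomical metadata
#'
#' Emulates the heterogeneous anatomical coverage of depth-electrode
#' implantations: channels are assigned regions from `region_pool`, a subset
#' is marked informative (carrying state-dependent signal components), and —
#' when `n_channels >= 10` and the pool allows it — at least one occipital
#' and one white-matter channel are included so the anatomical exclusion
#' rules downstream are exercised.
#'
#' Informative channels are only placed in gray-matter, non-occipital
#' regions, and are spread across both cortical and subcortical regions when
#' both domains are present in the eligible pool.
#'
#' @param n_channels Total channel count.
#' @param fraction_informative Fraction of channels carrying speech-state
#'   modulation (rounded to a count).
#' @param region_pool Character vector of region codes to draw from; defaults
#'   to all regions in [region_table()].
#' @param seed Integer seed.
#' @param snr Effect scale of the state-dependent components on informative
#'   channels (amplitude of the gated components relative to the unit-sd
#'   background); recycled to the informative count.
#' @param informative_regions Optional region codes to restrict informative
#'   channels to (e.g. to place them inside/outside the classical speech
#'   regions for exclusion experiments).
#'
#' @return A tibble with columns `name`, `region`, `domain`, `tissue`,
#'   `informative`, `snr`.
#' @export
#' @examples
#' generate_channel_specs(12, fraction_informative = 0.25, seed = 1)
generate_channel_specs <- function(n_channels,
                                   fraction_informative = 0.3,
                                   region_pool = region_table()$region,
                                   seed = 1L,
                                   snr = 1,
                                   informative_regions = NULL) {
  if (length(region_pool) == 0) stop("region pool is empty", call. = FALSE)
  if (fraction_informative < 0 || fraction_informative > 1)
    stop("fraction_informative must be in [0, 1]", call. = FALSE)
  tab <- region_table()
  unknown <- setdiff(region_pool, tab$region)
  if (length(unknown) > 0)
    stop("unknown regions: ", paste(unknown, collapse = ", "), call. = FALSE)

  with_seed(seed, {
    regions <- sample(region_pool, n_channels, replace = TRUE)
    # guarantee exclusion-rule coverage on reasonably sized montages
    if (n_channels >= 10) {
      if ("Occipital" %in% region_pool && !any(regions == "Occipital"))
        regions[1] <- "Occipital"
      if ("WhiteMatter" %in% region_pool && !any(regions == "WhiteMatter"))
        regions[2] <- "WhiteMatter"
    }

    eligible_regions <- setdiff(intersect(region_pool, tab$region[tab$tissue == "gray"]),
                                "Occipital")
    if (!is.null(informative_regions))
      eligible_regions <- intersect(eligible_regions, informative_regions)

    n_inf <- round(fraction_informative * n_channels)
    eligible_idx <- which(regions %in% eligible_regions)
    if (n_inf > 0 && length(eligible_regions) == 0)
      stop("no eligible regions for informative channels", call. = FALSE)
    if (n_inf > 0 && length(eligible_idx) < n_inf) {
      # re-seat enough channels into eligible regions to honor the count
      need <- n_inf - length(eligible_idx)
      movable <- setdiff(seq_len(n_channels), eligible_idx)
      movable <- movable[!(regions[movable] %in% c("Occipital", "WhiteMatter")) |
                           movable > 2 | n_channels < 10]
      take <- utils::head(movable, need)
      regions[take] <- sample(eligible_regions, length(take), replace = TRUE)
      eligible_idx <- which(regions %in% eligible_regions)
    }
    informative <- rep(FALSE, n_channels)
    if (n_inf > 0) {
      # spread across cortical and subcortical when both are available
      dom <- region_domain(regions)
      pick <- integer(0)
      for (d in c("cortical", "subcortical")) {
        cand <- eligible_idx[dom[eligible_idx] == d]
        if (length(cand) > 0 && n_inf >= 2)
          pick <- c(pick, cand[sample.int(length(cand), 1)])
      }
      remaining <- setdiff(eligible_idx, pick)
      extra <- n_inf - length(pick)
      if (extra > 0) pick <- c(pick, remaining[sample.int(length(remaining), extra)])
      informative[pick[seq_len(min(n_inf, length(pick)))]] <- TRUE
    }

    tibble::tibble(
      name = sprintf("ch%03d", seq_len(n_channels)),
      region = regions,
      domain = region_domain(regions),
      tissue = tab$tissue[match(regions, tab$region)],
      informative = informative,
      snr = ifelse(informative, rep_len(snr, n_channels), 0)
    )
  })
}
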