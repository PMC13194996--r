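#' Anatomical region table
#'
#' Region codes used throughout the package, with their anatomical domain
#' (cortical, subcortical, or none) and default tissue class. Cortical codes
#' follow the usual gyral abbreviations (SFG/MFG/IFG frontal gyri, STG/MTG/ITG
#' temporal gyri, Precen/Postcen central gyri, INS insula, FuG fusiform, Pcun
#' precuneus, SMG supramarginal, Angular, SPL/IPL parietal lobules, CG
#' cingulate, Occipital); subcortical codes are Tha (thalamus), Amyg
#' (amygdala), Hipp (hippocampus). `WhiteMatter` marks contacts outside gray
#' matter.
#'
#' @return A tibble with columns `region`, `domain` and `tissue`.
#' @export
#' @examples
#' region_table()
region_table <- function() {
  cortical <- c("SFG", "MFG", "IFG", "STG", "MTG", "ITG", "Precen",
                "Postcen", "INS", "FuG", "Pcun", "SMG", "Angular",
                "SPL", "IPL", "CG", "Occipital")
  subcortical <- c("Tha", "Amyg", "Hipp")
  tibble::tibble(
    region = c(cortical, subcortical, "WhiteMatter"),
    domain = c(rep("cortical", length(cortical)),
               rep("subcortical", length(subcortical)), "none"),
    tissue = c(rep("gray", length(cortical) + length(subcortical)), "white")
  )
}

#' Default set of classical speech-related regions
#'
#' The canonical language/motor set removed in the region-exclusion
#' robustness analysis: angular gyrus, superior/middle/inferior frontal gyri,
#' superior/middle/inferior temporal gyri, and precentral gyrus.
#'
#' @return Character vector of region codes.
#' @export
speech_regions <- function() {
  c("Angular", "SFG", "MFG", "IFG", "STG", "MTG", "ITG", "Precen")
}

region_domain <- function(region) {
  tab <- region_table()
  tab$domain[match(region, tab$region)]
}
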