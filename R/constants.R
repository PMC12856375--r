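#' Frozen feature orderings
#'
#' The four default-mode-network regions of interest and the six clinical
#' measures used throughout the package, in their canonical, frozen order.
#' Perturbation feature indices, input-bundle channel order and report rows
#' all follow these vectors, so they must never be reordered.
#'
#' @format `dmn_roi_names()` returns a character vector of length 4;
#'   `dmn_clinical_names()` returns a character vector of length 6.
#' @name orderings
NULL

#' @rdname orderings
#' @export
dmn_roi_names <- function() {
  c("PCC", "LP_L", "LP_R", "MPFC")
}

#' @rdname orderings
#' @export
dmn_clinical_names <- function() {
  c("ADAS13", "EcogPtTotal", "FAQ", "MoCA",
    "RAVLT_immediate", "RAVLT_pct_forgetting")
}

# long-form labels used in printed reports
.roi_labels <- c(
  PCC  = "posterior cingulate",
  LP_L = "left lateral parietal",
  LP_R = "right lateral parietal",
  MPFC = "medial prefrontal"
)

# plausible raw score ranges; truncation bounds for the synthetic generator
# and sanity bounds for loaded cohorts
.clinical_ranges <- list(
  ADAS13               = c(0, 85),
  EcogPtTotal          = c(1, 4),
  FAQ                  = c(0, 30),
  MoCA                 = c(0, 30),
  RAVLT_immediate      = c(0, 75),
  RAVLT_pct_forgetting = c(0, 100)
)

#' Raw-scale bounds of the clinical instruments
#'
#' Score ranges of the six neuropsychological measures on their native
#' scales (e.g. MoCA 0-30). Used as truncation bounds by the synthetic
#' generator.
#'
#' @return Named list of `c(min, max)` pairs, one per clinical measure.
#' @export
clinical_score_ranges <- function() .clinical_ranges
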