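#' Canonical hemosiderin content thresholds
#'
#' Intracytoplasmic hemosiderin is a continuum; the Doucet & Viel system cuts
#' it into 5 discrete grades. These thresholds define where this package cuts
#' the continuous pigment fraction (fraction of the cytoplasm covered by blue
#' pigment) into grades 0..4. They are a package convention, exposed so that
#' the generator, the graders and any user configuration share one definition.
#'
#' @return Numeric vector of 4 strictly ascending fractions in (0, 1); a cell
#'   with pigment fraction `p` receives grade `sum(thresholds <= p)`.
#' @export
#' @examples
#' hemosiderin_thresholds()
hemosiderin_thresholds <- function() {
  c(0.02, 0.25, 0.50, 0.75)
}

#' Grade a cell from its continuous pigment content
#'
#' Maps a pigment fraction in \[0, 1\] to a discrete hemosiderin grade 0..4 by
#' counting how many grade thresholds lie at or below it (half-open bins,
#' lower-inclusive at each threshold). Grade 0 is the absence of
#' intracytoplasmic hemosiderin; grade 4 a macrophage filled with it.
#'
#' @param p numeric vector of pigment fractions in \[0, 1\].
#' @param thresholds 4 strictly ascending fractions in (0, 1), see
#'   [hemosiderin_thresholds()].
#' @return Integer vector of grades in 0..4.
#' @export
#' @examples
#' grade_from_content(c(0, 0.30, 1))  # 0, 2, 4
grade_from_content <- function(p, thresholds = hemosiderin_thresholds()) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("pigment content must be within [0, 1]")
  }
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0) ||
      any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must be 4 strictly ascending fractions in (0, 1)")
  }
  grades <- rowSums(outer(p, thresholds, ">="))
  as.integer(grades)
}

#' Classify EIPH from a total hemosiderin score
#'
#' Exercise-induced pulmonary hemorrhage is called positive when the THS
#' reaches the published diagnostic cut-off of 75 score points. A score
#' exactly at the cut-off is positive (the rule is "< 75" vs ">= 75"); the
#' cut-off is configurable.
#'
#' @param ths numeric THS value(s) in \[0, 400\].
#' @param cutoff diagnostic cut-off in score points (default 75).
#' @return Logical vector, `TRUE` where `ths >= cutoff`.
#' @export
#' @examples
#' classify_eiph(c(0, 74.9, 75))  # FALSE FALSE TRUE
classify_eiph <- function(ths, cutoff = 75) {
  if (!is.numeric(ths) || any(!is.finite(ths))) stop("ths must be finite")
  if (any(ths < 0 | ths > 400)) stop("ths out of range [0, 400]")
  ths >= cutoff
}
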