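#' Compute the total hemosiderin score for one slide and rater
#'
#' The THS sums the 5-tier hemosiderin grades of the enumerated alveolar
#' macrophages and expresses the sum per 100 cells, i.e.
#' `ths = 100 * mean(grade)`, ranging 0 (all cells free of hemosiderin) to
#' 400 (all cells filled). The published protocol enumerates at least 300
#' macrophages; fewer cells are an error unless `allow_fewer = TRUE` (slides
#' with under 300 scoreable cells are normally excluded). All annotated cells
#' enter the score, not just the first 300.
#'
#' @param annotations annotation table for a single slide and single rater
#'   (see [cell_annotations()]).
#' @param min_cells minimum cell count required by the protocol (default 300).
#' @param allow_fewer accept fewer than `min_cells` cells (used e.g. for
#'   sparse rendered images).
#' @param cutoff diagnostic cut-off passed to [classify_eiph()].
#' @return A one-row `data.frame` (a THS record) with columns `slide_id`,
#'   `rater_id`, `n_cells`, `ths`, `eiph_positive`.
#' @export
#' @examples
#' ann <- cell_annotations("s1", "r1", x = seq_len(300), y = 0,
#'                         grade = rep(2, 300))
#' compute_ths(ann)  # ths 200, EIPH positive
compute_ths <- function(annotations, min_cells = 300, allow_fewer = FALSE,
                        cutoff = 75) {
  if (NROW(annotations) == 0) stop("no annotations")
  annotations <- validate_annotations(annotations)
  slide <- unique(annotations$slide_id)
  rater <- unique(annotations$annotator_id)
  if (length(slide) != 1L) stop("annotations span several slides")
  if (length(rater) != 1L) stop("annotations span several raters")
  n <- nrow(annotations)
  if (n < min_cells && !allow_fewer) {
    stop("insufficient cells: ", n, " < ", min_cells)
  }
  ths <- 100 * mean(annotations$grade)
  data.frame(
    slide_id = slide,
    rater_id = rater,
    n_cells = n,
    ths = ths,
    eiph_positive = classify_eiph(ths, cutoff = cutoff),
    stringsAsFactors = FALSE
  )
}

#' Mean annotators' THS for one slide
#'
#' The mean of the human annotators' THS values for a slide, used as a
#' consensus reference in which each annotator's systematic error is averaged
#' out. Records from the reserved raters `"ground_truth"` and `"algorithm"`
#' are not accepted.
#'
#' @param records THS records (rows as returned by [compute_ths()]) for a
#'   single slide, human annotators only.
#' @return The arithmetic mean THS (score points).
#' @export
mean_annotator_ths <- function(records) {
  if (NROW(records) == 0) stop("no THS records")
  if (length(unique(records$slide_id)) != 1L) {
    stop("records span several slides")
  }
  if (any(records$rater_id %in% .reserved_raters)) {
    stop("records must come from annotators, not reserved raters")
  }
  mean(records$ths)
}

#' Arrange THS records into a complete slide-by-rater table
#'
#' Builds the fully crossed, single-measurement slide x rater matrix that the
#' agreement analysis operates on. Every rater must score every slide.
#'
#' @param records stacked THS records ([compute_ths()] rows).
#' @return Numeric matrix, rows = slides, columns = raters (both sorted),
#'   entries = THS.
#' @export
ths_table <- function(records) {
  if (NROW(records) == 0) stop("no THS records")
  slides <- sort(unique(records$slide_id))
  raters <- sort(unique(records$rater_id))
  tab <- matrix(NA_real_, length(slides), length(raters),
                dimnames = list(slides, raters))
  idx <- cbind(match(records$slide_id, slides), match(records$rater_id, raters))
  if (anyDuplicated(idx)) stop("duplicate (slide, rater) THS records")
  tab[idx] <- records$ths
  if (anyNA(tab)) stop("incomplete design: some (slide, rater) cells missing")
  tab
}
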