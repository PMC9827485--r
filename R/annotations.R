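#' Construct a table of cell annotations
#'
#' A cell annotation is one point-labelled alveolar macrophage: the slide it
#' sits on, who labelled it, the centroid pixel coordinates of the spot
#' annotation, and the Doucet & Viel hemosiderin grade (0 = no
#' intracytoplasmic hemosiderin, 4 = cell filled with hemosiderin).
#' Coordinates are 0-based pixels, x rightward, y downward, at 0.25 um/px.
#'
#' The rater ids `"ground_truth"` and `"algorithm"` are reserved for the
#' reference annotation set and the image-grading stage; they are valid
#' annotators here but are excluded from annotator-only aggregates such as
#' [mean_annotator_ths()].
#'
#' @param slide_id character slide identifiers.
#' @param annotator_id character rater identifiers.
#' @param x,y non-negative pixel coordinates of the cell centroid.
#' @param grade integer hemosiderin grade in 0..4.
#' @return A `data.frame` with columns `slide_id`, `annotator_id`, `x`, `y`,
#'   `grade`.
#' @export
#' @examples
#' cell_annotations("s1", "rater1", x = c(10, 40), y = c(5, 5), grade = c(0, 3))
cell_annotations <- function(slide_id, annotator_id, x, y, grade) {
  n <- length(x)
  ann <- data.frame(
    slide_id = rep_len(as.character(slide_id), n),
    annotator_id = rep_len(as.character(annotator_id), n),
    x = as.numeric(x),
    y = rep_len(as.numeric(y), n),
    grade = rep_len(grade, n),
    stringsAsFactors = FALSE
  )
  validate_annotations(ann)
}

#' Validate an annotation table
#'
#' Checks the column contract shared by every stage of the pipeline:
#' grades are integers 0..4 and coordinates are non-negative.
#'
#' @param ann a data.frame of annotations (see [cell_annotations()]).
#' @return `ann`, invisibly unchanged, with `grade` coerced to integer.
#' @export
validate_annotations <- function(ann) {
  required <- c("slide_id", "annotator_id", "x", "y", "grade")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols)) {
    stop("annotation table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  check_grades(ann$grade)
  ann$grade <- as.integer(ann$grade)
  if (any(!is.finite(ann$x)) || any(!is.finite(ann$y)) ||
      any(ann$x < 0) || any(ann$y < 0)) {
    stop("coordinates must be finite and non-negative")
  }
  ann
}

# grades must be whole numbers in 0..4; fractional grades are rejected,
# never rounded
check_grades <- function(grade) {
  if (length(grade) == 0) return(invisible(grade))
  if (!is.numeric(grade) || any(!is.finite(grade)) ||
      any(grade != floor(grade))) {
    stop("grades must be integers in 0..4 (fractional grades are rejected)")
  }
  if (any(grade < 0 | grade > 4)) {
    stop("grades must be integers in 0..4")
  }
  invisible(grade)
}

# internal: ids reserved for non-annotator raters
.reserved_raters <- c("ground_truth", "algorithm")
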