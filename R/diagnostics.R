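#' Diagnostic accuracy of EIPH calls against a reference
#'
#' Compares each rater's per-slide EIPH classification (THS at the cut-off)
#' with a reference classification (e.g. the ground-truth THS or the mean
#' annotators' THS). Pooled accuracy is the observation-level mean over all
#' rater x slide calls, which equals the mean of the per-rater accuracies on
#' a complete design.
#'
#' @param ths_records stacked THS records for the evaluated raters.
#' @param reference THS records, one per slide (single reference rater).
#' @param cutoff diagnostic cut-off (default 75).
#' @return List with `per_rater` (named accuracies), `pooled`, `n_slides`,
#'   `reference_id`.
#' @export
diagnostic_accuracy <- function(ths_records, reference, cutoff = 75) {
  if (NROW(reference) == 0 || NROW(ths_records) == 0) stop("empty input")
  if (anyDuplicated(reference$slide_id)) {
    stop("reference must contain one record per slide")
  }
  ref_call <- classify_eiph(reference$ths, cutoff)
  names(ref_call) <- reference$slide_id
  raters <- sort(unique(ths_records$rater_id))
  per <- vapply(raters, function(r) {
    rec <- ths_records[ths_records$rater_id == r, ]
    if (!setequal(rec$slide_id, reference$slide_id)) {
      stop("rater ", r, " does not cover the reference slides")
    }
    mean(classify_eiph(rec$ths, cutoff) == ref_call[rec$slide_id])
  }, numeric(1))
  pooled <- mean(classify_eiph(ths_records$ths, cutoff) ==
                   ref_call[ths_records$slide_id])
  list(per_rater = per, pooled = pooled,
       n_slides = nrow(reference),
       reference_id = unique(reference$rater_id))
}

#' Fraction of slides with k-of-A consensus on the EIPH diagnosis
#'
#' A slide is consensual at level `k` when at least `k` of the `A` raters
#' agree on the diagnosis, i.e. `max(#positive, #negative) >= k`.
#'
#' @param ths_table S x A THS matrix ([ths_table()]).
#' @param cutoff diagnostic cut-off.
#' @param k required number of agreeing raters, `1 <= k <= A`.
#' @return Fraction of slides reaching consensus at `k`.
#' @export
#' @examples
#' tab <- matrix(c(100, 100, 100, 80, 40, 100), nrow = 3)
#' consensus_fraction(tab, k = 2)
consensus_fraction <- function(ths_table, cutoff = 75, k) {
  A <- ncol(ths_table)
  if (k < 1 || k > A) stop("k must be within 1..A")
  pos <- rowSums(ths_table >= cutoff)
  mean(pmax(pos, A - pos) >= k)
}

#' Spearman rank correlation, tolerant of censored values
#'
#' Rank correlation with average ranks for ties. Values censored at a
#' detection limit (e.g. iron < 0.4 umol/L) should be recorded at the limit;
#' they then enter as ties at the limit, which `floor_at` can also enforce.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param floor_at optional detection limit applied to `y` via `pmax`.
#' @return The Spearman correlation in \[-1, 1\], or `NA` (with a warning)
#'   when either vector is constant.
#' @export
rank_correlation <- function(x, y, floor_at = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (!is.null(floor_at)) y <- pmax(y, floor_at)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant vector: rank correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Assemble the diagnostic report of a simulated study
#'
#' Aggregates the outputs of the scoring, matching, agreement, and
#' diagnostic stages into one deterministic report structure: THS tables raw
#' and standardized, variance components and error reductions, the
#' uncertainty interval, diagnostic accuracies against the ground truth and
#' against the mean annotators' THS, the consensus curve over k, grade
#' confusion and matched fraction, and rank correlations with chemistry.
#'
#' @param ths_raw S x A THS matrix of the annotators.
#' @param ths_standardized matching grade-standardized matrix, or NULL.
#' @param ground_truth THS records of the reserved rater `"ground_truth"`,
#'   one per slide.
#' @param manifests slide manifests with chemistry columns filled, or NULL.
#' @param algorithm THS records of the reserved rater `"algorithm"` (one per
#'   slide), or NULL.
#' @param matched_fraction overall fraction of annotator spots matched to the
#'   ground truth, or NULL.
#' @param confusion pooled [grade_confusion()] against the ground truth, or
#'   NULL.
#' @param cutoff diagnostic cut-off.
#' @param coverage uncertainty-interval coverage.
#' @return Object of class `eiph_report` (a nested list, JSON-serializable
#'   via [report_to_json()]).
#' @export
build_report <- function(ths_raw, ths_standardized = NULL, ground_truth,
                         manifests = NULL, algorithm = NULL,
                         matched_fraction = NULL, confusion = NULL,
                         cutoff = 75, coverage = 0.8) {
  if (missing(ths_raw) || is.null(ths_raw)) stop("missing stage output: scoring (ths_raw)")
  if (missing(ground_truth) || is.null(ground_truth)) {
    stop("missing stage output: ground truth THS records")
  }
  S <- nrow(ths_raw); A <- ncol(ths_raw)
  gt <- ground_truth[match(rownames(ths_raw), ground_truth$slide_id), ]
  if (anyNA(gt$ths)) stop("ground truth does not cover all slides")

  mean_ann <- rowMeans(ths_raw)
  mean_ref <- data.frame(slide_id = rownames(ths_raw),
                         rater_id = "mean_annotators", ths = mean_ann,
                         stringsAsFactors = FALSE)
  long <- data.frame(
    slide_id = rep(rownames(ths_raw), A),
    rater_id = rep(colnames(ths_raw), each = S),
    ths = as.vector(ths_raw), stringsAsFactors = FALSE
  )

  errors <- measurement_errors(ths_raw)
  interval <- uncertainty_interval(errors, cutoff = cutoff,
                                   coverage = coverage)
  vc <- variance_components(ths_raw)

  report <- list(
    schema = "hemoscore-report/1",
    design = list(n_slides = S, n_annotators = A, cutoff = cutoff),
    ths = list(
      raw = .mat_to_list(ths_raw),
      standardized = if (!is.null(ths_standardized)) .mat_to_list(ths_standardized),
      ground_truth = stats::setNames(as.list(gt$ths), gt$slide_id),
      mean_annotators = stats::setNames(as.list(unname(mean_ann)),
                                        rownames(ths_raw)),
      algorithm = if (!is.null(algorithm)) {
        stats::setNames(as.list(algorithm$ths), algorithm$slide_id)
      }
    ),
    agreement = list(
      variance_components = unclass(vc)[c("sigma2_slide", "sigma2_annotator",
                                          "sigma2_residual", "icc_agreement",
                                          "error_partition")],
      error_reduction = if (!is.null(ths_standardized)) {
        red <- error_reduction(ths_raw, ths_standardized)
        list(overall = red$overall, between_annotator = red$between_annotator,
             residual = red$residual)
      },
      uncertainty_interval = unclass(interval)[c("q_low", "q_high", "lower",
                                                 "upper", "coverage")]
    ),
    accuracy = list(
      vs_ground_truth = diagnostic_accuracy(long, gt, cutoff),
      vs_mean_annotators = diagnostic_accuracy(long, mean_ref, cutoff),
      algorithm_vs_ground_truth = if (!is.null(algorithm)) {
        gt_alg <- gt[gt$slide_id %in% algorithm$slide_id, , drop = FALSE]
        diagnostic_accuracy(algorithm, gt_alg, cutoff)
      }
    ),
    consensus = list(
      k = seq_len(A),
      fraction = vapply(seq_len(A), function(k) {
        consensus_fraction(ths_raw, cutoff, k)
      }, numeric(1)),
      standardized_fraction = if (!is.null(ths_standardized)) {
        vapply(seq_len(A), function(k) {
          consensus_fraction(ths_standardized, cutoff, k)
        }, numeric(1))
      }
    ),
    matching = list(
      matched_fraction = matched_fraction,
      confusion = if (!is.null(confusion)) {
        list(matrix = unname(apply(confusion$matrix, 1, as.list)),
             accuracy = confusion$accuracy,
             one_off_fraction = confusion$one_off_fraction,
             a_higher_fraction = confusion$a_higher_fraction)
      }
    ),
    correlations = if (!is.null(manifests) && S >= 3) {
      mf <- manifests[match(rownames(ths_raw), manifests$slide_id), ]
      list(
        mean_annotators_vs_ground_truth = rank_correlation(mean_ann, gt$ths),
        mean_annotators_vs_iron = rank_correlation(mean_ann, mf$iron),
        mean_annotators_vs_rbc = rank_correlation(mean_ann, mf$rbc),
        mean_annotators_vs_hemoglobin = rank_correlation(mean_ann,
                                                         mf$hemoglobin),
        ground_truth_vs_iron = rank_correlation(gt$ths, mf$iron),
        algorithm_vs_ground_truth = if (!is.null(algorithm) &&
                                        nrow(algorithm) >= 3) {
          gt_alg <- gt[match(algorithm$slide_id, gt$slide_id), ]
          rank_correlation(algorithm$ths, gt_alg$ths)
        }
      )
    }
  )
  structure(report, class = c("eiph_report", "list"))
}

.mat_to_list <- function(m) {
  list(slides = rownames(m), raters = colnames(m),
       values = unname(apply(m, 1, as.list)))
}

#' Serialize a report to canonical JSON
#'
#' @param report an `eiph_report` from [build_report()] or [run_pipeline()].
#' @param path optional file path; when given the JSON is written there.
#' @return The JSON string, invisibly when written to file.
#' @export
report_to_json <- function(report, path = NULL) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 10,
                           null = "null", na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
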