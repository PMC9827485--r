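#' Variance components of a fully crossed slide-by-annotator THS table
#'
#' Decomposes THS variability under the two-way crossed random-effects model
#' `y_sa = mu + slide_s + annotator_a + e_sa` of a fully crossed, single
#' measurement agreement design. The slide component is true between-case
#' variability; the annotator component is the systematic error (reproducible
#' between-rater offsets); the residual is the random error (within-rater
#' inconsistency).
#'
#' The reference estimator (`method = "anova_mom"`) equates observed to
#' expected mean squares on the balanced table:
#' `sigma2_residual = MSE`, `sigma2_annotator = (MSA - MSE) / S`,
#' `sigma2_slide = (MSS - MSE) / A`, with negative estimates truncated to 0
#' (with a warning). `method = "reml"` fits the same model by REML through
#' \pkg{lme4} as a secondary route.
#'
#' Two ratio summaries are reported: `icc_agreement`, the conventional
#' agreement intraclass correlation
#' `sigma2_slide / (sigma2_slide + sigma2_annotator + sigma2_residual)`, and
#' `error_partition`, the share of the measurement error that is systematic,
#' `sigma2_annotator / (sigma2_annotator + sigma2_residual)`.
#'
#' @param table numeric S x A matrix (slides x annotators), complete; see
#'   [ths_table()].
#' @param method `"anova_mom"` (default, closed form) or `"reml"`.
#' @return Object of class `variance_components`: the three components, both
#'   ratios, `method`, and `degenerate` (TRUE when all components are 0, in
#'   which case the ratios are reported as 0).
#' @export
#' @examples
#' tab <- outer(c(50, 150, 250), c(-10, 0, 10), "+")
#' variance_components(tab)
variance_components <- function(table, method = c("anova_mom", "reml")) {
  method <- match.arg(method)
  if (!is.matrix(table) || !is.numeric(table)) {
    stop("table must be a numeric matrix (slides x annotators)")
  }
  if (anyNA(table)) stop("incomplete design: missing cells")
  S <- nrow(table); A <- ncol(table)
  if (S < 2 || A < 2) stop("need at least 2 slides and 2 annotators (S>=2, A>=2)")

  if (method == "anova_mom") {
    grand <- mean(table)
    row_m <- rowMeans(table)
    col_m <- colMeans(table)
    mss <- A * sum((row_m - grand)^2) / (S - 1)
    msa <- S * sum((col_m - grand)^2) / (A - 1)
    resid <- table - outer(row_m, rep(1, A)) -
      outer(rep(1, S), col_m) + grand
    mse <- sum(resid^2) / ((S - 1) * (A - 1))
    comp <- c(slide = (mss - mse) / A,
              annotator = (msa - mse) / S,
              residual = mse)
    if (any(comp < 0)) {
      warning("negative variance component estimate truncated to 0")
      comp <- pmax(comp, 0)
    }
  } else {
    long <- data.frame(
      y = as.vector(table),
      slide = factor(rep(rownames(table) %||% seq_len(S), A)),
      annotator = factor(rep(colnames(table) %||% seq_len(A), each = S))
    )
    fit <- lme4::lmer(y ~ 1 + (1 | slide) + (1 | annotator), data = long,
                      REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    get <- function(g) vc$vcov[match(g, vc$grp)]
    comp <- c(slide = get("slide"), annotator = get("annotator"),
              residual = get("Residual"))
  }

  tot <- sum(comp)
  err <- comp[["annotator"]] + comp[["residual"]]
  structure(list(
    sigma2_slide = comp[["slide"]],
    sigma2_annotator = comp[["annotator"]],
    sigma2_residual = comp[["residual"]],
    icc_agreement = if (tot > 0) comp[["slide"]] / tot else 0,
    error_partition = if (err > 0) comp[["annotator"]] / err else 0,
    method = method,
    degenerate = tot == 0
  ), class = "variance_components")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    paste0("variance_components (%s):\n",
           "  slide      %10.3f\n  annotator  %10.3f\n  residual   %10.3f\n",
           "  ICC (agreement)           %.3f\n",
           "  error partition (systematic share) %.3f\n"),
    x$method, x$sigma2_slide, x$sigma2_annotator, x$sigma2_residual,
    x$icc_agreement, x$error_partition))
  if (x$degenerate) cat("  (degenerate: all components zero)\n")
  invisible(x)
}

#' Measurement-error reduction due to grade standardization
#'
#' Fits the variance-component model to the THS table before and after grade
#' standardization and reports the percentage reduction of the overall
#' measurement error `sigma2_annotator + sigma2_residual`, of the
#' between-annotator (systematic) component, and of the residual (random)
#' component.
#'
#' @param raw THS table before standardization.
#' @param standardized THS table after [standardize_grades()]; same slides
#'   and annotators.
#' @param method estimator passed to [variance_components()].
#' @return Object of class `error_reduction` with percentages `overall`,
#'   `between_annotator`, `residual` (NA with `undefined` flag where the raw
#'   component is 0) and the two component fits.
#' @export
error_reduction <- function(raw, standardized, method = "anova_mom") {
  if (!identical(dim(raw), dim(standardized))) {
    stop("raw and standardized tables must share slides and annotators")
  }
  if (!is.null(dimnames(raw)) && !is.null(dimnames(standardized)) &&
      !identical(dimnames(raw), dimnames(standardized))) {
    stop("raw and standardized tables must share slides and annotators")
  }
  vr <- variance_components(raw, method = method)
  vs <- variance_components(standardized, method = method)
  pct <- function(num_raw, num_std) {
    if (num_raw <= 0) NA_real_ else 100 * (1 - num_std / num_raw)
  }
  overall_raw <- vr$sigma2_annotator + vr$sigma2_residual
  overall_std <- vs$sigma2_annotator + vs$sigma2_residual
  structure(list(
    overall = pct(overall_raw, overall_std),
    between_annotator = pct(vr$sigma2_annotator, vs$sigma2_annotator),
    residual = pct(vr$sigma2_residual, vs$sigma2_residual),
    undefined = c(overall = overall_raw <= 0,
                  between_annotator = vr$sigma2_annotator <= 0,
                  residual = vr$sigma2_residual <= 0),
    raw = vr, standardized = vs
  ), class = "error_reduction")
}

#' @export
print.error_reduction <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", v)
  cat("error_reduction due to grade standardization:\n",
      "  overall:           ", fmt(x$overall), "\n",
      "  between-annotator: ", fmt(x$between_annotator), "\n",
      "  residual:          ", fmt(x$residual), "\n", sep = "")
  invisible(x)
}

#' Per-observation measurement errors of a THS table
#'
#' The measurement error of annotator a on slide s is the difference between
#' that annotator's THS and the mean THS of all annotators on the slide:
#' `e_sa = y_sa - mean_a(y_s.)`. Errors are centered within each slide by
#' construction.
#'
#' @param table S x A THS matrix.
#' @return S x A numeric matrix of signed errors (score points).
#' @export
measurement_errors <- function(table) {
  if (!is.matrix(table) || anyNA(table)) stop("table must be complete")
  sweep(table, 1, rowMeans(table))
}

#' Diagnostic uncertainty interval around the EIPH cut-off
#'
#' Maps the spread of the annotators' measurement errors onto the diagnostic
#' cut-off: with the default 80% coverage the interval runs from
#' `cutoff + q10(errors)` to `cutoff + q90(errors)`. THS values inside the
#' interval do not reproducibly yield the same EIPH diagnosis across raters.
#' Quantiles use linear interpolation of order statistics
#' ([stats::quantile()] type 7); the convention is exposed because interval
#' bounds at fixed data depend on it.
#'
#' @param errors numeric vector (or matrix) of signed measurement errors.
#' @param cutoff diagnostic cut-off (default 75).
#' @param coverage nominal interior coverage in (0, 1) (default 0.8).
#' @param type quantile type passed to [stats::quantile()].
#' @return Object of class `uncertainty_interval`: `q_low`, `q_high`
#'   (error-scale quantiles), `lower`, `upper` (THS scale), `coverage`,
#'   `cutoff`.
#' @export
#' @examples
#' uncertainty_interval(seq(-50, 50, by = 10))  # [35, 115]
uncertainty_interval <- function(errors, cutoff = 75, coverage = 0.8,
                                 type = 7) {
  errors <- as.numeric(errors)
  if (length(errors) < 2) stop("need at least 2 errors")
  if (!is.finite(coverage) || coverage <= 0 || coverage >= 1) {
    stop("coverage must be in (0, 1)")
  }
  alpha <- (1 - coverage) / 2
  q <- stats::quantile(errors, probs = c(alpha, 1 - alpha), type = type,
                       names = FALSE)
  structure(list(
    q_low = q[1], q_high = q[2],
    lower = cutoff + q[1], upper = cutoff + q[2],
    coverage = coverage, cutoff = cutoff
  ), class = "uncertainty_interval")
}

#' @export
print.uncertainty_interval <- function(x, ...) {
  cat(sprintf(
    "%.0f%% uncertainty interval around THS cut-off %g: [%.1f, %.1f]\n",
    100 * x$coverage, x$cutoff, x$lower, x$upper))
  invisible(x)
}
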