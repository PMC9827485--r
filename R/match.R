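#' Match two point-annotation sets of one slide
#'
#' Two spot annotations are considered the same cell when the Euclidean
#' distance between their center coordinates is at most `max_distance`
#' (50 px at the study's 0.25 um/px scale). Among all one-to-one assignments
#' restricted to such candidate pairs, the match of maximum cardinality and,
#' among those, minimum total matched distance is returned. Feasibility at
#' the radius is decided on squared distances so behaviour at exactly 50 px
#' is not subject to square-root rounding. Ties between equal-cost optima are
#' broken deterministically towards low set-a then low set-b indices via an
#' infinitesimal index perturbation of the cost.
#'
#' @param set_a,set_b annotation tables from the same slide.
#' @param max_distance matching radius in pixels (default 50).
#' @return An object of class `match_result`: list with `pairs` (data.frame
#'   `index_a`, `index_b`, `distance`), `unmatched_a`, `unmatched_b` (integer
#'   row indices), and `max_distance`.
#' @export
#' @examples
#' a <- cell_annotations("s", "r1", x = c(0, 10), y = 0, grade = c(1, 2))
#' b <- cell_annotations("s", "r2", x = 4, y = 0, grade = 1)
#' match_annotations(a, b)$pairs
match_annotations <- function(set_a, set_b, max_distance = 50) {
  if (NROW(set_a) && NROW(set_b)) {
    slides <- unique(c(set_a$slide_id, set_b$slide_id))
    if (length(slides) != 1L) stop("annotation sets span different slides")
  }
  na <- NROW(set_a); nb <- NROW(set_b)
  empty <- function() {
    structure(list(
      pairs = data.frame(index_a = integer(0), index_b = integer(0),
                         distance = numeric(0)),
      unmatched_a = seq_len(na), unmatched_b = seq_len(nb),
      max_distance = max_distance
    ), class = "match_result")
  }
  if (na == 0 || nb == 0) return(empty())

  d2 <- outer(set_a$x, set_b$x, "-")^2 + outer(set_a$y, set_b$y, "-")^2
  feasible <- d2 <= max_distance^2
  if (!any(feasible)) return(empty())

  # restrict the assignment problem to annotations with at least one
  # candidate partner; at default cell spacing (> 2 * radius) the candidate
  # graph is a disjoint set of single edges and no solver is needed
  ai <- which(rowSums(feasible) > 0)
  bi <- which(colSums(feasible) > 0)
  sub <- feasible[ai, bi, drop = FALSE]
  if (all(rowSums(sub) == 1) && all(colSums(sub) == 1)) {
    idx <- which(sub, arr.ind = TRUE)
    pa <- ai[idx[, 1]]; pb <- bi[idx[, 2]]
  } else {
    cost <- sqrt(d2[ai, bi, drop = FALSE])
    big <- sum(cost[sub]) + max_distance + 1
    # tiny index preference: < 1 ulp of any real distance difference we care
    # about, but makes the chosen optimum deterministic and order-stable
    eps <- 1e-9 / (length(ai) * length(bi))
    pert <- outer(seq_along(ai), seq_along(bi),
                  function(i, j) (i - 1) * length(bi) + (j - 1)) * eps
    m <- length(ai); n <- length(bi)
    C <- matrix(4 * big, m + n, m + n)
    Cab <- cost + pert
    Cab[!sub] <- 4 * big
    C[seq_len(m), seq_len(n)] <- Cab
    for (i in seq_len(m)) C[i, n + i] <- big
    for (j in seq_len(n)) C[m + j, j] <- big
    C[m + seq_len(n), n + seq_len(m)] <- 0
    sol <- clue::solve_LSAP(C)
    ia <- seq_len(m)
    ja <- as.integer(sol[ia])
    keep <- ja <= n & sub[cbind(ia, pmin(ja, n))]
    pa <- ai[ia[keep]]; pb <- bi[ja[keep]]
  }
  ord <- order(pa)
  pairs <- data.frame(index_a = pa[ord], index_b = pb[ord],
                      distance = sqrt(d2[cbind(pa[ord], pb[ord])]))
  structure(list(
    pairs = pairs,
    unmatched_a = setdiff(seq_len(na), pairs$index_a),
    unmatched_b = setdiff(seq_len(nb), pairs$index_b),
    max_distance = max_distance
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("match_result:", nrow(x$pairs), "pairs,",
      length(x$unmatched_a), "unmatched in A,",
      length(x$unmatched_b), "unmatched in B",
      sprintf("(radius %g px)\n", x$max_distance))
  invisible(x)
}

#' Standardize an annotator's grades against a reference set
#'
#' Exchanges each annotator grade with the grade of the matched reference
#' cell (e.g. the ground-truth annotation set), keeping the annotator's
#' coordinates and cell selection. Annotations without a match within the
#' radius are excluded from the standardized set, mirroring the exclusion of
#' unmatched annotations from standardized grading.
#'
#' @param annotator_set annotations to standardize.
#' @param reference_set reference annotations of the same slide.
#' @param max_distance matching radius in pixels.
#' @return The matched subset of `annotator_set` with grades replaced by the
#'   reference grades.
#' @export
standardize_grades <- function(annotator_set, reference_set,
                               max_distance = 50) {
  if (NROW(reference_set) == 0) stop("empty reference set")
  m <- match_annotations(annotator_set, reference_set,
                         max_distance = max_distance)
  out <- annotator_set[m$pairs$index_a, , drop = FALSE]
  out$grade <- reference_set$grade[m$pairs$index_b]
  rownames(out) <- NULL
  out
}

#' Grade confusion over matched annotation pairs
#'
#' Tabulates the 5x5 grade confusion between two raters over the matched
#' pairs only (unmatched annotations carry no comparable grade). Reports the
#' same-grade accuracy, the fraction of divergent pairs differing by exactly
#' one grade level, and the fraction of divergent pairs where rater A graded
#' higher than rater B.
#'
#' @param match a [match_annotations()] result for (`set_a`, `set_b`).
#' @param set_a,set_b the annotation sets the match was computed from.
#' @return An object of class `grade_confusion`: `matrix` (5x5 counts, rows =
#'   A's grade 0..4, columns = B's), `n_pairs`, `accuracy`,
#'   `one_off_fraction`, `a_higher_fraction`, and `no_divergent` (TRUE when
#'   all pairs agree, in which case the divergent-pair fractions are reported
#'   as 0).
#' @export
grade_confusion <- function(match, set_a, set_b) {
  if (nrow(match$pairs) == 0) stop("no matched cells")
  .grade_confusion_core(set_a$grade[match$pairs$index_a],
                        set_b$grade[match$pairs$index_b])
}

# core over paired grade vectors; also used to pool matches across
# slides and annotators
.grade_confusion_core <- function(ga, gb) {
  if (length(ga) == 0) stop("no matched cells")
  lev <- 0:4
  mat <- table(factor(ga, levels = lev), factor(gb, levels = lev))
  mat <- matrix(as.integer(mat), 5, 5,
                dimnames = list(as.character(lev), as.character(lev)))
  n <- length(ga)
  agree <- sum(ga == gb)
  div <- n - agree
  structure(list(
    matrix = mat,
    n_pairs = n,
    accuracy = agree / n,
    one_off_fraction = if (div > 0) sum(abs(ga - gb) == 1) / div else 0,
    a_higher_fraction = if (div > 0) sum(ga > gb) / div else 0,
    no_divergent = div == 0
  ), class = "grade_confusion")
}

#' @export
print.grade_confusion <- function(x, ...) {
  cat(sprintf(
    "grade_confusion: %d pairs, accuracy %.1f%%, one-off %.1f%%, A-higher %.1f%%%s\n",
    x$n_pairs, 100 * x$accuracy, 100 * x$one_off_fraction,
    100 * x$a_higher_fraction,
    if (x$no_divergent) " (no divergent pairs)" else ""))
  print(x$matrix)
  invisible(x)
}
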