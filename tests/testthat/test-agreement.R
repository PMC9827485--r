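test_that("pure annotator offsets load entirely on the systematic component", {
  tab <- matrix(rep(c(0, 10, 20, 30), each = 5), nrow = 5)
  dimnames(tab) <- list(paste0("s", 1:5), paste0("a", 1:4))
  vc <- variance_components(tab)
  expect_equal(vc$sigma2_residual, 0)
  expect_equal(vc$sigma2_slide, 0)
  expect_gt(vc$sigma2_annotator, 0)
  expect_equal(vc$error_partition, 1)
  expect_equal(vc$icc_agreement, 0)
})

test_that("a constant table is degenerate with zero components", {
  tab <- matrix(100, 4, 3)
  vc <- variance_components(tab)
  expect_equal(vc$sigma2_slide + vc$sigma2_annotator + vc$sigma2_residual, 0)
  expect_true(vc$degenerate)
  expect_equal(vc$icc_agreement, 0)
  expect_equal(vc$error_partition, 0)
})

test_that("design requirements are enforced", {
  expect_error(variance_components(matrix(1:4, 1, 4)), "S>=2")
  expect_error(variance_components(matrix(1:4, 4, 1)), "S>=2")
  tab <- matrix(rnorm(12), 4, 3)
  tab[2, 2] <- NA
  expect_error(variance_components(tab), "incomplete")
})

test_that("method-of-moments estimates recover known variance components", {
  # crossed design at the study scale: S=52 slides, A=10 annotators
  set.seed(88)
  S <- 52; A <- 10
  truth <- c(slide = 2500, annotator = 900, residual = 400)
  est <- matrix(NA_real_, 200, 3)
  for (r in 1:200) {
    y <- 150 + rnorm(S, 0, sqrt(truth[1]))[row(matrix(0, S, A))] +
      rnorm(A, 0, sqrt(truth[2]))[col(matrix(0, S, A))] +
      rnorm(S * A, 0, sqrt(truth[3]))
    y <- matrix(y, S, A)
    vc <- variance_components(y)
    est[r, ] <- c(vc$sigma2_slide, vc$sigma2_annotator, vc$sigma2_residual)
  }
  expect_equal(colMeans(est), unname(truth), tolerance = 0.10)
})

test_that("MoM agrees with the independent REML fit on a generic table", {
  set.seed(9)
  tab <- 150 + outer(rnorm(20, 0, 50), rep(1, 6)) +
    outer(rep(1, 20), rnorm(6, 0, 30)) + matrix(rnorm(120, 0, 20), 20)
  mom <- variance_components(tab, method = "anova_mom")
  reml <- variance_components(tab, method = "reml")
  expect_equal(mom$sigma2_slide, reml$sigma2_slide, tolerance = 0.02)
  expect_equal(mom$sigma2_annotator, reml$sigma2_annotator, tolerance = 0.02)
  expect_equal(mom$sigma2_residual, reml$sigma2_residual, tolerance = 0.02)
})

test_that("components reconstruct the grand variance and ratios are
           scale-invariant", {
  set.seed(10)
  tab <- 100 + outer(rnorm(12, 0, 40), rep(1, 5)) +
    outer(rep(1, 12), rnorm(5, 0, 25)) + matrix(rnorm(60, 0, 15), 12)
  vc <- variance_components(tab)
  # MoM identity: total sample variance ~ sum of components
  expect_equal(vc$sigma2_slide + vc$sigma2_annotator + vc$sigma2_residual,
               stats::var(as.vector(tab)), tolerance = 0.15)
  vc2 <- variance_components(tab * 3.7)
  expect_equal(vc2$icc_agreement, vc$icc_agreement)
  expect_equal(vc2$error_partition, vc$error_partition)
})

test_that("error reduction is 0% for identical tables, 100% for removed
           offsets, undefined for zero raw components", {
  set.seed(11)
  noise <- matrix(rnorm(40, 0, 10), 8, 5)
  offsets <- outer(rep(1, 8), c(-20, -10, 0, 10, 20))
  raw <- 150 + offsets + noise
  red0 <- suppressWarnings(error_reduction(raw, raw))
  expect_equal(red0$overall, 0)
  expect_equal(red0$between_annotator, 0)
  expect_equal(red0$residual, 0)
  # removing the annotator offsets wipes the systematic component (the
  # noise-only table yields a slightly negative MoM annotator estimate,
  # truncated to 0 with a warning by design)
  red <- suppressWarnings(error_reduction(raw, 150 + noise))
  expect_equal(red$between_annotator, 100, tolerance = 1e-6)
  # raw table without any systematic error: that reduction is undefined
  red_na <- suppressWarnings(error_reduction(150 + noise, 150 + noise / 2))
  expect_true(is.na(red_na$between_annotator))
  expect_true(red_na$undefined[["between_annotator"]])
  expect_error(error_reduction(raw, raw[, 1:3]), "share")
})

test_that("measurement errors are slide-centered differences to the mean", {
  tab <- matrix(c(60, 80), 1, 2)
  expect_equal(as.vector(measurement_errors(tab)), c(-10, 10))
  expect_equal(measurement_errors(matrix(5, 3, 4)),
               matrix(0, 3, 4))
  set.seed(12)
  tab2 <- matrix(runif(50, 0, 400), 10, 5)
  e <- measurement_errors(tab2)
  expect_equal(rowSums(e), rep(0, 10))  # centering identity per slide
})

test_that("the uncertainty interval interpolates error quantiles around the
           cut-off", {
  ui <- uncertainty_interval(seq(-50, 50, by = 10))
  expect_equal(ui$q_low, -40)
  expect_equal(ui$q_high, 40)
  expect_equal(ui$lower, 35)
  expect_equal(ui$upper, 115)
  # degenerate zero-error case collapses onto the cut-off
  ui0 <- uncertainty_interval(c(0, 0, 0))
  expect_equal(c(ui0$lower, ui0$upper), c(75, 75))
  expect_error(uncertainty_interval(0), "at least 2")
  expect_error(uncertainty_interval(c(-1, 1), coverage = 1), "coverage")
  # width is monotone under a mean-preserving spread
  set.seed(13)
  e <- rnorm(500, 0, 10)
  wide <- uncertainty_interval(e * 2)
  narrow <- uncertainty_interval(e)
  expect_gte(wide$upper - wide$lower, narrow$upper - narrow$lower)
})
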