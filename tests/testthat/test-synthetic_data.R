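test_that("study generation is deterministic and honours the design", {
  cfg <- study_config(n_samples = 3, cell_range = c(320, 500))
  s1 <- generate_study(cfg, seed = 123)
  s2 <- generate_study(cfg, seed = 123)
  expect_identical(s1, s2)
  s3 <- generate_study(cfg, seed = 124)
  expect_false(identical(s1$cells$content, s3$cells$content))
  # paired slides per lavage sample carry both stains and one severity
  expect_equal(nrow(s1$manifests), 6)
  for (sm in split(s1$manifests, s1$manifests$sample_id)) {
    expect_setequal(sm$stain, c("prussian_blue", "turnbull_blue"))
    expect_equal(length(unique(sm$severity)), 1)
  }
  expect_true(all(s1$manifests$n_macrophages >= 320 &
                    s1$manifests$n_macrophages <= 500))
})

test_that("default study draws per-slide macrophage counts within 596-8954", {
  st <- generate_study(seed = 31)
  expect_equal(nrow(st$manifests), 52)
  expect_true(all(st$manifests$n_macrophages >= 596 &
                    st$manifests$n_macrophages <= 8954))
  counts <- table(st$cells$slide_id)
  expect_equal(sort(as.integer(counts)),
               sort(st$manifests$n_macrophages))
})

test_that("severity 0 yields all-grade-0 slides; severity 1 yields EIPH", {
  cfg0 <- study_config(n_samples = 2, cell_range = c(300, 340),
                       severity_range = c(0, 0))
  st0 <- generate_study(cfg0, seed = 7)
  expect_true(all(st0$cells$grade == 0))
  by_slide <- tapply(st0$cells$grade, st0$cells$slide_id,
                     function(g) 100 * mean(g))
  expect_true(all(by_slide == 0))
  cfg1 <- study_config(n_samples = 2, cell_range = c(300, 340),
                       severity_range = c(1, 1))
  st1 <- generate_study(cfg1, seed = 7)
  ths1 <- tapply(st1$cells$grade, st1$cells$slide_id,
                 function(g) 100 * mean(g))
  expect_true(all(ths1 >= 75))
})

test_that("generated cells respect spacing, extent, and the grade contract", {
  st <- desk_study(n_samples = 1, cell_range = c(320, 380), seed = 3,
                   stains = "prussian_blue")
  cells <- st$cells
  mf <- st$manifests[1, ]
  expect_true(all(cells$x >= 0 & cells$x <= mf$width))
  expect_true(all(cells$y >= 0 & cells$y <= mf$height))
  # minimum center spacing above twice the matching radius
  d <- as.matrix(stats::dist(cells[, c("x", "y")]))
  diag(d) <- Inf
  expect_gt(min(d), 100)
  # stored grades reproduce grade_from_content on stored contents
  expect_equal(cells$grade, grade_from_content(cells$content))
  # single-cell slide
  one <- generate_slide(
    data.frame(slide_id = "t", stain = "prussian_blue", severity = 0.5,
               n_macrophages = 1, width = 400, height = 400),
    seed = 1)
  expect_equal(nrow(one), 1)
  # extent too small for the requested count
  expect_error(generate_slide(
    data.frame(slide_id = "t", stain = "prussian_blue", severity = 0.5,
               n_macrophages = 100, width = 400, height = 400),
    seed = 1), "extent too small")
})

test_that("the identity annotator reproduces the ground truth exactly", {
  st <- desk_study(n_samples = 1, cell_range = c(310, 330), seed = 21,
                   stains = "prussian_blue")
  ident <- annotator_profile("ident")
  ann <- simulate_annotator(st$cells, ident, seed = 4)
  expect_equal(nrow(ann), 300)
  # every annotation coincides with a ground-truth cell, same grade
  key_gt <- paste(round(st$cells$x, 6), round(st$cells$y, 6), st$cells$grade)
  key_ann <- paste(round(ann$x, 6), round(ann$y, 6), ann$grade)
  expect_true(all(key_ann %in% key_gt))
})

test_that("annotator simulation is seeded, bounded, and pattern-complete", {
  st <- desk_study(n_samples = 1, cell_range = c(400, 420), seed = 22,
                   stains = "prussian_blue")
  for (pattern in c("uniform_random", "clustered_fields", "meander")) {
    p <- annotator_profile(paste0("p_", pattern), selection_pattern = pattern,
                           perception_sd = 0.05, jitter_sd = 10)
    a1 <- simulate_annotator(st$cells, p, seed = 5)
    a2 <- simulate_annotator(st$cells, p, seed = 5)
    expect_identical(a1, a2)
    expect_equal(nrow(a1), 300)
  }
  # n_target beyond available macrophages errors
  big <- annotator_profile("big", n_target = 1000)
  expect_error(simulate_annotator(st$cells, big, seed = 1), "exceeds")
  # profile validation
  expect_error(annotator_profile("x", misid_rate = 1), "misid_rate")
  expect_error(annotator_profile("ground_truth"), "reserved")
  expect_error(annotator_profile("x", n_target = 100), "protocol")
})

test_that("misidentified annotations stay unmatched at the expected rate", {
  st <- desk_study(n_samples = 2, cell_range = c(400, 500), seed = 23,
                   stains = "prussian_blue")
  frac <- vapply(st$manifests$slide_id, function(sid) {
    cells <- st$cells[st$cells$slide_id == sid, ]
    p <- annotator_profile(paste0("m", sid), misid_rate = 0.23,
                           jitter_sd = 10)
    ann <- simulate_annotator(cells, p, seed = substream_seed(77, sid))
    ref <- gt_annotations_of(st$cells, sid)
    m <- match_annotations(ann, ref)
    nrow(m$pairs) / nrow(ann)
  }, numeric(1))
  # binomial expectation 0.77; 2 slides x 300 annotations
  expect_equal(mean(frac), 0.77, tolerance = 0.05)
})

test_that("more negative threshold shifts inflate the expected THS bias", {
  st <- desk_study(n_samples = 2, cell_range = c(350, 450), seed = 24,
                   stains = "prussian_blue")
  bias_at <- function(shift) {
    mean(vapply(st$manifests$slide_id, function(sid) {
      cells <- st$cells[st$cells$slide_id == sid, ]
      p <- annotator_profile("b", threshold_shift = shift)
      ann <- simulate_annotator(cells, p, seed = substream_seed(3, sid))
      gt_ths <- 100 * mean(cells$grade)
      compute_ths(ann, allow_fewer = TRUE)$ths - gt_ths
    }, numeric(1)))
  }
  b0 <- bias_at(0)
  b1 <- bias_at(-0.05)
  b2 <- bias_at(-0.10)
  expect_gt(b1, b0)
  expect_gt(b2, b1)
  expect_gt(b2, 0)
})

test_that("chemistry is censored at the detection limit and tracks the THS", {
  mf <- data.frame(slide_id = "t", stain = "prussian_blue", severity = 0,
                   n_macrophages = 10, width = 100, height = 100,
                   iron = NA_real_, iron_censored = NA, rbc = NA_real_,
                   hemoglobin = NA_real_)
  # zero score, zero baseline: noise alone stays under the limit often;
  # whenever it does the value must sit exactly at the limit, flagged
  p0 <- chemistry_params(baseline = 0, noise_meanlog = log(0.01),
                         noise_sdlog = 0.1)
  out <- simulate_chemistry(mf, 0, p0, seed = 2)
  expect_true(out$iron_censored)
  expect_equal(out$iron, 0.4)
  expect_error(simulate_chemistry(mf, 500, p0, seed = 1), "0, 400")
  expect_error(chemistry_params(baseline = -1), "non-negative")

  st <- generate_study(study_config(cell_range = c(596, 1200)), seed = 41)
  manifests <- simulate_study_chemistry(st, seed = 41)
  gt_ths <- tapply(st$cells$grade, st$cells$slide_id,
                   function(g) 100 * mean(g))[manifests$slide_id]
  # censoring: no value strictly inside (0, 0.4)
  expect_true(all(manifests$iron >= 0.4 | manifests$iron == 0))
  # iron tracks chronic hemorrhage; acute markers do not
  expect_gt(rank_correlation(manifests$iron, as.numeric(gt_ths)), 0.6)
  expect_lt(abs(rank_correlation(manifests$rbc, as.numeric(gt_ths))), 0.3)
  expect_lt(abs(rank_correlation(manifests$hemoglobin, as.numeric(gt_ths))),
            0.3)
})

test_that("substream seeds are deterministic and label-sensitive", {
  expect_identical(substream_seed(1, "a"), substream_seed(1, "a"))
  expect_false(substream_seed(1, "a") == substream_seed(1, "b"))
  expect_false(substream_seed(1, "a") == substream_seed(2, "a"))
  s <- vapply(1:1000, function(i) substream_seed(5, "slide", i), integer(1))
  expect_true(all(s >= 1 & s <= 2^31 - 1))
})
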