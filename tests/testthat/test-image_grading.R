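# helper: a small rendered slide with well-separated cells of known content
render_fixture <- function(contents, seed = 1, stain = "prussian_blue",
                           distractor = FALSE, spacing = 140) {
  n <- length(contents) + as.integer(distractor)
  ncols <- ceiling(sqrt(n))
  xs <- ((seq_len(n) - 1) %% ncols + 0.5) * spacing
  ys <- ((seq_len(n) - 1) %/% ncols + 0.5) * spacing
  cells <- data.frame(
    slide_id = "img1", cell_id = sprintf("c%03d", seq_len(n)),
    x = xs, y = ys,
    content = c(contents, if (distractor) 0),
    grade = grade_from_content(c(contents, if (distractor) 0)),
    is_macrophage = c(rep(TRUE, length(contents)), if (distractor) FALSE),
    stringsAsFactors = FALSE
  )
  render_slide_image(cells, stain = stain, seed = seed)
}

test_that("rendering reproduces the requested pigment fractions", {
  rs <- render_fixture(c(0, 0.1, 0.3, 0.6, 0.9), seed = 2)
  expect_equal(rs$registry$pigment_fraction, c(0, 0.1, 0.3, 0.6, 0.9),
               tolerance = 0.02)
  expect_true(all(abs(rs$registry$pigment_fraction -
                        rs$registry$content) <= 0.05))
  # determinism
  rs2 <- render_fixture(c(0, 0.1, 0.3, 0.6, 0.9), seed = 2)
  expect_identical(rs$image, rs2$image)
  # empty cell list: blank background
  blank <- render_slide_image(
    data.frame(slide_id = character(0), cell_id = character(0),
               x = numeric(0), y = numeric(0), content = numeric(0),
               grade = integer(0), is_macrophage = logical(0)),
    seed = 1)
  expect_true(all(blank$image > 0.8))
  # cells outside the extent are rejected
  bad <- data.frame(slide_id = "b", cell_id = "c1", x = 395, y = 395,
                    content = 0, grade = 0L, is_macrophage = TRUE)
  expect_error(
    render_slide_image(bad, params = render_params(width = 400, height = 400),
                       seed = 1),
    "extent overflow")
})

test_that("pixel classification recovers the rendered classes", {
  # blank white image is pure background
  white <- array(1, c(20, 30, 3))
  cm <- classify_pixels(white)
  expect_true(all(cm == 0))
  # a pure-blue patch is pigment under default windows
  blue <- array(rep(c(0, 0, 1), each = 100), c(10, 10, 3))
  expect_true(all(classify_pixels(blue) == 3))
  expect_error(classify_pixels(matrix(1, 5, 5)), "RGB")
  # round trip on one rendered cell: pigment pixel count within 10%
  rs <- render_fixture(0.4, seed = 3)
  cm1 <- classify_pixels(rs$image, stain = rs$stain)
  pig_px <- sum(cm1 == 3)
  target <- rs$registry$pigment_fraction * rs$registry$cyto_px
  expect_equal(pig_px, target, tolerance = 0.10)
  # both stain variants land in the pigment window
  rs_tb <- render_fixture(0.4, seed = 3, stain = "turnbull_blue")
  cm_tb <- classify_pixels(rs_tb$image, stain = "turnbull_blue")
  expect_equal(sum(cm_tb == 3), target, tolerance = 0.10)
})

test_that("segmentation finds separated cells and rejects anucleate
           objects", {
  cm <- classify_pixels(render_fixture(c(0.2, 0.5), seed = 4)$image)
  cells <- segment_cells(cm)
  expect_equal(nrow(cells), 2)
  rs <- render_fixture(c(0.2, 0.5), seed = 4)
  d <- outer(cells$x, rs$registry$x[rs$registry$is_macrophage], "-")^2 +
    outer(cells$y, rs$registry$y[rs$registry$is_macrophage], "-")^2
  expect_true(all(apply(sqrt(d), 1, min) <= 10))
  # anucleate distractor is dropped by the nucleus rule
  rs_d <- render_fixture(c(0.2, 0.5), seed = 5, distractor = TRUE)
  cells_d <- segment_cells(classify_pixels(rs_d$image))
  expect_equal(nrow(cells_d), 2)
  # empty class map yields no cells
  empty <- structure(matrix(0L, 50, 50), class = "pixel_class_map")
  expect_equal(nrow(segment_cells(empty)), 0)
})

test_that("image scoring round-trips contents into grades and a THS", {
  contents <- c(0, 0.005, 0.1, 0.15, 0.3, 0.4, 0.55, 0.6, 0.8, 0.95)
  rs <- render_fixture(contents, seed = 6)
  sc <- score_image(rs, stain = rs$stain)
  expect_equal(nrow(sc$cells), length(contents))
  expect_equal(sc$ths_record$rater_id, "algorithm")
  expect_equal(sc$ths_record$slide_id, "img1")
  # per-cell grades: match detections to the registry and compare
  reg_ann <- cell_annotations("img1", "ground_truth", rs$registry$x,
                              rs$registry$y, rs$registry$grade)
  m <- match_annotations(sc$annotations, reg_ann)
  expect_equal(nrow(m$pairs), length(contents))
  expect_equal(sc$annotations$grade[m$pairs$index_a],
               reg_ann$grade[m$pairs$index_b])
  expect_equal(sc$ths_record$ths, 100 * mean(grade_from_content(contents)),
               tolerance = 0.01)
  # all grade-0 cells give THS 0
  rs0 <- render_fixture(rep(0, 9), seed = 7)
  expect_equal(score_image(rs0, stain = rs0$stain)$ths_record$ths, 0)
})

test_that("image grading is deterministic and monotone in content", {
  contents <- c(0.05, 0.2, 0.45, 0.7)
  rs <- render_fixture(contents, seed = 8)
  s1 <- score_image(rs, stain = rs$stain)
  s2 <- score_image(rs, stain = rs$stain)
  expect_identical(s1$annotations, s2$annotations)
  # raising every cell's content never lowers the algorithmic THS
  rs_up <- render_fixture(pmin(1, contents + 0.15), seed = 8)
  s_up <- score_image(rs_up, stain = rs_up$stain)
  expect_gte(s_up$ths_record$ths, s1$ths_record$ths)
})
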