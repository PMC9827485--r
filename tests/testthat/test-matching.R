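test_that("matching radius is inclusive at exactly 50 px and exact there", {
  a <- make_ann(0, 0, rater = "rA")
  b50 <- make_ann(30, 40, rater = "rB")   # distance exactly 50
  m <- match_annotations(a, b50)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$distance, 50)
  b51 <- make_ann(0, 51, rater = "rB")
  m2 <- match_annotations(a, b51)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$unmatched_a, 1L)
  expect_equal(m2$unmatched_b, 1L)
  # non-integer boundary: sqrt(50^2) must not be rounded past the radius
  bexact <- make_ann(sqrt(2) * 25, sqrt(2) * 25, rater = "rB")
  expect_equal(nrow(match_annotations(a, bexact)$pairs), 1)
})

test_that("assignment picks the minimum-distance one-to-one matching", {
  a <- make_ann(c(0, 10), c(0, 0), rater = "rA")
  b <- make_ann(4, 0, rater = "rB")
  m <- match_annotations(a, b)
  expect_equal(m$pairs$index_a, 1L)
  expect_equal(m$pairs$index_b, 1L)
  expect_equal(m$pairs$distance, 4)
  expect_equal(m$unmatched_a, 2L)
  # a greedy nearest-first matcher would fail this: (0,0)-(0,30) at 30 px
  # blocks (0,60)'s only partner unless assignment is globally optimal
  a2 <- make_ann(c(0, 0), c(0, 60), rater = "rA")
  b2 <- make_ann(c(0, 0), c(30, 35), rater = "rB")
  m2 <- match_annotations(a2, b2)
  expect_equal(nrow(m2$pairs), 2)
})

test_that("matching agrees with the brute-force assignment oracle", {
  set.seed(101)
  for (i in 1:120) {
    inst <- random_match_instance()
    m <- match_annotations(inst$a, inst$b)
    oracle <- brute_force_match(inst$a, inst$b)
    expect_equal(nrow(m$pairs), oracle$cardinality)
    expect_equal(sum(m$pairs$distance), oracle$total, tolerance = 1e-8)
    # invariants
    expect_true(all(m$pairs$distance <= 50))
    expect_false(anyDuplicated(m$pairs$index_a) > 0)
    expect_false(anyDuplicated(m$pairs$index_b) > 0)
  }
})

test_that("matching is invariant to annotation order and near-symmetric", {
  set.seed(202)
  for (i in 1:20) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- make_ann(runif(na, 0, 150), runif(na, 0, 150), rater = "rA")
    b <- make_ann(runif(nb, 0, 150), runif(nb, 0, 150), rater = "rB")
    m <- match_annotations(a, b)
    perm_a <- sample(na); perm_b <- sample(nb)
    mp <- match_annotations(a[perm_a, ], b[perm_b, ])
    # compare as coordinate-pair sets (continuous coords: distances distinct)
    key <- function(m, a, b) {
      sort(paste(round(a$x[m$pairs$index_a], 9),
                 round(b$x[m$pairs$index_b], 9)))
    }
    expect_equal(key(mp, a[perm_a, ], b[perm_b, ]), key(m, a, b))
    # swapping the sets preserves the matched pair set
    ms <- match_annotations(b, a)
    expect_equal(nrow(ms$pairs), nrow(m$pairs))
    expect_equal(sum(ms$pairs$distance), sum(m$pairs$distance),
                 tolerance = 1e-8)
  }
})

test_that("mixed slide ids are rejected", {
  a <- make_ann(0, 0, slide = "s1", rater = "rA")
  b <- make_ann(0, 0, slide = "s2", rater = "rB")
  expect_error(match_annotations(a, b), "different slides")
})

test_that("standardization swaps grades for matched cells and drops the rest", {
  a <- make_ann(c(0, 200), c(0, 0), grade = c(3, 2), rater = "rA")
  ref <- make_ann(5, 0, grade = 2, rater = "ground_truth")
  std <- standardize_grades(a, ref)
  expect_equal(nrow(std), 1)          # unmatched annotation excluded
  expect_equal(std$grade, 2L)         # reference grade adopted
  expect_equal(std$x, 0)              # annotator coordinates kept
  expect_equal(std$annotator_id, "rA")
  # identity reference: grades and count preserved
  self <- standardize_grades(a, a)
  expect_equal(self$grade, a$grade)
  expect_equal(nrow(self), nrow(a))
  expect_error(standardize_grades(a, a[0, ]), "empty reference")
})

test_that("grade confusion counts matched pairs and divergence fractions", {
  a <- make_ann(c(0, 100, 200), grade = c(0, 1, 2), rater = "rA")
  b <- make_ann(c(0, 100, 200), grade = c(1, 1, 4), rater = "rB")
  m <- match_annotations(a, b)
  conf <- grade_confusion(m, a, b)
  expect_equal(conf$n_pairs, 3)
  expect_equal(conf$accuracy, 1 / 3)
  expect_equal(conf$one_off_fraction, 1 / 2)   # of 2 divergent pairs, (0,1)
  expect_equal(conf$a_higher_fraction, 0)
  expect_equal(sum(conf$matrix), 3)
  expect_equal(conf$matrix["1", "1"], 1L)
  # swapped inputs: transposed matrix, complementary a-higher fraction
  ms <- match_annotations(b, a)
  conf_s <- grade_confusion(ms, b, a)
  expect_equal(conf_s$matrix, t(conf$matrix))
  expect_equal(conf_s$a_higher_fraction, 1 - conf$a_higher_fraction)
  # all-agreeing pairs: flagged, fractions reported as 0
  conf_id <- grade_confusion(match_annotations(a, a), a, a)
  expect_true(conf_id$no_divergent)
  expect_equal(conf_id$accuracy, 1)
  expect_equal(conf_id$one_off_fraction, 0)
  expect_error(grade_confusion(match_annotations(a, make_ann(900, rater = "rB")),
                               a, b), "no matched cells")
})

test_that("identity annotators match completely with diagonal confusion", {
  st <- desk_study(n_samples = 1, cell_range = c(320, 360), seed = 5,
                   stains = "prussian_blue")
  sid <- st$manifests$slide_id[1]
  ref <- gt_annotations_of(st$cells, sid)
  ident <- annotator_profile("ident", threshold_shift = 0, perception_sd = 0,
                             misid_rate = 0, jitter_sd = 0)
  ann <- simulate_annotator(st$cells, ident, seed = 9)
  m <- match_annotations(ann, ref)
  expect_equal(nrow(m$pairs), nrow(ann))       # matched fraction 1.0
  expect_equal(max(m$pairs$distance), 0)       # at distance 0
  conf <- grade_confusion(m, ann, ref)
  expect_equal(conf$accuracy, 1)
  expect_equal(sum(conf$matrix) - sum(diag(conf$matrix)), 0L)
})
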