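# Fixture builders and independent oracles shared across test files.

# quick annotation table builder
make_ann <- function(x, y = 0, grade = 0, slide = "s1", rater = "r1") {
  n <- length(x)
  cell_annotations(slide, rater, x, rep_len(y, n), rep_len(grade, n))
}

# Brute-force matching oracle: exhaustively enumerates every one-to-one
# assignment restricted to pairs within the radius, and returns the maximum
# cardinality and, among those, the minimum total distance. Independent of
# the package's assignment solver.
brute_force_match <- function(set_a, set_b, max_distance = 50) {
  na <- nrow(set_a); nb <- nrow(set_b)
  if (na == 0 || nb == 0) return(list(cardinality = 0L, total = 0))
  d2 <- outer(set_a$x, set_b$x, "-")^2 + outer(set_a$y, set_b$y, "-")^2
  feasible <- d2 <= max_distance^2
  d <- sqrt(d2)
  best <- list(cardinality = 0L, total = 0)
  recurse <- function(i, used_b, card, total) {
    if (i > na) {
      if (card > best$cardinality ||
          (card == best$cardinality && total < best$total - 1e-12)) {
        best <<- list(cardinality = card, total = total)
      }
      return(invisible(NULL))
    }
    # prune: even matching all remaining cannot beat the best cardinality
    remaining <- na - i + 1L
    if (card + remaining < best$cardinality) return(invisible(NULL))
    recurse(i + 1L, used_b, card, total)  # leave a_i unmatched
    for (j in which(feasible[i, ] & !used_b)) {
      used_b[j] <- TRUE
      recurse(i + 1L, used_b, card + 1L, total + d[i, j])
      used_b[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, nb), 0L, 0)
  best
}

# random matching instance with up to max_n points per set
random_match_instance <- function(max_n = 8, box = 250) {
  na <- sample(0:max_n, 1); nb <- sample(0:max_n, 1)
  list(
    a = if (na > 0) make_ann(runif(na, 0, box), runif(na, 0, box),
                             sample(0:4, na, TRUE), rater = "rA") else
      make_ann(numeric(0), numeric(0), integer(0), rater = "rA"),
    b = if (nb > 0) make_ann(runif(nb, 0, box), runif(nb, 0, box),
                             sample(0:4, nb, TRUE), rater = "rB") else
      make_ann(numeric(0), numeric(0), integer(0), rater = "rB")
  )
}

# small desk-scale study used by several end-to-end tests
desk_study <- function(n_samples = 4, cell_range = c(350, 600), seed = 11,
                       stains = c("prussian_blue", "turnbull_blue")) {
  generate_study(study_config(n_samples = n_samples, cell_range = cell_range,
                              stains = stains), seed = seed)
}

# ground-truth annotation set of one slide
gt_annotations_of <- function(cells, sid) {
  cc <- cells[cells$slide_id == sid, ]
  cell_annotations(cc$slide_id, "ground_truth", cc$x, cc$y, cc$grade)
}

# THS tables (raw and grade-standardized) for a panel of profiles on a study
panel_ths_tables <- function(study, profiles, seed, match_radius = 50) {
  slides <- study$manifests$slide_id
  raw <- list(); std <- list()
  for (sid in slides) {
    cells <- study$cells[study$cells$slide_id == sid, ]
    ref <- gt_annotations_of(study$cells, sid)
    for (p in profiles) {
      ann <- simulate_annotator(cells, p,
                                seed = substream_seed(seed, sid,
                                                      p$annotator_id),
                                match_radius = match_radius)
      key <- paste(sid, p$annotator_id)
      raw[[key]] <- compute_ths(ann, allow_fewer = TRUE)
      std_ann <- standardize_grades(ann, ref, max_distance = match_radius)
      std[[key]] <- compute_ths(std_ann, allow_fewer = TRUE)
    }
  }
  list(raw = ths_table(do.call(rbind, raw)),
       std = ths_table(do.call(rbind, std)))
}
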