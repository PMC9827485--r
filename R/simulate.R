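#' Default configuration of the simulated scoring study
#'
#' Returns the parameters of the synthetic study the package emulates: paired
#' iron-stained cytologic slides from bronchoalveolar lavage samples, each
#' carrying every alveolar macrophage as a ground-truth annotation. The
#' defaults mirror the structure of the motivating study: 26 lavage samples
#' each contributing one Prussian-blue and one Turnbull-blue slide (52 slides
#' total) with 596--8954 macrophages per slide.
#'
#' Cell hemosiderin content is a two-component mixture indexed by slide
#' severity: a "clean" component confined below the grade-1 threshold
#' (`clean_scale * Beta(clean_shape1, clean_shape2)`) and a "pigmented"
#' `Beta(pig_shape1, pig_shape2)` component whose mixture weight equals the
#' severity, so severity 0 yields an entirely grade-0 slide and severity 1 a
#' heavily pigmented one.
#'
#' Cell centers are placed on a jittered grid with minimum center spacing
#' `spacing` (default 110 px, more than twice the 50 px matching radius, so
#' matches are unambiguous at defaults).
#'
#' @param n_samples number of lavage samples (each yields one slide per stain).
#' @param stains stain(s) applied; paired slides share a sample and severity.
#' @param cell_range min/max macrophages per slide.
#' @param severity_range range of the per-sample severity, drawn uniformly.
#' @param spacing minimum center-to-center distance between cells (px).
#' @param jitter_amp half-width of the uniform placement jitter (px).
#' @param stain_content_offset additive content offset applied to
#'   Turnbull-stained slides (default 0; a positive value reproduces
#'   higher Turnbull scores).
#' @param clean_scale,clean_shape1,clean_shape2 clean-component parameters.
#' @param pig_shape1,pig_shape2 pigmented-component Beta parameters.
#' @param thresholds canonical grade thresholds.
#' @param chemistry chemistry simulation parameters, see [chemistry_params()].
#' @return A named list of study parameters.
#' @export
study_config <- function(n_samples = 26,
                         stains = c("prussian_blue", "turnbull_blue"),
                         cell_range = c(596, 8954),
                         severity_range = c(0.02, 0.85),
                         spacing = 110,
                         jitter_amp = 15,
                         stain_content_offset = 0,
                         clean_scale = 0.02, clean_shape1 = 1, clean_shape2 = 3,
                         pig_shape1 = 1.8, pig_shape2 = 1.2,
                         thresholds = hemosiderin_thresholds(),
                         chemistry = chemistry_params()) {
  stains <- match.arg(stains, c("prussian_blue", "turnbull_blue"),
                      several.ok = TRUE)
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (length(cell_range) != 2L || cell_range[1] < 1 ||
      cell_range[2] < cell_range[1]) {
    stop("invalid cell_range")
  }
  if (any(severity_range < 0 | severity_range > 1) ||
      severity_range[2] < severity_range[1]) {
    stop("invalid severity_range")
  }
  if (spacing <= 0 || jitter_amp < 0) stop("invalid spacing/jitter")
  list(
    n_samples = n_samples, stains = stains, cell_range = cell_range,
    severity_range = severity_range, spacing = spacing,
    jitter_amp = jitter_amp, stain_content_offset = stain_content_offset,
    clean_scale = clean_scale, clean_shape1 = clean_shape1,
    clean_shape2 = clean_shape2, pig_shape1 = pig_shape1,
    pig_shape2 = pig_shape2, thresholds = thresholds, chemistry = chemistry
  )
}

# grid pitch guaranteeing the minimum spacing under +/- jitter_amp jitter
.grid_pitch <- function(config) config$spacing + 2 * config$jitter_amp

.stain_abbrev <- c(prussian_blue = "pb", turnbull_blue = "tb")

#' Generate a synthetic scoring study
#'
#' Draws slide manifests and the complete ground-truth cell set for a
#' simulated study: per-sample severities, per-slide macrophage counts within
#' the configured range, grid-jittered non-overlapping cell coordinates, and
#' continuous hemosiderin contents graded through the canonical thresholds.
#' Fully deterministic: one master seed is expanded into per-slide substreams
#' via [substream_seed()].
#'
#' @param config study parameters from [study_config()].
#' @param seed master integer seed.
#' @return A list with `manifests` (one row per slide: `slide_id`,
#'   `sample_id`, `stain`, `severity`, `n_macrophages`, `width`, `height`,
#'   plus chemistry columns left `NA` until [simulate_chemistry()]) and
#'   `cells` (ground-truth table: `slide_id`, `cell_id`, `x`, `y`, `content`,
#'   `grade`, `is_macrophage`).
#' @export
#' @examples
#' st <- generate_study(study_config(n_samples = 2, cell_range = c(50, 80)),
#'                      seed = 1)
#' table(st$cells$grade)
generate_study <- function(config = study_config(), seed) {
  pitch <- .grid_pitch(config)
  manifests <- with_seed(substream_seed(seed, "study"), {
    rows <- list()
    for (i in seq_len(config$n_samples)) {
      severity <- stats::runif(1, config$severity_range[1],
                               config$severity_range[2])
      for (stain in config$stains) {
        n <- as.integer(round(stats::runif(1, config$cell_range[1],
                                           config$cell_range[2])))
        ncol_grid <- ceiling(sqrt(n))
        nrow_grid <- ceiling(n / ncol_grid)
        rows[[length(rows) + 1L]] <- data.frame(
          slide_id = sprintf("s%02d_%s", i, .stain_abbrev[[stain]]),
          sample_id = sprintf("sample%02d", i),
          stain = stain, severity = severity, n_macrophages = n,
          width = ncol_grid * pitch, height = nrow_grid * pitch,
          iron = NA_real_, iron_censored = NA,
          rbc = NA_real_, hemoglobin = NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
  cells <- do.call(rbind, lapply(seq_len(nrow(manifests)), function(k) {
    generate_slide(manifests[k, ],
                   seed = substream_seed(seed, "slide", manifests$slide_id[k]),
                   config = config)
  }))
  rownames(manifests) <- rownames(cells) <- NULL
  list(manifests = manifests, cells = cells)
}

#' Generate the ground-truth cells of one slide
#'
#' Realizes a slide manifest: places `n_macrophages` cell centers on a
#' jittered grid inside the slide extent (minimum center spacing
#' `config$spacing`), draws each cell's continuous hemosiderin content from
#' the severity-indexed mixture, and assigns its canonical grade.
#'
#' @param manifest one manifest row (see [generate_study()]).
#' @param seed integer seed for this slide's substream.
#' @param config study parameters.
#' @return Ground-truth cell `data.frame` for the slide.
#' @export
generate_slide <- function(manifest, seed, config = study_config()) {
  n <- manifest$n_macrophages
  if (n < 1) stop("n_macrophages must be >= 1")
  pitch <- .grid_pitch(config)
  ncol_grid <- floor(manifest$width / pitch)
  nrow_grid <- floor(manifest$height / pitch)
  if (ncol_grid * nrow_grid < n) {
    stop("slide extent too small for ", n, " cells at spacing ",
         config$spacing)
  }
  with_seed(seed, {
    sites <- sample.int(ncol_grid * nrow_grid, n)
    gx <- (sites - 1L) %% ncol_grid
    gy <- (sites - 1L) %/% ncol_grid
    x <- (gx + 0.5) * pitch + stats::runif(n, -config$jitter_amp,
                                           config$jitter_amp)
    y <- (gy + 0.5) * pitch + stats::runif(n, -config$jitter_amp,
                                           config$jitter_amp)
    pigmented <- stats::rbinom(n, 1, manifest$severity) == 1
    content <- numeric(n)
    content[!pigmented] <- config$clean_scale *
      stats::rbeta(sum(!pigmented), config$clean_shape1, config$clean_shape2)
    content[pigmented] <- stats::rbeta(sum(pigmented), config$pig_shape1,
                                       config$pig_shape2)
    if (manifest$stain == "turnbull_blue" && config$stain_content_offset != 0) {
      content <- pmin(1, pmax(0, content + config$stain_content_offset))
    }
    data.frame(
      slide_id = manifest$slide_id,
      cell_id = sprintf("%s_c%05d", manifest$slide_id, seq_len(n)),
      x = x, y = y, content = content,
      grade = grade_from_content(content, config$thresholds),
      is_macrophage = TRUE,
      stringsAsFactors = FALSE
    )
  })
}

#' Default annotator profiles
#'
#' Ten simulated annotators with heterogeneous systematic bias, random
#' perception error and selection behaviour, calibrated to the error
#' structure the interobserver analysis assumes: grade-threshold shifts are
#' predominantly negative (annotators tend to apply lower thresholds, i.e.
#' assign higher grades than the reference), per-cell perception noise is
#' moderate, about 23% of annotations land on non-macrophage objects, and
#' spot placement jitters by ~10 px.
#'
#' @param n number of annotators (<= 10 uses the first `n` default profiles;
#'   larger `n` recycles the bias pattern).
#' @param threshold_shift,perception_sd,misid_rate,jitter_sd,n_target optional
#'   overrides, recycled across annotators.
#' @return A list of profile lists with fields `annotator_id`,
#'   `threshold_shift`, `perception_sd`, `selection_pattern`, `n_target`,
#'   `misid_rate`, `jitter_sd`.
#' @export
annotator_profiles <- function(n = 10,
                               threshold_shift = NULL,
                               perception_sd = 0.06,
                               misid_rate = 0.23,
                               jitter_sd = 10,
                               n_target = 300) {
  default_shifts <- c(-0.10, -0.08, -0.065, -0.05, -0.04,
                      -0.03, -0.02, -0.01, 0.005, 0.02)
  shifts <- if (is.null(threshold_shift)) {
    rep_len(default_shifts, n)
  } else {
    rep_len(threshold_shift, n)
  }
  patterns <- rep_len(c("uniform_random", "clustered_fields", "meander"), n)
  lapply(seq_len(n), function(i) {
    annotator_profile(
      annotator_id = sprintf("annotator%02d", i),
      threshold_shift = shifts[i],
      perception_sd = rep_len(perception_sd, n)[i],
      selection_pattern = patterns[i],
      n_target = rep_len(n_target, n)[i],
      misid_rate = rep_len(misid_rate, n)[i],
      jitter_sd = rep_len(jitter_sd, n)[i]
    )
  })
}

#' Construct and validate a single annotator profile
#'
#' @param annotator_id rater identifier (must not be reserved).
#' @param threshold_shift signed shift applied to all grade thresholds
#'   (negative = grades inflated relative to the reference).
#' @param perception_sd sd of per-cell content perception noise (fraction).
#' @param selection_pattern how the annotator picks cells to enumerate.
#' @param n_target number of annotations to produce (protocol minimum 300).
#' @param misid_rate probability an annotation lands on a non-macrophage.
#' @param jitter_sd sd of the spot-placement jitter (px).
#' @param allow_small permit `n_target < 300` (off-protocol studies).
#' @return A validated profile list.
#' @export
annotator_profile <- function(annotator_id,
                              threshold_shift = 0,
                              perception_sd = 0,
                              selection_pattern = c("uniform_random",
                                                    "clustered_fields",
                                                    "meander"),
                              n_target = 300,
                              misid_rate = 0,
                              jitter_sd = 0,
                              allow_small = FALSE) {
  selection_pattern <- match.arg(selection_pattern)
  if (annotator_id %in% .reserved_raters) {
    stop("annotator_id '", annotator_id, "' is reserved")
  }
  if (misid_rate < 0 || misid_rate >= 1) stop("misid_rate must be in [0, 1)")
  if (perception_sd < 0 || jitter_sd < 0) stop("negative noise parameter")
  if (n_target < 300 && !allow_small) {
    stop("n_target below the 300-cell protocol minimum; set allow_small")
  }
  list(annotator_id = annotator_id, threshold_shift = threshold_shift,
       perception_sd = perception_sd, selection_pattern = selection_pattern,
       n_target = as.integer(n_target), misid_rate = misid_rate,
       jitter_sd = jitter_sd)
}

#' Simulate one annotator scoring one slide
#'
#' Selects `n_target` annotations following the profile's selection pattern,
#' perceives each selected cell's content with Gaussian noise, grades it
#' through thresholds shifted by `threshold_shift` (a negative shift lowers
#' every grade boundary and therefore inflates grades), jitters the spot
#' placement (truncated inside the matching radius so true cells stay
#' matchable), and replaces a binomial `misid_rate` fraction of annotations
#' with spots on non-macrophage locations at least `match_radius` away from
#' every true cell (graded 0--1, emulating unpigmented leukocytes).
#'
#' @param cells ground-truth cells of one slide ([generate_slide()]).
#' @param profile annotator profile ([annotator_profile()]).
#' @param seed integer seed.
#' @param match_radius matching radius in px (used to truncate jitter and to
#'   place misidentified annotations out of reach).
#' @param thresholds base grade thresholds before the profile shift.
#' @return Annotation `data.frame` (see [cell_annotations()]).
#' @export
simulate_annotator <- function(cells, profile, seed, match_radius = 50,
                               thresholds = hemosiderin_thresholds()) {
  macro <- cells[cells$is_macrophage, , drop = FALSE]
  n_avail <- nrow(macro)
  if (n_avail < profile$n_target) {
    stop("n_target (", profile$n_target, ") exceeds available macrophages (",
         n_avail, ")")
  }
  slide <- unique(cells$slide_id)
  if (length(slide) != 1L) stop("cells span several slides")
  with_seed(seed, {
    n_mis <- stats::rbinom(1, profile$n_target, profile$misid_rate)
    n_sel <- profile$n_target - n_mis
    sel <- switch(profile$selection_pattern,
      uniform_random = sample.int(n_avail, n_sel),
      clustered_fields = {
        n_fields <- max(3L, min(8L, ceiling(n_sel / 60)))
        centers <- macro[sample.int(n_avail, n_fields), c("x", "y")]
        dmin <- Reduce(pmin, lapply(seq_len(n_fields), function(f) {
          sqrt((macro$x - centers$x[f])^2 + (macro$y - centers$y[f])^2)
        }))
        order(dmin)[seq_len(n_sel)]
      },
      meander = {
        band <- 3 * .grid_pitch(study_config())
        key <- floor(macro$y / band) * 1e7 +
          ifelse(floor(macro$y / band) %% 2 == 0, macro$x, -macro$x)
        order(key)[seq_len(n_sel)]
      }
    )
    chosen <- macro[sel, , drop = FALSE]

    # perception: noisy content graded through shifted thresholds
    perceived <- pmin(1, pmax(0, chosen$content +
                                stats::rnorm(n_sel, 0, profile$perception_sd)))
    th <- thresholds + profile$threshold_shift
    th <- pmin(pmax(th, 1e-6), 1 - 1e-6)
    grade <- grade_from_content(perceived, th)

    # spot placement jitter, truncated strictly inside the matching radius
    dx <- stats::rnorm(n_sel, 0, profile$jitter_sd)
    dy <- stats::rnorm(n_sel, 0, profile$jitter_sd)
    r <- sqrt(dx^2 + dy^2)
    cap <- 0.9 * match_radius
    scale <- ifelse(r > cap, cap / r, 1)
    ann <- data.frame(
      slide_id = slide, annotator_id = profile$annotator_id,
      x = pmax(0, chosen$x + dx * scale), y = pmax(0, chosen$y + dy * scale),
      grade = grade, stringsAsFactors = FALSE
    )

    if (n_mis > 0) {
      pts <- .sample_far_points(cells, n_mis, match_radius)
      mis <- data.frame(
        slide_id = slide, annotator_id = profile$annotator_id,
        x = pts$x, y = pts$y,
        grade = sample(0:1, n_mis, replace = TRUE, prob = c(0.8, 0.2)),
        stringsAsFactors = FALSE
      )
      ann <- rbind(ann, mis)
    }
    validate_annotations(ann)
  })
}

# rejection-sample points >= radius away from every cell center
.sample_far_points <- function(cells, n, radius) {
  xmax <- max(cells$x); ymax <- max(cells$y)
  out_x <- numeric(0); out_y <- numeric(0)
  tries <- 0L
  while (length(out_x) < n) {
    m <- (n - length(out_x)) * 4L
    px <- stats::runif(m, 0, xmax)
    py <- stats::runif(m, 0, ymax)
    ok <- vapply(seq_len(m), function(k) {
      min((cells$x - px[k])^2 + (cells$y - py[k])^2) >= radius^2
    }, logical(1))
    out_x <- c(out_x, px[ok]); out_y <- c(out_y, py[ok])
    tries <- tries + 1L
    if (tries > 200L) stop("could not place misidentified annotations")
  }
  list(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

#' Default chemistry simulation parameters
#'
#' Iron tracks chronic hemorrhage: it rises with the ground-truth THS through
#' a cell-density factor and multiplicative noise, and is censored below the
#' 0.4 umol/L detection limit of the assay. RBC count and hemoglobin are
#' acute-bleeding markers drawn independently of the THS.
#'
#' @param baseline iron intercept (umol/L).
#' @param slope iron rise over the full THS range (umol/L).
#' @param density_sdlog log-sd of the per-slide cell-density factor.
#' @param noise_meanlog,noise_sdlog lognormal additive noise parameters.
#' @param detection_limit censoring floor (umol/L).
#' @param rbc_meanlog,rbc_sdlog lognormal RBC count (cells/uL) parameters.
#' @param hgb_meanlog,hgb_sdlog lognormal hemoglobin (g/L) parameters.
#' @return Parameter list.
#' @export
chemistry_params <- function(baseline = 0.15, slope = 4.0,
                             density_sdlog = 0.3,
                             noise_meanlog = log(0.08), noise_sdlog = 0.6,
                             detection_limit = 0.4,
                             rbc_meanlog = log(300), rbc_sdlog = 1.0,
                             hgb_meanlog = log(0.4), hgb_sdlog = 0.6) {
  p <- list(baseline = baseline, slope = slope, density_sdlog = density_sdlog,
            noise_meanlog = noise_meanlog, noise_sdlog = noise_sdlog,
            detection_limit = detection_limit, rbc_meanlog = rbc_meanlog,
            rbc_sdlog = rbc_sdlog, hgb_meanlog = hgb_meanlog,
            hgb_sdlog = hgb_sdlog)
  if (baseline < 0 || slope < 0 || density_sdlog < 0 || noise_sdlog < 0 ||
      detection_limit < 0 || rbc_sdlog < 0 || hgb_sdlog < 0) {
    stop("chemistry parameters must be non-negative")
  }
  p
}

#' Simulate lavage-fluid chemistry for one slide
#'
#' Fills the manifest's `iron`, `rbc` and `hemoglobin` fields. Iron is
#' `baseline + slope * (ths/400) * density + lognormal noise` with values
#' below the detection limit recorded at the limit and flagged censored (no
#' emitted value falls strictly between 0 and the limit). RBC and hemoglobin
#' are drawn independently of the THS.
#'
#' @param manifest one manifest row.
#' @param ground_truth_ths the slide's ground-truth THS in \[0, 400\].
#' @param params [chemistry_params()].
#' @param seed integer seed.
#' @return The manifest row with chemistry fields filled.
#' @export
simulate_chemistry <- function(manifest, ground_truth_ths,
                               params = chemistry_params(), seed) {
  if (!is.finite(ground_truth_ths) || ground_truth_ths < 0 ||
      ground_truth_ths > 400) {
    stop("ground_truth_ths must be in [0, 400]")
  }
  with_seed(seed, {
    density <- exp(stats::rnorm(1, 0, params$density_sdlog))
    iron <- params$baseline +
      params$slope * (ground_truth_ths / 400) * density +
      stats::rlnorm(1, params$noise_meanlog, params$noise_sdlog)
    censored <- iron < params$detection_limit
    manifest$iron <- if (censored) params$detection_limit else iron
    manifest$iron_censored <- censored
    manifest$rbc <- stats::rlnorm(1, params$rbc_meanlog, params$rbc_sdlog)
    manifest$hemoglobin <- stats::rlnorm(1, params$hgb_meanlog,
                                         params$hgb_sdlog)
    manifest
  })
}

#' Simulate chemistry for every slide of a study
#'
#' Convenience wrapper applying [simulate_chemistry()] per slide under
#' per-slide substreams, using each slide's ground-truth THS.
#'
#' @param study list with `manifests` and `cells` ([generate_study()]).
#' @param params [chemistry_params()].
#' @param seed master seed.
#' @return The manifests with chemistry columns filled.
#' @export
simulate_study_chemistry <- function(study, params = chemistry_params(),
                                     seed) {
  manifests <- study$manifests
  for (k in seq_len(nrow(manifests))) {
    sid <- manifests$slide_id[k]
    gt <- 100 * mean(study$cells$grade[study$cells$slide_id == sid])
    manifests[k, ] <- simulate_chemistry(
      manifests[k, ], gt, params,
      seed = substream_seed(seed, "chemistry", sid)
    )
  }
  manifests
}
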