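#' Read a cell-annotation CSV
#'
#' Expects a header with columns `slide_id`, `annotator_id`, `x_px`, `y_px`,
#' `grade` (UTF-8, "." decimal). Every row is validated; errors name the
#' offending row and field.
#'
#' @param path CSV path.
#' @return Annotation `data.frame` (see [cell_annotations()]).
#' @export
read_annotations <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  required <- c("slide_id", "annotator_id", "x_px", "y_px", "grade")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  check_num <- function(v, field, pattern, msg) {
    bad <- which(!grepl(pattern, trimws(v)))
    if (length(bad)) {
      stop("row ", bad[1], ": invalid ", field, " (", msg, "): '",
           v[bad[1]], "'")
    }
  }
  num_re <- "^[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$"
  check_num(raw$x_px, "x_px", num_re, "non-negative number required")
  check_num(raw$y_px, "y_px", num_re, "non-negative number required")
  check_num(raw$grade, "grade", "^[0-4]$", "integer 0-4 required")
  cell_annotations(raw$slide_id, raw$annotator_id,
                   as.numeric(raw$x_px), as.numeric(raw$y_px),
                   as.integer(raw$grade))
}

#' Write a cell-annotation CSV
#'
#' Canonical column order (`slide_id`, `annotator_id`, `x_px`, `y_px`,
#' `grade`) and deterministic row order (slide, then annotator, then input
#' cell order), so identical records always produce byte-identical files.
#'
#' @param records annotation `data.frame`.
#' @param path output CSV path.
#' @export
write_annotations <- function(records, path) {
  if (NROW(records)) {
    records <- validate_annotations(records)
    ord <- order(records$slide_id, records$annotator_id)
    records <- records[ord, ]
  }
  out <- data.frame(slide_id = records$slide_id,
                    annotator_id = records$annotator_id,
                    x_px = records$x, y_px = records$y,
                    grade = records$grade, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a slide-by-rater THS table as wide CSV
#'
#' Rows are slides, columns raters; the first column holds the slide id.
#'
#' @param table S x A THS matrix with dimnames.
#' @param path CSV path.
#' @export
write_ths_table <- function(table, path) {
  df <- data.frame(slide_id = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ths_table
#' @export
read_ths_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Assemble a full pipeline run configuration
#'
#' Bundles every tunable of the simulated-study pipeline: the master seed,
#' the study generator parameters, the annotator panel, the diagnostic
#' cut-off and matching radius, the uncertainty-interval convention, and how
#' many slides to render and grade through the image stage.
#'
#' @param seed master integer seed.
#' @param study [study_config()].
#' @param annotators list of [annotator_profile()]s.
#' @param cutoff diagnostic cut-off (score points).
#' @param match_radius matching radius (px).
#' @param min_cells protocol minimum cell count per THS.
#' @param allow_fewer accept THS over fewer than `min_cells` cells.
#' @param coverage uncertainty-interval coverage.
#' @param quantile_type quantile convention ([stats::quantile()] type).
#' @param image_slides how many slides (smallest first) to render and score
#'   with the rule-based image grader; 0 disables the image stage.
#' @param render [render_params()].
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1,
                       study = study_config(),
                       annotators = annotator_profiles(),
                       cutoff = 75,
                       match_radius = 50,
                       min_cells = 300,
                       allow_fewer = FALSE,
                       coverage = 0.8,
                       quantile_type = 7,
                       image_slides = 0,
                       render = render_params()) {
  structure(list(seed = seed, study = study, annotators = annotators,
                 cutoff = cutoff, match_radius = match_radius,
                 min_cells = min_cells, allow_fewer = allow_fewer,
                 coverage = coverage, quantile_type = quantile_type,
                 image_slides = image_slides, render = render),
            class = c("run_config", "list"))
}

#' Write / read a run configuration as YAML
#'
#' The YAML file round-trips losslessly through [run_config()] semantics and
#' carries the explicit `seed`.
#'
#' @param config a `run_config`.
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  writeLines(yaml::as.yaml(unclass(config), precision = 15), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = c("run_config", "list"))
}

# 32-bit FNV-1a hash of the canonical JSON of a config, for provenance
config_hash <- function(config) {
  s <- as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                     digits = 10))
  h <- 2166136261
  for (code in utf8ToInt(s)) {
    # xor the low byte only (codes are < 256); h stays a double
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), code)
    # 32-bit multiply by the FNV prime 16777619, done in two 16-bit halves
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full simulated-study pipeline
#'
#' Executes, under one master seed, the stages of the scoring study:
#' simulate (slides, ground truth, chemistry), annotate (the configured
#' annotator panel), image (render and grade a subset of slides with the
#' rule-based grader), score (THS tables), match/standardize (against the
#' ground truth), agreement (variance components, error reduction,
#' uncertainty interval), and diagnostics (accuracies, consensus,
#' correlations), assembled by [build_report()]. Stage timings and seeds are
#' logged via `message()`; any stage error aborts with the stage name and
#' config hash. Every output is reproducible byte-for-byte from (config,
#' seed).
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, manifests, ground truth,
#'   annotations, THS tables and the JSON report are written there.
#' @param quiet suppress stage messages.
#' @return The `eiph_report` list, with a `provenance` element recording the
#'   seed and config hash.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         quiet = FALSE) {
  hash <- config_hash(config)
  seed <- config$seed
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed [config ", hash, "]: ",
           conditionMessage(e), call. = FALSE)
    })
    say("stage %-12s %6.1fs [seed %d, config %s]", name,
        proc.time()[["elapsed"]] - t0, seed, hash)
    res
  }

  sim <- stage("simulate", {
    st <- generate_study(config$study, seed = seed)
    st$manifests <- simulate_study_chemistry(st, config$study$chemistry,
                                             seed = seed)
    st
  })
  slides <- sim$manifests$slide_id
  cells_by_slide <- split(sim$cells, sim$cells$slide_id)[slides]

  annotations <- stage("annotate", {
    out <- list()
    for (sid in slides) {
      for (p in config$annotators) {
        out[[paste(sid, p$annotator_id)]] <- simulate_annotator(
          cells_by_slide[[sid]], p,
          seed = substream_seed(seed, "annotate", sid, p$annotator_id),
          match_radius = config$match_radius,
          thresholds = config$study$thresholds
        )
      }
    }
    out
  })

  gt_annotations <- lapply(cells_by_slide, function(cc) {
    cell_annotations(cc$slide_id, "ground_truth", cc$x, cc$y, cc$grade)
  })
  gt_records <- stage("score", {
    gt <- do.call(rbind, lapply(gt_annotations, compute_ths,
                                allow_fewer = TRUE, cutoff = config$cutoff))
    rownames(gt) <- NULL
    gt
  })
  raw_records <- do.call(rbind, lapply(annotations, compute_ths,
                                       min_cells = config$min_cells,
                                       allow_fewer = config$allow_fewer,
                                       cutoff = config$cutoff))
  ths_raw <- ths_table(raw_records)

  algorithm <- if (config$image_slides > 0) {
    stage("image", {
      chosen <- sim$manifests$slide_id[
        order(sim$manifests$n_macrophages)][seq_len(config$image_slides)]
      recs <- lapply(chosen, function(sid) {
        rs <- render_slide_image(
          cells_by_slide[[sid]],
          stain = sim$manifests$stain[sim$manifests$slide_id == sid],
          params = config$render,
          seed = substream_seed(seed, "render", sid)
        )
        score_image(rs, stain = rs$stain,
                    thresholds = config$study$thresholds,
                    cutoff = config$cutoff)$ths_record
      })
      do.call(rbind, recs)
    })
  }

  std <- stage("standardize", {
    ga_pool <- integer(0); gb_pool <- integer(0)
    n_total <- 0L; n_matched <- 0L
    std_records <- list()
    for (sid in slides) {
      ref <- gt_annotations[[sid]]
      for (p in config$annotators) {
        key <- paste(sid, p$annotator_id)
        ann <- annotations[[key]]
        m <- match_annotations(ann, ref, max_distance = config$match_radius)
        n_total <- n_total + nrow(ann)
        n_matched <- n_matched + nrow(m$pairs)
        ga_pool <- c(ga_pool, ann$grade[m$pairs$index_a])
        gb_pool <- c(gb_pool, ref$grade[m$pairs$index_b])
        std_ann <- ann[m$pairs$index_a, , drop = FALSE]
        std_ann$grade <- ref$grade[m$pairs$index_b]
        std_records[[key]] <- compute_ths(std_ann, allow_fewer = TRUE,
                                          cutoff = config$cutoff)
      }
    }
    list(
      table = ths_table(do.call(rbind, std_records)),
      matched_fraction = n_matched / n_total,
      confusion = .grade_confusion_core(ga_pool, gb_pool)
    )
  })

  report <- stage("report", {
    build_report(
      ths_raw = ths_raw, ths_standardized = std$table,
      ground_truth = gt_records, manifests = sim$manifests,
      algorithm = algorithm, matched_fraction = std$matched_fraction,
      confusion = std$confusion, cutoff = config$cutoff,
      coverage = config$coverage
    )
  })
  report$provenance <- list(seed = seed, config_hash = hash)

  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(sim$manifests, file.path(out_dir, "manifests.csv"),
                       row.names = FALSE, quote = FALSE)
      gt_all <- do.call(rbind, gt_annotations)
      write_annotations(gt_all, file.path(out_dir, "ground_truth.csv"))
      write_annotations(do.call(rbind, annotations),
                        file.path(out_dir, "annotations.csv"))
      write_ths_table(ths_raw, file.path(out_dir, "ths_raw.csv"))
      write_ths_table(std$table, file.path(out_dir, "ths_standardized.csv"))
      report_to_json(report, file.path(out_dir, "report.json"))
      invisible(NULL)
    })
  }
  report
}
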