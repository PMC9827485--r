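#' Default rendering parameters for synthetic iron-stained cytology
#'
#' The renderer draws each alveolar macrophage as an elliptical cytoplasm
#' with an eccentric Nuclear-Fast-Red-toned nucleus and blue hemosiderin
#' granules covering a pixel fraction of the cytoplasm equal to the cell's
#' continuous content. The two iron stains differ only in pigment hue
#' (Prussian blue deeper/bluer, Turnbull's blue greener). The background is
#' near-white with additive Gaussian noise.
#'
#' @param cyto_radius min/max ellipse semi-axes (px); ~60-70 px cell
#'   diameters at the study's 0.25 um/px scale.
#' @param nucleus_radius min/max nucleus radius (px).
#' @param granule_radius hemosiderin granule radius (px); small granules give
#'   fine control of the rendered pigment fraction.
#' @param background background intensity in \[0, 1\].
#' @param noise_sd additive pixel noise sd.
#' @param cytoplasm,nucleus,pigment_prussian,pigment_turnbull RGB triplets.
#' @param margin blank border around the outermost cells (px) when the
#'   extent is derived from the cells.
#' @param width,height optional fixed extent (px).
#' @return Parameter list.
#' @export
render_params <- function(cyto_radius = c(26, 34),
                          nucleus_radius = c(8, 11),
                          granule_radius = 2,
                          background = 0.96,
                          noise_sd = 0.008,
                          cytoplasm = c(0.84, 0.80, 0.82),
                          nucleus = c(0.78, 0.30, 0.42),
                          pigment_prussian = c(0.12, 0.30, 0.70),
                          pigment_turnbull = c(0.10, 0.44, 0.62),
                          margin = 70,
                          width = NULL, height = NULL) {
  list(cyto_radius = cyto_radius, nucleus_radius = nucleus_radius,
       granule_radius = granule_radius, background = background,
       noise_sd = noise_sd, cytoplasm = cytoplasm, nucleus = nucleus,
       pigment_prussian = pigment_prussian,
       pigment_turnbull = pigment_turnbull, margin = margin,
       width = width, height = height)
}

#' Render a synthetic iron-stained slide image
#'
#' Rasterizes ground-truth cells into an RGB image together with a rendering
#' registry recording, per cell, the rendered centroid and the achieved
#' pigment pixel fraction (pigment pixels over cytoplasm pixels, nucleus
#' excluded). Cells flagged `is_macrophage = FALSE` are drawn without a
#' nucleus (anucleate distractors). Deterministic under `seed`.
#'
#' @param cells ground-truth cell table ([generate_slide()]); an empty table
#'   yields a blank background image.
#' @param stain `"prussian_blue"` or `"turnbull_blue"` (pigment hue only).
#' @param params [render_params()].
#' @param seed integer seed.
#' @return Object of class `rendered_slide`: `image` (height x width x 3
#'   array in \[0, 1\]), `registry` (per-cell data.frame with `x`, `y`,
#'   `content`, `grade`, `is_macrophage`, `pigment_fraction`, `cyto_px`),
#'   `stain`, `width`, `height`.
#' @export
render_slide_image <- function(cells,
                               stain = c("prussian_blue", "turnbull_blue"),
                               params = render_params(), seed) {
  stain <- match.arg(stain)
  n <- NROW(cells)
  rmax <- max(params$cyto_radius)
  if (n > 0) {
    width <- params$width %||% ceiling(max(cells$x) + params$margin)
    height <- params$height %||% ceiling(max(cells$y) + params$margin)
    if (any(cells$x - rmax < -1) || any(cells$y - rmax < -1) ||
        any(cells$x + rmax > width) || any(cells$y + rmax > height)) {
      stop("extent overflow: cells do not fit the image at the cell radius")
    }
  } else {
    width <- params$width %||% 400
    height <- params$height %||% 400
  }

  with_seed(seed, {
    R <- matrix(params$background, height, width)
    G <- matrix(params$background, height, width)
    B <- matrix(params$background, height, width)
    pig_col <- if (stain == "prussian_blue") params$pigment_prussian
               else params$pigment_turnbull

    reg <- vector("list", n)
    for (k in seq_len(n)) {
      cx <- cells$x[k]; cy <- cells$y[k]
      rx <- stats::runif(1, params$cyto_radius[1], params$cyto_radius[2])
      ry <- stats::runif(1, params$cyto_radius[1], params$cyto_radius[2])
      # pixel grid of the bounding box (1-based indices; x = col-1, y = row-1)
      cols <- max(1L, floor(cx + 1 - rx)):min(width, ceiling(cx + 1 + rx))
      rows <- max(1L, floor(cy + 1 - ry)):min(height, ceiling(cy + 1 + ry))
      px <- expand.grid(row = rows, col = cols)
      inside <- ((px$col - 1 - cx) / rx)^2 + ((px$row - 1 - cy) / ry)^2 <= 1
      px <- px[inside, ]
      idx <- (px$col - 1L) * height + px$row  # linear indices into matrices

      shade <- stats::rnorm(1, 0, 0.012)
      R[idx] <- params$cytoplasm[1] + shade
      G[idx] <- params$cytoplasm[2] + shade
      B[idx] <- params$cytoplasm[3] + shade

      is_macro <- isTRUE(cells$is_macrophage[k])
      nuc_mask <- rep(FALSE, nrow(px))
      if (is_macro) {
        nr <- stats::runif(1, params$nucleus_radius[1],
                           params$nucleus_radius[2])
        ang <- stats::runif(1, 0, 2 * pi)
        off <- stats::runif(1, 0, 0.35) * min(rx, ry)
        ncx <- cx + cos(ang) * off; ncy <- cy + sin(ang) * off
        nuc_mask <- (px$col - 1 - ncx)^2 + (px$row - 1 - ncy)^2 <= nr^2
        R[idx[nuc_mask]] <- params$nucleus[1] + shade
        G[idx[nuc_mask]] <- params$nucleus[2] + shade
        B[idx[nuc_mask]] <- params$nucleus[3] + shade
      }

      cyto <- which(!nuc_mask)
      n_cyto <- length(cyto)
      content <- cells$content[k]
      target <- round(content * n_cyto)
      pig_sel <- logical(nrow(px))
      if (target > 0) {
        gr2 <- params$granule_radius^2
        guard <- 0L
        while (sum(pig_sel[cyto]) < target && guard < 20000L) {
          ctr <- cyto[sample.int(n_cyto, 1)]
          gmask <- (px$col - px$col[ctr])^2 + (px$row - px$row[ctr])^2 <= gr2
          gmask[nuc_mask] <- FALSE
          new <- which(gmask & !pig_sel)
          need <- target - sum(pig_sel[cyto])
          if (length(new) > need) new <- new[seq_len(need)]
          pig_sel[new] <- TRUE
          guard <- guard + 1L
        }
        pidx <- idx[pig_sel]
        R[pidx] <- pig_col[1] + shade
        G[pidx] <- pig_col[2] + shade
        B[pidx] <- pig_col[3] + shade
      }

      reg[[k]] <- data.frame(
        slide_id = cells$slide_id[k], cell_id = cells$cell_id[k],
        x = cx, y = cy, content = content, grade = cells$grade[k],
        is_macrophage = is_macro,
        pigment_fraction = if (n_cyto > 0) sum(pig_sel[cyto]) / n_cyto else 0,
        cyto_px = n_cyto, stringsAsFactors = FALSE
      )
    }

    R <- R + stats::rnorm(length(R), 0, params$noise_sd)
    G <- G + stats::rnorm(length(G), 0, params$noise_sd)
    B <- B + stats::rnorm(length(B), 0, params$noise_sd)
    img <- array(c(pmin(pmax(R, 0), 1), pmin(pmax(G, 0), 1),
                   pmin(pmax(B, 0), 1)), dim = c(height, width, 3))
    registry <- if (n > 0) do.call(rbind, reg) else
      data.frame(slide_id = character(0), cell_id = character(0),
                 x = numeric(0), y = numeric(0), content = numeric(0),
                 grade = integer(0), is_macrophage = logical(0),
                 pigment_fraction = numeric(0), cyto_px = integer(0))
    rownames(registry) <- NULL
    structure(list(image = img, registry = registry, stain = stain,
                   width = width, height = height),
              class = "rendered_slide")
  })
}

#' @export
print.rendered_slide <- function(x, ...) {
  cat(sprintf("rendered_slide: %d x %d px, %s, %d cells\n",
              x$width, x$height, x$stain, nrow(x$registry)))
  invisible(x)
}

#' Write a rendered slide (or plain RGB array) to PNG
#'
#' @param image a `rendered_slide` or a height x width x 3 array in \[0, 1\].
#' @param path output PNG path.
#' @export
write_slide_png <- function(image, path) {
  if (inherits(image, "rendered_slide")) image <- image$image
  png::writePNG(image, path)
  invisible(path)
}

#' Read an RGB image from PNG
#'
#' @param path PNG path.
#' @return height x width x 3 numeric array in \[0, 1\].
#' @export
read_slide_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
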