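#' Default HSV windows for pixel classification
#'
#' Pixel classes are assigned from hue/saturation/value windows: blue
#' hemosiderin pigment (blue-cyan hue band, saturated), Nuclear-Fast-Red
#' nuclei (red hue band, saturated), near-white background (bright,
#' unsaturated), and cytoplasm (everything else). The pigment hue band is
#' wide enough for both the Prussian-blue and the greener Turnbull-blue
#' variant; per-stain overrides are accepted.
#'
#' @param stain stain the windows are tuned for.
#' @return List of window bounds (hue in \[0, 1\]).
#' @export
pixel_class_params <- function(stain = c("prussian_blue", "turnbull_blue")) {
  stain <- match.arg(stain)
  list(
    pigment_hue = c(0.45, 0.83),
    pigment_sat_min = 0.22,
    nucleus_hue_max = 0.08,   # red wraps around 0
    nucleus_hue_min = 0.85,
    nucleus_sat_min = 0.22,
    background_val_min = 0.90,
    background_sat_max = 0.20
  )
}

.pixel_levels <- c(background = 0L, cytoplasm = 1L, nucleus = 2L,
                   pigment = 3L)

#' Classify image pixels into cytologic classes
#'
#' Assigns every pixel of an 8-bit-equivalent RGB image to one of
#' background, cytoplasm, nucleus or (blue hemosiderin) pigment using the
#' HSV windows of [pixel_class_params()]. Precedence: pigment, nucleus,
#' background, cytoplasm.
#'
#' @param image height x width x 3 RGB array in \[0, 1\].
#' @param stain stain of the slide (selects default windows).
#' @param params window list, see [pixel_class_params()].
#' @return Object of class `pixel_class_map`: integer matrix (height x
#'   width) with values 0 = background, 1 = cytoplasm, 2 = nucleus,
#'   3 = pigment.
#' @export
classify_pixels <- function(image,
                            stain = c("prussian_blue", "turnbull_blue"),
                            params = NULL) {
  stain <- match.arg(stain)
  if (is.null(params)) params <- pixel_class_params(stain)
  if (length(dim(image)) != 3L || dim(image)[3] < 3) {
    stop("image must be an RGB array (height x width x 3)")
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  hsv <- grDevices::rgb2hsv(
    r = as.vector(image[, , 1]),
    g = as.vector(image[, , 2]),
    b = as.vector(image[, , 3]), maxColorValue = 1
  )
  hue <- hsv[1, ]; sat <- hsv[2, ]; val <- hsv[3, ]
  lab <- rep(.pixel_levels[["cytoplasm"]], h * w)
  is_bg <- val >= params$background_val_min & sat <= params$background_sat_max
  lab[is_bg] <- .pixel_levels[["background"]]
  is_nuc <- sat >= params$nucleus_sat_min &
    (hue <= params$nucleus_hue_max | hue >= params$nucleus_hue_min)
  lab[is_nuc] <- .pixel_levels[["nucleus"]]
  is_pig <- sat >= params$pigment_sat_min &
    hue >= params$pigment_hue[1] & hue <= params$pigment_hue[2]
  lab[is_pig] <- .pixel_levels[["pigment"]]
  structure(matrix(lab, h, w), class = "pixel_class_map")
}

#' Segment macrophage candidates from a pixel class map
#'
#' Connected components of the non-background classes after morphological
#' closing become cell candidates. Components larger than `max_area` are
#' split by watershed on the distance transform (touching cells); components
#' without any nucleus pixel are rejected (anucleate objects are not
#' macrophages), as are components outside the plausible area range. The
#' per-cell pigment fraction is pigment pixels over non-nucleus component
#' pixels, the same convention the renderer's registry uses.
#'
#' @param classmap a [classify_pixels()] result.
#' @param min_area,max_area plausible cell areas (px^2) at the study scale.
#' @param brush_size diameter of the closing brush (odd integer).
#' @return `data.frame` of detected cells: `x`, `y` (0-based centroid),
#'   `cell_area`, `nucleus_px`, `pigment_px`, `pigment_fraction`.
#' @export
segment_cells <- function(classmap, min_area = 800, max_area = 6000,
                          brush_size = 5) {
  cm <- unclass(classmap)
  mask <- cm > 0L
  if (!any(mask)) {
    return(data.frame(x = numeric(0), y = numeric(0), cell_area = integer(0),
                      nucleus_px = integer(0), pigment_px = integer(0),
                      pigment_fraction = numeric(0)))
  }
  closed <- EBImage::closing(EBImage::Image(mask * 1),
                             EBImage::makeBrush(brush_size, shape = "disc"))
  labels <- EBImage::bwlabel(closed > 0.5)
  lab <- EBImage::imageData(labels)

  # split oversized components (touching cells) by watershed on the
  # distance transform, restricted to those components
  areas <- tabulate(lab[lab > 0])
  if (any(areas > max_area)) {
    too_big <- which(areas > max_area)
    sub <- array(0, dim = dim(lab))
    sub[lab %in% too_big] <- 1
    wt <- EBImage::watershed(EBImage::distmap(EBImage::Image(sub)),
                             tolerance = 3, ext = 1)
    wt_lab <- EBImage::imageData(wt)
    offset <- max(lab)
    lab[sub == 1] <- wt_lab[sub == 1] + offset
  }

  ids <- sort(unique(lab[lab > 0]))
  out <- lapply(ids, function(id) {
    pix <- which(lab == id)
    area <- length(pix)
    if (area < min_area || area > max_area) return(NULL)
    cls <- cm[pix]
    nuc <- sum(cls == .pixel_levels[["nucleus"]])
    if (nuc == 0) return(NULL)  # anucleate: not a macrophage
    pig <- sum(cls == .pixel_levels[["pigment"]])
    rr <- (pix - 1L) %% nrow(cm) + 1L
    cc <- (pix - 1L) %/% nrow(cm) + 1L
    data.frame(x = mean(cc) - 1, y = mean(rr) - 1, cell_area = area,
               nucleus_px = nuc, pigment_px = pig,
               pigment_fraction = if (area > nuc) pig / (area - nuc) else 0)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(x = numeric(0), y = numeric(0), cell_area = integer(0),
                      nucleus_px = integer(0), pigment_px = integer(0),
                      pigment_fraction = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Score a rendered slide image with the rule-based grader
#'
#' The full image-grading pipeline: classify pixels, segment macrophage
#' candidates, grade each by its pigment fraction through the canonical
#' thresholds, and compute a THS over all detections under the reserved
#' rater id `"algorithm"`. Deterministic: same image and parameters give the
#' identical annotation set.
#'
#' @param image RGB array or `rendered_slide`.
#' @param stain stain of the slide.
#' @param slide_id slide identifier for the emitted annotations.
#' @param thresholds grade thresholds on the pigment fraction.
#' @param min_area,max_area passed to [segment_cells()].
#' @param pixel_params optional [pixel_class_params()] override.
#' @param allow_fewer accept fewer than 300 detections (sparse images).
#' @param cutoff diagnostic cut-off.
#' @return List with `annotations` (annotator_id `"algorithm"`), `cells`
#'   (the segmentation table with grades), and `ths_record`.
#' @export
score_image <- function(image, stain = c("prussian_blue", "turnbull_blue"),
                        slide_id = "slide",
                        thresholds = hemosiderin_thresholds(),
                        min_area = 800, max_area = 6000,
                        pixel_params = NULL, allow_fewer = TRUE,
                        cutoff = 75) {
  stain <- match.arg(stain)
  if (inherits(image, "rendered_slide")) {
    slide_ids <- unique(image$registry$slide_id)
    if (length(slide_ids) == 1L) slide_id <- slide_ids
    image <- image$image
  }
  cm <- classify_pixels(image, stain = stain, params = pixel_params)
  cells <- segment_cells(cm, min_area = min_area, max_area = max_area)
  if (nrow(cells) == 0) stop("no cells detected")
  cells$grade <- grade_from_content(pmin(1, cells$pigment_fraction),
                                    thresholds)
  ann <- cell_annotations(slide_id, "algorithm", cells$x, cells$y,
                          cells$grade)
  list(
    annotations = ann,
    cells = cells,
    ths_record = compute_ths(ann, allow_fewer = allow_fewer, cutoff = cutoff)
  )
}
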