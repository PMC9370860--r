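#' Configuration for automatic mask generation
#'
#' Parameters of the colour-threshold + morphological-cleanup labeller used
#' on controlled-environment images. The colour rule is a red-dominance
#' test; the cleanup drops small connected components (strictly below
#' `min_area`), removes protruding stems via erosion followed by an
#' eccentricity threshold on the moment-equivalent ellipse of each
#' component, restores surviving bodies by dilation, and finally fills
#' holes.
#'
#' @param red_min minimum red intensity (8-bit).
#' @param red_green_margin minimum R - G difference (8-bit).
#' @param red_blue_margin minimum R - B difference (8-bit).
#' @param min_area components with area strictly below this are removed.
#'   The default 64 px is calibrated for 256 x 256 frames; scale it
#'   quadratically with resolution (see [scaled_min_area()]).
#' @param erosion_radius disk radius (px) of the stem-separating erosion.
#' @param dilation_radius disk radius (px) of the restoring dilation.
#' @param eccentricity_max components whose post-erosion eccentricity
#'   exceeds this are discarded as stem-like; in \[0, 1).
#' @param connectivity 4 or 8 (component labeling).
#' @return An object of class `autolabel_config`.
#' @export
autolabel_config <- function(red_min = 130, red_green_margin = 40,
                             red_blue_margin = 40, min_area = 64,
                             erosion_radius = 3, dilation_radius = 3,
                             eccentricity_max = 0.92, connectivity = 8L) {
  if (min_area < 1) stopf("min_area must be >= 1")
  if (erosion_radius < 1) stopf("erosion_radius must be >= 1")
  if (dilation_radius < 1) stopf("dilation_radius must be >= 1")
  if (eccentricity_max < 0 || eccentricity_max >= 1)
    stopf("eccentricity_max must lie in [0, 1)")
  connectivity <- check_connectivity(connectivity)
  structure(list(red_min = red_min, red_green_margin = red_green_margin,
                 red_blue_margin = red_blue_margin, min_area = min_area,
                 erosion_radius = erosion_radius,
                 dilation_radius = dilation_radius,
                 eccentricity_max = eccentricity_max,
                 connectivity = connectivity),
            class = "autolabel_config")
}

#' @rdname autolabel_config
#' @param image_size (height, width) of the frames to be labelled.
#' @param ref_area the `min_area` appropriate at the reference 256 x 256
#'   resolution.
#' @return `scaled_min_area`: `min_area` rescaled by pixel count, >= 1.
#' @export
scaled_min_area <- function(image_size, ref_area = 64) {
  max(1, round(ref_area * prod(as.numeric(image_size)) / 256^2))
}

#' Per-pixel fruit colour thresholding
#'
#' Purely per-pixel red-dominance test: a pixel is fruit iff
#' `R >= red_min` and `R - G >= red_green_margin` and
#' `R - B >= red_blue_margin`. No spatial context is used.
#'
#' @param image H x W x 3 array of 8-bit RGB intensities.
#' @param config an [autolabel_config()].
#' @return Binary H x W mask.
#' @export
threshold_fruit_pixels <- function(image, config = autolabel_config()) {
  check_rgb_image(image)
  r <- image[, , 1]; gr <- image[, , 2]; b <- image[, , 3]
  (r >= config$red_min &
     (r - gr) >= config$red_green_margin &
     (r - b) >= config$red_blue_margin) + 0
}

#' Remove connected components smaller than a threshold
#'
#' Components with area strictly below `min_area` are zeroed; all other
#' pixels are unchanged, so the output is pixel-wise contained in the input.
#'
#' @param mask binary H x W matrix.
#' @param min_area minimum surviving area in pixels (>= 1).
#' @param connectivity 4 or 8.
#' @return Binary mask.
#' @export
remove_small_components <- function(mask, min_area, connectivity = 8L) {
  check_binary_mask(mask)
  if (min_area < 1) stopf("min_area must be >= 1")
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask)
  areas <- tabulate(lab, nbins = max(lab))
  keep <- which(areas >= min_area)
  (matrix(lab %in% keep, nrow(mask), ncol(mask))) + 0
}

#' Measure connected components as moment-equivalent ellipses
#'
#' For each connected component, area, centroid and the ellipse with the
#' same second-order central moments. Second moments carry the
#' pixel-as-unit-square correction (+1/12), so single-pixel and straight
#' one-pixel-wide components have well-defined axes. Eccentricity is
#' `sqrt(1 - (b/a)^2)` for semi-axes a >= b.
#'
#' @param mask binary H x W matrix.
#' @param connectivity 4 or 8.
#' @return Data frame with one row per component: `area`, `centroid_row`,
#'   `centroid_col` (0-based pixel coordinates), `ellipse_semi_major`,
#'   `ellipse_semi_minor`, `eccentricity`.
#' @export
measure_components <- function(mask, connectivity = 8L) {
  check_binary_mask(mask)
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  out <- data.frame(area = integer(0), centroid_row = numeric(0),
                    centroid_col = numeric(0),
                    ellipse_semi_major = numeric(0),
                    ellipse_semi_minor = numeric(0),
                    eccentricity = numeric(0))
  if (n == 0L) return(out)
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  for (k in seq_len(n)) {
    rows <- idx[labs == k, 1] - 1  # 0-based
    cols <- idx[labs == k, 2] - 1
    area <- length(rows)
    mr <- mean(rows); mc <- mean(cols)
    # central second moments with unit-square pixel correction
    mu_rr <- mean((rows - mr)^2) + 1 / 12
    mu_cc <- mean((cols - mc)^2) + 1 / 12
    mu_rc <- mean((rows - mr) * (cols - mc))
    common <- sqrt((mu_rr - mu_cc)^2 + 4 * mu_rc^2)
    l1 <- (mu_rr + mu_cc + common) / 2
    l2 <- (mu_rr + mu_cc - common) / 2
    a <- 2 * sqrt(l1); b <- 2 * sqrt(max(l2, 0))
    ecc <- if (a > 0) sqrt(max(0, 1 - (b / a)^2)) else 0
    out <- rbind(out, data.frame(area = area, centroid_row = mr,
                                 centroid_col = mc,
                                 ellipse_semi_major = a,
                                 ellipse_semi_minor = b,
                                 eccentricity = ecc))
  }
  out
}

#' Discard stem-like protrusions from a fruit mask
#'
#' Erodes by a disk of `erosion_radius` (detaching or deleting thin
#' protruding stems), drops every post-erosion component whose
#' moment-ellipse eccentricity exceeds `eccentricity_max`, then restores the
#' surviving bodies by a disk dilation of `dilation_radius`.
#'
#' @inheritParams threshold_fruit_pixels
#' @param mask binary H x W matrix.
#' @return Binary mask free of surviving high-eccentricity components.
#' @export
discard_stems <- function(mask, config = autolabel_config()) {
  check_binary_mask(mask)
  er <- erode_disk(mask, config$erosion_radius)
  lab <- label_components(er, config$connectivity)
  if (max(lab) > 0L) {
    shapes <- measure_components(er, config$connectivity)
    keep <- which(shapes$eccentricity <= config$eccentricity_max)
    er <- matrix(lab %in% keep, nrow(mask), ncol(mask)) + 0
  }
  dilate_disk(er, config$dilation_radius)
}

#' Fill interior holes of a binary mask
#'
#' Every background region not connected to the image border is set to
#' foreground, so the output contains the input pixel-wise. Background
#' connectivity is taken complementary to the foreground `connectivity`
#' (4 when the foreground is 8-connected, and vice versa).
#'
#' @param mask binary H x W matrix.
#' @param connectivity foreground connectivity, 4 or 8.
#' @return Binary mask with holes filled.
#' @export
fill_holes <- function(mask, connectivity = 8L) {
  check_binary_mask(mask)
  connectivity <- check_connectivity(connectivity)
  bg_conn <- if (connectivity == 8L) 4L else 8L
  h <- nrow(mask); w <- ncol(mask)
  bg <- mask == 0
  reach <- matrix(FALSE, h, w)
  reach[1, ] <- bg[1, ]; reach[h, ] <- bg[h, ]
  reach[, 1] <- bg[, 1]; reach[, w] <- bg[, w]
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (bg_conn == 8L)
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  repeat {
    new <- reach
    for (o in offs)
      new <- new | shift_mat(reach, o[1], o[2], fill = FALSE)
    new <- new & bg
    if (identical(new, reach)) break
    reach <- new
  }
  (!reach) + 0
}

#' Automatic mask generation for controlled-environment images
#'
#' The full labeller: per-pixel colour thresholding, then noise removal
#' ([remove_small_components()]), stem discarding ([discard_stems()]), and
#' hole filling ([fill_holes()]), in that order.
#'
#' @param image H x W x 3 array of 8-bit RGB intensities.
#' @param config an [autolabel_config()].
#' @return Binary H x W mask.
#' @export
autolabel <- function(image, config = autolabel_config()) {
  mask <- threshold_fruit_pixels(image, config)
  mask <- remove_small_components(mask, config$min_area, config$connectivity)
  mask <- discard_stems(mask, config)
  fill_holes(mask, config$connectivity)
}
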