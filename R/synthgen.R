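#' Scene specification for the synthetic orchard-style image generator
#'
#' Describes one synthetic scene. Four scene kinds mirror the acquisition
#' conditions the training cascade consumes:
#' \describe{
#'   \item{set1}{harvested fruits on a neutral grey background, uniform
#'     lighting (no shadows).}
#'   \item{set2}{same arrangement under harsh, non-uniform lighting: a
#'     multiplicative illumination gradient plus elliptical cast shadows.}
#'   \item{negative}{fruitless field-style background (foliage, branches,
#'     optionally dry-leaf blobs); the ground-truth mask is all zeros.}
#'   \item{field}{full field scene: foliage, branches, fruits under
#'     non-uniform light, and yellow-brown dry-leaf confuser blobs whose
#'     colour overlaps the fruit hue.}
#' }
#'
#' @param scene_kind one of `"set1"`, `"set2"`, `"negative"`, `"field"`.
#' @param image_size integer (height, width) in pixels, each >= 32.
#' @param n_fruits number of fruits; forced to 0 for negative scenes.
#' @param fruit_color_range 2 x 3 matrix of RGB lower/upper bounds for the
#'   per-fruit base colour. Default: deep red/crimson, R in \[150, 220\],
#'   G and B in \[20, 80\].
#' @param background_color RGB triple of the neutral background (set1/set2).
#' @param stem_probability probability that a fruit carries a protruding
#'   stem (stems are never part of the ground truth).
#' @param shadow_strength fraction in \[0, 1\] scaling the illumination
#'   gradient and cast shadows; must be 0 for set1.
#' @param confuser_count number of dry-leaf confuser blobs (field and
#'   negative scenes; must be 0 for set1/set2).
#' @param seed integer seed; identical specs (including seed) reproduce
#'   bit-identical scenes.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(scene_kind = c("set1", "set2", "negative", "field"),
                       image_size = c(96L, 96L),
                       n_fruits = NULL,
                       fruit_color_range = default_fruit_color_range(),
                       background_color = c(120, 120, 120),
                       stem_probability = 0.7,
                       shadow_strength = NULL,
                       confuser_count = NULL,
                       seed = 1L) {
  scene_kind <- match.arg(scene_kind)
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(!is.finite(image_size)) ||
      any(image_size < 32L))
    stopf("image_size must be two integers >= 32")
  if (is.null(n_fruits))
    n_fruits <- switch(scene_kind, set1 = 3L, set2 = 3L, negative = 0L,
                       field = 4L)
  n_fruits <- as.integer(n_fruits)
  if (is.na(n_fruits) || n_fruits < 0L) stopf("n_fruits must be >= 0")
  if (scene_kind == "negative" && n_fruits != 0L)
    stopf("negative scenes are fruit-free: n_fruits must be 0")
  if (scene_kind %in% c("set1", "set2") && n_fruits < 1L)
    stopf("%s scenes must contain at least one fruit", scene_kind)
  if (is.null(shadow_strength))
    shadow_strength <- switch(scene_kind, set1 = 0, set2 = 0.5,
                              negative = 0.4, field = 0.4)
  if (shadow_strength < 0 || shadow_strength > 1)
    stopf("shadow_strength must lie in [0, 1]")
  if (scene_kind == "set1" && shadow_strength != 0)
    stopf("set1 scenes have shadow_strength = 0")
  if (is.null(confuser_count))
    confuser_count <- switch(scene_kind, set1 = 0L, set2 = 0L,
                             negative = 4L, field = 5L)
  confuser_count <- as.integer(confuser_count)
  if (is.na(confuser_count) || confuser_count < 0L)
    stopf("confuser_count must be >= 0")
  if (scene_kind %in% c("set1", "set2") && confuser_count != 0L)
    stopf("%s scenes carry no confuser blobs", scene_kind)
  if (stem_probability < 0 || stem_probability > 1)
    stopf("stem_probability must lie in [0, 1]")
  fruit_color_range <- validate_color_range(fruit_color_range)
  structure(list(scene_kind = scene_kind, image_size = image_size,
                 n_fruits = n_fruits, fruit_color_range = fruit_color_range,
                 background_color = as.numeric(background_color),
                 stem_probability = stem_probability,
                 shadow_strength = shadow_strength,
                 confuser_count = confuser_count,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' @rdname scene_spec
#' @export
default_fruit_color_range <- function() {
  rbind(lo = c(150, 20, 20), hi = c(220, 80, 80))
}

validate_color_range <- function(rng) {
  rng <- as.matrix(rng)
  if (!all(dim(rng) == c(2L, 3L)) || any(rng < 0) || any(rng > 255) ||
      any(rng[1, ] > rng[2, ]))
    stopf("fruit_color_range must be a 2 x 3 matrix of RGB bounds in [0,255]")
  rng
}

# 0-based pixel-centre coordinate grids (origin top-left, row-major).
coord_grids <- function(h, w) {
  list(rr = matrix(0:(h - 1), h, w), cc = matrix(0:(w - 1), h, w, byrow = TRUE))
}

# Interior of a rotated ellipse evaluated at pixel centres; theta is the
# major-axis direction in the (col, row) plane.
ellipse_interior <- function(g, cy, cx, a, b, theta) {
  dx <- g$cc - cx; dy <- g$rr - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# Thick line segment (capsule without end caps beyond clamping) region.
segment_region <- function(g, y0, x0, theta, len, width) {
  dx <- cos(theta); dy <- sin(theta)
  px <- g$cc - x0; py <- g$rr - y0
  t <- pmin(pmax(px * dx + py * dy, 0), len)
  d2 <- (px - t * dx)^2 + (py - t * dy)^2
  d2 <= (width / 2)^2
}

paint <- function(img, region, color, noise_sd = 0) {
  n <- sum(region)
  if (n == 0L) return(img)
  for (ch in 1:3) {
    plane <- img[, , ch]
    val <- rep(color[ch], n)
    if (noise_sd > 0) val <- val + rnorm(n, 0, noise_sd)
    plane[region] <- val
    img[, , ch] <- plane
  }
  img
}

#' Generate one synthetic scene with exact ground truth
#'
#' Renders the scene described by `spec` and returns the image together with
#' its analytic ground-truth mask: fruit bodies are filled ellipses (axis
#' ratio in \[0.7, 1\]) and the mask covers fruit bodies only — protruding
#' stems, dry-leaf confusers, branches and foliage are background.
#'
#' @param spec a [scene_spec()].
#' @return A [labeled_sample] whose provenance is the scene kind. Attributes
#'   `scene_spec`, `fruits` (data frame of ellipse parameters, 0-based
#'   centre coordinates), `confusers`, and `regions` (logical stem and
#'   confuser pixel sets) expose the renderer's analytic shapes.
#' @export
generate_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) stopf("spec must be a scene_spec")
  with_rng(spec$seed, render_scene(spec))
}

render_scene <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  g <- coord_grids(h, w)
  smin <- min(h, w)
  img <- array(0, c(h, w, 3))
  field_like <- spec$scene_kind %in% c("negative", "field")

  ## --- background -------------------------------------------------------
  if (field_like) {
    base <- c(58, 108, 52)
    t1 <- box_mean(matrix(runif(h * w, -1, 1), h, w), 2)
    t2 <- box_mean(matrix(runif(h * w, -1, 1), h, w), 5)
    for (ch in 1:3)
      img[, , ch] <- base[ch] * (1 + 1.1 * t1 + 2.2 * t2)
  } else {
    for (ch in 1:3)
      img[, , ch] <- spec$background_color[ch] +
        matrix(rnorm(h * w, 0, 3), h, w)
  }

  ## --- branches (field-like scenes) -------------------------------------
  if (field_like) {
    n_branch <- sample(2:4, 1)
    for (i in seq_len(n_branch)) {
      y0 <- runif(1, 0, h - 1); x0 <- runif(1, 0, w - 1)
      theta <- runif(1, 0, pi)
      len <- runif(1, 0.5, 1.2) * smin
      width <- runif(1, 2.5, 5)
      img <- paint(img, segment_region(g, y0, x0, theta, len, width),
                   c(108, 78, 48), noise_sd = 4)
    }
  }

  ## --- fruit geometry ---------------------------------------------------
  # controlled acquisitions lay fruits out well apart on the surface, so
  # set1/set2 enforce non-touching placement; field fruits may cluster.
  # Controlled scenes are close-ups (large fruit); field-like scenes are
  # far views from the moving platform, so their fruits are leaf-scale.
  sep_gap <- if (field_like) -0.1 else 0.15
  fruit_scale <- if (field_like) c(0.05, 0.09) else c(0.09, 0.16)
  fruits <- data.frame(cy = numeric(0), cx = numeric(0), a = numeric(0),
                       b = numeric(0), theta = numeric(0))
  for (i in seq_len(spec$n_fruits)) {
    a <- runif(1, fruit_scale[1], fruit_scale[2]) * smin
    b <- a * runif(1, 0.7, 1.0)
    for (try in 1:40) {
      cy <- runif(1, a + 2, h - a - 3)
      cx <- runif(1, a + 2, w - a - 3)
      ok <- nrow(fruits) == 0 ||
        all(sqrt((fruits$cy - cy)^2 + (fruits$cx - cx)^2) >
              (1 + sep_gap) * (fruits$a + a))
      if (ok) break
    }
    # after 40 rejections accept the last draw (overlap allowed; the mask
    # is the union of ellipse interiors)
    fruits <- rbind(fruits, data.frame(cy = cy, cx = cx, a = a, b = b,
                                       theta = runif(1, 0, pi)))
  }

  ## --- confusers: dry-leaf blobs overlapping the fruit hue --------------
  confusers <- data.frame(cy = numeric(0), cx = numeric(0), a = numeric(0),
                          b = numeric(0), theta = numeric(0))
  confuser_region <- matrix(FALSE, h, w)
  for (i in seq_len(spec$confuser_count)) {
    a <- runif(1, 0.05, 0.09) * smin
    b <- a * runif(1, 0.35, 0.7)
    for (try in 1:25) {
      cy <- runif(1, a + 1, h - a - 2)
      cx <- runif(1, a + 1, w - a - 2)
      ok <- nrow(fruits) == 0 ||
        all(sqrt((fruits$cy - cy)^2 + (fruits$cx - cx)^2) >
              1.2 * (fruits$a + a))
      if (ok) break
    }
    theta <- runif(1, 0, pi)
    confusers <- rbind(confusers,
                       data.frame(cy = cy, cx = cx, a = a, b = b,
                                  theta = theta))
    region <- ellipse_interior(g, cy, cx, a, b, theta)
    color <- c(runif(1, 180, 220), runif(1, 140, 180), runif(1, 40, 90))
    img <- paint(img, region, color, noise_sd = 5)
    confuser_region <- confuser_region | region
  }

  ## --- stems, then fruit bodies on top ----------------------------------
  stem_region <- matrix(FALSE, h, w)
  mask_l <- matrix(FALSE, h, w)
  fruit_regions <- vector("list", nrow(fruits))
  for (i in seq_len(nrow(fruits))) {
    f <- fruits[i, ]
    fruit_regions[[i]] <- ellipse_interior(g, f$cy, f$cx, f$a, f$b, f$theta)
    if (runif(1) < spec$stem_probability) {
      dir_sign <- sample(c(-1, 1), 1)
      sx <- f$cx + dir_sign * f$a * cos(f$theta)
      sy <- f$cy + dir_sign * f$a * sin(f$theta)
      len <- runif(1, 0.10, 0.25) * 2 * f$a
      width <- sample(2:4, 1)
      theta_s <- f$theta + if (dir_sign < 0) pi else 0
      region <- segment_region(g, sy, sx, theta_s, len, width)
      img <- paint(img, region, c(80, 62, 38), noise_sd = 3)
      stem_region <- stem_region | region
    }
  }
  lo <- spec$fruit_color_range[1, ]; hi <- spec$fruit_color_range[2, ]
  for (i in seq_len(nrow(fruits))) {
    color <- lo + runif(3) * (hi - lo)
    img <- paint(img, fruit_regions[[i]], color, noise_sd = 4)
    mask_l <- mask_l | fruit_regions[[i]]
  }
  stem_region <- stem_region & !mask_l
  confuser_region <- confuser_region & !mask_l

  ## --- illumination gradient and cast shadows ---------------------------
  if (spec$shadow_strength > 0) {
    ss <- spec$shadow_strength
    phi <- runif(1, 0, 2 * pi)
    proj <- g$cc * cos(phi) + g$rr * sin(phi)
    t <- (proj - min(proj)) / max(1e-9, diff(range(proj)))
    gain <- 1 - 0.55 * ss * t
    shadow <- matrix(FALSE, h, w)
    n_extra <- if (field_like || nrow(fruits) == 0) 2L else 0L
    for (i in seq_len(nrow(fruits))) {
      if (runif(1) > 0.8) next
      f <- fruits[i, ]
      off <- runif(1, 1.0, 1.8) * f$a
      shadow <- shadow | ellipse_interior(
        g, f$cy + off * sin(phi), f$cx + off * cos(phi),
        runif(1, 1.1, 1.6) * f$a, runif(1, 0.8, 1.2) * f$b,
        runif(1, 0, pi))
    }
    for (i in seq_len(n_extra)) {
      shadow <- shadow | ellipse_interior(
        g, runif(1, 0, h - 1), runif(1, 0, w - 1),
        runif(1, 0.1, 0.2) * smin, runif(1, 0.07, 0.15) * smin,
        runif(1, 0, pi))
    }
    gain <- gain * ifelse(shadow, 1 - 0.55 * ss, 1)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * gain
  }

  ## --- sensor noise, quantisation ---------------------------------------
  img <- img + array(rnorm(h * w * 3, 0, 2), c(h, w, 3))
  img <- round(clip255(img))

  out <- labeled_sample(img, mask_l + 0, provenance = spec$scene_kind,
                        sample_id = sprintf("%s-s%d", spec$scene_kind,
                                            spec$seed))
  attr(out, "scene_spec") <- spec
  attr(out, "fruits") <- fruits
  attr(out, "confusers") <- confusers
  attr(out, "regions") <- list(stem = stem_region, confuser = confuser_region)
  out
}

#' Generate a dataset from a list of scene specifications
#'
#' One sample per spec, in input order, with unique sample ids (duplicated
#' kind/seed combinations get a numeric suffix; they remain deterministic
#' duplicates of the same scene).
#'
#' @param specs non-empty list of [scene_spec()] objects.
#' @return List of [labeled_sample] objects.
#' @export
generate_dataset <- function(specs) {
  if (!is.list(specs) || length(specs) == 0L)
    stopf("specs must be a non-empty list of scene_spec objects")
  samples <- lapply(specs, generate_scene)
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "-")
    for (i in seq_along(samples)) samples[[i]]$sample_id <- ids[i]
  }
  samples
}

#' Convenience constructor: n scenes of one kind with consecutive seeds
#'
#' @param scene_kind scene kind, as in [scene_spec()].
#' @param n number of scenes.
#' @param seed base seed; scene i uses seed `seed + i - 1`.
#' @param ... further arguments passed to [scene_spec()].
#' @return List of [labeled_sample] objects.
#' @export
generate_batch <- function(scene_kind, n, seed = 1L, ...) {
  if (n < 1L) stopf("n must be >= 1")
  generate_dataset(lapply(seq_len(n) - 1L, function(i)
    scene_spec(scene_kind = scene_kind, seed = seed + i, ...)))
}
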