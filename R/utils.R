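#' @keywords internal
#' @importFrom stats rnorm runif
"_PACKAGE"

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a private RNG stream
#'
#' Saves and restores the global `.Random.seed`, so seeded package
#' operations never perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_rng <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("seed must be a single finite number, got %s", deparse(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit string hash (polynomial rolling hash), used to derive
# per-sample augmentation seeds and manifest hashes.
hash_string <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

is_rgb_image <- function(img) {
  is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L &&
    is.numeric(img)
}

check_rgb_image <- function(img, what = "image") {
  if (!is_rgb_image(img))
    stopf("%s must be an H x W x 3 numeric array (8-bit RGB)", what)
  if (min(img) < 0 || max(img) > 255)
    stopf("%s intensities must lie in [0, 255]", what)
  invisible(img)
}

is_binary_mask <- function(mask) {
  is.matrix(mask) && is.numeric(mask) && all(mask %in% c(0, 1))
}

check_binary_mask <- function(mask, what = "mask") {
  if (!is.matrix(mask) || !is.numeric(mask))
    stopf("%s must be a numeric H x W matrix", what)
  if (!all(mask %in% c(0, 1)))
    stopf("%s must contain only values 0 and 1", what)
  invisible(mask)
}

check_connectivity <- function(connectivity) {
  if (!connectivity %in% c(4L, 8L))
    stopf("connectivity must be 4 or 8, got %s", deparse(connectivity))
  as.integer(connectivity)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  if (length(rs) > 0 && length(cs) > 0)
    out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Label connected components of a binary mask
#'
#' Two-dimensional connected-component labeling with selectable 4- or
#' 8-connectivity, returning an integer matrix with background 0 and
#' components numbered 1..k in raster (column-major) order of their first
#' pixel.
#'
#' @param mask binary matrix over \{0, 1\}.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer label matrix of the same shape as `mask`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  check_binary_mask(mask)
  connectivity <- check_connectivity(connectivity)
  h <- nrow(mask); w <- ncol(mask)
  fg <- mask != 0
  lab <- matrix(0, h, w)
  lab[fg] <- which(fg)          # provisional label = linear index
  lab[!fg] <- Inf
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8L)
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  repeat {
    new <- lab
    for (o in offs)
      new <- pmin(new, shift_mat(lab, o[1], o[2], fill = Inf))
    new[!fg] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  lab[!fg] <- 0
  # renumber to consecutive 1..k preserving raster order of first occurrence
  ids <- unique(lab[lab > 0])
  out <- matrix(0L, h, w)
  if (length(ids) > 0)
    out[lab > 0] <- match(lab[lab > 0], sort(ids))
  out
}

#' Analytic disk structuring element
#'
#' Square (2r+1) x (2r+1) binary kernel containing the pixels whose centre
#' distance from the kernel centre is at most `radius`.
#'
#' @param radius integer radius in pixels (>= 1).
#' @return Binary matrix kernel.
#' @export
disk_kernel <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1)
    stopf("radius must be a single number >= 1")
  r <- as.integer(radius)
  d <- seq(-r, r)
  k <- outer(d^2, d^2, "+") <= radius^2
  storage.mode(k) <- "integer"
  k
}

# Binary erosion / dilation with a disk, via EBImage. Border convention
# (shared with the test oracles): erosion treats out-of-image as foreground,
# dilation as background.
erode_disk <- function(mask, radius) {
  check_binary_mask(mask)
  out <- as.matrix(EBImage::erode(mask + 0, disk_kernel(radius)))
  (out > 0.5) + 0
}

dilate_disk <- function(mask, radius) {
  check_binary_mask(mask)
  out <- as.matrix(EBImage::dilate(mask + 0, disk_kernel(radius)))
  (out > 0.5) + 0
}

# Box mean filter with window (2r+1), normalised by the in-image window
# area (windows are clamped at the borders). Exact via integral images.
box_mean <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  ii <- matrix(0, h + 1, w + 1)
  ii[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  r1 <- pmax(seq_len(h) - r, 1); r2 <- pmin(seq_len(h) + r, h)
  c1 <- pmax(seq_len(w) - r, 1); c2 <- pmin(seq_len(w) + r, w)
  s <- ii[r2 + 1, c2 + 1, drop = FALSE] - ii[r1, c2 + 1, drop = FALSE] -
    ii[r2 + 1, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
  area <- outer(r2 - r1 + 1, c2 - c1 + 1)
  s / area
}
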