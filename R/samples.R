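#' Labeled image/mask pair
#'
#' The carrier type consumed by every training and evaluation step: an 8-bit
#' RGB image, its binary fruit mask (1 = fruit pixel) and a provenance tag
#' recording how the label was obtained.
#'
#' @param image H x W x 3 numeric array of 8-bit intensities.
#' @param mask H x W binary matrix over \{0, 1\}, aligned 1:1 with `image`.
#' @param provenance one of `"set1"`, `"set2"`, `"negative"`, `"field"`,
#'   `"synthetic-gt"`, `"pseudo"`.
#' @param sample_id unique string identifier.
#' @return An object of class `labeled_sample`.
#' @export
labeled_sample <- function(image, mask, provenance, sample_id) {
  check_rgb_image(image)
  check_binary_mask(mask)
  if (!identical(dim(image)[1:2], dim(mask)))
    stopf("image (%d x %d) and mask (%d x %d) sizes differ",
          dim(image)[1], dim(image)[2], nrow(mask), ncol(mask))
  provenance <- match.arg(provenance,
    c("set1", "set2", "negative", "field", "synthetic-gt", "pseudo"))
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id))
    stopf("sample_id must be a non-empty string")
  structure(list(image = image, mask = mask, provenance = provenance,
                 sample_id = sample_id),
            class = "labeled_sample")
}

#' @export
print.labeled_sample <- function(x, ...) {
  cat(sprintf("<labeled_sample %s: %d x %d, %s, %d fruit px>\n",
              x$sample_id, nrow(x$mask), ncol(x$mask), x$provenance,
              sum(x$mask)))
  invisible(x)
}

#' Read / write 8-bit RGB images and binary masks as PNG
#'
#' Masks are stored single-channel with values \{0, 255\} (255 = fruit).
#'
#' @param path file path.
#' @return `read_image_png`: H x W x 3 array in \[0, 255\];
#'   `read_mask_png`: binary H x W matrix.
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  round(x * 255)
}

#' @rdname read_image_png
#' @param image H x W x 3 array in \[0, 255\].
#' @export
write_image_png <- function(image, path) {
  check_rgb_image(image)
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' @rdname read_image_png
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  (x > 0.5) + 0
}

#' @rdname read_image_png
#' @param mask binary H x W matrix.
#' @export
write_mask_png <- function(mask, path) {
  check_binary_mask(mask)
  png::writePNG(mask, target = path)
  invisible(path)
}

#' Write a dataset of labeled samples to disk with a JSON manifest
#'
#' Images are written as 8-bit RGB PNG and masks as single-channel PNG with
#' values \{0, 255\}. `manifest.json` lists, per sample: id, relative paths,
#' provenance, and (when the sample came from the synthetic generator) its
#' full scene specification.
#'
#' @param samples list of [labeled_sample] objects.
#' @param dir output directory, created if missing.
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(samples, dir) {
  if (length(samples) == 0L) stopf("samples must be non-empty")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(samples, function(s) {
    img_rel <- paste0(s$sample_id, ".png")
    msk_rel <- paste0(s$sample_id, "_mask.png")
    write_image_png(s$image, file.path(dir, img_rel))
    write_mask_png(s$mask, file.path(dir, msk_rel))
    row <- list(sample_id = s$sample_id, image = img_rel, mask = msk_rel,
                provenance = s$provenance)
    spec <- attr(s, "scene_spec")
    if (!is.null(spec)) row$scene_spec <- unclass(spec)
    row
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(rows, manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a dataset previously written by [write_dataset()]
#'
#' @param manifest path to `manifest.json`.
#' @return List of [labeled_sample] objects.
#' @export
read_dataset <- function(manifest) {
  rows <- jsonlite::read_json(manifest)
  dir <- dirname(manifest)
  lapply(rows, function(row) {
    labeled_sample(read_image_png(file.path(dir, row$image)),
                   read_mask_png(file.path(dir, row$mask)),
                   row$provenance, row$sample_id)
  })
}
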