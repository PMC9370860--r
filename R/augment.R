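#' Deterministic 20-fold paired augmentation plans
#'
#' Each original image yields exactly 20 derived images by combining
#' right-angle rotations, horizontal reflection, and photometric contrast /
#' exposure changes. The 8 geometric variants
#' (\{0, 90, 180, 270\} degrees x \{identity, horizontal flip\}) are cycled
#' and paired with photometric slots: variants 1-8 are geometric only,
#' 9-16 additionally apply a contrast gain sampled in \[0.7, 1.3\] (about
#' mid-grey 128), and 17-20 an exposure offset sampled in \[-30, +30\].
#' Right-angle geometry keeps masks free of interpolation artifacts.
#'
#' @param seed integer seed; plans are deterministic in it.
#' @return An `augmentation_plan`: a list of exactly 20 transform specs.
#' @export
default_plan <- function(seed = 0L) {
  gains <- with_rng(seed, runif(8, 0.7, 1.3))
  offsets <- with_rng(seed + 1L, runif(4, -30, 30))
  plan <- vector("list", 20L)
  for (i in 0:19) {
    geom <- i %% 8
    photo_slot <- i %/% 8          # 0: none, 1: contrast, 2: exposure
    tf <- list(rotation = (geom %% 4) * 90L, hflip = geom >= 4,
               photometric = "none", value = NA_real_)
    if (photo_slot == 1L) {
      tf$photometric <- "contrast"; tf$value <- gains[geom + 1]
    } else if (photo_slot == 2L) {
      tf$photometric <- "exposure"; tf$value <- offsets[geom + 1]
    }
    plan[[i + 1]] <- tf
  }
  structure(plan, class = "augmentation_plan", seed = as.integer(seed))
}

rotate90_array <- function(x, k) {
  k <- ((k %/% 90L) %% 4L)
  if (k == 0L) return(x)
  rot1 <- function(m) t(m[nrow(m):1, , drop = FALSE])  # 90 deg CW
  f <- function(m) { for (i in seq_len(k)) m <- rot1(m); m }
  if (is.matrix(x)) return(f(x))
  planes <- lapply(1:3, function(ch) f(x[, , ch]))
  out <- array(0, c(dim(planes[[1]]), 3))
  for (ch in 1:3) out[, , ch] <- planes[[ch]]
  out
}

hflip_array <- function(x) {
  if (is.matrix(x)) return(x[, ncol(x):1, drop = FALSE])
  x[, dim(x)[2]:1, , drop = FALSE]
}

apply_transform <- function(sample, tf) {
  img <- sample$image; mask <- sample$mask
  img <- rotate90_array(img, tf$rotation)
  mask <- rotate90_array(mask, tf$rotation)
  if (isTRUE(tf$hflip)) { img <- hflip_array(img); mask <- hflip_array(mask) }
  if (tf$photometric == "contrast") {
    img <- clip255(round(128 + tf$value * (img - 128)))
  } else if (tf$photometric == "exposure") {
    img <- clip255(round(img + tf$value))
  }
  labeled_sample(img, mask, sample$provenance, sample$sample_id)
}

#' Apply a 20-transform plan to one labeled sample
#'
#' Geometric transforms are applied identically to image and mask (masks
#' stay binary; right-angle rotations and flips are pixel permutations);
#' photometric transforms touch the image only, clipped to \[0, 255\].
#'
#' @param sample a [labeled_sample].
#' @param plan an [default_plan()] augmentation plan.
#' @return List of exactly 20 [labeled_sample]s; ids get suffixes
#'   `-aug01` .. `-aug20`.
#' @export
apply_plan <- function(sample, plan) {
  if (!inherits(sample, "labeled_sample")) stopf("sample must be a labeled_sample")
  if (!inherits(plan, "augmentation_plan") || length(plan) != 20L)
    stopf("plan must be an augmentation_plan of length 20")
  lapply(seq_along(plan), function(i) {
    out <- apply_transform(sample, plan[[i]])
    out$sample_id <- sprintf("%s-aug%02d", sample$sample_id, i)
    attr(out, "source_sample_id") <- sample$sample_id
    attr(out, "transform") <- plan[[i]]
    out
  })
}

#' Augment a dataset 20-fold
#'
#' Every input sample yields exactly 20 derived samples, so the output
#' length is always 20 x the input length. Per-sample plans are derived
#' deterministically from `(seed, sample_id)`.
#'
#' @param samples non-empty list of [labeled_sample]s.
#' @param seed integer master seed.
#' @return List of `20 * length(samples)` samples.
#' @export
augment_dataset <- function(samples, seed = 0L) {
  if (!is.list(samples) || length(samples) == 0L)
    stopf("samples must be a non-empty list")
  out <- lapply(samples, function(s) {
    sub_seed <- (as.integer(seed) %% 65536L) * 32749L + hash_string(s$sample_id) %% 32749L
    apply_plan(s, default_plan(sub_seed))
  })
  unlist(out, recursive = FALSE)
}
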