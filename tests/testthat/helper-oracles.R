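# Brute-force oracles, written independently of the package internals:
# queue-based flood fill for labeling, border flood fill for hole filling,
# direct min/max filters for disk morphology, per-pixel loops for metrics.

# flood-fill connected-component labeling (BFS, explicit queue)
oracle_label <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8)
    rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else rbind(c(-1,0), c(1,0), c(0,-1), c(0,1))
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] == 1 && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(nb))) {
          r <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
          if (r >= 1 && r <= h && cc >= 1 && cc <= w &&
              mask[r, cc] == 1 && lab[r, cc] == 0L) {
            lab[r, cc] <- cur
            queue <- c(queue, list(c(r, cc)))
          }
        }
      }
    }
  }
  lab
}

oracle_remove_small <- function(mask, min_area, connectivity = 8) {
  lab <- oracle_label(mask, connectivity)
  out <- mask
  if (max(lab) > 0) for (k in seq_len(max(lab))) {
    if (sum(lab == k) < min_area) out[lab == k] <- 0
  }
  out
}

# border flood fill on the background, then invert
oracle_fill_holes <- function(mask, connectivity = 8) {
  bg_conn <- if (connectivity == 8) 4 else 8
  inv <- 1 - mask
  lab <- oracle_label(inv, bg_conn)
  h <- nrow(mask); w <- ncol(mask)
  border_labels <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  border_labels <- border_labels[border_labels > 0]
  out <- matrix(1, h, w)
  out[lab %in% border_labels] <- 0
  out
}

# direct morphology: pixelwise min/max over the disk neighbourhood.
# Border convention: out-of-image counts as foreground for erosion and
# background for dilation.
oracle_disk_offsets <- function(radius) {
  off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  off[off$dr^2 + off$dc^2 <= radius^2, ]
}

oracle_erode <- function(mask, radius) {
  off <- oracle_disk_offsets(radius)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    keep <- 1
    for (k in seq_len(nrow(off))) {
      r <- i + off$dr[k]; cc <- j + off$dc[k]
      if (r >= 1 && r <= h && cc >= 1 && cc <= w && mask[r, cc] == 0) {
        keep <- 0; break
      }
    }
    out[i, j] <- keep
  }
  out
}

oracle_dilate <- function(mask, radius) {
  off <- oracle_disk_offsets(radius)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    hit <- 0
    for (k in seq_len(nrow(off))) {
      r <- i + off$dr[k]; cc <- j + off$dc[k]
      if (r >= 1 && r <= h && cc >= 1 && cc <= w && mask[r, cc] == 1) {
        hit <- 1; break
      }
    }
    out[i, j] <- hit
  }
  out
}

oracle_discard_stems <- function(mask, cfg) {
  er <- oracle_erode(mask, cfg$erosion_radius)
  lab <- oracle_label(er, cfg$connectivity)
  if (max(lab) > 0) for (k in seq_len(max(lab))) {
    px <- which(lab == k, arr.ind = TRUE)
    rows <- px[, 1] - 1; cols <- px[, 2] - 1
    mu_rr <- mean((rows - mean(rows))^2) + 1 / 12
    mu_cc <- mean((cols - mean(cols))^2) + 1 / 12
    mu_rc <- mean((rows - mean(rows)) * (cols - mean(cols)))
    comm <- sqrt((mu_rr - mu_cc)^2 + 4 * mu_rc^2)
    a2 <- (mu_rr + mu_cc + comm) / 2
    b2 <- max((mu_rr + mu_cc - comm) / 2, 0)
    ecc <- sqrt(max(0, 1 - b2 / a2))
    if (ecc > cfg$eccentricity_max) er[lab == k] <- 0
  }
  oracle_dilate(er, cfg$dilation_radius)
}

# per-pixel confusion tally with an explicit double loop
oracle_confusion <- function(pred, gt) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    if (pred[i, j] == 1 && gt[i, j] == 1) tp <- tp + 1
    else if (pred[i, j] == 0 && gt[i, j] == 0) tn <- tn + 1
    else if (pred[i, j] == 1 && gt[i, j] == 0) fp <- fp + 1
    else fn <- fn + 1
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# set-operation IoU per class: |A intersect B| / |A union B|
oracle_iou_sets <- function(pred, gt, class_value) {
  A <- which(pred == class_value); B <- which(gt == class_value)
  if (length(A) == 0 && length(B) == 0) return(1)
  length(intersect(A, B)) / length(union(A, B))
}

random_mask <- function(h, w, p = 0.4) {
  matrix(rbinom(h * w, 1, p), h, w)
}

# small deterministic RGB test image
flat_image <- function(h, w, color) {
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- color[ch]
  img
}
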