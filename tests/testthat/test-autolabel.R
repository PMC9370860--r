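test_that("colour threshold implements the red-dominance predicate per pixel", {
  cfg <- autolabel_config()
  expect_equal(sum(threshold_fruit_pixels(flat_image(8, 8, c(120, 120, 120)),
                                          cfg)), 0)
  img <- flat_image(5, 5, c(90, 90, 90))
  img[3, 4, ] <- c(200, 50, 50)
  m <- threshold_fruit_pixels(img, cfg)
  expect_equal(sum(m), 1)
  expect_equal(m[3, 4], 1)
  # brute-force per-pixel oracle on a generated scene
  s <- generate_scene(scene_spec("set1", seed = 4))
  got <- threshold_fruit_pixels(s$image, cfg)
  r <- s$image[, , 1]; g <- s$image[, , 2]; b <- s$image[, , 3]
  for (i in seq(1, 96, by = 7)) for (j in seq(1, 96, by = 7)) {
    want <- as.numeric(r[i, j] >= cfg$red_min &&
                         r[i, j] - g[i, j] >= cfg$red_green_margin &&
                         r[i, j] - b[i, j] >= cfg$red_blue_margin)
    expect_equal(got[i, j], want)
  }
  expect_error(threshold_fruit_pixels(matrix(0, 4, 4), cfg), "RGB")
})

test_that("small-component removal matches the flood-fill oracle and is strict", {
  expect_equal(remove_small_components(matrix(0, 8, 8), 5), matrix(0, 8, 8))
  m <- matrix(0, 20, 20)
  m[2:3, 2:3] <- 1               # area 4
  m[8:14, 8:14] <- 1             # area 49
  out <- remove_small_components(m, 10)
  expect_equal(sum(out), 49)
  # area exactly min_area survives ("below a threshold" is strict)
  m2 <- matrix(0, 10, 10); m2[2:4, 2:4] <- 1
  expect_equal(remove_small_components(m2, 9), m2)
  expect_equal(sum(remove_small_components(m2, 10)), 0)
  expect_error(remove_small_components(m2, 0), "min_area")
  # randomized oracle equivalence, both connectivities
  withr::with_seed(11, {
    for (rep in 1:8) {
      rm_ <- random_mask(24, 24, 0.35)
      for (conn in c(4L, 8L)) {
        expect_equal(remove_small_components(rm_, 6, conn),
                     oracle_remove_small(rm_, 6, conn))
      }
    }
  })
})

test_that("component labeling agrees with BFS flood fill and EBImage", {
  withr::with_seed(5, {
    for (rep in 1:6) {
      m <- random_mask(20, 20, 0.4)
      for (conn in c(4L, 8L)) {
        lab <- label_components(m, conn)
        orc <- oracle_label(m, conn)
        expect_equal(max(lab), max(orc))
        # same partition (labels may be numbered differently)
        expect_equal(length(unique(paste(lab, orc))), max(lab) + 1)
      }
      # EBImage::bwlabel is 4-connected: independent package cross-check
      expect_equal(max(label_components(m, 4L)),
                   max(EBImage::bwlabel(m)))
    }
  })
})

test_that("moment ellipses match closed-form eccentricity for analytic shapes", {
  g <- expand.grid(r = 0:99, c = 0:99)
  circle <- matrix(as.numeric((g$r - 50)^2 + (g$c - 50)^2 <= 20^2), 100, 100)
  sh <- measure_components(circle)
  expect_equal(nrow(sh), 1)
  expect_lt(sh$eccentricity, 0.1)
  expect_equal(sh$centroid_row, 50, tolerance = 0.01)
  ell <- matrix(as.numeric(((g$r - 50) / 30)^2 + ((g$c - 50) / 50)^2 <= 1),
                100, 100)
  sh2 <- measure_components(ell)
  expect_equal(sh2$eccentricity, 0.8, tolerance = 0.02 * 0.8)
  expect_equal(sh2$ellipse_semi_major / sh2$ellipse_semi_minor, 50 / 30,
               tolerance = 0.02)
  two <- circle
  two[1:6, 1:6] <- 1
  expect_equal(nrow(measure_components(two)), 2)
  expect_equal(nrow(measure_components(matrix(0, 5, 5))), 0)
})

test_that("rotated analytic ellipses keep closed-form eccentricity", {
  g <- expand.grid(r = 0:79, c = 0:79)
  for (th in c(pi / 6, pi / 3, 2.1)) {
    u <- (g$c - 40) * cos(th) + (g$r - 40) * sin(th)
    v <- -(g$c - 40) * sin(th) + (g$r - 40) * cos(th)
    ell <- matrix(as.numeric((u / 30)^2 + (v / 15)^2 <= 1), 80, 80)
    sh <- measure_components(ell)
    expect_equal(sh$eccentricity, sqrt(1 - (15 / 30)^2),
                 tolerance = 0.02 * sqrt(0.75))
  }
})

test_that("stem discarding removes thin protrusions, keeps fruit bodies", {
  # circle + attached 3-px stem on a 64x64 canvas, morphology oracle
  g <- expand.grid(r = 0:63, c = 0:63)
  circle <- (g$r - 32)^2 + (g$c - 28)^2 <= 14^2
  stem <- g$r >= 31 & g$r <= 33 & g$c >= 42 & g$c <= 52
  m <- matrix(as.numeric(circle | stem), 64, 64)
  cfg <- autolabel_config()
  out <- discard_stems(m, cfg)
  expect_identical(out, oracle_discard_stems(m, cfg))
  stem_px <- matrix(as.numeric(stem & !circle), 64, 64)
  expect_equal(sum(out * stem_px) / sum(stem_px), 0, tolerance = 0.10)
  body <- matrix(as.numeric(circle), 64, 64)
  expect_gt(sum(out * body) / sum(body), 0.95)
  expect_equal(discard_stems(matrix(0, 16, 16), cfg), matrix(0, 16, 16))
})

test_that("erode-dilate round trip with equal radii retains >= 95% of a circle", {
  g <- expand.grid(r = 0:63, c = 0:63)
  m <- matrix(as.numeric((g$r - 32)^2 + (g$c - 32)^2 <= 20^2), 64, 64)
  out <- discard_stems(m, autolabel_config())
  expect_gt(sum(out * m) / sum(m), 0.95)
})

test_that("eccentricity filter drops detached elongated components", {
  # wide bar that survives erosion as a separate high-eccentricity blob
  m <- matrix(0, 40, 60)
  m[17:24, 5:55] <- 1
  cfg <- autolabel_config(erosion_radius = 2, dilation_radius = 2,
                          eccentricity_max = 0.92)
  out <- discard_stems(m, cfg)
  expect_equal(sum(out), 0)
  expect_identical(out, oracle_discard_stems(m, cfg))
})

test_that("hole filling matches the border flood-fill oracle", {
  g <- expand.grid(r = 0:39, c = 0:39)
  d2 <- (g$r - 20)^2 + (g$c - 20)^2
  ring <- matrix(as.numeric(d2 <= 15^2 & d2 >= 8^2), 40, 40)
  disk <- matrix(as.numeric(d2 <= 15^2), 40, 40)
  expect_identical(fill_holes(ring), disk)
  expect_identical(fill_holes(disk), disk)      # idempotent, no holes
  withr::with_seed(23, {
    for (rep in 1:10) {
      m <- random_mask(32, 32, 0.45)
      for (conn in c(4L, 8L))
        expect_identical(fill_holes(m, conn), oracle_fill_holes(m, conn))
    }
  })
})

test_that("morphological cleanup operators are monotone and idempotent", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      m <- random_mask(28, 28, 0.4)
      rs <- remove_small_components(m, 5)
      expect_true(all(rs <= m))                       # never adds
      expect_identical(remove_small_components(rs, 5), rs)  # idempotent
      fh <- fill_holes(m)
      expect_true(all(fh >= m))                       # never removes
      expect_identical(fill_holes(fh), fh)
    }
  })
})

test_that("full autolabel recovers generator ground truth on set1 scenes", {
  cfg <- autolabel_config(min_area = scaled_min_area(c(96, 96)))
  ious <- vapply(1:8, function(i) {
    s <- generate_scene(scene_spec("set1", seed = 400 + i))
    m <- autolabel(s$image, cfg)
    sum(m == 1 & s$mask == 1) / sum(m == 1 | s$mask == 1)
  }, numeric(1))
  expect_gt(mean(ious), 0.9)
  # all-background image -> empty mask
  expect_equal(sum(autolabel(flat_image(48, 48, c(120, 120, 120)), cfg)), 0)
})

test_that("noise speckles are removed: one fruit gives one component", {
  s <- generate_scene(scene_spec("set1", n_fruits = 1, seed = 9))
  img <- s$image
  # add 3-px fruit-coloured speckles
  for (p in list(c(4, 4), c(90, 8), c(8, 88))) {
    img[p[1], p[2], ] <- c(200, 40, 40)
    img[p[1] + 1, p[2], ] <- c(200, 40, 40)
    img[p[1], p[2] + 1, ] <- c(200, 40, 40)
  }
  cfg <- autolabel_config(min_area = scaled_min_area(c(96, 96)))
  out <- autolabel(img, cfg)
  expect_equal(max(oracle_label(out, 8)), 1)
})

test_that("autolabel config validates its ranges", {
  expect_error(autolabel_config(min_area = 0), "min_area")
  expect_error(autolabel_config(eccentricity_max = 1), "eccentricity_max")
  expect_error(autolabel_config(erosion_radius = 0), "erosion_radius")
  expect_error(autolabel_config(connectivity = 6), "connectivity")
})
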