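test_that("confusion counts match the per-pixel oracle and conserve pixels", {
  allf <- matrix(1, 6, 7)
  cc <- confusion_counts(allf, allf)
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 42, tn = 0, fp = 0, fn = 0))
  comp <- confusion_counts(1 - allf, allf)
  expect_equal(comp$tp, 0); expect_equal(comp$tn, 0)
  withr::with_seed(7, {
    for (rep in 1:6) {
      p <- random_mask(16, 16); g <- random_mask(16, 16)
      got <- confusion_counts(p, g)
      want <- oracle_confusion(p, g)
      expect_equal(unclass(got)[c("tp", "tn", "fp", "fn")],
                   want[c("tp", "tn", "fp", "fn")])
      expect_equal(got$tp + got$tn + got$fp + got$fn, 256)
    }
  })
  expect_error(confusion_counts(matrix(0, 3, 3), matrix(0, 3, 4)), "shapes")
})

test_that("precision, recall and F1 follow their defining ratios", {
  prf <- precision_recall_f1(list(tp = 3, fp = 1, fn = 1))
  expect_equal(unname(prf), c(0.75, 0.75, 0.75))
  # empty-vs-empty convention: perfect
  expect_equal(unname(precision_recall_f1(list(tp = 0, fp = 0, fn = 0))),
               c(1, 1, 1))
  # undefined members drop to 0
  expect_equal(precision_recall_f1(list(tp = 0, fp = 3, fn = 0))[["f1"]], 0)
  expect_equal(precision_recall_f1(list(tp = 0, fp = 0, fn = 2))[["recall"]], 0)
  # F1 = 2 IoU / (1 + IoU): tp=2, fp=1, fn=1 -> IoU 0.5 -> F1 2/3
  expect_equal(precision_recall_f1(list(tp = 2, fp = 1, fn = 1))[["f1"]],
               2 / 3)
})

test_that("IoU metrics match set-operation oracles and weighted averaging", {
  p <- matrix(1, 4, 4); g <- matrix(1, 4, 4)
  expect_equal(unname(iou_metrics(confusion_counts(p, g))), c(1, 1))
  withr::with_seed(19, {
    for (rep in 1:8) {
      pr <- random_mask(12, 12); gt <- random_mask(12, 12)
      cc <- confusion_counts(pr, gt)
      iou <- iou_metrics(cc)
      iou_f <- oracle_iou_sets(pr, gt, 1)
      iou_b <- oracle_iou_sets(pr, gt, 0)
      expect_equal(iou[["mean_iou"]], (iou_f + iou_b) / 2)
      share_f <- sum(gt) / length(gt)
      expect_equal(iou[["weighted_iou"]],
                   share_f * iou_f + (1 - share_f) * iou_b)
    }
  })
})

test_that("weighted IoU weights class IoUs by ground-truth share", {
  # construct exact counts: fruit IoU 0.5 (tp=10, fn=10), bg IoU 1.0,
  # bg share 0.9 -> weighted 0.95, mean 0.75... bg IoU must be 1 with fn>0?
  # fn pixels are bg predictions on fruit gt: bg fp = fn. Use direct fields:
  w <- pomseg:::per_class_counts(list(tp = 10, tn = 180, fp = 0, fn = 10))
  expect_equal(pomseg:::class_iou(w$fruit), 0.5)
  # background IoU = tn / (tn + fn_gt-as-fp) = 180/190
  expect_equal(pomseg:::class_iou(w$background), 180 / 190)
  iou <- iou_metrics(list(tp = 10, tn = 180, fp = 0, fn = 10))
  expect_equal(iou[["weighted_iou"]],
               0.1 * 0.5 + 0.9 * (180 / 190))
})

test_that("accuracy metrics: global vs per-class mean", {
  # all-background prediction on a 90% background image
  g <- matrix(0, 10, 10); g[1, 1:10] <- 1
  p <- matrix(0, 10, 10)
  acc <- accuracy_metrics(confusion_counts(p, g))
  expect_equal(acc[["global_accuracy"]], 0.9)
  expect_equal(acc[["mean_accuracy"]], 0.5)
  expect_equal(unname(accuracy_metrics(confusion_counts(g, g))), c(1, 1))
  withr::with_seed(3, {
    pr <- random_mask(16, 16); gt <- random_mask(16, 16)
    o <- oracle_confusion(pr, gt)
    acc <- accuracy_metrics(confusion_counts(pr, gt))
    expect_equal(acc[["global_accuracy"]], (o$tp + o$tn) / 256)
    expect_equal(acc[["mean_accuracy"]],
                 (o$tp / (o$tp + o$fn) + o$tn / (o$tn + o$fp)) / 2)
  })
})

test_that("F1 equals 2*IoU/(1+IoU) to machine precision on random masks", {
  withr::with_seed(29, {
    for (rep in 1:20) {
      pr <- random_mask(10, 10); gt <- random_mask(10, 10)
      cc <- confusion_counts(pr, gt)
      f1 <- precision_recall_f1(cc)[["f1"]]
      iou_f <- cc$tp / (cc$tp + cc$fp + cc$fn)
      expect_equal(f1, 2 * iou_f / (1 + iou_f), tolerance = 1e-14)
      # IoU(fruit) <= min(P, R)
      prf <- precision_recall_f1(cc)
      expect_lte(iou_f, min(prf[["precision"]], prf[["recall"]]) + 1e-15)
    }
  })
})

test_that("swapping pred and gt swaps fp and fn", {
  withr::with_seed(41, {
    pr <- random_mask(14, 14); gt <- random_mask(14, 14)
    a <- confusion_counts(pr, gt); b <- confusion_counts(gt, pr)
    expect_equal(a$fp, b$fn); expect_equal(a$fn, b$fp)
    expect_equal(a$tp, b$tp); expect_equal(a$tn, b$tn)
  })
})

test_that("per-image averaging: report means equal the arithmetic mean", {
  # two images engineered to F1 0.8 and 0.6; reported F1 must be 0.7
  g1 <- matrix(0, 10, 10); g1[1:2, 1:4] <- 1       # 8 fruit px
  p1 <- matrix(0, 10, 10); p1[1, 1:4] <- 1; p1[2, 1:2] <- 1
  # tp=6, fn=2, fp=0 -> P=1, R=0.75, F1 = 6/7... engineer simpler:
  g2 <- matrix(0, 10, 10); g2[1:3, 1] <- 1
  p2 <- g2
  samples <- list(labeled_sample(flat_image(10, 10, c(1, 1, 1)), g1, "field", "a"),
                  labeled_sample(flat_image(10, 10, c(1, 1, 1)), g2, "field", "b"))
  rep <- evaluate_predictions(list(p1, p2), samples)
  f1s <- rep$per_image$f1
  expect_equal(rep$summary[["f1"]], mean(f1s))
  expect_equal(nrow(rep$per_image), 2)
  # single-image test set: summary equals that image's metrics
  rep1 <- evaluate_predictions(list(p1), samples[1])
  expect_equal(rep1$summary[["f1"]], rep1$per_image$f1[1])
})

test_that("evaluating an empty test set is an error", {
  m <- structure(list(trained = TRUE), class = "pomseg_model")
  expect_error(evaluate_test_set(m, list()), "non-empty")
})

test_that("error maps use the four documented colours", {
  pred <- matrix(c(1, 0, 1, 0), 2, 2)
  gt <- matrix(c(1, 1, 0, 0), 2, 2)
  em <- error_map(pred, gt)
  expect_equal(em[1, 1, ], c(255, 255, 255))   # TP white
  expect_equal(em[2, 1, ], c(255, 0, 255))     # FN magenta
  expect_equal(em[1, 2, ], c(0, 255, 0))       # FP green
  expect_equal(em[2, 2, ], c(0, 0, 0))         # TN black
  allf <- matrix(1, 3, 3)
  expect_true(all(error_map(allf, allf) == 255))
  expect_true(all(error_map(matrix(0, 3, 3), allf)[, , 2] == 0))
})
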