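test_that("pixel confusion counts match the brute-force loop oracle", {
  expect_equal(unlist(unclass(confusion_counts(matrix(FALSE, 8, 8),
                                               matrix(FALSE, 8, 8)))),
               c(tp = 0L, fp = 0L, fn = 0L, tn = 64L))
  set.seed(91)
  for (i in 1:50) {
    pred <- random_mask(); gt <- random_mask()
    got <- confusion_counts(pred, gt)
    want <- oracle_confusion_loop(pred, gt)
    expect_identical(c(tp = got$tp, fp = got$fp, fn = got$fn, tn = got$tn), want)
  }
  # identical masks have no errors
  m <- random_mask()
  cc <- confusion_counts(m, m)
  expect_equal(cc$fp + cc$fn, 0L)
  expect_error(confusion_counts(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "shape")
})

test_that("dsc matches hand arithmetic and its edge conventions", {
  expect_equal(dsc(confusion(6, 2, 4)), 12 / 18)
  expect_equal(dsc(confusion(0, 0, 0, 10)), 1)        # both empty
  m <- random_mask()
  expect_equal(dsc(confusion_counts(m, m)), 1)
  expect_equal(dsc(confusion_counts(m, !m)), 0)       # disjoint
})

test_that("dsc is the harmonic mean of precision and recall", {
  set.seed(92)
  for (i in 1:20) {
    sm <- seg_metrics(random_mask(), random_mask())
    if (sm$precision > 0 && sm$recall > 0) {
      expect_equal(sm$dsc,
                   2 * sm$precision * sm$recall / (sm$precision + sm$recall),
                   tolerance = 1e-12)
    }
  }
})

test_that("volume metrics pool counts over slices and honor empty-mask conventions", {
  set.seed(93)
  gt <- lapply(1:3, function(i) random_mask())
  pred <- lapply(1:3, function(i) random_mask())
  got <- seg_metrics(pred, gt)
  o <- Reduce(`+`, Map(oracle_confusion_loop, pred, gt))
  expect_equal(got$dsc, 2 * o["tp"] / (2 * o["tp"] + o["fp"] + o["fn"]),
               ignore_attr = TRUE)
  expect_equal(got$recall, o["tp"] / (o["tp"] + o["fn"]), ignore_attr = TRUE)
  expect_equal(got$precision, o["tp"] / (o["tp"] + o["fp"]), ignore_attr = TRUE)
  # permutation invariance of slice order
  expect_equal(seg_metrics(pred[c(3, 1, 2)], gt[c(3, 1, 2)]), got)
  # perfect prediction
  expect_equal(as.numeric(seg_metrics(gt, gt)), c(1, 1, 1))
  # empty prediction vs non-empty truth: recall 0, dsc 0, precision 1
  empty <- lapply(gt, function(m) m & FALSE)
  sm <- seg_metrics(empty, gt)
  expect_equal(as.numeric(sm), c(0, 0, 1))
})

test_that("slice detection follows the overlap rule", {
  e <- matrix(FALSE, 8, 8)
  blob1 <- e; blob1[2:3, 2:3] <- TRUE
  blob2 <- e; blob2[6:7, 6:7] <- TRUE
  expect_equal(detect_slice(e, e), "TN")
  expect_equal(detect_slice(e, blob1), "FN")
  expect_equal(detect_slice(blob1, e), "FP")
  expect_equal(detect_slice(blob1, blob1), "TP")
  expect_equal(detect_slice(blob2, blob1), "FN") # non-empty but disjoint: the miss dominates
  tal <- detection_tally(list(e, blob1, blob1, blob2), list(e, e, blob1, blob1))
  expect_equal(c(tal$tp, tal$fp, tal$fn, tal$tn), c(1, 1, 1, 1))
})

test_that("detection metrics reproduce hand-computed percentages", {
  got <- detection_metrics(confusion(15, 3, 2, 80))
  expect_equal(round(got$accuracy, 1), 95.0)
  expect_equal(round(got$sensitivity, 1), 88.2)
  expect_equal(round(got$specificity, 1), 96.4)
  expect_equal(round(got$ppv, 1), 83.3)
  expect_equal(round(got$npv, 1), 97.6)
  # undefined ratios are missing, not zero
  all_tn <- detection_metrics(confusion(0, 0, 0, 25))
  expect_equal(all_tn$accuracy, 100)
  expect_true(is.na(all_tn$sensitivity) && is.na(all_tn$ppv))
  all_tp <- detection_metrics(confusion(25, 0, 0, 0))
  expect_equal(all_tp$accuracy, 100)
  expect_true(is.na(all_tp$specificity) && is.na(all_tp$npv))
  expect_error(detection_metrics(confusion(0, 0, 0, 0)), "no slices")
})

test_that("accuracy lies between sensitivity and specificity", {
  set.seed(94)
  for (i in 1:50) {
    tal <- confusion(sample(0:30, 1), sample(0:30, 1), sample(0:30, 1), sample(0:30, 1))
    dm <- detection_metrics(tal)
    if (!is.na(dm$sensitivity) && !is.na(dm$specificity)) {
      expect_gte(dm$accuracy, min(dm$sensitivity, dm$specificity) - 1e-9)
      expect_lte(dm$accuracy, max(dm$sensitivity, dm$specificity) + 1e-9)
    }
  }
})

test_that("dataset summaries use sample SD and handle single scans", {
  one <- dataset_summary(tibble::tibble(dsc = 0.9))
  expect_equal(one$sd, 0)
  two <- dataset_summary(tibble::tibble(dsc = c(1.0, 0.5)))
  expect_equal(two$mean, 0.75)
  three <- dataset_summary(tibble::tibble(dsc = c(0.8, 0.9, 0.7)))
  expect_equal(three$mean, 0.8)
  expect_equal(three$sd, 0.1)
  expect_error(dataset_summary(tibble::tibble(dsc = numeric(0))), "no scans")
})
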