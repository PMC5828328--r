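test_that("confusion_matrix counts (true class, predicted class) pairs", {
  truth <- matrix(c(0, 0, 1, 1), 2)
  pred <- matrix(c(0, 1, 1, 0), 2)
  cm <- confusion_matrix(pred, truth)$counts
  # rows = true class, columns = predicted class
  expect_equal(cm, matrix(c(1, 1, 1, 1), 2))
  # frozen hand case: 16 pixels
  truth <- matrix(c(rep(0, 10), rep(1, 6)), 4)
  pred <- truth
  pred[1] <- 1L  # one background pixel flipped to vessel
  cm <- confusion_matrix(pred, truth)$counts
  expect_equal(cm, matrix(c(9, 0, 1, 6), 2))
  expect_error(confusion_matrix(matrix(0, 2, 2), matrix(0, 3, 3)))
})

test_that("pixel metrics match the published closed forms", {
  cm <- as_confusion(matrix(c(8, 1, 2, 5), 2))  # n00=8 n01=2 n10=1 n11=5
  m <- pixel_metrics(cm)
  expect_equal(m$pA, 13 / 16)
  expect_equal(m$pA, 0.8125)
  expect_equal(m$mA, (8 / 10 + 5 / 6) / 2)
  expect_equal(m$mA, 0.81666667, tolerance = 1e-7)
  expect_equal(m$mIU, (8 / 11 + 5 / 8) / 2)
  expect_equal(m$mIU, 0.67613636, tolerance = 1e-7)
  # a perfect prediction scores 1 on everything
  p <- pixel_metrics(as_confusion(matrix(c(12, 0, 0, 4), 2)))
  expect_equal(c(p$pA, p$mA, p$mIU), c(1, 1, 1))
})

test_that("pixel metrics skip degenerate classes rather than divide by 0", {
  # truth has no vessel pixels at all; a correct all-background prediction
  cm <- as_confusion(matrix(c(16, 0, 0, 0), 2))
  m <- pixel_metrics(cm)
  expect_equal(m$pA, 1)
  expect_equal(m$mA, 1)   # vessel class excluded (t_i = 0)
  expect_equal(m$mIU, 1)  # vessel class excluded (t_i + p_i = 0)
  # truth empty but prediction marks vessels: vessel IU defined (0), mA not
  cm2 <- as_confusion(matrix(c(12, 0, 4, 0), 2))
  m2 <- pixel_metrics(cm2)
  expect_equal(m2$mA, 12 / 16)
  expect_equal(m2$mIU, (12 / 16 + 0) / 2)
})

test_that("pixel metrics agree with the counting-loop oracle on random masks", {
  set.seed(21)
  for (trial in 1:50) {
    truth <- random_mask(8, 8)
    pred <- random_mask(8, 8)
    m <- pixel_metrics(confusion_matrix(pred, truth))
    o <- oracle_pixel_metrics(pred, truth)
    expect_equal(m$pA, o$pA)
    expect_equal(m$mA, o$mA)
    expect_equal(m$mIU, o$mIU)
  }
})

test_that("component extraction respects connectivity and size threshold", {
  mask <- matrix(0L, 6, 6)
  mask[1, 1] <- 1L
  mask[2, 2] <- 1L  # diagonal neighbor of (1,1)
  mask[5:6, 5:6] <- 1L
  cfg8 <- object_match_config(min_component_px = 1L, connectivity = 8)
  cfg4 <- object_match_config(min_component_px = 1L, connectivity = 4)
  expect_equal(length(extract_components(mask, cfg8)), 2L)
  expect_equal(length(extract_components(mask, cfg4)), 3L)
  # size filter drops the 2-pixel diagonal pair under 8-connectivity
  cfg_min3 <- object_match_config(min_component_px = 3L, connectivity = 8)
  comps <- extract_components(mask, cfg_min3)
  expect_equal(length(comps), 1L)
  expect_equal(comps[[1]]$size, 4L)
  expect_error(extract_components(matrix(2L, 2, 2)), "binary")
})

test_that("component labeling matches the BFS oracle on random masks", {
  set.seed(31)
  for (conn in c(4, 8)) {
    for (trial in 1:25) {
      mask <- random_mask(12, 12, p = 0.35)
      cfg <- object_match_config(min_component_px = 1L, connectivity = conn)
      comps <- extract_components(mask, cfg)
      ol <- oracle_label(mask, conn)
      expect_equal(length(comps), max(ol))
      # same partition of foreground pixels (compare as sets of sets)
      pk <- sort(vapply(comps, function(c) {
        paste(sort(c$pixels[, 1] + nrow(mask) * c$pixels[, 2]),
              collapse = ",")
      }, character(1)))
      ok <- sort(vapply(seq_len(max(ol)), function(id) {
        w <- which(ol == id) - 1L
        paste(sort(w), collapse = ",")
      }, character(1)))
      expect_identical(pk, ok)
    }
  }
})

test_that("object counting matches exhaustive matching on random masks", {
  set.seed(41)
  cfg <- object_match_config(min_component_px = 2L, iou_threshold = 0.25,
                             connectivity = 8)
  for (trial in 1:20) {
    truth <- random_mask(10, 10, p = 0.3)
    pred <- random_mask(10, 10, p = 0.3)
    # keep the oracle's exhaustive enumeration tractable
    if (length(extract_components(pred, cfg)) > 4L) next
    got <- count_fp_fn(pred, truth, cfg)
    want <- oracle_match_counts(pred, truth, min_px = 2, thr = 0.25)
    expect_equal(got$tp, want$tp)
    expect_equal(got$fp, want$fp)
    expect_equal(got$fn, want$fn)
  }
})

test_that("object counting handles empty and identical predictions", {
  truth <- matrix(0L, 20, 20)
  truth[2:8, 2:8] <- 1L
  truth[12:19, 12:19] <- 1L
  cfg <- object_match_config(min_component_px = 30L)
  # empty prediction: no false positives, every truth object missed
  e <- count_fp_fn(matrix(0L, 20, 20), truth, cfg)
  expect_equal(e$fp, 0L)
  expect_equal(e$fn, 2L)
  expect_equal(e$tp, 0L)
  # identical masks: perfect matching
  p <- count_fp_fn(truth, truth, cfg)
  expect_equal(p$fp, 0L)
  expect_equal(p$fn, 0L)
  expect_equal(p$tp, 2L)
  expect_equal(p$matches$iou, c(1, 1))
  # both empty
  z <- count_fp_fn(matrix(0L, 5, 5), matrix(0L, 5, 5))
  expect_equal(c(z$tp, z$fp, z$fn), c(0L, 0L, 0L))
})

test_that("matching is one-to-one under the IoU threshold", {
  truth <- matrix(0L, 12, 24)
  truth[2:11, 2:11] <- 1L  # one 100-px truth object
  pred <- matrix(0L, 12, 24)
  pred[2:11, 2:6] <- 1L    # overlaps truth, IoU = 50/100 = 0.5
  pred[2:11, 14:20] <- 1L  # disjoint from truth
  cfg <- object_match_config(min_component_px = 30L, iou_threshold = 0.25)
  r <- count_fp_fn(pred, truth, cfg)
  expect_equal(r$tp, 1L)
  expect_equal(r$fp, 1L)  # the second prediction cannot reuse the truth
  expect_equal(r$fn, 0L)
  expect_equal(r$matches$iou, 0.5)
})
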