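test_that("boundary MAD reproduces hand-computed distances and symmetry", {
  a <- rep(10, 6)
  expect_equal(boundary_mad(a, a), 0)
  expect_equal(boundary_mad(a, rep(13, 6)), 3)  # both directed terms are 3
  set.seed(2)
  x <- sample(5:50, 12)
  y <- sample(5:50, 12)
  expect_equal(boundary_mad(x, y), boundary_mad(y, x))
  expect_error(boundary_mad(numeric(0), a), "empty")
  # bounded by the image diagonal for in-image boundaries
  expect_lte(boundary_mad(rep(1, 12), rep(60, 12)), sqrt(60^2 + 12^2))
})

test_that("boundary RMSE matches its closed forms", {
  a <- c(3, 6, 1, 9)
  expect_equal(boundary_rmse(a, a), 0)
  expect_equal(boundary_rmse(c(13, 6, 1, 9), c(10, 10, 1, 9)), 2.5)
  expect_equal(boundary_rmse(a + 4, a), 4)  # constant offset k -> |k|
  expect_error(boundary_rmse(a, c(1, 2)), "same number")
})

test_that("Dice hits identity, disjointness and the hand-computed overlap", {
  m <- matrix(FALSE, 20, 20)
  gt <- m; gt[1:10, 1:10] <- TRUE
  expect_equal(dice_coefficient(gt, gt), 1)
  other <- m; other[11:20, 11:20] <- TRUE
  expect_equal(dice_coefficient(gt, other), 0)
  # |GT| = 100, |SEG| = 80, overlap 70 -> 140/180
  seg <- m; seg[1:10, 1:7] <- TRUE; seg[11:20, 1] <- TRUE
  expect_equal(sum(seg), 80)
  expect_equal(sum(seg & gt), 70)
  expect_equal(dice_coefficient(seg, gt), 140 / 180)
  expect_error(dice_coefficient(m, m), "empty")
})

test_that("confusion metrics reproduce Eq.-style substitutions", {
  m <- matrix(FALSE, 20, 20)
  gt <- m; gt[1:10, 1:10] <- TRUE
  expect_equal(unname(confusion_metrics(gt, gt)), c(1, 1, 0))
  comp <- !gt
  expect_equal(unname(confusion_metrics(comp, gt)), c(0, 0, 1))
  # TP = 90, FN = 10, FP = 5, TN = 895
  gt2 <- matrix(FALSE, 20, 50); gt2[, 1:5] <- TRUE       # 100 positives
  seg2 <- gt2; seg2[1:10, 1] <- FALSE                    # lose 10 -> FN
  seg2[1:5, 6] <- TRUE                                   # gain 5 -> FP
  cm <- confusion_metrics(seg2, gt2)
  expect_equal(unname(cm["accuracy"]), 985 / 1000)
  expect_equal(unname(cm["sensitivity"]), 0.9)
  expect_equal(unname(cm["error_rate"]), 5 / 900)
  expect_error(confusion_metrics(m, m), "TP \\+ FN")
})

test_that("confusion metrics are invariant under joint translation", {
  m <- matrix(FALSE, 30, 30)
  gt <- m; gt[5:12, 4:20] <- TRUE
  seg <- m; seg[6:13, 4:20] <- TRUE
  gt2 <- m; gt2[15:22, 8:24] <- TRUE
  seg2 <- m; seg2[16:23, 8:24] <- TRUE
  expect_equal(confusion_metrics(seg, gt), confusion_metrics(seg2, gt2))
  expect_equal(dice_coefficient(seg, gt), dice_coefficient(seg2, gt2))
})

test_that("layer masks partition the ILM..RPE-Choroid band", {
  ph <- generate_phantom(small_spec())
  masks <- layer_masks(ph$boundaries, height = 96)
  total <- Reduce(`+`, masks)
  expect_true(all(total <= 1))  # masks disjoint
  W <- ncol(total)
  rowmat <- matrix(seq_len(96), 96, W)
  band <- rowmat >= matrix(ph$boundaries[, 1], 96, W, byrow = TRUE) &
    rowmat < matrix(ph$boundaries[, 8], 96, W, byrow = TRUE)
  expect_equal(total == 1, band)
})

test_that("full evaluation report is exact on a self-comparison", {
  ph <- generate_phantom(small_spec())
  ev <- evaluate_segmentation(ph$boundaries, ph$boundaries, height = 96)
  expect_true(all(ev$boundaries$mad == 0))
  expect_true(all(ev$boundaries$rmse == 0))
  expect_true(all(ev$layer_dice == 1))
  expect_equal(unname(ev$rnflt),
               c(1, 1, 0, 1))
})
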