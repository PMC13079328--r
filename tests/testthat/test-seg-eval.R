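test_that("overlap metrics follow the TP-based formulas", {
  dims <- c(18, 18, 18)
  a <- grid_from_voxels(as.matrix(expand.grid(2:4, 2:4, 2)), dims)
  expect_equal(overlap_metrics(a, a),
               list(precision = 1, recall = 1, overall_dice = 1))
  # 10 voxels each, 5 overlapping
  pred <- grid_from_voxels(cbind(1:10, 3, 3), dims)
  truth <- grid_from_voxels(cbind(6:15, 3, 3), dims)
  m <- overlap_metrics(pred, truth)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$overall_dice, 0.5)
  # empty prediction: recall 0, precision missing
  empty <- grid_from_voxels(matrix(numeric(0), ncol = 3), dims)
  m2 <- overlap_metrics(empty, truth)
  expect_true(is.na(m2$precision))
  expect_equal(m2$recall, 0)
  expect_equal(m2$overall_dice, 0)
  m3 <- overlap_metrics(empty, empty)
  expect_true(all(is.na(unlist(m3))))
})

test_that("overall dice is symmetric and precision/recall swap", {
  set.seed(101)
  for (r in 1:6) {
    p <- random_mask(c(10, 10, 10), 0.2)
    t <- random_mask(c(10, 10, 10), 0.2)
    if (sum(p$values) == 0 || sum(t$values) == 0) next
    mp <- overlap_metrics(p, t)
    mt <- overlap_metrics(t, p)
    expect_equal(mp$overall_dice, mt$overall_dice)
    expect_equal(mp$precision, mt$recall)
    expect_equal(mp$recall, mt$precision)
  }
})

test_that("voxel-wise dice averages per-truth-lesion dice", {
  dims <- c(16, 16, 16)
  # truth lesion of 4 voxels; prediction covers 2 of them, nothing else
  truth <- grid_from_voxels(cbind(2:5, 3, 3), dims)
  pred <- grid_from_voxels(cbind(2:3, 3, 3), dims)
  expect_equal(voxelwise_dice(pred, truth), 2 * 2 / (2 + 4))
  # two lesions: one matched exactly, one missed
  truth2 <- grid_from_voxels(rbind(cbind(2:4, 3, 3), cbind(10:12, 10, 10)),
                             dims)
  pred2 <- grid_from_voxels(cbind(2:4, 3, 3), dims)
  expect_equal(voxelwise_dice(pred2, truth2), 0.5)
  expect_equal(voxelwise_dice(truth2, truth2), 1)
  empty <- grid_from_voxels(matrix(numeric(0), ncol = 3), dims)
  expect_error(voxelwise_dice(pred, empty), "lesion")
})

test_that("lesion-wise dice counts lesion hits, misses and spurious", {
  dims <- c(16, 16, 16)
  truth <- grid_from_voxels(rbind(cbind(2:4, 3, 3), cbind(10:12, 10, 10)),
                            dims)
  # hits one lesion exactly, adds one spurious component
  pred <- grid_from_voxels(rbind(cbind(2:4, 3, 3), cbind(7:8, 14, 14)), dims)
  expect_equal(lesionwise_dice(pred, truth), 2 * 1 / (2 * 1 + 1 + 1))
  expect_equal(lesionwise_dice(truth, truth), 1)
  empty <- grid_from_voxels(matrix(numeric(0), ncol = 3), dims)
  expect_equal(lesionwise_dice(empty, truth), 0)
  expect_error(lesionwise_dice(empty, empty), "empty")
})

test_that("both lesion-level dice variants reach 1 only on exact match", {
  dims <- c(14, 14, 14)
  truth <- grid_from_voxels(rbind(cbind(2:4, 3, 3), cbind(9:10, 9, 9)), dims)
  expect_equal(voxelwise_dice(truth, truth), 1)
  expect_equal(lesionwise_dice(truth, truth), 1)
  # adding one voxel to a matched component breaks voxel-wise but not
  # lesion-wise dice
  pv <- truth$values
  pv[6, 4, 4] <- 1L  # touches nothing else
  pred <- voxel_grid(pv, truth$spacing)
  expect_lt(voxelwise_dice(pred, truth), 1)
})

test_that("agreement stats use average ranks and population moments", {
  expect_equal(agreement_stats(c(1, 2, 3), c(2, 3, 4)),
               list(spearman_rho = 1, lin_ccc = 4 / 7))
  ident <- agreement_stats(c(3, 1, 7, 5), c(3, 1, 7, 5))
  expect_equal(ident$spearman_rho, 1)
  expect_equal(ident$lin_ccc, 1)
  expect_equal(agreement_stats(c(1, 2, 3), c(3, 2, 1))$spearman_rho, -1)
  expect_true(is.na(agreement_stats(c(1, 1, 1), c(1, 2, 3))$spearman_rho))
  expect_error(agreement_stats(1:4, 1:5), "mismatch")
  expect_error(agreement_stats(1:2, 1:2), "3")
})

test_that("concordance never exceeds Pearson correlation in magnitude", {
  set.seed(111)
  for (r in 1:50) {
    x <- rnorm(20, sd = runif(1, 0.5, 3))
    y <- 0.5 * x + rnorm(20, mean = runif(1, -2, 2))
    ccc <- agreement_stats(x, y)$lin_ccc
    expect_lte(abs(ccc), abs(cor(x, y)) + 1e-12)
  }
})

test_that("cohort evaluation reports per-subject metrics and agreement", {
  set.seed(121)
  dims <- c(12, 12, 12)
  truths <- lapply(1:4, function(i) random_mask(dims, 0.1))
  preds <- lapply(truths, function(t) {
    v <- t$values
    drop <- which(v == 1L)
    v[sample(drop, length(drop) %/% 4)] <- 0L
    voxel_grid(v, t$spacing)
  })
  ev <- evaluate_segmentation(preds, truths)
  expect_equal(nrow(ev$per_subject), 4)
  expect_true(all(ev$per_subject$precision == 1))   # pred subset of truth
  expect_true(all(ev$per_subject$recall < 1))
  expect_equal(ev$agreement$measure, c("count", "volume"))
})
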