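test_that("distance bins use half-open-above 5 mm intervals", {
  expect_equal(as.character(bin_distance(c(0, 5, 5.0001, 30, 30.5, Inf))),
               c("WITHIN", "B5", "B10", "B30", "OVER30", "OVER30"))
  expect_equal(as.character(bin_distance(c(10, 15.0001, 25))),
               c("B10", "B20", "B25"))
  expect_error(bin_distance(-1), "negative")
})

test_that("proximity categories coarsen the bins consistently", {
  expect_equal(as.character(proximity_category(c(0, 5, 5.1, Inf))),
               c("WITHIN", "NEAR", "FAR", "FAR"))
  expect_error(proximity_category(-0.5), "negative")
  # coarsening: WITHIN<->WITHIN, B5<->NEAR, farther bins<->FAR
  set.seed(61)
  d <- c(0, runif(200, 0, 40), 5, 30, Inf)
  b <- as.character(bin_distance(d))
  p <- as.character(proximity_category(d))
  expect_true(all(p[b == "WITHIN"] == "WITHIN"))
  expect_true(all(p[b == "B5"] == "NEAR"))
  expect_true(all(p[!b %in% c("WITHIN", "B5")] == "FAR"))
})

test_that("expanding window keeps searching past the first Chebyshev hit", {
  # first hit at r=2 is (2,2,2) at sqrt(12) ~ 3.46; the true minimum is
  # (3,0,0) at 3.0, found only by continuing the expansion
  b <- grid_from_voxels(rbind(c(2, 2, 2), c(3, 0, 0)))
  expect_equal(min_distance_to_boundary(c(0, 0, 0), b), 3.0)
  expect_equal(brute_force_min_distance(c(0, 0, 0), b), 3.0)
  b1 <- grid_from_voxels(c(3, 0, 0))
  expect_equal(min_distance_to_boundary(c(0, 0, 0), b1), 3.0)
  b2 <- grid_from_voxels(c(1, 1, 0))
  expect_equal(min_distance_to_boundary(c(0, 0, 0), b2), sqrt(2))
  # boundary voxel at the point itself
  b3 <- grid_from_voxels(c(2, 3, 4))
  expect_equal(min_distance_to_boundary(c(2, 3, 4), b3), 0)
  # empty boundary signals no lesion
  empty <- grid_from_voxels(matrix(numeric(0), ncol = 3))
  expect_identical(min_distance_to_boundary(c(0, 0, 0), empty), Inf)
})

test_that("window search equals the exhaustive minimum exactly", {
  set.seed(71)
  n_checked <- 0
  for (i in 1:300) {
    dims <- sample(6:24, 3, replace = TRUE)
    sp <- if (i %% 2) c(1, 1, 1) else runif(3, 0.4, 2.5)
    m <- random_mask(dims, p = runif(1, 0.002, 0.05), spacing = sp)
    if (sum(m$values) == 0) next
    p <- runif(3) * (dims - 1) * sp
    expect_identical(min_distance_to_boundary(p, m),
                     brute_force_min_distance(p, m))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 250)
})

test_that("distances are invariant under joint integer translation", {
  set.seed(81)
  vox <- cbind(sample(2:6, 5, TRUE), sample(2:6, 5, TRUE), sample(2:6, 5, TRUE))
  shift <- c(3, 2, 4)
  b0 <- grid_from_voxels(vox, dims = c(16, 16, 16))
  b1 <- grid_from_voxels(sweep(vox, 2, shift, `+`), dims = c(16, 16, 16))
  for (r in 1:20) {
    p <- runif(3, 0, 6)
    expect_equal(min_distance_to_boundary(p, b0),
                 min_distance_to_boundary(p + shift, b1), tolerance = 1e-12)
  }
})

test_that("subject profile applies the within-lesion and no-lesion rules", {
  dims <- c(24, 24, 24)
  # WML: small solid block; one EPVS inside it, one 3 mm away
  wml_vox <- as.matrix(expand.grid(10:13, 10:13, 10:13))
  wml <- grid_from_voxels(wml_vox, dims)
  epvs <- grid_from_voxels(rbind(c(11, 11, 11), c(16, 11, 11)), dims)
  cc <- connected_components(epvs, 26)
  prof <- subject_distance_profile(cc$components, wml)
  expect_true(prof$has_wml)
  expect_equal(unname(prof$histogram[["WITHIN"]]), 1)
  expect_equal(unname(prof$histogram[["B5"]]), 1)
  expect_equal(sum(prof$histogram), 2)
  expect_equal(prof$records$distance_mm[prof$records$within_wml], 0)

  # no WML: all distances infinite, flagged
  nowml <- grid_from_voxels(matrix(numeric(0), ncol = 3), dims)
  prof2 <- subject_distance_profile(cc$components, nowml)
  expect_false(prof2$has_wml)
  expect_equal(unname(prof2$histogram[["OVER30"]]), 2)
  expect_true(all(is.infinite(prof2$records$distance_mm)))

  # no EPVS: empty profile with all-zero histogram
  prof3 <- subject_distance_profile(
    connected_components(nowml, 26)$components, wml)
  expect_equal(nrow(prof3$records), 0)
  expect_true(all(prof3$histogram == 0))
})

test_that("bin histogram always sums to the number of components", {
  set.seed(91)
  for (rep in 1:5) {
    dims <- c(28, 28, 28)
    epvs <- random_mask(dims, p = 0.01)
    wml <- grid_from_voxels(
      as.matrix(expand.grid(12:16, 12:16, 12:16)), dims)
    cc <- connected_components(epvs, 26)
    prof <- subject_distance_profile(cc$components, wml)
    expect_equal(sum(prof$histogram), cc$n)
    px <- table(prof$records$proximity)
    expect_equal(sum(px), cc$n)
  }
})
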