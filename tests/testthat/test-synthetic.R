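test_that("identical config and seed regenerate the cohort bit-identically", {
  cfg <- small_sim_config(n = 4)
  a <- simulate_cohort(cfg, seed = 9)
  b <- simulate_cohort(cfg, seed = 9)
  expect_identical(a$truth, b$truth)
  for (i in seq_len(cfg$n)) {
    expect_identical(a$subjects[[i]]$epvs_idx, b$subjects[[i]]$epvs_idx)
    expect_identical(a$subjects[[i]]$wml_idx, b$subjects[[i]]$wml_idx)
  }
  c2 <- simulate_cohort(cfg, seed = 10)
  expect_false(identical(a$truth, c2$truth))
})

test_that("cohort bookkeeping: group split, files, manifest consumability", {
  cfg <- small_sim_config(n = 9)
  dir <- tempfile("cohort")
  co <- simulate_cohort(cfg, seed = 3, dir = dir)
  expect_equal(nrow(co$manifest), 9)
  expect_equal(length(list.files(dir, "_epvs\\.nii\\.gz$")), 9)
  expect_equal(length(list.files(dir, "_wml\\.nii\\.gz$")), 9)
  expect_equal(as.vector(table(co$truth$group)[c("CU", "MCI", "AD")]),
               c(5, 3, 1))
  # the written manifest is readable and drives the pipeline unchanged
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(man$subject_id, co$manifest$subject_id)
  met <- run_metrics(man[1:2, ])
  expect_equal(nrow(met), 2)
  expect_length(attr(met, "failures"), 0)
  unlink(dir, recursive = TRUE)
})

test_that("truth bin counts equal the pipeline's bin histogram", {
  co <- simulate_cohort(small_sim_config(n = 8), seed = 17)
  met <- run_metrics(co)
  bcols <- paste0("bin_", distance_bins())
  expect_identical(as.matrix(met[bcols]),
                   as.matrix(co$truth[match(met$subject_id,
                                            co$truth$subject_id), bcols]),
                   ignore_attr = TRUE)
  # and both sum to the component count
  expect_true(all(rowSums(met[bcols]) == met$n_epvs))
})

test_that("a group with zero-lesion probability one is flagged downstream", {
  g <- data.frame(label = "G", fraction = 1, count_log_rate_offset = 0,
                  wml_pct_mean = 0.6, wml_sdlog = 0.7, age_mean = 74,
                  age_sd = 8, p_female = 0.5, p_amyloid_pos = 0.4,
                  p_apoe4 = 0.35, p_no_wml = 1, stringsAsFactors = FALSE)
  co <- simulate_cohort(sim_config(n = 4, grid_shape = c(48L, 48L, 48L),
                                   groups = g), seed = 5)
  met <- run_metrics(co)
  expect_true(all(!met$has_wml))
  expect_true(all(met$epvs_count_wml == 0))
  expect_true(all(met$wml_volume_mm3 == 0))
  # all components land in the terminal distance bin
  expect_true(all(met$bin_OVER30 == met$n_epvs))
})

test_that("placement intensity concentrates EPVS near lesions when A > 0", {
  n <- 24
  co0 <- simulate_cohort(one_group_config(n, grid = 48,
                                          coupling_amplitude = 0),
                         seed = 23)
  coA <- simulate_cohort(one_group_config(n, grid = 48,
                                          coupling_amplitude = 8,
                                          coupling_scale = 5),
                         seed = 23)
  near_share <- function(co) {
    tr <- co$truth[co$truth$has_wml, ]
    sum(tr$bin_WITHIN + tr$bin_B5) / sum(tr$n_epvs_components)
  }
  expect_gt(near_share(coA), near_share(co0) + 0.05)
})

test_that("with A = 0 placement is uniform over eligible tissue", {
  # near-lesion share under uniform placement should match the share of
  # eligible voxels within 5 mm of the boundary (centroid jitter from
  # tubule stamping makes this approximate)
  n <- 30
  cfg <- one_group_config(n, grid = 48, coupling_amplitude = 0)
  co <- simulate_cohort(cfg, seed = 29)
  tmpl <- co$template
  d <- tmpl$dims
  exp_share <- obs_near <- obs_tot <- 0
  for (i in seq_len(n)) {
    if (!co$truth$has_wml[i]) next
    wml <- array(0L, d)
    wml[co$subjects[[i]]$wml_idx] <- 1L
    bnd <- boundary_shell(voxel_grid(wml, cfg$spacing_mm))
    df <- pvstopo:::.edt3d(as.integer(bnd$values), d, cfg$spacing_mm)
    el <- tmpl$eligible
    exp_share <- exp_share + mean(df[el] <= 5) * co$truth$n_epvs_components[i]
    obs_near <- obs_near + co$truth$bin_WITHIN[i] + co$truth$bin_B5[i]
    obs_tot <- obs_tot + co$truth$n_epvs_components[i]
  }
  expect_equal(obs_near / obs_tot, exp_share / obs_tot, tolerance = 0.35)
})

test_that("group rate offsets are recovered from realized counts", {
  # two groups with a true rate ratio of 1.5 at the count-generation
  # level; fit on the generator's realized component counts
  g <- data.frame(label = c("A", "B"), fraction = c(0.5, 0.5),
                  count_log_rate_offset = c(0, log(1.5)),
                  wml_pct_mean = 0.6, wml_sdlog = 0.7, age_mean = 74,
                  age_sd = 8, p_female = 0.5, p_amyloid_pos = 0.4,
                  p_apoe4 = 0.35, p_no_wml = 0.02, stringsAsFactors = FALSE)
  co <- simulate_cohort(sim_config(n = 160, grid_shape = c(48L, 48L, 48L),
                                   groups = g), seed = 31)
  d <- co$truth
  m <- suppressWarnings(fit_count_model(
    d, "n_epvs_components", predictors = c("group", "age", "sex"),
    family = "nb", group = "group", ref_level = "A"))
  b <- m$results[m$results$term == "groupB", ]
  expect_gt(b$ci_high, 1.2)
  expect_equal(b$beta_exp, 1.5, tolerance = 0.25)
})
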