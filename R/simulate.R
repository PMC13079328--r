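#' Simulation configuration for synthetic EPVS/WML cohorts
#'
#' Defines the study conditions the generator emulates: a three-group
#' cohort (CU, MCI, AD, in the approximate 55/34/11 proportions of a
#' typical aging cohort) of paired EPVS and WML masks inside an
#' ellipsoidal brain on a 96^3 grid at 1 mm isotropic spacing. Total
#' EPVS counts per subject are negative-binomial with group rate-ratio
#' structure and a positive dependence on lesion burden; EPVS are placed
#' with an intensity that decays with distance d from the WML boundary,
#' `lambda(d) = 1 + A exp(-d / tau)`, and stamped as random-orientation
#' tubules. With probability `within_wml_zero_prob`, a subject's
#' within-WML EPVS are relocated outside the lesion, producing the
#' structural zeros that motivate the zero-inflated count model for the
#' within-lesion region (roughly 60% of subjects have a zero
#' within-lesion count at these defaults).
#'
#' Group-level defaults follow the demographics of an aging AD-continuum
#' cohort: mean age 73/74.7/77.1 years, female fraction 0.59/0.44/0.43,
#' amyloid-positive fraction 0.27/0.45/0.82 and WML burden 0.51/0.69/0.83
#' per cent of ICV for CU/MCI/AD respectively.
#'
#' @param n total number of subjects (split across groups by `fraction`).
#' @param grid_shape integer triple, default `c(96, 96, 96)`.
#' @param spacing_mm voxel spacing, default 1 mm isotropic.
#' @param groups data.frame with columns `label`, `fraction`,
#'   `count_log_rate_offset`, `wml_pct_mean` (lognormal location for WML
#'   volume as % of ICV), `wml_sdlog`, `age_mean`, `age_sd`, `p_female`,
#'   `p_amyloid_pos`, `p_apoe4`, `p_no_wml`; defaults as described.
#' @param nb_dispersion NB dispersion alpha (variance `mu + alpha mu^2`).
#' @param count_intercept log expected EPVS count for a reference
#'   subject.
#' @param age_effect,sex_effect log-rate effects per SD of age and for
#'   male sex.
#' @param wml_count_coef log-rate effect per log-unit of WML burden
#'   (centered), giving the positive lesion-burden/count association.
#' @param coupling_amplitude A >= 0 in the placement intensity.
#' @param coupling_scale tau > 0 (mm) in the placement intensity.
#' @param within_wml_zero_prob structural-zero probability pi.
#' @param epvs_length_range tubule length range in voxels.
#' @param wml_seed_range range of the number of WML seed points.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 60,
                       grid_shape = c(96L, 96L, 96L),
                       spacing_mm = c(1, 1, 1),
                       groups = NULL,
                       nb_dispersion = 0.5,
                       count_intercept = log(40),
                       age_effect = 0.1,
                       sex_effect = 0.1,
                       wml_count_coef = 0.3,
                       coupling_amplitude = 4,
                       coupling_scale = 5,
                       within_wml_zero_prob = 0.41,
                       epvs_length_range = c(3L, 8L),
                       wml_seed_range = c(1L, 4L)) {
  if (is.null(groups)) {
    groups <- data.frame(
      label = c("CU", "MCI", "AD"),
      fraction = c(0.55, 0.34, 0.11),
      count_log_rate_offset = c(0, log(1.23), log(1.1)),
      wml_pct_mean = c(0.51, 0.69, 0.83),
      wml_sdlog = c(0.7, 0.7, 0.7),
      age_mean = c(73.0, 74.7, 77.1),
      age_sd = c(8.1, 8.1, 8.4),
      p_female = c(0.59, 0.44, 0.43),
      p_amyloid_pos = c(0.27, 0.45, 0.82),
      p_apoe4 = c(0.32, 0.38, 0.78),
      p_no_wml = c(0.03, 0.02, 0.01),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(groups$fraction > 0), !anyDuplicated(groups$label),
            nb_dispersion > 0, coupling_amplitude >= 0,
            coupling_scale > 0,
            within_wml_zero_prob >= 0, within_wml_zero_prob <= 1)
  structure(list(
    n = as.integer(n), grid_shape = as.integer(grid_shape),
    spacing_mm = as.numeric(spacing_mm), groups = groups,
    nb_dispersion = nb_dispersion, count_intercept = count_intercept,
    age_effect = age_effect, sex_effect = sex_effect,
    wml_count_coef = wml_count_coef,
    coupling_amplitude = coupling_amplitude,
    coupling_scale = coupling_scale,
    within_wml_zero_prob = within_wml_zero_prob,
    epvs_length_range = as.integer(epvs_length_range),
    wml_seed_range = as.integer(wml_seed_range)), class = "sim_config")
}

# Shared anatomy template: ellipsoidal brain, a white-matter shell
# (aseg-style label 2), cortical gray matter (label 3) and two
# basal-ganglia blobs (labels 11 and 50). Identical across subjects of a
# cohort; only lesions and EPVS vary.
sim_template <- function(config) {
  d <- config$grid_shape
  ctr <- (d - 1) / 2
  ax <- 0.88 * (d / 2 - 2)
  x <- (seq_len(d[1]) - 1 - ctr[1]) / ax[1]
  y <- (seq_len(d[2]) - 1 - ctr[2]) / ax[2]
  z <- (seq_len(d[3]) - 1 - ctr[3]) / ax[3]
  rho2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  lab <- array(0L, d)
  lab[rho2 <= 1] <- 3L                       # cortical GM
  lab[rho2 <= 0.8^2] <- 2L                   # WM shell
  core <- rho2 <= 0.35^2
  lab[core] <- 3L                            # deep GM core
  blob <- function(cx, semi) {
    bx <- (seq_len(d[1]) - 1 - (ctr[1] + cx)) / semi[1]
    by <- (seq_len(d[2]) - 1 - ctr[2]) / semi[2]
    bz <- (seq_len(d[3]) - 1 - ctr[3]) / semi[3]
    outer(outer(bx^2, by^2, `+`), bz^2, `+`) <= 1
  }
  lab[blob(-10, c(6, 8, 7))] <- 11L          # left BG
  lab[blob(10, c(6, 8, 7))] <- 50L           # right BG
  region_source <- voxel_grid(lab, config$spacing_mm)
  wm <- lab == 2L
  bg <- lab %in% default_region_labels()$bg
  eligible <- which(wm | bg)
  list(region_source = region_source,
       wm_idx = which(wm),
       eligible = eligible,
       icv_mm3 = sum(lab != 0L) * prod(config$spacing_mm),
       dims = d)
}

# Stamp a tubule of `len` voxels along a random direction from a center
# voxel; returns linear indices (1-based), in-bounds, unique.
stamp_tubule <- function(center_lin, len, dims) {
  i0 <- center_lin - 1L
  cx <- i0 %% dims[1]
  cy <- (i0 %/% dims[1]) %% dims[2]
  cz <- i0 %/% (dims[1] * dims[2])
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  t <- seq(0, len - 1)
  x <- round(cx + t * u[1]); y <- round(cy + t * u[2])
  z <- round(cz + t * u[3])
  ok <- x >= 0 & y >= 0 & z >= 0 &
        x < dims[1] & y < dims[2] & z < dims[3]
  unique(1L + x[ok] + dims[1] * (y[ok] + dims[2] * z[ok]))
}

#' Simulate one subject's EPVS and WML masks
#'
#' Draws covariates, grows a WML mask from random white-matter seeds by
#' stochastic dilation to a lognormal target volume, draws the total
#' EPVS count from a negative binomial, places EPVS centers with the
#' distance-decay intensity `1 + A exp(-d / tau)` (d from an exact
#' Euclidean distance transform of the lesion boundary) and stamps each
#' as a random-orientation tubule. Tubules centered outside the lesion
#' are clipped against it so EPVS and WML masks stay disjoint except for
#' deliberately placed within-lesion EPVS; with probability pi the
#' subject's within-lesion EPVS are relocated outside (a structural
#' zero). Ground-truth distances and bins are then derived from the
#' final masks with the exhaustive-minimum distance oracle, so the truth
#' table and the analysis pipeline describe exactly the same geometry.
#'
#' @param config a [sim_config()].
#' @param group row index into `config$groups`.
#' @param subject_id subject identifier string.
#' @param template internal anatomy template (computed if `NULL`).
#' @return List with `epvs` and `wml` (`voxel_grid`s), `region_source`,
#'   and `truth` (one-row data.frame incl. realized counts, bin counts
#'   and the structural-zero flag).
#' @export
simulate_subject <- function(config, group = 1L, subject_id = "S1",
                             template = NULL) {
  if (is.null(template)) template <- sim_template(config)
  g <- config$groups[group, ]
  d <- template$dims
  sp <- config$spacing_mm
  voxvol <- prod(sp)

  age <- round(rnorm(1, g$age_mean, g$age_sd), 1)
  sex <- if (runif(1) < g$p_female) "female" else "male"
  tracer <- sample(c("FBP", "FBB"), 1)
  has_pet <- runif(1) > 0.13
  suvr <- if (!has_pet) NA_real_ else {
    thr <- if (tracer == "FBP") 1.11 else 1.08
    pos <- runif(1) < g$p_amyloid_pos
    round(if (pos) thr + abs(rnorm(1, 0.15, 0.1))
          else thr - abs(rnorm(1, 0.12, 0.06)) - 0.005, 3)
  }
  a4 <- runif(2) < g$p_apoe4
  other <- sample(c("e2", "e3"), 2, replace = TRUE, prob = c(0.1, 0.9))
  apoe <- paste(sort(ifelse(a4, "e4", other)), collapse = "/")

  # lesion mask
  no_wml <- runif(1) < g$p_no_wml
  wml_vals <- array(0L, d)
  if (!no_wml) {
    target_pct <- exp(rnorm(1, log(g$wml_pct_mean), g$wml_sdlog))
    target_vox <- max(20L, round(target_pct / 100 * template$icv_mm3 /
                                   voxvol))
    if (target_vox > 0.5 * length(template$wm_idx))
      stop("target WML volume exceeds available white matter",
           call. = FALSE)
    n_seed <- sample(seq(config$wml_seed_range[1],
                         config$wml_seed_range[2]), 1)
    seeds <- sample(template$wm_idx, n_seed)
    wm_allowed <- integer(prod(d))
    wm_allowed[template$wm_idx] <- 1L
    grown <- .grow_region3d(as.integer(seeds - 1L), wm_allowed, d,
                            as.integer(target_vox), 0.6)
    wml_vals <- array(grown, d)
  }
  wml <- voxel_grid(wml_vals, sp)
  has_wml <- any(wml_vals == 1L)

  # EPVS count and placement weights
  wml_pct <- 100 * sum(wml_vals) * voxvol / template$icv_mm3
  eta <- config$count_intercept + g$count_log_rate_offset +
    config$age_effect * (age - 74) / 8 +
    config$sex_effect * (sex == "male") +
    if (has_wml) config$wml_count_coef * (log(wml_pct) - log(0.6)) else 0
  n_epvs <- rnbinom(1, size = 1 / config$nb_dispersion, mu = exp(eta))

  epvs_vals <- array(0L, d)
  forced_zero <- FALSE
  bnd <- if (has_wml) boundary_shell(wml) else NULL
  if (n_epvs > 0) {
    el <- template$eligible
    if (has_wml) {
      dist_field <- .edt3d(as.integer(bnd$values), d, sp)
      w <- 1 + config$coupling_amplitude *
        exp(-dist_field[el] / config$coupling_scale)
    } else w <- rep(1, length(el))
    centers <- el[sample.int(length(el), n_epvs, replace = TRUE,
                             prob = w)]
    forced_zero <- has_wml && runif(1) < config$within_wml_zero_prob
    if (forced_zero) {
      inside <- wml_vals[centers] == 1L
      if (any(inside)) {
        out_el <- el[wml_vals[el] == 0L]
        centers[inside] <- out_el[sample.int(length(out_el),
                                             sum(inside), replace = TRUE,
                                             prob = w[wml_vals[el] == 0L])]
      }
    }
    lens <- sample(seq(config$epvs_length_range[1],
                       config$epvs_length_range[2]),
                   n_epvs, replace = TRUE)
    for (k in seq_len(n_epvs)) {
      vox <- stamp_tubule(centers[k], lens[k], d)
      if (wml_vals[centers[k]] == 0L) vox <- vox[wml_vals[vox] == 0L]
      epvs_vals[vox] <- 1L
    }
  }
  epvs <- voxel_grid(epvs_vals, sp)

  # ground truth from the final masks, by exhaustive minimum over the
  # boundary voxels (same definition as brute_force_min_distance, with
  # the boundary coordinates hoisted out of the component loop)
  cc <- connected_components(epvs, 26)
  dists <- numeric(cc$n)
  if (cc$n > 0) {
    if (has_wml) {
      b0 <- which(bnd$values == 1L) - 1L
      bx <- (b0 %% d[1]) * sp[1]
      by <- ((b0 %/% d[1]) %% d[2]) * sp[2]
      bz <- (b0 %/% (d[1] * d[2])) * sp[3]
    }
    cen <- as.matrix(cc$components[, c("cx_mm", "cy_mm", "cz_mm")])
    ii <- cbind(pmin(pmax(round(cen[, 1] / sp[1]), 0), d[1] - 1) + 1,
                pmin(pmax(round(cen[, 2] / sp[2]), 0), d[2] - 1) + 1,
                pmin(pmax(round(cen[, 3] / sp[3]), 0), d[3] - 1) + 1)
    within <- has_wml & (wml_vals[ii] == 1L)
    for (k in seq_len(cc$n)) {
      dists[k] <- if (within[k]) 0
        else if (!has_wml) Inf
        else sqrt(min((bx - cen[k, 1])^2 + (by - cen[k, 2])^2 +
                      (bz - cen[k, 3])^2))
    }
  }
  bins <- table(bin_distance(dists))
  truth <- data.frame(
    subject_id = subject_id, group = g$label, age = age, sex = sex,
    amyloid_suvr = suvr, tracer = if (has_pet) tracer else NA_character_,
    apoe = apoe, icv_mm3 = template$icv_mm3,
    wml_volume_mm3 = sum(wml_vals) * voxvol,
    has_wml = has_wml, forced_zero = forced_zero,
    n_epvs_placed = n_epvs, n_epvs_components = cc$n,
    stringsAsFactors = FALSE)
  for (b in distance_bins()) truth[[paste0("bin_", b)]] <-
    as.integer(bins[[b]])
  list(epvs = epvs, wml = wml, region_source = template$region_source,
       truth = truth)
}

#' Simulate a cohort of paired EPVS/WML masks with known ground truth
#'
#' Generates `config$n` subjects (group membership by the configured
#' fractions, deterministically interleaved), each with its own RNG
#' substream derived from `seed` by a counter scheme, so the cohort is
#' bit-reproducible and independent of evaluation order. If `dir` is
#' given, masks are written as NIfTI and the manifest and truth tables
#' as CSV, ready for [run_metrics()]; otherwise everything is returned
#' in memory.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param dir optional output directory.
#' @return An object of class `pvs_cohort`: list with `manifest`
#'   (data.frame in the [read_manifest()] layout), `truth` (data.frame),
#'   and, for in-memory cohorts, `subjects` (list of per-subject mask
#'   lists) and `template`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L,
                            dir = NULL) {
  ng <- nrow(config$groups)
  counts <- diff(round(cumsum(c(0, config$groups$fraction)) /
                         sum(config$groups$fraction) * config$n))
  counts[ng] <- config$n - sum(counts[-ng])
  group_of <- rep(seq_len(ng), counts)
  template <- sim_template(config)
  subjects <- vector("list", config$n)
  truth <- vector("list", config$n)
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  manifest <- vector("list", config$n)
  for (i in seq_len(config$n)) {
    set.seed((as.integer(seed) + i * 7919L) %% 2147483647L)
    sid <- sprintf("S%04d", i)
    s <- simulate_subject(config, group_of[i], sid, template)
    truth[[i]] <- s$truth
    paths <- if (!is.null(dir)) {
      ep <- file.path(dir, paste0(sid, "_epvs.nii.gz"))
      wp <- file.path(dir, paste0(sid, "_wml.nii.gz"))
      write_mask(s$epvs, ep)
      write_mask(s$wml, wp)
      c(ep, wp)
    } else c(NA_character_, NA_character_)
    manifest[[i]] <- data.frame(
      subject_id = sid, epvs_mask = paths[1], wml_mask = paths[2],
      region_source = NA_character_, icv_mm3 = s$truth$icv_mm3,
      age = s$truth$age, sex = s$truth$sex,
      diagnosis = s$truth$group, amyloid_suvr = s$truth$amyloid_suvr,
      tracer = s$truth$tracer, apoe = s$truth$apoe,
      stringsAsFactors = FALSE)
    # store masks sparsely (foreground indices): EPVS and WML occupy a
    # tiny fraction of the grid, so a 500-subject cohort stays small
    if (is.null(dir))
      subjects[[i]] <- list(epvs_idx = which(s$epvs$values == 1L),
                            wml_idx = which(s$wml$values == 1L))
  }
  manifest <- do.call(rbind, manifest)
  truth <- do.call(rbind, truth)
  if (!is.null(dir)) {
    rs <- file.path(dir, "region_source.nii.gz")
    write_mask(template$region_source, rs)
    manifest$region_source <- rs
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE,
              na = "")
    subjects <- NULL
  }
  structure(list(manifest = manifest, truth = truth,
                 subjects = subjects, template = template,
                 config = config, seed = seed, dir = dir),
            class = "pvs_cohort")
}
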