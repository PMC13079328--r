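#' Per-subject regional and distance metrics
#'
#' For every subject, builds the five region masks, computes EPVS counts
#' and volumes per region (intersection rule), ICV-normalized burdens,
#' the WML boundary shell, and the distance profile of every EPVS
#' component with its 5 mm bin histogram. Accepts either a manifest
#' data.frame (mask paths are read from disk) or an in-memory
#' `pvs_cohort` from [simulate_cohort()]. By default a failing subject
#' is skipped and logged rather than aborting the cohort.
#'
#' @param x manifest data.frame (layout of [read_manifest()]) or a
#'   `pvs_cohort`.
#' @param connectivity component connectivity (default 26).
#' @param label_config region label ids, see [build_region_set()].
#' @param strict abort on the first failing subject.
#' @return data.frame with one row per subject: `subject_id`,
#'   `icv_mm3`, per-region `epvs_count_*`, `epvs_volume_mm3_*` and
#'   `epvs_volume_pct_icv_*` for wb/wm/bg/wml/non_wml, `wml_volume_mm3`,
#'   `wml_volume_pct_icv`, `n_epvs`, bin counts `bin_WITHIN` ...
#'   `bin_OVER30`, `has_wml`. Failed subjects are recorded in the
#'   `failures` attribute.
#' @export
run_metrics <- function(x, connectivity = 26,
                        label_config = default_region_labels(),
                        strict = FALSE) {
  in_memory <- inherits(x, "pvs_cohort")
  manifest <- if (in_memory) x$manifest else x
  if (!nrow(manifest)) stop("empty manifest", call. = FALSE)
  region_cache <- new.env(parent = emptyenv())
  static_for <- function(key, region_source) {
    if (is.null(region_cache[[key]]))
      region_cache[[key]] <- region_static(region_source, label_config)
    region_cache[[key]]
  }
  rows <- vector("list", nrow(manifest))
  failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    res <- tryCatch({
      if (in_memory) {
        region_source <- x$template$region_source
        d <- dim(region_source$values)
        sp <- region_source$spacing
        dense <- function(idx) {
          v <- array(0L, d)
          v[idx] <- 1L
          voxel_grid(v, sp)
        }
        epvs <- dense(x$subjects[[i]]$epvs_idx)
        wml <- dense(x$subjects[[i]]$wml_idx)
        st <- static_for(".template", region_source)
      } else {
        epvs <- read_mask(manifest$epvs_mask[i], expect_binary = TRUE)
        wml <- read_mask(manifest$wml_mask[i], expect_binary = TRUE)
        rp <- manifest$region_source[i]
        if (is.null(region_cache[[paste0("src:", rp)]]))
          region_cache[[paste0("src:", rp)]] <- read_mask(rp)
        region_source <- region_cache[[paste0("src:", rp)]]
        st <- static_for(rp, region_source)
      }
      geo <- check_geometry(list(epvs, wml, region_source))
      if (!geo$pass) stop(geo$message)
      subject_metrics_row(sid, manifest$icv_mm3[i], epvs, wml, st,
                          connectivity)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- sprintf("subject %s: %s", sid, conditionMessage(res))
      if (strict) stop(msg, call. = FALSE)
      failures <- c(failures, msg)
      message("skipping ", msg)
    } else rows[[i]] <- res
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

# Number of connected pieces among a small set of voxel coordinates
# (0-based, k x 3). Union-find; intersections of thin EPVS with a
# region are at most a few voxels, so the quadratic scan is cheap.
count_pieces <- function(coords, connectivity = 26) {
  k <- nrow(coords)
  if (k == 0L) return(0L)
  if (k == 1L) return(1L)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    dd <- abs(coords[i, ] - coords[j, ])
    m <- max(dd); s <- sum(dd)
    adj <- if (connectivity == 26) m <= 1
      else if (connectivity == 18) m <= 1 && s <= 2
      else s == 1
    if (adj) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(k), find, integer(1))))
}

# One SubjectMetrics row. Regional counts use the intersection rule
# (components of EPVS-intersect-region); because EPVS are tiny, the
# intersection's components are computed per whole-mask component from
# its own voxels rather than by relabeling the full grid. Equivalence
# with regional_epvs_metrics() is covered by tests.
subject_metrics_row <- function(sid, icv, epvs, wml, st, connectivity) {
  cc <- connected_components(epvs, connectivity)
  d <- dim(epvs$values)
  voxvol <- prod(epvs$spacing)
  idx <- which(epvs$values == 1L)
  i0 <- idx - 1L
  coords <- cbind(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2]))
  labs <- cc$labels[idx]
  by_comp <- split(seq_along(idx), labs)
  wmlv <- wml$values[idx] == 1L
  wbv <- st$wb$values[idx] == 1L
  in_region <- list(wb = wbv,
                    wm = st$wm$values[idx] == 1L,
                    bg = st$bg$values[idx] == 1L,
                    wml = wmlv,
                    non_wml = wbv & !wmlv)
  row <- data.frame(subject_id = sid, icv_mm3 = icv,
                    stringsAsFactors = FALSE)
  for (rn in names(in_region)) {
    inr <- in_region[[rn]]
    cnt <- 0L
    for (members in by_comp) {
      sel <- members[inr[members]]
      if (length(sel))
        cnt <- cnt + count_pieces(coords[sel, , drop = FALSE],
                                  connectivity)
    }
    vol <- sum(inr) * voxvol
    row[[paste0("epvs_count_", rn)]] <- cnt
    row[[paste0("epvs_volume_mm3_", rn)]] <- vol
    row[[paste0("epvs_volume_pct_icv_", rn)]] <- normalize_by_icv(vol, icv)
  }
  row$wml_volume_mm3 <- mask_volume_mm3(wml)
  row$wml_volume_pct_icv <- normalize_by_icv(row$wml_volume_mm3, icv)
  row$n_epvs <- cc$n
  prof <- subject_distance_profile(cc$components, wml)
  for (b in distance_bins())
    row[[paste0("bin_", b)]] <- prof$histogram[[b]]
  row$has_wml <- prof$has_wml
  row
}

fit_or_na <- function(expr) {
  tryCatch(expr, error = function(e) NULL, warning = function(w) {
    tryCatch(suppressWarnings(expr), error = function(e) NULL)
  })
}

take_terms <- function(model, pattern) {
  if (is.null(model) || is.null(model$results)) return(NULL)
  model$results[grepl(pattern, model$results$term), , drop = FALSE]
}

#' Cohort-level statistical analysis
#'
#' Joins per-subject metrics to the cohort manifest and fits the full
#' analysis battery: group comparisons of counts and volumes per region
#' (NB for counts, ZINB for the within-lesion region, log-Gaussian for
#' volumes), the EPVS-WML volumetric association per region, its
#' interaction with group, per-distance-bin group models, per-bin
#' WML-volume models, and a sensitivity variant of the bin group models
#' with WML log-volume as an additional covariate. Age and sex enter all
#' models as fixed covariates. Every table carries raw and
#' Benjamini-Hochberg adjusted p-values, adjusted within that table's
#' family of tests. Subjects without any lesion are kept in bin models
#' (their EPVS fall in the terminal distance bin) but excluded from
#' models conditioning on log lesion volume.
#'
#' @param metrics data.frame from [run_metrics()].
#' @param manifest manifest data.frame with `subject_id`, `age`, `sex`
#'   and the grouping column.
#' @param group name of the grouping column (default `"diagnosis"`).
#' @param ref_level reference group level (default the first of
#'   CU/MCI/AD present).
#' @param covariates fixed covariates (default age and sex).
#' @return Named list of result data.frames: `group_counts`,
#'   `group_volumes`, `wml_assoc_counts`, `wml_assoc_volumes`,
#'   `interactions`, `bin_group_counts`, `bin_wml_counts`,
#'   `bin_group_sensitivity`.
#' @export
run_stats <- function(metrics, manifest, group = "diagnosis",
                      ref_level = NULL, covariates = c("age", "sex")) {
  need <- c("subject_id", covariates, group)
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop("manifest missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- merge(metrics, manifest[, need], by = "subject_id")
  if (is.null(ref_level)) {
    lev <- unique(df[[group]])
    ref_level <- intersect(c("CU", "CU_Abneg", "Abneg"), lev)[1]
    if (is.na(ref_level)) ref_level <- sort(lev)[1]
  }
  df[[group]] <- stats::relevel(factor(df[[group]]), ref = ref_level)
  df$wml_log_volume <- ifelse(df$wml_volume_pct_icv > 0,
                              log(df$wml_volume_pct_icv), NA)
  regions <- c("wb", "wm", "bg", "wml", "non_wml")
  gpat <- paste0("^", group)

  collect <- function(items) {
    out <- do.call(rbind, items[!vapply(items, is.null, logical(1))])
    if (!is.null(out) && nrow(out)) {
      out$p_fdr <- fdr_adjust(out$p_value)
      rownames(out) <- NULL
    }
    out
  }
  label_rows <- function(tab, what) {
    if (is.null(tab) || !nrow(tab)) return(NULL)
    cbind(data.frame(analysis = what, stringsAsFactors = FALSE), tab)
  }

  # 1-2: group comparisons per region
  gc <- list(); gv <- list()
  for (rn in regions) {
    fam <- if (rn == "wml") "zinb" else "nb"
    m <- fit_or_na(fit_count_model(
      df, paste0("epvs_count_", rn), predictors = c(group, covariates),
      family = fam, group = group, ref_level = ref_level,
      family_id = "group_counts"))
    gc[[rn]] <- label_rows(take_terms(m, gpat), rn)
    mv <- fit_or_na(fit_log_volume_model(
      df, paste0("epvs_volume_pct_icv_", rn),
      predictors = c(group, covariates), group = group,
      ref_level = ref_level, family_id = "group_volumes"))
    gv[[rn]] <- label_rows(take_terms(mv, gpat), rn)
  }

  # 3: EPVS-WML association per region (lesion-bearing subjects)
  dfw <- df[!is.na(df$wml_log_volume), , drop = FALSE]
  ac <- list(); av <- list()
  for (rn in regions) {
    fam <- if (rn == "wml") "zinb" else "nb"
    m <- fit_or_na(fit_count_model(
      dfw, paste0("epvs_count_", rn),
      predictors = c("wml_log_volume", covariates), family = fam,
      family_id = "wml_assoc_counts"))
    ac[[rn]] <- label_rows(take_terms(m, "^wml_log_volume"), rn)
    mv <- fit_or_na(fit_log_volume_model(
      dfw, paste0("epvs_volume_pct_icv_", rn),
      predictors = c("wml_log_volume", covariates),
      family_id = "wml_assoc_volumes"))
    av[[rn]] <- label_rows(take_terms(mv, "^wml_log_volume"), rn)
  }

  # 4: WML-volume x group interactions (count outcome)
  ints <- list()
  if (length(unique(dfw[[group]])) >= 2L) {
    for (rn in regions) {
      m <- fit_or_na(interaction_model(
        dfw, paste0("epvs_count_", rn), group = group,
        wml_col = "wml_log_volume", outcome_type = "count",
        predictors = covariates, ref_level = ref_level,
        family_id = "interactions"))
      ints[[rn]] <- label_rows(take_terms(m, ":"), rn)
    }
  }

  # 5: per-bin group models; 6: per-bin WML-volume models
  bg_items <- list(); bw_items <- list(); sens_items <- list()
  for (b in distance_bins()) {
    col <- paste0("bin_", b)
    fam <- if (b == "WITHIN") "zinb" else "nb"
    m <- fit_or_na(fit_count_model(
      df, col, predictors = c(group, covariates), family = fam,
      group = group, ref_level = ref_level,
      family_id = "bin_group_counts"))
    bg_items[[b]] <- label_rows(take_terms(m, gpat), b)
    mw <- fit_or_na(fit_count_model(
      dfw, col, predictors = c("wml_log_volume", covariates),
      family = "nb", family_id = "bin_wml_counts"))
    bw_items[[b]] <- label_rows(take_terms(mw, "^wml_log_volume"), b)
    ms <- fit_or_na(fit_count_model(
      dfw, col, predictors = c(group, "wml_log_volume", covariates),
      family = fam, group = group, ref_level = ref_level,
      family_id = "bin_group_sensitivity"))
    sens_items[[b]] <- label_rows(take_terms(ms, gpat), b)
  }

  list(group_counts = collect(gc),
       group_volumes = collect(gv),
       wml_assoc_counts = collect(ac),
       wml_assoc_volumes = collect(av),
       interactions = collect(ints),
       bin_group_counts = collect(bg_items),
       bin_wml_counts = collect(bw_items),
       bin_group_sensitivity = collect(sens_items))
}
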