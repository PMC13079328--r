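#' Default region label ids (FreeSurfer aseg color-table convention)
#'
#' Basal ganglia: caudate, putamen, pallidum, accumbens and thalamus of
#' both hemispheres; white matter: cerebral white matter of both
#' hemispheres. Fully overridable through the `label_config` argument of
#' [build_region_set()].
#'
#' @return Named list of integer vectors with elements `bg` and `wm`.
#' @export
default_region_labels <- function() {
  list(
    bg = c(10L, 11L, 12L, 13L, 26L, 49L, 50L, 51L, 52L, 58L),
    wm = c(2L, 41L)
  )
}

#' Build the five analysis region masks
#'
#' From an integer label volume (aseg-style) or a pair of binary masks,
#' constructs whole-brain (WB), white matter (WM), basal ganglia (BG),
#' WML and non-WML masks on one grid. Non-WML is always WB minus WML.
#' WM and BG are taken as produced (no exclusion of WML voxels) unless
#' `exclude_wml_from_tissue` is set.
#'
#' @param region_source a `voxel_grid` label volume, or a named list with
#'   binary `voxel_grid`s `wm` and `bg` (WB then defaults to their union
#'   unless `brain_mask` is supplied).
#' @param wml_mask binary `voxel_grid`.
#' @param label_config list with integer vectors `bg` and `wm`; defaults
#'   to [default_region_labels()].
#' @param brain_mask optional binary `voxel_grid` overriding the WB mask.
#' @param exclude_wml_from_tissue if `TRUE`, remove WML voxels from the
#'   WM and BG masks.
#' @return A list of class `region_set` with binary `voxel_grid`s
#'   `wb`, `wm`, `bg`, `wml`, `non_wml`.
#' @export
build_region_set <- function(region_source, wml_mask,
                             label_config = default_region_labels(),
                             brain_mask = NULL,
                             exclude_wml_from_tissue = FALSE) {
  assert_binary_grid(wml_mask, "wml_mask")
  d <- dim(wml_mask$values)
  sp <- wml_mask$spacing
  as_bin <- function(v) voxel_grid(array(as.integer(v), d), sp)
  st <- region_static(region_source, label_config, brain_mask)
  rep <- check_geometry(list(st$wb, wml_mask))
  if (!rep$pass) stop("region source / WML ", rep$message, call. = FALSE)
  wb <- st$wb; wm <- st$wm; bg <- st$bg
  if (exclude_wml_from_tissue) {
    wm <- as_bin(wm$values == 1L & wml_mask$values == 0L)
    bg <- as_bin(bg$values == 1L & wml_mask$values == 0L)
  }
  non_wml <- as_bin(wb$values == 1L & wml_mask$values == 0L)
  structure(list(wb = wb, wm = wm, bg = bg, wml = wml_mask,
                 non_wml = non_wml), class = "region_set")
}

# WML-independent region masks (WB/WM/BG), computable once per shared
# label volume and reused across subjects.
region_static <- function(region_source,
                          label_config = default_region_labels(),
                          brain_mask = NULL) {
  if (is_voxel_grid(region_source)) {
    d <- dim(region_source$values)
    sp <- region_source$spacing
    as_bin <- function(v) voxel_grid(array(as.integer(v), d), sp)
    lv <- region_source$values
    for (nm in c("bg", "wm")) {
      absent <- setdiff(label_config[[nm]], unique(as.integer(lv)))
      if (length(absent) == length(label_config[[nm]]))
        warning("no configured ", toupper(nm),
                " labels present in label volume", call. = FALSE)
    }
    bg <- as_bin(lv %in% label_config$bg)
    wm <- as_bin(lv %in% label_config$wm)
    wb <- if (is.null(brain_mask)) as_bin(lv != 0L) else brain_mask
  } else {
    stopifnot(is.list(region_source),
              all(c("wm", "bg") %in% names(region_source)))
    wm <- region_source$wm
    bg <- region_source$bg
    rep <- check_geometry(list(wm, bg))
    if (!rep$pass) stop("region masks ", rep$message, call. = FALSE)
    wb <- if (is.null(brain_mask)) {
      d <- dim(wm$values)
      voxel_grid(array(as.integer(wm$values == 1L | bg$values == 1L), d),
                 wm$spacing)
    } else brain_mask
  }
  assert_binary_grid(wb, "brain_mask")
  list(wb = wb, wm = wm, bg = bg)
}

#' Regional EPVS count and volume
#'
#' Intersects the EPVS mask with a region mask voxelwise, then counts
#' connected components of the intersection and sums its volume. Note
#' this is deliberately not a partition: a component straddling a region
#' border contributes (a piece) to both regions, and a single EPVS whose
#' intersection with the region splits in two is counted twice. The
#' alternative centroid-based assignment (each component assigned to the
#' region containing its centroid, a true partition) is available via
#' `rule = "centroid"` and is the rule used by the distance analysis.
#'
#' @param epvs_mask,region_mask binary `voxel_grid`s on one grid.
#' @param connectivity component connectivity (default 26).
#' @param rule `"intersection"` (default) or `"centroid"`.
#' @return A list with `count` and `volume_mm3`.
#' @export
regional_epvs_metrics <- function(epvs_mask, region_mask,
                                  connectivity = 26,
                                  rule = c("intersection", "centroid")) {
  rule <- match.arg(rule)
  assert_binary_grid(epvs_mask, "epvs_mask")
  assert_binary_grid(region_mask, "region_mask")
  rep <- check_geometry(list(epvs_mask, region_mask))
  if (!rep$pass) stop(rep$message, call. = FALSE)
  d <- dim(epvs_mask$values)
  inter <- voxel_grid(array(
    as.integer(epvs_mask$values == 1L & region_mask$values == 1L), d),
    epvs_mask$spacing)
  if (rule == "intersection") {
    cc <- connected_components(inter, connectivity)
    return(list(count = cc$n, volume_mm3 = mask_volume_mm3(inter)))
  }
  # centroid rule: whole-mask components assigned by rounded centroid index
  cc <- connected_components(epvs_mask, connectivity)
  if (cc$n == 0L) return(list(count = 0L, volume_mm3 = 0))
  sp <- epvs_mask$spacing
  ix <- pmin(pmax(round(cc$components$cx_mm / sp[1]), 0), d[1] - 1) + 1
  iy <- pmin(pmax(round(cc$components$cy_mm / sp[2]), 0), d[2] - 1) + 1
  iz <- pmin(pmax(round(cc$components$cz_mm / sp[3]), 0), d[3] - 1) + 1
  inside <- region_mask$values[cbind(ix, iy, iz)] == 1L
  list(count = sum(inside),
       volume_mm3 = sum(cc$components$volume_mm3[inside]))
}

#' Express a volume as a percentage of intracranial volume
#'
#' @param volume_mm3 volume in cubic mm, >= 0.
#' @param icv_mm3 intracranial volume in cubic mm, > 0.
#' @return `100 * volume_mm3 / icv_mm3`.
#' @export
normalize_by_icv <- function(volume_mm3, icv_mm3) {
  if (any(!is.finite(icv_mm3)) || any(icv_mm3 <= 0))
    stop("icv_mm3 must be positive", call. = FALSE)
  if (any(volume_mm3 < 0)) stop("volume_mm3 must be >= 0", call. = FALSE)
  100 * volume_mm3 / icv_mm3
}
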