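#' Connected components of a binary 3D mask
#'
#' Labels foreground voxels into connected components under 6-, 18- or
#' 26-connectivity. Component ids are assigned in order of each
#' component's first voxel in array (column-major) order, so the labeling
#' is deterministic for a fixed input. The default connectivity is 26:
#' EPVS are thin oblique tubules that fragment under face-only adjacency.
#'
#' @param mask binary `voxel_grid`.
#' @param connectivity 6, 18 or 26.
#' @return A list with `labels` (integer 3D array, 0 = background),
#'   `n` (component count) and `components`, a data.frame with one row
#'   per component: `component_id`, `voxel_count`, `volume_mm3`, and
#'   world-space centroid columns `cx_mm`, `cy_mm`, `cz_mm` (unweighted
#'   mean of 0-based voxel indices times spacing).
#' @export
connected_components <- function(mask, connectivity = 26) {
  assert_binary_grid(mask)
  connectivity <- match.arg(as.character(connectivity), c("26", "18", "6"))
  connectivity <- as.integer(connectivity)
  d <- dim(mask$values)
  lab <- .cc_label3d(as.integer(mask$values), d, connectivity)
  n <- attr(lab, "n_components")
  labels <- array(lab, d)
  if (n == 0L) {
    comps <- data.frame(component_id = integer(0), voxel_count = integer(0),
                        volume_mm3 = numeric(0), cx_mm = numeric(0),
                        cy_mm = numeric(0), cz_mm = numeric(0))
    return(list(labels = labels, n = 0L, components = comps))
  }
  idx <- which(lab > 0L)
  lb <- lab[idx]
  # 0-based voxel indices per axis from linear index
  i0 <- idx - 1L
  x <- i0 %% d[1]
  y <- (i0 %/% d[1]) %% d[2]
  z <- i0 %/% (d[1] * d[2])
  cnt <- tabulate(lb, nbins = n)
  sp <- mask$spacing
  comps <- data.frame(
    component_id = seq_len(n),
    voxel_count = cnt,
    volume_mm3 = cnt * prod(sp),
    cx_mm = as.numeric(rowsum(x, lb)) / cnt * sp[1],
    cy_mm = as.numeric(rowsum(y, lb)) / cnt * sp[2],
    cz_mm = as.numeric(rowsum(z, lb)) / cnt * sp[3]
  )
  list(labels = labels, n = n, components = comps)
}

#' Erode a binary mask with the 6-connected cross kernel
#'
#' A voxel survives iff it and all six face neighbors are foreground;
#' the outside of the array counts as background, so border voxels never
#' survive.
#'
#' @param mask binary `voxel_grid`.
#' @return Eroded binary `voxel_grid`.
#' @export
erode_cross <- function(mask) {
  assert_binary_grid(mask)
  d <- dim(mask$values)
  out <- .erode_cross3d(as.integer(mask$values), d)
  voxel_grid(array(out, d), mask$spacing)
}

#' Boundary shell of a binary mask
#'
#' The foreground voxels removed by one cross-kernel erosion:
#' `mask AND NOT erode_cross(mask)`. This is the inner one-voxel surface
#' layer used as the lesion boundary for all distance computations.
#'
#' @param mask binary `voxel_grid`.
#' @return Binary `voxel_grid` with the shell.
#' @export
boundary_shell <- function(mask) {
  eroded <- erode_cross(mask)
  voxel_grid(array(as.integer(mask$values == 1L & eroded$values == 0L),
                   dim(mask$values)), mask$spacing)
}

#' Centroid of a set of voxels in world coordinates
#'
#' Unweighted per-axis mean of 0-based voxel indices, times spacing.
#'
#' @param voxel_indices integer matrix (n x 3) of 0-based indices.
#' @param spacing_mm numeric length 3.
#' @return Numeric length-3 centroid in mm.
#' @export
component_centroid <- function(voxel_indices, spacing_mm) {
  voxel_indices <- rbind(voxel_indices)
  if (nrow(voxel_indices) < 1L) stop("empty component", call. = FALSE)
  colMeans(voxel_indices) * spacing_mm
}

#' Foreground volume of a binary mask in cubic millimetres
#'
#' @param mask binary `voxel_grid`.
#' @return Foreground voxel count times voxel volume.
#' @export
mask_volume_mm3 <- function(mask) {
  assert_binary_grid(mask)
  sum(mask$values) * prod(mask$spacing)
}
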