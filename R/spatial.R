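#' Distance bin labels, in order
#'
#' Half-open-above 5 mm bins from 0 mm (within the lesion) to 30 mm, with
#' a terminal open bin: `WITHIN` (d = 0), `B5` (0 < d <= 5), `B10`
#' (5 < d <= 10), ..., `B30` (25 < d <= 30), `OVER30` (d > 30, including
#' subjects with no lesion, whose distances are infinite). Exact
#' multiples fall in the lower bin so that bin `B5` and the "near"
#' penumbra category (<= 5 mm) agree.
#'
#' @return Character vector of the eight bin labels.
#' @export
distance_bins <- function() {
  c("WITHIN", "B5", "B10", "B15", "B20", "B25", "B30", "OVER30")
}

#' Assign a distance to its 5 mm bin
#'
#' @param d numeric vector of distances in mm (>= 0, may be `Inf`).
#' @return Factor with levels [distance_bins()].
#' @export
bin_distance <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("negative distance", call. = FALSE)
  lab <- ifelse(d == 0, "WITHIN",
         ifelse(d <= 5, "B5",
         ifelse(d <= 10, "B10",
         ifelse(d <= 15, "B15",
         ifelse(d <= 20, "B20",
         ifelse(d <= 25, "B25",
         ifelse(d <= 30, "B30", "OVER30")))))))
  factor(lab, levels = distance_bins())
}

#' Penumbra proximity category
#'
#' `WITHIN` at 0 mm, `NEAR` for 0 < d <= 5 mm (approximating the lesion
#' penumbra), `FAR` beyond 5 mm (including infinite distances). A
#' coarsening of [bin_distance()]: `WITHIN -> WITHIN`, `B5 -> NEAR`,
#' all farther bins `-> FAR`.
#'
#' @param d numeric vector of distances in mm (>= 0, may be `Inf`).
#' @return Factor with levels `WITHIN`, `NEAR`, `FAR`.
#' @export
proximity_category <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("negative distance", call. = FALSE)
  lab <- ifelse(d == 0, "WITHIN", ifelse(d <= 5, "NEAR", "FAR"))
  factor(lab, levels = c("WITHIN", "NEAR", "FAR"))
}

#' Minimum Euclidean distance from a point to a boundary mask
#'
#' Exact minimum over all foreground voxels of the Euclidean distance (in
#' mm, voxel centers at 0-based index times spacing) from `centroid_mm`.
#' Implemented as an expanding cubic (Chebyshev) search window that keeps
#' growing after the first hit until no voxel outside the window can beat
#' the current best, so the result equals the exhaustive minimum exactly
#' — a first window hit need not be the Euclidean nearest voxel.
#'
#' @param centroid_mm numeric length-3 point in mm.
#' @param boundary binary `voxel_grid` with at least one foreground voxel.
#' @return Distance in mm; `Inf` if the boundary is empty (no lesion).
#' @export
min_distance_to_boundary <- function(centroid_mm, boundary) {
  assert_binary_grid(boundary, "boundary")
  .min_dist_expand(as.numeric(centroid_mm),
                   as.integer(boundary$values),
                   dim(boundary$values), boundary$spacing)
}

#' Exhaustive minimum distance (reference oracle)
#'
#' Brute-force minimum over all boundary voxels, vectorized in R and
#' independent of the expanding-window search; used to verify exact
#' equivalence of [min_distance_to_boundary()].
#'
#' @inheritParams min_distance_to_boundary
#' @return Distance in mm; `Inf` if the boundary is empty.
#' @export
brute_force_min_distance <- function(centroid_mm, boundary) {
  assert_binary_grid(boundary, "boundary")
  idx <- which(boundary$values == 1L)
  if (!length(idx)) return(Inf)
  d <- dim(boundary$values)
  sp <- boundary$spacing
  i0 <- idx - 1L
  x <- (i0 %% d[1]) * sp[1]
  y <- ((i0 %/% d[1]) %% d[2]) * sp[2]
  z <- (i0 %/% (d[1] * d[2])) * sp[3]
  sqrt(min((x - centroid_mm[1])^2 + (y - centroid_mm[2])^2 +
           (z - centroid_mm[3])^2))
}

#' Per-subject distance profile of EPVS relative to the WML boundary
#'
#' For every EPVS component, computes the minimum Euclidean distance from
#' its centroid to the nearest WML boundary voxel, regardless of the
#' tissue (white matter or basal ganglia) the EPVS sits in. A component
#' whose centroid, rounded to the nearest voxel index, lies inside the
#' WML mask is "within WML": it is excluded from the distance search and
#' assigned distance 0. If the subject has no WML voxels at all, every
#' distance is `Inf` (binned as `OVER30`) and `has_wml` is `FALSE` so the
#' statistical layer can include or exclude such subjects explicitly.
#'
#' @param epvs_components data.frame of components as returned in
#'   `connected_components(...)$components`.
#' @param wml_mask binary `voxel_grid`.
#' @param boundary optional precomputed [boundary_shell()] of `wml_mask`.
#' @return A list of class `distance_profile`: `records` (data.frame with
#'   `component_id`, centroid columns, `distance_mm`, `within_wml`,
#'   `bin`, `proximity`), `histogram` (named integer vector over
#'   [distance_bins()]) and `has_wml`.
#' @export
subject_distance_profile <- function(epvs_components, wml_mask,
                                     boundary = NULL) {
  assert_binary_grid(wml_mask, "wml_mask")
  if (is.null(boundary)) boundary <- boundary_shell(wml_mask)
  has_wml <- any(wml_mask$values == 1L)
  n <- nrow(epvs_components)
  d <- dim(wml_mask$values)
  sp <- wml_mask$spacing
  if (n == 0L) {
    rec <- data.frame(component_id = integer(0), cx_mm = numeric(0),
                      cy_mm = numeric(0), cz_mm = numeric(0),
                      distance_mm = numeric(0), within_wml = logical(0),
                      bin = factor(character(0), levels = distance_bins()),
                      proximity = factor(character(0),
                                         levels = c("WITHIN", "NEAR", "FAR")))
    hist <- setNames(integer(length(distance_bins())), distance_bins())
    return(structure(list(records = rec, histogram = hist,
                          has_wml = has_wml), class = "distance_profile"))
  }
  cen <- as.matrix(epvs_components[, c("cx_mm", "cy_mm", "cz_mm")])
  ii <- cbind(pmin(pmax(round(cen[, 1] / sp[1]), 0), d[1] - 1) + 1,
              pmin(pmax(round(cen[, 2] / sp[2]), 0), d[2] - 1) + 1,
              pmin(pmax(round(cen[, 3] / sp[3]), 0), d[3] - 1) + 1)
  within <- has_wml & (wml_mask$values[ii] == 1L)
  dist <- numeric(n)
  for (k in seq_len(n)) {
    dist[k] <- if (within[k]) 0
      else if (!has_wml) Inf
      else min_distance_to_boundary(cen[k, ], boundary)
  }
  rec <- data.frame(component_id = epvs_components$component_id,
                    cx_mm = cen[, 1], cy_mm = cen[, 2], cz_mm = cen[, 3],
                    distance_mm = dist, within_wml = within,
                    bin = bin_distance(dist),
                    proximity = proximity_category(dist))
  hist <- table(rec$bin)
  hist <- setNames(as.integer(hist), names(hist))
  structure(list(records = rec, histogram = hist, has_wml = has_wml),
            class = "distance_profile")
}
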