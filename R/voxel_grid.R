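#' 3D voxel grid
#'
#' A minimal container for a 3D image on a regular grid: an integer array
#' plus per-axis voxel spacing in millimetres. All geometry in the package
#' is computed in axis-aligned index space scaled by the spacing; world
#' coordinates are `index * spacing` with 0-based indices, so distances
#' are invariant to rigid reorientation of a subject's (coregistered,
#' same-grid) masks and the affine's rotational part is deliberately
#' ignored.
#'
#' @param values 3D array (logical or integer). Logical arrays are stored
#'   as 0/1 integers.
#' @param spacing_mm numeric length-3, voxel edge lengths in mm; all > 0.
#' @param binary if `TRUE`, require values to be in \{0, 1\}.
#' @return An object of class `voxel_grid` with elements `values`
#'   (integer 3D array) and `spacing` (numeric length 3).
#' @export
voxel_grid <- function(values, spacing_mm = c(1, 1, 1), binary = FALSE) {
  if (is.logical(values)) values <- array(as.integer(values), dim(values))
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array, got ", length(dim(values)),
         " dimensions", call. = FALSE)
  if (any(dim(values) < 1L)) stop("all grid dimensions must be >= 1")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive finite numbers", call. = FALSE)
  storage.mode(values) <- "integer"
  rng <- range(values)
  is_binary <- rng[1] >= 0L && rng[2] <= 1L
  if (binary && !is_binary)
    stop("binary mask contains values outside {0, 1}", call. = FALSE)
  structure(list(values = values, spacing = spacing_mm,
                 is_binary = is_binary),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d, spacing %s mm, %d foreground\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              sum(x$values != 0L)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

assert_binary_grid <- function(grid, arg = "mask") {
  if (!is_voxel_grid(grid)) stop("`", arg, "` must be a voxel_grid")
  ok <- if (!is.null(grid$is_binary)) grid$is_binary
    else { r <- range(grid$values); r[1] >= 0L && r[2] <= 1L }
  if (!ok)
    stop("`", arg, "` is not binary (values outside {0, 1})", call. = FALSE)
  invisible(grid)
}

#' Check geometric consistency of a set of grids
#'
#' Masks entering a joint analysis must live on the same grid. Shapes must
#' match exactly; spacings must agree within 1e-4 mm per axis (header
#' round-off tolerance).
#'
#' @param masks list of `voxel_grid` objects, length >= 2.
#' @param tol_mm per-axis spacing tolerance in mm.
#' @return A list with `pass` (logical) and `message` (character,
#'   naming the first offending axis on failure).
#' @export
check_geometry <- function(masks, tol_mm = 1e-4) {
  stopifnot(is.list(masks), length(masks) >= 2L)
  ref <- masks[[1]]
  for (i in seq_along(masks)[-1]) {
    g <- masks[[i]]
    ds <- which(dim(ref$values) != dim(g$values))
    if (length(ds))
      return(list(pass = FALSE, message = sprintf(
        "shape mismatch on axis %d: %d vs %d (grid 1 vs grid %d)",
        ds[1], dim(ref$values)[ds[1]], dim(g$values)[ds[1]], i)))
    sp <- which(abs(ref$spacing - g$spacing) > tol_mm)
    if (length(sp))
      return(list(pass = FALSE, message = sprintf(
        "spacing mismatch on axis %d: %g vs %g mm (grid 1 vs grid %d)",
        sp[1], ref$spacing[sp[1]], g$spacing[sp[1]], i)))
  }
  list(pass = TRUE, message = "geometry consistent")
}
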