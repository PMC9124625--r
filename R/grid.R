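#' Construct a regular 3D dose grid
#'
#' A `dose_grid` is a regular scalar field of absorbed dose in Gy with spatial
#' metadata. The axis convention is fixed throughout the package: x = left-right
#' (mm), y = inferior-superior (mm, increasing towards the head), z =
#' anterior-posterior (mm, increasing anteriorly). Contour planes are axial
#' (x-z) at constant y.
#'
#' @param values 3D numeric array of dose in Gy, dims `(nx, ny, nz)`. All
#'   values must be finite and non-negative.
#' @param origin numeric length-3: (x, y, z) coordinate in mm of the centre of
#'   voxel `[1, 1, 1]`.
#' @param spacing numeric length-3: voxel pitch (sx, sy, sz) in mm, strictly
#'   positive.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, origin, spacing) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers (mm)")
  if (anyNA(values) || !all(is.finite(values)))
    stop("dose values must be finite")
  if (any(values < 0))
    stop("dose values must be non-negative")
  structure(
    list(values = values, origin = as.numeric(origin),
         spacing = as.numeric(spacing)),
    class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %d x %d x %d voxels, spacing %.3g/%.3g/%.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.1f, %.1f, %.1f) mm, dose range [%.3g, %.3g] Gy\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel-centre coordinates along each grid axis
#' @param grid a `dose_grid`.
#' @return list with numeric vectors `x`, `y`, `z` (mm).
#' @export
grid_axes <- function(grid) {
  d <- dim(grid$values)
  list(x = grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3])
}

#' Voxel volume of a grid in cc
#' @param grid a `dose_grid`.
#' @return voxel volume in cm^3.
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

#' Trilinear interpolation of a dose grid
#'
#' Samples the grid at arbitrary points by trilinear interpolation of the
#' eight surrounding voxel-centre values. Points outside the voxel-centre
#' lattice hull return `NA` (callers decide whether that is an error).
#'
#' @param grid a `dose_grid`.
#' @param points numeric matrix `n x 3` of (x, y, z) mm.
#' @return numeric vector of interpolated doses (Gy), `NA` where out of extent.
#' @export
interp_dose <- function(grid, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  d <- dim(grid$values)
  # fractional voxel index (1-based)
  f <- sweep(sweep(points, 2, grid$origin, "-"), 2, grid$spacing, "/") + 1
  out <- rep(NA_real_, nrow(points))
  ok <- f[, 1] >= 1 & f[, 1] <= d[1] &
        f[, 2] >= 1 & f[, 2] <= d[2] &
        f[, 3] >= 1 & f[, 3] <= d[3]
  if (!any(ok)) return(out)
  f <- f[ok, , drop = FALSE]
  i0 <- pmin(pmax(floor(f), 1), matrix(d - 1L, nrow(f), 3, byrow = TRUE))
  w <- f - i0                                    # in [0, 1]
  v <- grid$values
  g <- function(a, b, c) v[cbind(i0[, 1] + a, i0[, 2] + b, i0[, 3] + c)]
  out[ok] <-
    g(0, 0, 0) * (1 - w[, 1]) * (1 - w[, 2]) * (1 - w[, 3]) +
    g(1, 0, 0) * w[, 1]       * (1 - w[, 2]) * (1 - w[, 3]) +
    g(0, 1, 0) * (1 - w[, 1]) * w[, 2]       * (1 - w[, 3]) +
    g(0, 0, 1) * (1 - w[, 1]) * (1 - w[, 2]) * w[, 3] +
    g(1, 1, 0) * w[, 1]       * w[, 2]       * (1 - w[, 3]) +
    g(1, 0, 1) * w[, 1]       * (1 - w[, 2]) * w[, 3] +
    g(0, 1, 1) * (1 - w[, 1]) * w[, 2]       * w[, 3] +
    g(1, 1, 1) * w[, 1]       * w[, 2]       * w[, 3]
  out
}
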