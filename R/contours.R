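#' Construct a planar contour
#'
#' A contour is a simple (non-self-intersecting) polygon in an axial x-z plane
#' at a fixed inferior-superior coordinate `y_slice`. The polygon is closed
#' implicitly: the last vertex connects back to the first.
#'
#' @param y_slice inferior-superior coordinate of the plane (mm).
#' @param points numeric matrix `n x 2` of (x, z) vertices in mm, `n >= 3`.
#' @param check if `TRUE` (default) verify simplicity; internal callers that
#'   construct polygons known to be simple may skip the O(n^2) check.
#' @return An object of class `contour`.
#' @export
contour <- function(y_slice, points, check = TRUE) {
  points <- matrix(as.numeric(points), ncol = 2)
  if (!is.finite(y_slice)) stop("`y_slice` must be finite")
  if (nrow(points) < 3L) stop("a contour needs at least 3 vertices")
  if (!all(is.finite(points))) stop("contour vertices must be finite")
  if (check && .self_intersects(points))
    stop("contour polygon is self-intersecting")
  structure(list(y_slice = as.numeric(y_slice), points = points),
            class = "contour")
}

# Segment-pair intersection test over non-adjacent edges (even-odd geometry
# only needs simple polygons; O(n^2) is fine at the vertex counts used here).
.self_intersects <- function(p) {
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]    # edge n is adjacent to edge 1
    if (!length(js)) next
    if (any(.seg_cross(a[i, ], b[i, ], a[js, , drop = FALSE],
                       b[js, , drop = FALSE]))) return(TRUE)
  }
  FALSE
}

.seg_cross <- function(p1, p2, q1, q2) {
  d <- p2 - p1
  e <- q2 - q1
  den <- d[1] * e[, 2] - d[2] * e[, 1]
  rx <- q1[, 1] - p1[1]
  rz <- q1[, 2] - p1[2]
  t <- (rx * e[, 2] - rz * e[, 1]) / den
  u <- (rx * d[2] - rz * d[1]) / den
  ok <- abs(den) > 1e-12
  ok & t > 1e-12 & t < 1 - 1e-12 & u > 1e-12 & u < 1 - 1e-12
}

#' Polygon area of a contour
#'
#' Shoelace area, orientation-independent, converted from mm^2 to cm^2.
#'
#' @param contour a [contour()].
#' @return area in cm^2 (strictly positive for a valid contour).
#' @export
polygon_area <- function(contour) {
  p <- contour$points
  n <- nrow(p)
  if (n < 3L) stop("a contour needs at least 3 vertices")
  j <- c(2:n, 1)
  a_mm2 <- abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
  a_mm2 / 100
}

#' Polygon centroid (area-weighted) of a contour, in mm
#' @param contour a [contour()].
#' @return numeric length-2 (x, z) mm.
#' @export
polygon_centroid <- function(contour) {
  p <- contour$points
  n <- nrow(p)
  j <- c(2:n, 1)
  cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  a2 <- sum(cr)
  if (abs(a2) < 1e-12) return(colMeans(p))
  c(sum((p[, 1] + p[j, 1]) * cr), sum((p[, 2] + p[j, 2]) * cr)) / (3 * a2)
}

#' Construct a structure (named set of planar contours)
#'
#' @param name structure label, e.g. `"external"` or `"spinal_cord"`.
#' @param contours list of [contour()] objects; they are sorted by `y_slice`.
#'   At most one polygon per slice: multi-island slices are rejected.
#' @param role one of `"external"`, `"spinal_cord"`, `"sc_prv"`, `"other"`.
#' @return An object of class `rt_structure`.
#' @export
rt_structure <- function(name, contours,
                         role = c("other", "external", "spinal_cord", "sc_prv")) {
  role <- match.arg(role)
  if (!length(contours)) stop("a structure needs at least one contour")
  if (!all(vapply(contours, inherits, logical(1), "contour")))
    stop("`contours` must be a list of contour objects")
  ys <- vapply(contours, function(ct) ct$y_slice, numeric(1))
  if (anyDuplicated(ys))
    stop(sprintf("structure '%s' has more than one polygon on a slice; %s",
                 name, "multi-island slices are not supported"))
  structure(list(name = name, contours = contours[order(ys)], role = role),
            class = "rt_structure")
}

#' @export
print.rt_structure <- function(x, ...) {
  ys <- structure_slices(x)
  cat(sprintf("<rt_structure> '%s' (%s): %d slices, y in [%.1f, %.1f] mm\n",
              x$name, x$role, length(ys), min(ys), max(ys)))
  invisible(x)
}

#' Slice positions of a structure
#' @param struct an [rt_structure()].
#' @return sorted numeric vector of y_slice values (mm).
#' @export
structure_slices <- function(struct)
  vapply(struct$contours, function(ct) ct$y_slice, numeric(1))

#' Even-odd point-in-polygon test
#'
#' Ray-crossing test of points against a polygon in the x-z plane. A point on
#' an edge may land on either side; callers should not rely on boundary
#' behaviour.
#'
#' @param px,pz numeric vectors of point coordinates (mm).
#' @param poly numeric matrix `n x 2` of polygon vertices (mm).
#' @return logical vector.
#' @export
point_in_polygon <- function(px, pz, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; zi <- poly[i, 2]
    xj <- poly[j, 1]; zj <- poly[j, 2]
    crosses <- ((zi > pz) != (zj > pz)) &
      (px < (xj - xi) * (pz - zi) / (zj - zi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a structure onto a dose grid
#'
#' A voxel belongs to the mask iff its centre lies inside the structure's
#' polygon on the nearest contour slice in y, provided that slice is within
#' half a slice spacing (the larger of the grid's y pitch and the structure's
#' own slice pitch). Even-odd point-in-polygon at voxel centres; no
#' partial-volume weighting.
#'
#' @param struct an [rt_structure()].
#' @param grid a [dose_grid()].
#' @return list with `mask` (logical array over the grid), `n_voxels`,
#'   `volume_cc` (= n_voxels x voxel volume). A structure entirely outside the
#'   grid yields an empty mask with a warning.
#' @export
rasterize_structure <- function(struct, grid) {
  ax <- grid_axes(grid)
  ys <- structure_slices(struct)
  slice_pitch <- if (length(ys) > 1) stats::median(diff(ys)) else grid$spacing[2]
  tol_y <- max(grid$spacing[2], slice_pitch) / 2
  mask <- array(FALSE, dim(grid$values))
  for (iy in seq_along(ax$y)) {
    k <- which.min(abs(ys - ax$y[iy]))
    if (abs(ys[k] - ax$y[iy]) > tol_y) next
    poly <- struct$contours[[k]]$points
    # bounding-box prefilter: only test voxel centres the polygon can reach
    ix <- which(ax$x >= min(poly[, 1]) & ax$x <= max(poly[, 1]))
    iz <- which(ax$z >= min(poly[, 2]) & ax$z <= max(poly[, 2]))
    if (!length(ix) || !length(iz)) next
    xz <- expand.grid(x = ax$x[ix], z = ax$z[iz])
    inside <- point_in_polygon(xz$x, xz$z, poly)
    if (any(inside))
      mask[ix, iy, iz] <- mask[ix, iy, iz] |
        matrix(inside, length(ix), length(iz))
  }
  n <- sum(mask)
  if (n == 0L)
    warning(sprintf("structure '%s' rasterizes to an empty mask", struct$name))
  list(mask = mask, n_voxels = n, volume_cc = n * voxel_volume_cc(grid))
}

#' Voxel-centre coordinates of a rasterized mask
#' @param mask logical 3D array (or result of [rasterize_structure()]).
#' @param grid the [dose_grid()] the mask lives on.
#' @return numeric matrix `n x 3` of (x, y, z) mm.
#' @export
mask_centers <- function(mask, grid) {
  if (is.list(mask)) mask <- mask$mask
  idx <- which(mask, arr.ind = TRUE)
  cbind(grid$origin[1] + (idx[, 1] - 1) * grid$spacing[1],
        grid$origin[2] + (idx[, 2] - 1) * grid$spacing[2],
        grid$origin[3] + (idx[, 3] - 1) * grid$spacing[3])
}
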