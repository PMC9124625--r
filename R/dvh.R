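#' Near-maximum dose at a volume threshold (D0.1cc-style metric)
#'
#' Discrete voxel-accumulation definition with no sub-voxel interpolation:
#' in-mask voxel doses are sorted descending (stable sort) and voxel volumes
#' accumulated; the returned dose is that of the voxel at which the cumulative
#' volume first reaches `v`. `v = 0` returns the plain voxel maximum.
#'
#' @param grid a [dose_grid()].
#' @param mask logical array over the grid, or a [rasterize_structure()]
#'   result.
#' @param v volume threshold in cc (default 0.1, the spinal-cord convention).
#' @return dose in Gy.
#' @export
dmax_vol <- function(grid, mask, v = 0.1) {
  if (is.list(mask)) mask <- mask$mask
  doses <- grid$values[mask]
  dmax_from_doses(doses, voxel_volume_cc(grid), v)
}

#' Near-maximum dose from a vector of voxel doses
#'
#' Workhorse behind [dmax_vol()], also used when doses are evaluated directly
#' at voxel centres (each sample carries one voxel volume).
#'
#' @param doses numeric vector of voxel doses in Gy.
#' @param voxel_cc volume represented by each dose sample, cc.
#' @param v volume threshold in cc.
#' @return dose in Gy.
#' @export
dmax_from_doses <- function(doses, voxel_cc, v = 0.1) {
  if (!length(doses)) stop("empty structure: no in-mask voxels")
  if (v < 0) stop("volume threshold must be non-negative")
  total <- length(doses) * voxel_cc
  if (total < v)
    stop(sprintf("mask volume %.4g cc is below the %.4g cc threshold", total, v))
  if (v == 0) return(max(doses))
  s <- sort(doses, decreasing = TRUE, method = "radix")
  k <- ceiling(v / voxel_cc - 1e-12)
  s[k]
}

#' Cumulative dose-volume histogram
#'
#' Volume receiving at least each bin dose, on bins `0, w, 2w, ...` up to the
#' in-mask maximum.
#'
#' @param grid a [dose_grid()].
#' @param mask logical array or [rasterize_structure()] result.
#' @param bin_width bin width in Gy.
#' @return data.frame with `dose_gy` (ascending) and `volume_cc`
#'   (non-increasing; first entry equals the total mask volume).
#' @export
dvh <- function(grid, mask, bin_width = 0.1) {
  if (is.list(mask)) mask <- mask$mask
  doses <- grid$values[mask]
  if (!length(doses)) stop("empty structure: no in-mask voxels")
  if (bin_width <= 0) stop("bin width must be positive")
  bins <- seq(0, max(doses) + bin_width, by = bin_width)
  vol <- vapply(bins, function(d) sum(doses >= d), numeric(1)) *
    voxel_volume_cc(grid)
  data.frame(dose_gy = bins, volume_cc = vol)
}

#' Scale a per-fraction dose metric to the whole course
#'
#' Per-fraction metrics are converted to the total prescription scale by
#' linear multiplication with the fraction count (course default 33).
#'
#' @param fraction_metric dose in Gy for one fraction.
#' @param n_fractions number of fractions, `>= 1`.
#' @return course-scale dose in Gy.
#' @export
scale_to_course <- function(fraction_metric, n_fractions = 33) {
  if (length(n_fractions) != 1L || !is.finite(n_fractions) || n_fractions < 1)
    stop("`n_fractions` must be >= 1")
  fraction_metric * n_fractions
}

#' Percentage dose difference relative to the planned metric
#'
#' `100 * (metric - planned) / planned`, sign-preserving.
#'
#' @param metric dose in Gy.
#' @param planned planned dose in Gy, `> 0`.
#' @return percent difference.
#' @export
percent_diff <- function(metric, planned) {
  if (any(!is.finite(planned)) || any(planned <= 0))
    stop("planned dose must be positive")
  100 * (metric - planned) / planned
}
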