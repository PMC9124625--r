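#' Cranio-caudal region partition of the cord
#'
#' Half-open intervals `[y_min, y_max)` along the inferior-superior axis, one
#' per named neck region. A slice exactly at a boundary belongs to the
#' interval whose `y_min` it equals (deterministic tie-break). The canonical
#' regions are `C1_C3`, `C4_C5` and `C6_C7`; a `HEAD` reference interval is
#' optional.
#'
#' @param ... named length-2 numeric vectors `c(y_min, y_max)` in mm, or a
#'   single named list of such vectors.
#' @return An object of class `region_partition` (named list of intervals,
#'   ordered by y_min).
#' @export
region_partition <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && is.null(names(args)[1]))
    args <- args[[1]]
  if (is.null(names(args)) || any(names(args) == ""))
    stop("all regions must be named")
  iv <- lapply(args, function(v) {
    v <- as.numeric(v)
    if (length(v) != 2L || !all(is.finite(v)) || v[1] >= v[2])
      stop("each region must be c(y_min, y_max) with y_min < y_max")
    v
  })
  iv <- iv[order(vapply(iv, `[`, numeric(1), 1))]
  lo <- vapply(iv, `[`, numeric(1), 1)
  hi <- vapply(iv, `[`, numeric(1), 2)
  if (length(iv) > 1L && any(hi[-length(hi)] > lo[-1] + 1e-9))
    stop("region intervals overlap")
  structure(iv, class = "region_partition")
}

#' Region names of a partition
#' @param partition a [region_partition()].
#' @param sc_only drop the `HEAD` reference interval if present.
#' @export
region_names <- function(partition, sc_only = FALSE) {
  nm <- names(partition)
  if (sc_only) nm <- setdiff(nm, "HEAD")
  nm
}

#' Which region contains a y coordinate (half-open convention)
#' @param partition a [region_partition()].
#' @param y numeric vector of y coordinates (mm).
#' @return character vector of region names, `NA` where outside all regions.
#' @export
region_of <- function(partition, y) {
  out <- rep(NA_character_, length(y))
  for (nm in names(partition)) {
    iv <- partition[[nm]]
    out[y >= iv[1] & y < iv[2]] <- nm
  }
  out
}

#' Split a structure by cord region
#'
#' Each contour is assigned to the region whose half-open interval contains
#' its `y_slice`; contours outside all regions are dropped.
#'
#' @param struct an [rt_structure()].
#' @param partition a [region_partition()].
#' @return named list region -> [rt_structure()] (or `NULL` for regions with
#'   no contours).
#' @export
split_by_region <- function(struct, partition) {
  ys <- structure_slices(struct)
  reg <- region_of(partition, ys)
  out <- stats::setNames(vector("list", length(partition)), names(partition))
  for (nm in names(partition)) {
    keep <- which(!is.na(reg) & reg == nm)
    if (length(keep))
      out[[nm]] <- rt_structure(paste(struct$name, nm, sep = "::"),
                                struct$contours[keep], role = struct$role)
  }
  out
}

#' Median slice surface area (SSA) of a structure over a region
#'
#' The SSA of a region is the median polygon area over the structure's slices
#' whose y lies in the half-open interval; an even slice count takes the mean
#' of the two central values (standard median).
#'
#' @param external an [rt_structure()] (typically the body external contour).
#' @param region length-2 numeric `c(y_min, y_max)` mm, or a region name plus
#'   `partition`.
#' @param partition optional [region_partition()] when `region` is a name.
#' @return SSA in cm^2.
#' @export
region_ssa <- function(external, region, partition = NULL) {
  if (is.character(region)) {
    if (is.null(partition)) stop("a partition is needed to resolve a region name")
    region <- partition[[region]]
    if (is.null(region)) stop("unknown region name")
  }
  ys <- structure_slices(external)
  keep <- ys >= region[1] & ys < region[2]
  if (!any(keep))
    stop(sprintf("no contour slices in region [%g, %g) mm", region[1], region[2]))
  stats::median(vapply(external$contours[keep], polygon_area, numeric(1)))
}

#' Fractional contour change between planning CT and a treatment image
#'
#' `(ssa_ct - ssa_cbct) / ssa_ct`: positive values are shrinkage, negative
#' values swelling.
#'
#' @param ssa_ct planning SSA in cm^2 (must be > 0).
#' @param ssa_cbct treatment-day SSA in cm^2.
#' @return dimensionless fraction.
#' @export
contour_change <- function(ssa_ct, ssa_cbct) {
  if (any(!is.finite(ssa_ct)) || any(ssa_ct <= 0))
    stop("planning SSA must be positive")
  (ssa_ct - ssa_cbct) / ssa_ct
}

#' Construct a 3D setup-error shift vector
#'
#' Components in mm along the (left-right, inferior-superior,
#' anterior-posterior) axes. Sign convention: anatomy position at treatment
#' minus planned position, in plan coordinates; the rapid estimator adds this
#' vector to the planned cord contour.
#'
#' @param dx,dy,dz components in mm.
#' @return An object of class `shift_vector` (named numeric length 3).
#' @export
shift_vector <- function(dx = 0, dy = 0, dz = 0) {
  v <- c(dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz))
  if (!all(is.finite(v))) stop("shift components must be finite")
  structure(v, class = "shift_vector")
}

#' 3D setup-error magnitude
#'
#' Euclidean norm `sqrt(dx^2 + dy^2 + dz^2)` of a shift vector.
#'
#' @param shift a [shift_vector()] or numeric length-3.
#' @return magnitude in mm.
#' @export
three_d_error <- function(shift) {
  v <- as.numeric(shift)
  if (length(v) != 3L || !all(is.finite(v)))
    stop("`shift` must be 3 finite components")
  sqrt(sum(v^2))
}

#' Clip (shrink) the external contour by per-region area fractions
#'
#' Each slice polygon is scaled radially about its centroid so that the new
#' area equals `(1 - shrink) * old area` (linear scale factor
#' `sqrt(1 - shrink)`). This isotropic, area-matched shrink is the package's
#' declared stand-in for treatment-day body-contour reduction.
#'
#' @param external an [rt_structure()].
#' @param shrink either a single fraction applied to all slices, or a named
#'   numeric vector region -> fraction (requires `partition`). Fractions must
#'   lie in `[0, 1)`. Slices outside all named regions are left unchanged.
#' @param partition a [region_partition()] when `shrink` is per-region.
#' @return a new [rt_structure()] with scaled contours.
#' @export
clip_external <- function(external, shrink, partition = NULL) {
  if (any(!is.finite(shrink)) || any(shrink < 0) || any(shrink >= 1))
    stop("shrink fractions must lie in [0, 1)")
  per_region <- !is.null(names(shrink)) && all(nzchar(names(shrink)))
  if (per_region && is.null(partition))
    stop("a partition is needed for per-region shrink fractions")
  contours <- lapply(external$contours, function(ct) {
    f <- if (per_region) {
      reg <- region_of(partition, ct$y_slice)
      if (is.na(reg) || is.na(shrink[reg])) 0 else unname(shrink[reg])
    } else unname(shrink[1])
    if (f == 0) return(ct)
    cen <- polygon_centroid(ct)
    s <- sqrt(1 - f)
    p <- sweep(sweep(ct$points, 2, cen, "-") * s, 2, cen, "+")
    contour(ct$y_slice, p, check = FALSE)   # similarity transform keeps simplicity
  })
  rt_structure(external$name, contours, role = external$role)
}
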