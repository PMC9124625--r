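# Toy coplanar depth-dose engine.
#
# Declared model, not a clinical dose algorithm: per axial slice, N equally
# spaced coplanar beams deliver w_b(p) * exp(-mu * depth_b(p)), where depth is
# measured from the external surface along the beam axis and w_b is a fluence
# profile fixed in room coordinates -- a flat field with sigmoid penumbra aimed
# at the target axis, multiplied by a Gaussian cord-sparing notch centred on
# the *planned* cord axis. The notch puts the cord in a dose valley (any shift
# climbs the valley walls) and the depth term makes body shrinkage increase
# the cord dose, which are the two dose effects the pipeline studies.

#' Parameters of the toy dose engine
#'
#' @param n_beams number of equally spaced coplanar beams (default 36).
#' @param mu linear attenuation coefficient in 1/mm (default 0.005, about a
#'   6 MV beam in water).
#' @param prescription_gy course prescription at the reference target point
#'   (default 70 Gy).
#' @param n_fractions fraction count (default 33); engine output is one
#'   fraction.
#' @param target_center (x, z) mm of the target/beam axis in every slice.
#' @param field_radius half-width of the flat fluence plateau (mm).
#' @param field_penumbra sigmoid penumbra scale of the plateau edge (mm).
#' @param cord_center (x, z) mm of the planned cord axis (the notch centre,
#'   fixed in room coordinates).
#' @param notch_width named numeric: Gaussian notch sigma (mm) per region.
#'   Wider notches give flatter dose valleys (regions far from the target).
#' @param notch_depth named numeric in `[0, 1)`: fluence reduction at the
#'   notch centre per region; usually set by [calibrate_engine()].
#' @param partition a [region_partition()] used to map slice y to the regional
#'   notch parameters; slices outside all regions get no notch.
#' @param norm Gy per unit raw engine output; `NULL` until calibrated.
#' @return list of class `toy_engine_params`.
#' @export
toy_engine_params <- function(n_beams = 36, mu = 0.005, prescription_gy = 70,
                              n_fractions = 33, target_center = c(0, 0),
                              field_radius = 50, field_penumbra = 6,
                              cord_center = c(0, -25),
                              notch_width = c(C1_C3 = 9, C4_C5 = 14, C6_C7 = 24),
                              notch_depth = c(C1_C3 = 0.5, C4_C5 = 0.5,
                                              C6_C7 = 0.5),
                              partition = NULL, norm = NULL) {
  if (n_beams < 1) stop("need at least one beam")
  if (mu <= 0) stop("mu must be positive")
  if (any(notch_depth < 0) || any(notch_depth >= 1))
    stop("notch depths must lie in [0, 1)")
  structure(list(n_beams = as.integer(n_beams), mu = mu,
                 prescription_gy = prescription_gy,
                 n_fractions = n_fractions,
                 target_center = as.numeric(target_center),
                 field_radius = field_radius,
                 field_penumbra = field_penumbra,
                 cord_center = as.numeric(cord_center),
                 notch_width = notch_width, notch_depth = notch_depth,
                 partition = partition, norm = norm),
            class = "toy_engine_params")
}

# Distance from each point to the first polygon boundary crossing along
# direction (ux, uz); NA where the ray never crosses (point outside, or
# grazing). Exact for convex sections, a declared first-crossing
# simplification otherwise.
.depth_to_surface <- function(px, pz, poly, ux, uz) {
  n <- nrow(poly)
  tmin <- rep(Inf, length(px))
  v1x <- poly[, 1]; v1z <- poly[, 2]
  j <- c(2:n, 1)
  ex <- poly[j, 1] - v1x
  ez <- poly[j, 2] - v1z
  den <- ux * ez - uz * ex
  for (k in seq_len(n)) {
    if (abs(den[k]) < 1e-12) next
    rx <- v1x[k] - px
    rz <- v1z[k] - pz
    t <- (rx * ez[k] - rz * ex[k]) / den[k]
    s <- (rx * uz - rz * ux) / den[k]
    hit <- t > 1e-9 & s >= -1e-9 & s <= 1 + 1e-9
    tmin[hit] <- pmin(tmin[hit], t[hit])
  }
  tmin[!is.finite(tmin)] <- NA_real_
  tmin
}

# Raw (unnormalized) per-fraction dose of one slice at in-plane points.
# `poly` is the external polygon of that slice; points outside it get 0.
.slice_raw_dose <- function(px, pz, poly, params, notch_w, notch_b) {
  inside <- point_in_polygon(px, pz, poly)
  dose <- numeric(length(px))
  if (!any(inside)) return(dose)
  ix <- px[inside]; iz <- pz[inside]
  ct <- params$target_center
  cc <- params$cord_center
  nb <- params$n_beams
  acc <- numeric(length(ix))
  theta <- 2 * pi * (seq_len(nb) - 1) / nb
  for (b in seq_len(nb)) {
    dxb <- cos(theta[b]); dzb <- sin(theta[b])       # propagation direction
    nxb <- -dzb; nzb <- dxb                          # in-plane lateral axis
    l <- (ix - ct[1]) * nxb + (iz - ct[2]) * nzb
    plateau <- 1 / (1 + exp((abs(l) - params$field_radius) /
                              params$field_penumbra))
    fl <- plateau
    if (notch_b > 0) {
      l_sc <- (cc[1] - ct[1]) * nxb + (cc[2] - ct[2]) * nzb
      fl <- fl * (1 - notch_b * exp(-(l - l_sc)^2 / (2 * notch_w^2)))
    }
    depth <- .depth_to_surface(ix, iz, poly, -dxb, -dzb)
    depth[is.na(depth)] <- 0
    acc <- acc + fl * exp(-params$mu * depth)
  }
  dose[inside] <- acc / nb
  dose
}

# Nearest external contour index for each y, NA when farther than half a
# slice pitch (same matching rule as rasterize_structure()).
.nearest_slice <- function(external, y, tol_grid = NULL) {
  ys <- structure_slices(external)
  pitch <- if (length(ys) > 1) stats::median(diff(ys)) else Inf
  cand <- c(tol_grid, if (is.finite(pitch)) pitch)
  tol <- if (length(cand)) max(cand) / 2 else Inf   # single slice: one slab
  k <- vapply(y, function(yy) which.min(abs(ys - yy)), integer(1))
  k[abs(ys[k] - y) > tol] <- NA_integer_
  k
}

# Cosine-eased interpolation through (xs, vs) anchor points, flat beyond the
# outermost anchors. Zero slope at every anchor, monotone between neighbours.
.cosine_blend <- function(y, xs, vs) {
  o <- order(xs)
  xs <- xs[o]; vs <- vs[o]
  if (y <= xs[1]) return(vs[1])
  if (y >= xs[length(xs)]) return(vs[length(vs)])
  i <- findInterval(y, xs)
  t <- unname((y - xs[i]) / (xs[i + 1] - xs[i]))
  vs[i] + (vs[i + 1] - vs[i]) * (1 - cos(pi * t)) / 2
}

# Per-region notch parameters are anchored at the region centres and blended
# smoothly along y (anatomy and beam shaping vary continuously along the
# neck); the notch follows the planned cord axis beyond the partitioned
# interval.
.notch_params_at <- function(params, y) {
  if (is.null(params$partition)) return(c(w = 1, b = 0))
  regs <- intersect(names(params$partition), names(params$notch_depth))
  if (!length(regs)) return(c(w = 1, b = 0))
  centers <- vapply(params$partition[regs], mean, numeric(1))
  c(w = .cosine_blend(y, centers, unname(params$notch_width[regs])),
    b = .cosine_blend(y, centers, unname(params$notch_depth[regs])))
}

#' Evaluate the toy engine at arbitrary points
#'
#' Per-fraction dose in Gy at (x, y, z) points for a given external anatomy,
#' using the engine's calibrated normalization. Points outside the body (or on
#' slices with no external contour) receive zero dose.
#'
#' @param points numeric matrix `n x 3` (mm).
#' @param external the body [rt_structure()] (treatment-day anatomy).
#' @param params [toy_engine_params()] with `norm` set (see
#'   [calibrate_engine()]).
#' @return numeric vector of per-fraction doses (Gy).
#' @export
engine_dose_points <- function(points, external, params) {
  if (is.null(params$norm))
    stop("engine is not calibrated; run calibrate_engine() first")
  points <- matrix(as.numeric(points), ncol = 3)
  k <- .nearest_slice(external, points[, 2])
  dose <- numeric(nrow(points))
  for (ki in unique(k[!is.na(k)])) {
    sel <- which(!is.na(k) & k == ki)
    ct <- external$contours[[ki]]
    np <- .notch_params_at(params, ct$y_slice)
    dose[sel] <- .slice_raw_dose(points[sel, 1], points[sel, 3], ct$points,
                                 params, np["w"], np["b"])
  }
  dose * params$norm
}

#' Compute a full per-fraction dose grid with the toy engine
#'
#' Evaluates the engine at every voxel centre of `grid` for the external
#' anatomy rigidly displaced by `shift` (beams stay fixed in room
#' coordinates).
#'
#' @param external the planning body [rt_structure()].
#' @param shift anatomy shift (mm), default none.
#' @param grid a [dose_grid()] supplying the voxel lattice (its values are
#'   ignored).
#' @param params calibrated [toy_engine_params()].
#' @return a [dose_grid()] of per-fraction dose (Gy).
#' @export
toy_dose_engine <- function(external, shift = c(0, 0, 0), grid, params) {
  if (is.null(params$norm))
    stop("engine is not calibrated; run calibrate_engine() first")
  if (any(as.numeric(shift) != 0))
    external <- displace_structure(external, shift)
  ax <- grid_axes(grid)
  vals <- array(0, dim(grid$values))
  k <- .nearest_slice(external, ax$y, tol_grid = grid$spacing[2])
  xz <- expand.grid(x = ax$x, z = ax$z)
  for (iy in seq_along(ax$y)) {
    if (is.na(k[iy])) next
    ct <- external$contours[[k[iy]]]
    np <- .notch_params_at(params, ct$y_slice)
    d <- .slice_raw_dose(xz$x, xz$z, ct$points, params, np["w"], np["b"])
    vals[, iy, ] <- matrix(d, length(ax$x), length(ax$z)) * params$norm
  }
  dose_grid(vals, grid$origin, grid$spacing)
}

#' Calibrate the engine normalization on the planning anatomy
#'
#' Fixes the Gy-per-raw-output factor so that the notch-free reference dose at
#' the target axis (at reference slice `y_ref`) equals the per-fraction
#' prescription. The factor is computed once on the planning anatomy and
#' reused for all perturbed recalculations (fixed monitor units).
#'
#' @param params [toy_engine_params()].
#' @param external planning body [rt_structure()].
#' @param y_ref reference slice (mm); default: centre of the most superior
#'   partition region, or the median structure slice without a partition.
#' @return `params` with `norm` set.
#' @export
calibrate_engine <- function(params, external, y_ref = NULL) {
  if (is.null(y_ref)) {
    y_ref <- if (!is.null(params$partition)) {
      iv <- params$partition[[length(params$partition)]]
      mean(iv)
    } else stats::median(structure_slices(external))
  }
  k <- .nearest_slice(external, y_ref)
  if (is.na(k)) stop("reference slice has no external contour")
  ct <- external$contours[[k]]
  raw <- .slice_raw_dose(params$target_center[1], params$target_center[2],
                         ct$points, params, notch_w = 1, notch_b = 0)
  if (raw <= 0) stop("reference point receives no dose; check the geometry")
  params$norm <- (params$prescription_gy / params$n_fractions) / raw
  params
}
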