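# Synthetic neck phantom: per-region elliptical body sections with a
# posteriorly offset cord cylinder, on the course's 2.5 mm dose lattice.

# Regular n-gon approximating an ellipse, semi-axes (a, b) mm, with the
# vertex radius inflated so the polygon area equals pi*a*b exactly.
.ellipse_poly <- function(a, b, n = 48, center = c(0, 0)) {
  infl <- 1 / sqrt((n / (2 * pi)) * sin(2 * pi / n))
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + a * infl * cos(th), center[2] + b * infl * sin(th))
}

#' Specification of the synthetic neck phantom
#'
#' Defaults encode the study conditions: 2.5 mm lattice, 70 Gy in 33
#' fractions, per-region body slice areas equal to the planning-CT cohort
#' means (192.7 / 133.0 / 171.4 cm^2 for C1-C3 / C4-C5 / C6-C7), a 4 mm cord
#' cylinder 25 mm posterior of the body axis, and per-region planned cord
#' D0.1cc targets of 37.4 / 36.2 / 33.2 Gy.
#'
#' @param region_y named list of `c(y_min, y_max)` mm for the three cord
#'   regions (most inferior first).
#' @param slice_mm slice/lattice pitch in mm.
#' @param body_area_cm2 named per-region body cross-section areas (cm^2).
#' @param body_aspect anterior-posterior over left-right semi-axis ratio.
#' @param cord_radius cord cylinder radius (mm).
#' @param cord_center (x, z) mm of the cord axis.
#' @param prescription_gy,n_fractions course prescription.
#' @param planned_dmax_gy named per-region planned cord D0.1cc calibration
#'   targets (course scale, Gy).
#' @param y_margin how far (mm) the body external and the dose lattice extend
#'   beyond the partitioned cord interval, so that shifted cord contours stay
#'   on anatomy and on the grid.
#' @param grid_half_x,grid_half_z lattice half-extents (mm).
#' @param n_beams,mu,field_radius,field_penumbra,notch_width engine
#'   parameters, see [toy_engine_params()].
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(region_y = list(C6_C7 = c(0, 40), C4_C5 = c(40, 75),
                                         C1_C3 = c(75, 135)),
                         slice_mm = 2.5,
                         body_area_cm2 = c(C1_C3 = 192.7, C4_C5 = 133.0,
                                           C6_C7 = 171.4),
                         body_aspect = 0.75,
                         cord_radius = 4, cord_center = c(0, -25),
                         prescription_gy = 70, n_fractions = 33,
                         planned_dmax_gy = c(C1_C3 = 37.4, C4_C5 = 36.2,
                                             C6_C7 = 33.2),
                         y_margin = 15,
                         grid_half_x = 95, grid_half_z = 72.5,
                         n_beams = 36, mu = 0.005,
                         field_radius = 50, field_penumbra = 6,
                         notch_width = c(C1_C3 = 9, C4_C5 = 14, C6_C7 = 24)) {
  spec <- list(region_y = region_y, slice_mm = slice_mm, y_margin = y_margin,
               body_area_cm2 = body_area_cm2, body_aspect = body_aspect,
               cord_radius = cord_radius, cord_center = as.numeric(cord_center),
               prescription_gy = prescription_gy, n_fractions = n_fractions,
               planned_dmax_gy = planned_dmax_gy,
               grid_half_x = grid_half_x, grid_half_z = grid_half_z,
               n_beams = n_beams, mu = mu, field_radius = field_radius,
               field_penumbra = field_penumbra, notch_width = notch_width)
  if (spec$slice_mm <= 0 || spec$cord_radius <= 0)
    stop("dimensions must be positive")
  for (nm in names(region_y)) {
    a <- sqrt(100 * body_area_cm2[nm] / (pi * body_aspect))
    b <- a * body_aspect
    if (abs(cord_center[1]) + cord_radius >= a ||
        abs(cord_center[2]) + cord_radius >= b)
      stop(sprintf("cord cylinder is not strictly inside the %s body section",
                   nm))
  }
  class(spec) <- "phantom_spec"
  spec
}

#' Build the synthetic phantom and its planned dose
#'
#' Constructs the body external and cord structures on the lattice, calibrates
#' the engine (normalization on the planning anatomy, then per-region notch
#' depths so the planned regional cord D0.1cc hits the spec's targets), and
#' optionally computes the full planned dose grid at course scale.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed (the phantom is deterministic; kept for a uniform
#'   generator interface).
#' @param compute_plan compute the full planned [dose_grid()] (needed by the
#'   displaced-contour estimator); geometry-only phantoms are faster.
#' @return list of class `phantom`: `spec`, `external`, `sc`, `sc_regions`,
#'   `partition`, `params` (calibrated), `lattice` (empty grid), `plan`
#'   (course-scale planned dose grid or `NULL`), `planned` (named per-region
#'   planned D0.1cc, Gy).
#' @export
make_phantom <- function(spec = phantom_spec(), seed = 1, compute_plan = TRUE) {
  set.seed(seed)
  partition <- region_partition(spec$region_y)
  y_lo <- min(vapply(spec$region_y, `[`, numeric(1), 1))
  y_hi <- max(vapply(spec$region_y, `[`, numeric(1), 2))
  ys_ext <- seq(y_lo - spec$y_margin + spec$slice_mm / 2,
                y_hi + spec$y_margin - 1e-9, by = spec$slice_mm)
  ys_cord <- ys_ext[ys_ext >= y_lo & ys_ext < y_hi]

  # the body cross-section area tapers smoothly along the neck: anchored at
  # the region centres, cosine-blended in between, flat beyond
  area_centers <- vapply(partition[names(spec$body_area_cm2)], mean,
                         numeric(1))
  ext_contours <- lapply(ys_ext, function(y) {
    area <- .cosine_blend(y, area_centers, unname(spec$body_area_cm2))
    a <- sqrt(100 * area / (pi * spec$body_aspect))
    contour(y, .ellipse_poly(a, a * spec$body_aspect), check = FALSE)
  })
  external <- rt_structure("external", ext_contours, role = "external")
  sc_contours <- lapply(ys_cord, function(y)
    contour(y, .ellipse_poly(spec$cord_radius, spec$cord_radius, n = 24,
                             center = spec$cord_center), check = FALSE))
  sc <- rt_structure("spinal_cord", sc_contours, role = "spinal_cord")

  nx <- 2 * ceiling(spec$grid_half_x / spec$slice_mm) + 1
  nz <- 2 * ceiling(spec$grid_half_z / spec$slice_mm) + 1
  lattice <- dose_grid(array(0, c(nx, length(ys_ext), nz)),
                       origin = c(-(nx - 1) / 2 * spec$slice_mm, ys_ext[1],
                                  -(nz - 1) / 2 * spec$slice_mm),
                       spacing = rep(spec$slice_mm, 3))

  params <- toy_engine_params(
    n_beams = spec$n_beams, mu = spec$mu,
    prescription_gy = spec$prescription_gy, n_fractions = spec$n_fractions,
    target_center = c(0, 0), field_radius = spec$field_radius,
    field_penumbra = spec$field_penumbra, cord_center = spec$cord_center,
    notch_width = spec$notch_width,
    notch_depth = stats::setNames(rep(0.5, length(spec$notch_width)),
                                  names(spec$notch_width)),
    partition = partition)
  params <- calibrate_engine(params, external)

  sc_regions <- split_by_region(sc, partition)
  sc_pts <- lapply(sc_regions, function(s)
    mask_centers(rasterize_structure(s, lattice), lattice))
  vox_cc <- voxel_volume_cc(lattice)

  region_dmax <- function(p, reg) {
    doses <- engine_dose_points(sc_pts[[reg]], external, p)
    scale_to_course(dmax_from_doses(doses, vox_cc, 0.1), spec$n_fractions)
  }
  # notch-depth anchors are coupled through the smooth blending, so calibrate
  # by Gauss-Seidel sweeps: each pass solves every region's anchor with the
  # others held fixed
  for (sweep in 1:3) {
    for (reg in names(spec$planned_dmax_gy)) {
      target <- spec$planned_dmax_gy[[reg]]
      f <- function(b) {
        p <- params; p$notch_depth[reg] <- b
        region_dmax(p, reg) - target
      }
      if (f(0) < 0)
        stop(sprintf("planned D0.1cc target %.1f Gy unreachable in %s",
                     target, reg))
      params$notch_depth[reg] <- stats::uniroot(f, c(0, 0.985), tol = 1e-5)$root
    }
    err <- max(abs(vapply(names(spec$planned_dmax_gy), function(reg)
      region_dmax(params, reg) - spec$planned_dmax_gy[[reg]], numeric(1))))
    if (err < 0.02) break
  }

  plan <- NULL
  if (compute_plan) {
    plan <- toy_dose_engine(external, grid = lattice, params = params)
    plan$values <- plan$values * spec$n_fractions
  }
  planned <- vapply(names(spec$planned_dmax_gy), function(reg)
    region_dmax(params, reg), numeric(1))

  structure(list(spec = spec, external = external, sc = sc,
                 sc_regions = sc_regions, partition = partition,
                 params = params, lattice = lattice, plan = plan,
                 planned = planned),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> synthetic neck course\n")
  cat(sprintf("  %d slices at %.2g mm; prescription %g Gy / %d fractions\n",
              length(x$external$contours), x$spec$slice_mm,
              x$spec$prescription_gy, x$spec$n_fractions))
  cat("  planned cord D0.1cc (Gy):",
      paste(sprintf("%s %.1f", names(x$planned), x$planned), collapse = ", "),
      "\n")
  invisible(x)
}
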