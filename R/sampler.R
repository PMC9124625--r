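# Course sampler: regional setup errors and progressive shrink over the six
# imaging time points, with per-fraction dose recalculations by the toy
# engine for the delivered / setup-only / contour-only variants.

#' Uncertainty model of a synthetic course
#'
#' Per-region, per-axis Gaussian setup errors with an early/late phase break
#' at fraction 23, and a monotone per-region shrink schedule (zero at the
#' first imaged fraction, linear in fraction index to the configured course-end
#' fraction). Default per-axis parameters were solved so that the expected 3D
#' error magnitude matches the published per-phase regional means, with the
#' anterior-posterior means negative (the posterior tendency of neck setup
#' errors); the per-axis decomposition itself is an assumption of the
#' generator. Default end-of-course shrink fractions are the published
#' endpoint area reductions (6.69% / 12.93% / 17.91%).
#'
#' @param shift named list region -> list(early, late), each phase a list with
#'   `mean` and `sd` length-3 numeric (mm, LR/SI/AP order).
#' @param phase_break fraction index at which the late phase starts.
#' @param end_shrink named per-region course-end shrink fractions in `[0, 1)`.
#' @param shrink_rel_sd relative SD of the per-patient end shrink (truncated
#'   at 0).
#' @param dose_noise_pct SD, in percent points, of the recalculation noise
#'   added to the contour-only percent dose change when the linear dose
#'   response is used (default 0.1; the engine mode is deterministic).
#' @param timepoints imaged fraction indices.
#' @return list of class `uncertainty_model`.
#' @export
uncertainty_model <- function(
    shift = list(
      HEAD  = list(early = list(mean = c(0, 0, -0.2), sd = rep(1.25, 3)),
                   late  = list(mean = c(0, 0, -0.2), sd = rep(1.25, 3))),
      C1_C3 = list(early = list(mean = c(0, 0, -0.8), sd = rep(1.23, 3)),
                   late  = list(mean = c(0, 0, -1.2), sd = rep(1.56, 3))),
      C4_C5 = list(early = list(mean = c(0, 0, -1.0), sd = rep(1.48, 3)),
                   late  = list(mean = c(0, 0, -1.8), sd = rep(2.28, 3))),
      C6_C7 = list(early = list(mean = c(0, 0, -1.2), sd = rep(1.63, 3)),
                   late  = list(mean = c(0, 0, -2.0), sd = rep(2.38, 3)))),
    phase_break = 23,
    end_shrink = c(C1_C3 = 0.0669, C4_C5 = 0.1293, C6_C7 = 0.1791),
    shrink_rel_sd = 0.45,
    dose_noise_pct = 0.1,
    timepoints = c(1, 10, 17, 23, 28, 33)) {
  for (reg in names(shift)) for (ph in c("early", "late")) {
    p <- shift[[reg]][[ph]]
    if (length(p$mean) != 3L || length(p$sd) != 3L || any(p$sd < 0))
      stop("each shift phase needs mean and sd of length 3 with sd >= 0")
  }
  if (any(end_shrink < 0) || any(end_shrink >= 1))
    stop("end shrink fractions must lie in [0, 1)")
  if (dose_noise_pct < 0) stop("dose noise SD must be non-negative")
  structure(list(shift = shift, phase_break = phase_break,
                 end_shrink = end_shrink, shrink_rel_sd = shrink_rel_sd,
                 dose_noise_pct = dose_noise_pct, timepoints = timepoints),
            class = "uncertainty_model")
}

#' The all-zero uncertainty model
#'
#' Zero means, zero SDs, zero shrink: sampled courses reproduce the plan
#' exactly.
#' @param timepoints imaged fraction indices.
#' @export
null_uncertainty_model <- function(timepoints = c(1, 10, 17, 23, 28, 33)) {
  z <- list(mean = c(0, 0, 0), sd = c(0, 0, 0))
  uncertainty_model(
    shift = stats::setNames(
      rep(list(list(early = z, late = z)), 4),
      c("HEAD", "C1_C3", "C4_C5", "C6_C7")),
    end_shrink = c(C1_C3 = 0, C4_C5 = 0, C6_C7 = 0),
    shrink_rel_sd = 0, dose_noise_pct = 0, timepoints = timepoints)
}

.draw_shift <- function(model, region, fraction) {
  ph <- if (fraction >= model$phase_break) "late" else "early"
  p <- model$shift[[region]][[ph]]
  stats::rnorm(3, p$mean, p$sd)
}

#' Sample a complete synthetic course
#'
#' For each patient and imaged fraction: draws per-region setup shifts, builds
#' the shrunk external (per-region linear shrink schedule with per-patient
#' course-end variability), records regional slice surface areas, and
#' recalculates regional cord D0.1cc (course scale) with the toy engine for
#' three variants: `delivered` (shift + shrink), `setup` (shift only, planning
#' contour) and `contour` (shrink only, zero shift). Fully reproducible from
#' `seed`.
#'
#' @param model an [uncertainty_model()].
#' @param phantom a [make_phantom()] result (plan grid not required).
#' @param n_patients cohort size (default 10).
#' @param seed integer seed.
#' @param contour_dose_model `"engine"` (default) recalculates the
#'   contour-only variant with the toy engine; `"linear"` generates it from a
#'   known linear dose response `percent change = beta * contour change %` plus
#'   Gaussian noise, for parameter-recovery validation.
#' @param linear_beta slope (percent Dmax per percent area change) of the
#'   linear mode; its additive noise SD comes from the model's
#'   `dose_noise_pct`.
#' @param variants which dose variants to compute (subset of
#'   `c("delivered", "setup", "contour")`).
#' @return list of class `course`: `records` (long data.frame: one row per
#'   patient x fraction x region with shift components, SSA and course-scale
#'   dose metrics; the `HEAD` rows carry shifts only), `planned` (named
#'   per-region planned D0.1cc), `phantom`, `model`.
#' @export
sample_course <- function(model, phantom, n_patients = 10, seed = 1,
                          contour_dose_model = c("engine", "linear"),
                          linear_beta = 0.17,
                          variants = c("delivered", "setup", "contour")) {
  contour_dose_model <- match.arg(contour_dose_model)
  variants <- match.arg(variants, several.ok = TRUE)
  set.seed(seed)
  spec <- phantom$spec
  partition <- phantom$partition
  sc_regions <- names(phantom$planned)
  all_regions <- intersect(names(model$shift),
                           c("HEAD", sc_regions))
  vox_cc <- voxel_volume_cc(phantom$lattice)
  base_ssa <- vapply(sc_regions, function(r)
    region_ssa(phantom$external, r, partition), numeric(1))
  sc_pts <- lapply(phantom$sc_regions[sc_regions], function(s)
    mask_centers(rasterize_structure(s, phantom$lattice), phantom$lattice))

  course_dmax <- function(pts, external)
    scale_to_course(
      dmax_from_doses(engine_dose_points(pts, external, phantom$params),
                      vox_cc, 0.1),
      spec$n_fractions)

  rows <- vector("list", n_patients * length(model$timepoints) *
                   length(all_regions))
  ri <- 0L
  for (p in seq_len(n_patients)) {
    end_shrink <- pmax(0, pmin(0.95, stats::rnorm(
      length(model$end_shrink), model$end_shrink,
      model$shrink_rel_sd * model$end_shrink)))
    names(end_shrink) <- names(model$end_shrink)
    for (fr in model$timepoints) {
      frac_along <- (fr - 1) / (spec$n_fractions - 1)
      shrink <- end_shrink * frac_along
      clipped <- if (any(shrink > 0))
        clip_external(phantom$external, shrink, partition)
      else phantom$external
      shifts <- lapply(stats::setNames(all_regions, all_regions),
                       function(r) .draw_shift(model, r, fr))
      for (reg in all_regions) {
        ri <- ri + 1L
        s <- shifts[[reg]]
        if (reg == "HEAD") {
          rows[[ri]] <- data.frame(
            patient = p, fraction = fr, region = reg,
            dx = s[1], dy = s[2], dz = s[3],
            ssa_cm2 = NA_real_, shrink = NA_real_,
            dmax_planned = NA_real_, dmax_delivered = NA_real_,
            dmax_setup = NA_real_, dmax_contour = NA_real_,
            stringsAsFactors = FALSE)
          next
        }
        pts <- sc_pts[[reg]]
        # the TPS-analogue variants read Dmax on the lattice rasterization of
        # the shifted cord, as a recalculation on shifted anatomy would
        pts_s <- if (any(s != 0) &&
                     any(c("delivered", "setup") %in% variants)) {
          moved <- displace_structure(phantom$sc_regions[[reg]], s)
          mask_centers(rasterize_structure(moved, phantom$lattice),
                       phantom$lattice)
        } else pts
        d_del <- if ("delivered" %in% variants)
          course_dmax(pts_s, displace_structure(clipped, s)) else NA_real_
        d_set <- if ("setup" %in% variants)
          course_dmax(pts_s, displace_structure(phantom$external, s))
        else NA_real_
        d_con <- NA_real_
        if ("contour" %in% variants) {
          if (contour_dose_model == "engine") {
            d_con <- course_dmax(pts, clipped)
          } else {
            change_pct <- 100 * unname(shrink[reg])
            noise_sd <- if (is.null(model$dose_noise_pct)) 0
              else model$dose_noise_pct
            eps <- if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
            d_con <- phantom$planned[[reg]] *
              (1 + (linear_beta * change_pct + eps) / 100)
          }
        }
        rows[[ri]] <- data.frame(
          patient = p, fraction = fr, region = reg,
          dx = s[1], dy = s[2], dz = s[3],
          ssa_cm2 = (1 - unname(shrink[reg])) * base_ssa[[reg]],
          shrink = unname(shrink[reg]),
          dmax_planned = phantom$planned[[reg]],
          dmax_delivered = d_del, dmax_setup = d_set, dmax_contour = d_con,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(records = do.call(rbind, rows[seq_len(ri)]),
                 planned = phantom$planned, phantom = phantom, model = model),
            class = "course")
}

#' @export
print.course <- function(x, ...) {
  r <- x$records
  cat(sprintf("<course> %d patients x %d time points x %d regions\n",
              length(unique(r$patient)), length(unique(r$fraction)),
              length(unique(r$region))))
  invisible(x)
}
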