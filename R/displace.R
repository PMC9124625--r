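#' Rigidly displace a structure by a setup-error shift
#'
#' Every vertex is translated by (dx, dz) in-plane and every slice coordinate
#' by dy. Rigid: areas and inter-vertex distances are preserved.
#'
#' @param struct an [rt_structure()].
#' @param shift a [shift_vector()] or numeric length-3 (mm).
#' @return a translated [rt_structure()].
#' @export
displace_structure <- function(struct, shift) {
  s <- as.numeric(shift)
  if (length(s) != 3L || !all(is.finite(s)))
    stop("`shift` must be 3 finite components")
  contours <- lapply(struct$contours, function(ct)
    contour(ct$y_slice + s[2],
            cbind(ct$points[, 1] + s[1], ct$points[, 2] + s[3]),
            check = FALSE))
  rt_structure(struct$name, contours, role = struct$role)
}

#' Rapid cord-dose estimate after a regional setup shift
#'
#' The rapid estimation method: displace the planned cord contour of one
#' region by the measured regional setup error and sample the *planned* dose
#' grid by trilinear interpolation at the displaced voxel centres of the
#' planned rasterization (a rigid translation of the sampling points, so
#' sub-voxel shifts are resolved continuously). The planned dose distribution
#' itself is assumed unaffected by the shift. A zero shift reproduces the
#' planned Dmax exactly (identical code path).
#'
#' @param plan a [dose_grid()] holding the planned dose (course scale).
#' @param sc_region an [rt_structure()]: the planned cord contour of one
#'   region.
#' @param shift a [shift_vector()] (mm).
#' @param v volume threshold in cc (default 0.1).
#' @param constraint dose constraint in Gy used for the replanning flag
#'   (default 40, the cord planning constraint; use 45 for the cord PRV).
#' @param region label recorded in the estimate (defaults to the structure
#'   name).
#' @return a one-row data.frame (class `displaced_estimate`) with columns
#'   `region`, `dx`, `dy`, `dz`, `dmax_displaced`, `dmax_planned`,
#'   `percent_change`, `flag`.
#' @export
dmax_displaced <- function(plan, sc_region, shift, v = 0.1, constraint = 40,
                           region = sc_region$name) {
  s <- as.numeric(shift)
  ras0 <- withCallingHandlers(
    rasterize_structure(sc_region, plan),
    warning = function(w) invokeRestart("muffleWarning"))
  if (ras0$n_voxels == 0L)
    stop(sprintf("structure for region '%s' is outside the dose grid", region))
  pts0 <- mask_centers(ras0, plan)
  doses <- interp_dose(plan, sweep(pts0, 2, s, "+"))
  if (anyNA(doses))
    stop(sprintf(
      "displaced structure for region '%s' leaves the dose grid extent", region))
  d_disp <- dmax_from_doses(doses, voxel_volume_cc(plan), v)
  # identical code path for the planned value: zero-shift re-read
  d_plan <- dmax_from_doses(interp_dose(plan, pts0), voxel_volume_cc(plan), v)
  out <- data.frame(region = region, dx = s[1], dy = s[2], dz = s[3],
                    dmax_displaced = d_disp, dmax_planned = d_plan,
                    percent_change = percent_diff(d_disp, d_plan),
                    flag = d_disp > constraint,
                    stringsAsFactors = FALSE)
  class(out) <- c("displaced_estimate", class(out))
  out
}

#' Pooled regression of displaced estimates on recalculated setup doses
#'
#' Ordinary least squares of `dmax_displaced` on `dmax_setup`. The estimator
#' and the recalculation agree when the fit is close to the identity line; by
#' default pairs from all regions are pooled into a single fit (one fitting
#' formula serves every region), with a per-region mode available.
#'
#' @param dmax_setup numeric vector: recalculated setup-error doses (Gy).
#' @param dmax_displaced numeric vector: rapid estimates (Gy).
#' @param region optional factor for `mode = "by_region"`.
#' @param mode `"pooled"` (default) or `"by_region"`.
#' @return a `regression_fit` (list with `slope`, `intercept`, `r_squared`,
#'   `residual_mean`, `residual_sd`, `n`), or a named list of them.
#' @export
fit_displaced_vs_setup <- function(dmax_setup, dmax_displaced, region = NULL,
                                   mode = c("pooled", "by_region")) {
  mode <- match.arg(mode)
  if (mode == "by_region") {
    if (is.null(region)) stop("`region` is required for mode = 'by_region'")
    return(lapply(split(data.frame(x = dmax_setup, y = dmax_displaced),
                        region),
                  function(d) ols_fit(d$x, d$y)))
  }
  ols_fit(dmax_setup, dmax_displaced)
}

#' Ordinary least-squares fit with residual summary
#'
#' @param x,y numeric vectors, `length >= 3`.
#' @return object of class `regression_fit`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("at least 3 pairs are required")
  if (stats::sd(x) == 0) stop("degenerate fit: x has zero variance")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot < 1e-300) as.numeric(sum(res^2) < 1e-300)
    else 1 - sum(res^2) / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 residual_mean = mean(res),
                 residual_sd = stats::sd(res),
                 n = length(x)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "<regression_fit> slope %.4g, intercept %.4g, R^2 %.4f (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  cat(sprintf("  residuals %.3g +/- %.3g\n", x$residual_mean, x$residual_sd))
  invisible(x)
}

#' Replanning trigger report from displaced estimates
#'
#' Flags every regional estimate whose displaced dose exceeds the constraint
#' and names the worst-case region.
#'
#' @param estimates a data.frame of [dmax_displaced()] rows (rbind-ed).
#' @param constraint dose constraint in Gy (default 40; use 45 for the PRV).
#' @return list with `table` (per-region flags), `any_flag`, `worst_region`,
#'   `worst_dmax`, `constraint_gy`.
#' @export
trigger_replan <- function(estimates, constraint = 40) {
  if (!NROW(estimates)) stop("no estimates to evaluate")
  if (!is.finite(constraint) || constraint <= 0)
    stop("constraint must be positive")
  tab <- data.frame(region = estimates$region,
                    dmax_displaced = estimates$dmax_displaced,
                    percent_change = estimates$percent_change,
                    flag = estimates$dmax_displaced > constraint,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$region, method = "radix"), , drop = FALSE]
  worst <- which.max(estimates$dmax_displaced)
  list(table = tab,
       any_flag = any(tab$flag),
       worst_region = estimates$region[worst],
       worst_dmax = estimates$dmax_displaced[worst],
       constraint_gy = constraint)
}
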