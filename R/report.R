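# Course report: tabular analogues of the longitudinal summaries, percent
# dose differences, both regression fits and the replanning flags.

#' Run the full longitudinal analysis of a course
#'
#' Aggregates a sampled (or loaded) course into the standard outputs: the
#' per-time-point 3D setup-error table, the SSA/contour-change table, the
#' percent dose-difference summary, the per-region contour-change dose
#' regressions, the pooled displaced-vs-setup regression (when both variants
#' are present), and per-region replanning flags from the displaced estimates.
#'
#' @param course a [sample_course()] result (for fixture directories, read
#'   with [read_fixture()] and pass `records`/`planned` compatible fields plus
#'   the phantom via [make_phantom()]).
#' @param constraint_gy replanning dose constraint (default 40).
#' @param v volume threshold in cc for the displaced estimates (default 0.1).
#' @param estimate_displaced compute the displaced-contour estimate per
#'   record (requires the phantom's plan grid).
#' @return list of class `course_analysis` with `setup_errors`,
#'   `contour_changes`, `dose_diffs`, `contour_regressions`,
#'   `displaced_fit`, `estimates`, `replan`.
#' @export
run_course_analysis <- function(course, constraint_gy = 40, v = 0.1,
                                estimate_displaced = TRUE) {
  rec <- course$records
  ph <- course$phantom
  setup <- summarize_setup_errors(
    rec[, c("patient", "fraction", "region", "dx", "dy", "dz")])
  base_ssa <- vapply(names(course$planned), function(r)
    region_ssa(ph$external, r, ph$partition), numeric(1))
  contours <- summarize_contour_changes(rec, base_ssa)
  diffs <- dose_difference_summary(rec)
  regs <- course_contour_regressions(course)

  estimates <- NULL
  displaced_fit <- NULL
  replan <- NULL
  if (estimate_displaced && !is.null(ph$plan)) {
    sc_rows <- which(!is.na(rec$dmax_planned))
    est <- do.call(rbind, lapply(sc_rows, function(i) {
      e <- dmax_displaced(ph$plan, ph$sc_regions[[rec$region[i]]],
                          c(rec$dx[i], rec$dy[i], rec$dz[i]), v = v,
                          constraint = constraint_gy, region = rec$region[i])
      cbind(patient = rec$patient[i], fraction = rec$fraction[i], e)
    }))
    estimates <- est
    if (!all(is.na(rec$dmax_setup))) {
      ok <- sc_rows[!is.na(rec$dmax_setup[sc_rows])]
      displaced_fit <- fit_displaced_vs_setup(
        rec$dmax_setup[ok],
        est$dmax_displaced[match(ok, sc_rows)])
    }
    replan <- trigger_replan(est, constraint_gy)
  }
  structure(list(setup_errors = setup, contour_changes = contours,
                 dose_diffs = diffs, contour_regressions = regs,
                 displaced_fit = displaced_fit, estimates = estimates,
                 replan = replan),
            class = "course_analysis")
}

.fit_to_list <- function(f)
  f[c("slope", "intercept", "r_squared", "residual_mean", "residual_sd", "n")]

#' Write a course analysis to files
#'
#' Emits `table1.csv` (setup errors), `table2.csv` (SSA by time point) with
#' `table2_change.csv` (average contour change), `dose_diffs.csv`,
#' `regressions.json` and, when estimates exist, `estimates.csv`. CSVs use a
#' fixed column order and '.' decimals; reruns on the same analysis are
#' byte-identical.
#'
#' @param analysis a [run_course_analysis()] result.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  wcsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wcsv(analysis$setup_errors, "table1.csv")
  wcsv(analysis$contour_changes$by_timepoint, "table2.csv")
  wcsv(analysis$contour_changes$average_change, "table2_change.csv")
  wcsv(analysis$dose_diffs$summary, "dose_diffs.csv")
  if (!is.null(analysis$estimates)) wcsv(analysis$estimates, "estimates.csv")
  fits <- list(contour = lapply(analysis$contour_regressions, .fit_to_list))
  if (!is.null(analysis$displaced_fit))
    fits$displaced_vs_setup <- .fit_to_list(analysis$displaced_fit)
  p <- file.path(dir, "regressions.json")
  jsonlite::write_json(fits, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' @export
print.course_analysis <- function(x, ...) {
  cat("<course_analysis>\n")
  grand <- x$setup_errors[is.na(x$setup_errors$fraction), , drop = FALSE]
  cat("  3D setup error grand means (mm): ",
      paste(sprintf("%s %.1f", grand$region, grand$mean_mm), collapse = ", "),
      "\n", sep = "")
  ac <- x$contour_changes$average_change
  cat("  average contour change (%): ",
      paste(sprintf("%s %.1f", ac$region, ac$change_pct), collapse = ", "),
      "\n", sep = "")
  for (reg in names(x$contour_regressions)) {
    f <- x$contour_regressions[[reg]]
    cat(sprintf("  contour-dose fit %s: slope %.3f, R^2 %.3f\n",
                reg, f$slope, f$r_squared))
  }
  if (!is.null(x$displaced_fit))
    cat(sprintf(
      "  displaced vs setup: slope %.3f, R^2 %.3f, residuals %.2f +/- %.2f Gy\n",
      x$displaced_fit$slope, x$displaced_fit$r_squared,
      x$displaced_fit$residual_mean, x$displaced_fit$residual_sd))
  if (!is.null(x$replan)) {
    if (x$replan$any_flag)
      cat(sprintf("  REPLANNING TRIGGER: %s exceeds %.0f Gy (worst %.1f Gy)\n",
                  x$replan$worst_region, x$replan$constraint_gy,
                  x$replan$worst_dmax))
    else cat("  no replanning trigger\n")
  }
  invisible(x)
}
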