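# Course-level longitudinal analysis: setup-error and contour-change
# summaries, head-vs-region paired statistics, percent dose differences and
# the contour-change dose regression.

.check_records <- function(records,
                           need = c("patient", "fraction", "region")) {
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing columns: ", paste(miss, collapse = ", "))
  records
}

#' Summarize 3D setup errors per imaging time point and region
#'
#' Mean and SD of the 3D error magnitude `sqrt(dx^2+dy^2+dz^2)` for every
#' time point and region, plus an all-time-point grand mean per region. With
#' equal cell sizes the grand mean equals the mean of the per-time-point
#' means.
#'
#' @param records long data.frame with `patient`, `fraction`, `region`, `dx`,
#'   `dy`, `dz`. Every region must be present at every patient-fraction.
#' @return data.frame with `region`, `fraction` (`NA` for the grand-mean
#'   rows), `mean_mm`, `sd_mm`, `n`.
#' @export
summarize_setup_errors <- function(records) {
  .check_records(records, c("patient", "fraction", "region", "dx", "dy", "dz"))
  regions <- unique(records$region)
  cells <- table(records$region, records$patient, records$fraction)
  if (any(cells == 0))
    stop("missing data: some region is absent from a patient-fraction record")
  e3d <- sqrt(records$dx^2 + records$dy^2 + records$dz^2)
  agg <- function(sel) c(mean = mean(e3d[sel]),
                         sd = if (sum(sel) > 1) stats::sd(e3d[sel]) else 0,
                         n = sum(sel))
  out <- list()
  for (reg in regions) {
    for (fr in sort(unique(records$fraction))) {
      a <- agg(records$region == reg & records$fraction == fr)
      out[[length(out) + 1L]] <- data.frame(
        region = reg, fraction = fr, mean_mm = a["mean"], sd_mm = a["sd"],
        n = a["n"], stringsAsFactors = FALSE)
    }
    a <- agg(records$region == reg)
    out[[length(out) + 1L]] <- data.frame(
      region = reg, fraction = NA_real_, mean_mm = a["mean"], sd_mm = a["sd"],
      n = a["n"], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  row.names(out) <- NULL
  out
}

#' Summarize contour change per region over the course
#'
#' Per time point: cohort mean and SD of regional SSA. Per region: the average
#' contour change in percent. Two averaging conventions are supported:
#' `"cohort_mean"` (default) takes the mean over time points of the
#' fraction-wise change of the cohort-mean SSA against the cohort-mean
#' planning SSA; `"per_patient"` computes each record's change against its own
#' patient's planning SSA and averages all of them. The two coincide when
#' every patient shares the planning SSA.
#'
#' @param records long data.frame with `patient`, `fraction`, `region`,
#'   `ssa_cm2` (`HEAD` rows, which carry no SSA, are ignored).
#' @param planning_ssa named per-region planning SSA (cm^2), or a data.frame
#'   with `patient`, `region`, `ssa_cm2` for per-patient baselines.
#' @param method `"cohort_mean"` or `"per_patient"`.
#' @return list with `by_timepoint` (region, fraction, mean_cm2, sd_cm2) and
#'   `average_change` (region, change_pct, sd_pct).
#' @export
summarize_contour_changes <- function(records, planning_ssa,
                                      method = c("cohort_mean", "per_patient")) {
  method <- match.arg(method)
  .check_records(records, c("patient", "fraction", "region", "ssa_cm2"))
  records <- records[!is.na(records$ssa_cm2), , drop = FALSE]
  if (!nrow(records)) stop("no SSA observations in records")
  per_patient_base <- is.data.frame(planning_ssa)
  base_of <- function(reg, pat = NULL) {
    b <- if (per_patient_base) {
      sel <- planning_ssa$region == reg &
        (if (is.null(pat)) TRUE else planning_ssa$patient %in% pat)
      mean(planning_ssa$ssa_cm2[sel])
    } else unname(planning_ssa[reg])
    if (!is.finite(b) || b <= 0) stop("planning SSA must be positive")
    b
  }
  regions <- unique(records$region)
  frs <- sort(unique(records$fraction))
  bt <- do.call(rbind, lapply(regions, function(reg)
    do.call(rbind, lapply(frs, function(fr) {
      v <- records$ssa_cm2[records$region == reg & records$fraction == fr]
      data.frame(region = reg, fraction = fr, mean_cm2 = mean(v),
                 sd_cm2 = if (length(v) > 1) stats::sd(v) else 0,
                 stringsAsFactors = FALSE)
    }))))
  ac <- do.call(rbind, lapply(regions, function(reg) {
    if (method == "cohort_mean") {
      m <- bt$mean_cm2[bt$region == reg]
      ch <- 100 * contour_change(base_of(reg), m)
    } else {
      sel <- records$region == reg
      ch <- 100 * mapply(function(pat, v)
        contour_change(base_of(reg, pat), v),
        records$patient[sel], records$ssa_cm2[sel])
    }
    data.frame(region = reg, change_pct = mean(ch),
               sd_pct = if (length(ch) > 1) stats::sd(ch) else 0,
               stringsAsFactors = FALSE)
  }))
  list(by_timepoint = bt, average_change = ac)
}

#' Paired head-versus-region comparison of setup errors
#'
#' Two-sided Wilcoxon signed-rank test of the per-direction setup errors of
#' each cord region against the head reference, paired on patient-fraction.
#' Zero differences are dropped (the classical rule); the exact null is used
#' for small samples without ties and the tie-corrected normal approximation
#' otherwise. All differences zero raises a degeneracy error.
#'
#' @param records long data.frame with `patient`, `fraction`, `region` and
#'   shift columns; must contain a `HEAD` region.
#' @param direction axis to compare: `"x"` (left-right), `"y"`
#'   (inferior-superior) or `"z"` (anterior-posterior).
#' @return data.frame with `region`, `p_value`, `median_diff_mm`,
#'   `direction_of_difference`, `n_pairs`.
#' @export
compare_head_vs_region <- function(records, direction = c("z", "x", "y")) {
  direction <- match.arg(direction)
  col <- paste0("d", direction)
  .check_records(records, c("patient", "fraction", "region", col))
  if (!any(records$region == "HEAD"))
    stop("records contain no HEAD reference region")
  key <- paste(records$patient, records$fraction)
  head <- records[records$region == "HEAD", , drop = FALSE]
  head_val <- stats::setNames(head[[col]], paste(head$patient, head$fraction))
  regions <- setdiff(unique(records$region), "HEAD")
  out <- lapply(regions, function(reg) {
    sel <- records$region == reg
    x <- records[[col]][sel]
    h <- head_val[key[sel]]
    if (anyNA(h)) stop("unpaired observations: head record missing")
    d <- x - h
    if (all(d == 0))
      stop(sprintf("degenerate comparison for %s: all paired differences are zero",
                   reg))
    p <- suppressWarnings(
      stats::wilcox.test(x, h, paired = TRUE, exact = NULL)$p.value)
    md <- stats::median(d)
    data.frame(region = reg, p_value = p, median_diff_mm = md,
               direction_of_difference =
                 if (md < 0) "negative" else if (md > 0) "positive" else "none",
               n_pairs = length(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-region percent dose differences against the planned metric
#'
#' Course-scale percent differences of the delivered, setup-only and
#' contour-only D0.1cc variants against each region's own planned D0.1cc,
#' summarised as mean and range per region and variant.
#'
#' @param records a [sample_course()] records data.frame (or any long table
#'   with `region`, `dmax_planned` and `dmax_*` variant columns).
#' @return list with `per_record` (long: region, variant, patient, fraction,
#'   percent) and `summary` (region, variant, mean_pct, min_pct, max_pct).
#' @export
dose_difference_summary <- function(records) {
  .check_records(records, c("region", "dmax_planned"))
  variants <- intersect(c("dmax_delivered", "dmax_setup", "dmax_contour"),
                        names(records))
  keep <- !is.na(records$dmax_planned)
  rec <- records[keep, , drop = FALSE]
  long <- do.call(rbind, lapply(variants, function(v) {
    ok <- !is.na(rec[[v]])
    if (!any(ok)) return(NULL)
    data.frame(region = rec$region[ok],
               variant = sub("^dmax_", "", v),
               patient = rec$patient[ok], fraction = rec$fraction[ok],
               percent = percent_diff(rec[[v]][ok], rec$dmax_planned[ok]),
               stringsAsFactors = FALSE)
  }))
  summ <- do.call(rbind, lapply(split(
    long, list(long$region, long$variant), drop = TRUE), function(d)
      data.frame(region = d$region[1], variant = d$variant[1],
                 mean_pct = mean(d$percent), min_pct = min(d$percent),
                 max_pct = max(d$percent), stringsAsFactors = FALSE)))
  summ <- summ[order(summ$region, summ$variant, method = "radix"), ,
               drop = FALSE]
  row.names(summ) <- NULL
  list(per_record = long, summary = summ)
}

#' Fit the contour-change dose regression
#'
#' Ordinary least squares of the per-time-point cohort-mean percent change in
#' the contour-only D0.1cc on the per-time-point cohort-mean contour change,
#' per region.
#'
#' @param per_fraction_mean_change numeric: cohort-mean contour change (%) per
#'   time point.
#' @param per_fraction_mean_dmax_change numeric: cohort-mean percent Dmax
#'   change per time point.
#' @return a `regression_fit` (see [ols_fit()]).
#' @export
fit_contour_dose_regression <- function(per_fraction_mean_change,
                                        per_fraction_mean_dmax_change) {
  if (length(per_fraction_mean_change) < 3L)
    stop("at least 3 time points are required")
  ols_fit(per_fraction_mean_change, per_fraction_mean_dmax_change)
}

#' Predict the dose effect of a contour change from a fitted regression
#' @param fit a `regression_fit` from [fit_contour_dose_regression()].
#' @param change_pct contour change in percent.
#' @return predicted percent Dmax change.
#' @export
estimate_contour_effect <- function(fit, change_pct)
  fit$intercept + fit$slope * change_pct

#' Per-region contour-change regressions of a sampled course
#'
#' Builds the per-time-point cohort means of contour change and contour-only
#' percent Dmax change from course records and fits
#' [fit_contour_dose_regression()] per region.
#'
#' @param course a [sample_course()] result.
#' @return named list region -> `regression_fit`.
#' @export
course_contour_regressions <- function(course) {
  rec <- course$records
  rec <- rec[!is.na(rec$dmax_contour), , drop = FALSE]
  out <- list()
  for (reg in unique(rec$region)) {
    d <- rec[rec$region == reg, , drop = FALSE]
    frs <- sort(unique(d$fraction))
    x <- vapply(frs, function(fr)
      mean(100 * d$shrink[d$fraction == fr]), numeric(1))
    y <- vapply(frs, function(fr)
      mean(percent_diff(d$dmax_contour[d$fraction == fr],
                        d$dmax_planned[d$fraction == fr])), numeric(1))
    out[[reg]] <- fit_contour_dose_regression(x, y)
  }
  out
}
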