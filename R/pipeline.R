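#' Run the full cohort analysis
#'
#' Reproduces the statistics stage end to end on a cohort table:
#' Kruskal-Wallis comparisons of both hotspot markers across the six
#' histological groups with Dunn/Bonferroni pairwise post-hocs, a
#' Kruskal-Wallis test on the tumor-cell coverage category, Pearson
#' chi-square association tests of IDO status and intensity group with the
#' clinicopathological variables (on the malignant subset, complete cases
#' per test), Mann-Whitney comparisons of both immune infiltrates between
#' IDO-positive and IDO-negative tumors, Kaplan-Meier/log-rank
#' recurrence-free survival by IDO status (all malignant groups and primary
#' melanomas only), Cox regression of RFS on IDO status with histological
#' group or Breslow depth as covariate, and the Pearson correlation between
#' the two markers. Tests whose inputs are degenerate (zero margin, no
#' events, ...) are recorded with the error message instead of aborting the
#' report.
#'
#' @param cohort A `cohort_table` data frame (see [generate_cohort()] /
#'   [read_cohort_csv()]).
#' @param cox_covariate `"group"` (default) or `"breslow"`: adjustment
#'   covariate in the Cox model.
#' @param alpha Significance threshold recorded in the report (inclusive:
#'   p <= alpha is called significant).
#' @return An object of class `analysis_report`: named list of
#'   [test_result()] objects (or error records), plus `meta`.
#' @export
run_full_analysis <- function(cohort, cox_covariate = c("group", "breslow"),
                              alpha = 0.050) {
  cox_covariate <- match.arg(cox_covariate)
  required <- c(
    "group", "treg_count", "ido_stromal_count", "coverage_category",
    "intensity_category", "nodular_growth", "mitoses_present",
    "capsule_rupture", "event_recurrence", "recurrence_locoregional",
    "recurrence_distal", "rfs_years", "breslow_mm"
  )
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  cohort$group <- factor(cohort$group, levels = HISTOLOGICAL_GROUPS)
  ido_status <- dichotomize_ido_status(cohort$coverage_category)
  intensity_group <- group_intensity(cohort$intensity_category)
  mal <- cohort$group %in% MALIGNANT_GROUPS

  try_test <- function(expr) {
    tryCatch(expr, error = function(e) {
      structure(list(error = conditionMessage(e)), class = "test_error")
    })
  }
  split_by_group <- function(v) {
    split(v[!is.na(v)], droplevels(cohort$group[!is.na(v)]))
  }
  chi2_of <- function(rows, a, b) {
    ok <- rows & !is.na(a) & !is.na(b)
    tab <- table(factor(a[ok]), factor(b[ok]))
    pearson_chi2(tab)
  }

  report <- list()
  report$kw_treg_by_group <- try_test(kruskal_wallis(split_by_group(cohort$treg_count)))
  report$kw_ido_stromal_by_group <-
    try_test(kruskal_wallis(split_by_group(cohort$ido_stromal_count)))
  report$kw_coverage_by_group <-
    try_test(kruskal_wallis(split_by_group(cohort$coverage_category)))
  report$posthoc_treg <- try_test(pairwise_posthoc(split_by_group(cohort$treg_count)))
  report$posthoc_ido_stromal <-
    try_test(pairwise_posthoc(split_by_group(cohort$ido_stromal_count)))

  # association tests on the malignant subset, complete cases per test
  report$chi2_ido_nodular_growth <- try_test(chi2_of(mal, cohort$nodular_growth, ido_status))
  report$chi2_ido_mitoses <- try_test(chi2_of(mal, cohort$mitoses_present, ido_status))
  report$chi2_ido_recurrence <- try_test(chi2_of(mal, cohort$event_recurrence, ido_status))
  report$chi2_ido_locoregional <-
    try_test(chi2_of(mal, cohort$recurrence_locoregional, ido_status))
  report$chi2_ido_distal <- try_test(chi2_of(mal, cohort$recurrence_distal, ido_status))
  report$chi2_intensity_capsule_rupture <-
    try_test(chi2_of(mal, cohort$capsule_rupture, intensity_group))

  treg_med <- try_test(dichotomize_by_median(cohort$treg_count))
  ido_med <- try_test(dichotomize_by_median(cohort$ido_stromal_count))
  if (!inherits(treg_med, "test_error")) {
    report$chi2_treg_level_recurrence <-
      try_test(chi2_of(mal, cohort$event_recurrence, treg_med$labels))
  }
  if (!inherits(ido_med, "test_error")) {
    report$chi2_ido_stromal_level_mitoses <-
      try_test(chi2_of(mal, cohort$mitoses_present, ido_med$labels))
  }

  report$mwu_treg_by_ido_status <- try_test(mann_whitney_u(
    cohort$treg_count[mal & ido_status == "positive"],
    cohort$treg_count[mal & ido_status == "negative"]
  ))
  report$mwu_ido_stromal_by_ido_status <- try_test(mann_whitney_u(
    cohort$ido_stromal_count[mal & ido_status == "positive"],
    cohort$ido_stromal_count[mal & ido_status == "negative"]
  ))

  report$logrank_rfs_by_ido_status <- try_test(
    km_logrank(cohort$rfs_years[mal], cohort$event_recurrence[mal],
               ido_status[mal])$test
  )
  prim <- cohort$group %in% c("pT1", "pT4")
  report$logrank_rfs_primary_only <- try_test(
    km_logrank(cohort$rfs_years[prim], cohort$event_recurrence[prim],
               ido_status[prim])$test
  )

  cov_df <- if (cox_covariate == "group") {
    data.frame(
      ido_positive = as.integer(ido_status[mal] == "positive"),
      group = droplevels(cohort$group[mal])
    )
  } else {
    data.frame(
      ido_positive = as.integer(ido_status[mal] == "positive"),
      breslow_mm = cohort$breslow_mm[mal]
    )
  }
  cox_fit <- try_test(cox_regression(cohort$rfs_years[mal],
                                     cohort$event_recurrence[mal], cov_df))
  report$cox_rfs_ido <- if (inherits(cox_fit, "test_error")) cox_fit else
    cox_fit$tests[[1L]]

  report$pearson_treg_vs_ido_stromal <-
    try_test(pearson_correlation(cohort$treg_count, cohort$ido_stromal_count))

  report$meta <- list(
    n_samples = nrow(cohort),
    n_malignant = sum(mal),
    alpha = alpha,
    cox_covariate = cox_covariate,
    treg_median = if (!inherits(treg_med, "test_error")) treg_med$threshold else NA_real_,
    ido_stromal_median = if (!inherits(ido_med, "test_error")) ido_med$threshold else NA_real_
  )
  class(report) <- "analysis_report"
  report
}

#' Extract the p-values of an analysis report
#'
#' @param report An `analysis_report` from [run_full_analysis()].
#' @return Data frame with `test`, `statistic`, `p_value`, `n`,
#'   `significant` (at the report's alpha, inclusive). Post-hoc lists expand
#'   to one row per pair; failed tests appear with `NA`.
#' @export
report_pvalues <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  alpha <- report$meta$alpha
  rows <- list()
  add <- function(name, tr) {
    if (inherits(tr, "test_error")) {
      rows[[length(rows) + 1L]] <<- data.frame(
        test = name, statistic = NA_real_, p_value = NA_real_, n = NA_integer_,
        significant = NA
      )
    } else if (inherits(tr, "test_result")) {
      rows[[length(rows) + 1L]] <<- data.frame(
        test = name, statistic = tr$statistic, p_value = tr$p_value,
        n = sum(tr$n), significant = !is.na(tr$p_value) && tr$p_value <= alpha
      )
    }
  }
  for (nm in setdiff(names(report), "meta")) {
    item <- report[[nm]]
    if (is.list(item) && !inherits(item, c("test_result", "test_error"))) {
      for (tr in item) add(paste0(nm, ":", tr$method), tr)
    } else {
      add(nm, item)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.analysis_report <- function(x, ...) {
  pv <- report_pvalues(x)
  cat(sprintf(
    "<analysis_report> %d samples (%d malignant), alpha = %.3f\n",
    x$meta$n_samples, x$meta$n_malignant, x$meta$alpha
  ))
  print(pv, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an analysis report to JSON
#'
#' @param report An `analysis_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  pv <- report_pvalues(report)
  jsonlite::write_json(
    list(meta = report$meta, tests = pv),
    path, digits = NA, auto_unbox = TRUE, na = "null"
  )
  invisible(path)
}
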