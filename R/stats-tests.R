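#' Construct a test result
#'
#' Uniform container for every statistics-stage output: method label,
#' statistic, degrees of freedom (or NA), p-value, number of observations
#' used, and an optional multiplicity-adjustment label.
#'
#' @param method Method label.
#' @param statistic Test statistic.
#' @param df Degrees of freedom or `NA`.
#' @param p_value P-value in `[0, 1]`.
#' @param n Observations used.
#' @param adjustment Adjustment label or `NA`.
#' @param extra Optional named list of method-specific extras.
#' @return An object of class `test_result`.
#' @export
test_result <- function(method, statistic, df = NA_integer_, p_value, n,
                        adjustment = NA_character_, extra = NULL) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    stop("p_value must lie in [0, 1]")
  }
  structure(
    list(
      method = method, statistic = unname(statistic), df = unname(df),
      p_value = unname(p_value), n = n, adjustment = adjustment, extra = extra
    ),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf(
    "<test_result> %s: statistic = %.4g%s, p = %.4g (n = %s)%s\n",
    x$method, x$statistic,
    if (!is.na(x$df)) sprintf(", df = %s", format(x$df)) else "",
    x$p_value, paste(x$n, collapse = "/"),
    if (!is.na(x$adjustment)) paste0(" [", x$adjustment, "]") else ""
  ))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square test of
#' association, the form whose p-values match semi-quantitative IHC
#' association tables computed in standard statistical software.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return A [test_result()] (`df = 1`).
#' @examples
#' pearson_chi2(matrix(c(0, 6, 4, 2), 2)) # statistic 6, p ~= 0.0143
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(table < 0) || any(is.na(table))) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi-square test undefined: a table margin is zero")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  test_result(
    "pearson_chi2",
    statistic = res$statistic, df = as.integer(res$parameter),
    p_value = res$p.value, n = sum(table)
  )
}

#' Kruskal-Wallis rank test across histological groups
#'
#' @param groups List (>= 2) of non-empty numeric vectors, one per group.
#' @return A [test_result()] (tie-corrected H statistic, chi-square
#'   approximation with `length(groups) - 1` df).
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("kruskal_wallis() needs a list of >= 2 groups")
  }
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) == 0L)) stop("each group must be non-empty")
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1L) {
    # all observations tied: no rank variation, H = 0
    return(test_result("kruskal_wallis", 0, df = length(groups) - 1L,
                       p_value = 1, n = length(values)))
  }
  res <- stats::kruskal.test(values, g)
  test_result(
    "kruskal_wallis",
    statistic = res$statistic, df = as.integer(res$parameter),
    p_value = res$p.value, n = length(values)
  )
}

#' Dunn's pairwise post-hoc comparisons after Kruskal-Wallis
#'
#' Pairwise z-tests on pooled-rank means with the tie-corrected pooled
#' variance, Bonferroni-adjusted over the `k(k-1)/2` pairs.
#'
#' @param groups Named or unnamed list of numeric vectors.
#' @return List of [test_result()], one per group pair; `extra$pair` holds
#'   the group indices, `extra$p_raw` the unadjusted p-value.
#' @export
pairwise_posthoc <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("pairwise_posthoc() needs a list of >= 2 groups")
  }
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) == 0L)) stop("each group must be non-empty")
  k <- length(groups)
  nms <- names(groups)
  if (is.null(nms)) nms <- as.character(seq_len(k))
  values <- unlist(groups)
  gi <- rep(seq_len(k), lengths(groups))
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, gi, mean)
  ni <- lengths(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  s2 <- n * (n + 1) / 12 - tie_term
  m <- k * (k - 1) / 2
  out <- list()
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      se <- sqrt(s2 * (1 / ni[i] + 1 / ni[j]))
      z <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
      p_raw <- 2 * stats::pnorm(-abs(z))
      out[[length(out) + 1L]] <- test_result(
        sprintf("dunn_z[%s vs %s]", nms[i], nms[j]),
        statistic = z, df = NA_integer_,
        p_value = min(1, m * p_raw),
        n = ni[i] + ni[j], adjustment = "bonferroni",
        extra = list(pair = c(i, j), p_raw = p_raw)
      )
    }
  }
  out
}

#' Mann-Whitney U test
#'
#' Exact two-sided p-value when both groups have at most `exact_max`
#' observations and no ties; tie-corrected normal approximation otherwise
#' (no continuity correction). The statistic U counts pairs where an `x`
#' observation exceeds a `y` observation (ties count one half).
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_max Largest per-group size for the exact null distribution.
#' @return A [test_result()].
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty")
  }
  has_ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !has_ties && length(x) <= exact_max && length(y) <= exact_max
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                             correct = FALSE))
  test_result(
    "mann_whitney_u",
    statistic = res$statistic, p_value = res$p.value,
    n = c(length(x), length(y))
  )
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Equal-length numeric vectors (>= 3 complete pairs, neither
#'   constant).
#' @return A [test_result()]; the statistic is `r`, `extra$t` the t value.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  res <- stats::cor.test(x, y, method = "pearson")
  test_result(
    "pearson_correlation",
    statistic = unname(res$estimate), df = as.integer(res$parameter),
    p_value = res$p.value, n = length(x),
    extra = list(t = unname(res$statistic), conf_int = as.numeric(res$conf.int))
  )
}

#' Concordance between automated and manual counts, with manual override
#'
#' Computes the Pearson correlation between the automated and the manual
#' per-image counts and returns the final count vector in which QC-flagged
#' images (cells significantly over- or under-selected by the software) take
#' the manual value.
#'
#' @param auto_counts,manual_counts Aligned per-image count vectors.
#' @param qc_flags Logical vector: `TRUE` where the automated count is
#'   overridden by the manual one. Default: no overrides.
#' @return List with `concordance` (a [test_result()], statistic = r),
#'   `final_counts`, and `n_overridden`.
#' @export
interrater_concordance <- function(auto_counts, manual_counts,
                                   qc_flags = rep(FALSE, length(auto_counts))) {
  if (length(auto_counts) != length(manual_counts) ||
      length(qc_flags) != length(auto_counts)) {
    stop("auto_counts, manual_counts and qc_flags must have equal length")
  }
  r <- if (stats::sd(auto_counts) == 0 || stats::sd(manual_counts) == 0) {
    test_result("interrater_pearson_r", NA_real_, p_value = NA_real_,
                n = length(auto_counts))
  } else {
    res <- pearson_correlation(auto_counts, manual_counts)
    res$method <- "interrater_pearson_r"
    res
  }
  list(
    concordance = r,
    final_counts = ifelse(qc_flags, manual_counts, auto_counts),
    n_overridden = sum(qc_flags)
  )
}
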