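test_that("2x2 chi-square matches the closed-form margin formula", {
  r <- pearson_chi2(matrix(c(0, 6, 4, 2), 2))
  expect_equal(r$statistic, 6, tolerance = 1e-12)
  expect_equal(r$p_value, 0.0143, tolerance = 1e-3)
  expect_equal(r$df, 1L)
  # independence: proportional rows give statistic 0, p 1
  r0 <- pearson_chi2(matrix(c(2, 3, 4, 6), 2))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)
  expect_error(pearson_chi2(matrix(c(0, 0, 4, 2), 2)), "margin")
  set.seed(601)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    expect_equal(pearson_chi2(tab)$statistic, chi2_2x2_oracle(tab),
                 tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis reproduces hand rank computations and the tie-corrected oracle", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$statistic, 27 / 7, tolerance = 1e-10) # R1=6, R2=15 -> H=3.857
  # constant data: every observation tied, H = 0, p = 1
  rc <- kruskal_wallis(list(rep(5, 4), rep(5, 3)))
  expect_equal(rc$statistic, 0)
  expect_equal(rc$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), ">= 2")
  set.seed(602)
  for (i in 1:150) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j) sample(1:6, sample(3:6, 1), replace = TRUE))
    if (length(unique(unlist(groups))) == 1L) next
    expect_equal(kruskal_wallis(groups)$statistic, kw_oracle(groups),
                 tolerance = 1e-10)
  }
})

test_that("Dunn post-hoc z-tests carry the Bonferroni adjustment identity", {
  set.seed(603)
  groups <- list(a = rnorm(12), b = rnorm(12, 2), c = rnorm(12))
  ph <- pairwise_posthoc(groups)
  m <- 3 # k(k-1)/2
  expect_length(ph, m)
  for (tr in ph) {
    expect_equal(tr$p_value, min(1, m * tr$extra$p_raw), tolerance = 1e-12)
    expect_equal(tr$adjustment, "bonferroni")
  }
  # two identical groups: rank means equal, adjusted p = 1 for that pair
  g <- list(a = c(1, 5, 9), b = c(1, 5, 9), c = c(20, 25, 30))
  ph2 <- pairwise_posthoc(g)
  expect_equal(ph2[[1]]$p_value, 1)
})

test_that("a shifted group dominates the significant post-hoc pairs", {
  set.seed(604)
  hits_shift <- 0L; hits_null <- 0L; reps <- 60L
  for (i in seq_len(reps)) {
    groups <- list(a = rnorm(25), b = rnorm(25), c = rnorm(25, 2.2))
    ph <- pairwise_posthoc(groups)
    sig <- vapply(ph, function(t) t$p_value <= 0.05, logical(1))
    involves_c <- vapply(ph, function(t) 3L %in% t$extra$pair, logical(1))
    if (all(sig[involves_c])) hits_shift <- hits_shift + 1L
    if (any(sig[!involves_c])) hits_null <- hits_null + 1L
  }
  expect_gte(hits_shift, round(0.9 * reps))
  expect_lte(hits_null, round(0.25 * reps))
})

test_that("Mann-Whitney U agrees with enumeration and pair counting", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12) # 2 of 6 arrangements as extreme
  # identical samples: maximally central U, p = 1
  ri <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ri$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
  set.seed(605)
  for (i in 1:150) {
    x <- sample(1:20, sample(2:8, 1), replace = TRUE)
    y <- sample(1:20, sample(2:8, 1), replace = TRUE)
    expect_equal(unname(mann_whitney_u(x, y)$statistic), u_oracle(x, y),
                 tolerance = 1e-10)
  }
})

test_that("Pearson correlation matches the covariance-formula oracle", {
  x <- c(1, 2, 3, 5)
  expect_equal(pearson_correlation(x, x)$statistic, 1)
  expect_equal(pearson_correlation(x, -x)$statistic, -1)
  expect_error(pearson_correlation(x, rep(2, 4)), "constant")
  expect_error(pearson_correlation(1:4, 1:5), "equal length")
  set.seed(606)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(pearson_correlation(x, y)$statistic, pearson_oracle(x, y),
                 tolerance = 1e-10)
  }
})

test_that("log-rank test matches the risk-table oracle and degenerates sanely", {
  time <- c(1, 3, 4, 6, 8, 9, 11, 13)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  group <- rep(c("a", "b"), 4)
  km <- km_logrank(time, event, group)
  expect_equal(km$test$statistic, logrank_oracle(time, event, group),
               tolerance = 1e-8)
  # identical data in both groups: statistic 0, p 1
  km0 <- km_logrank(rep(time, 2), rep(event, 2), rep(c("a", "b"), each = 8))
  expect_equal(km0$test$statistic, 0, tolerance = 1e-12)
  expect_equal(km0$test$p_value, 1)
  expect_error(km_logrank(time, rep(0, 8), group), "no events")
  expect_error(km_logrank(time, event, rep("a", 8)), "two")
})

test_that("Kaplan-Meier estimates are proper survival curves", {
  set.seed(607)
  time <- rexp(40); event <- rbinom(40, 1, 0.7)
  group <- rep(c("a", "b"), 20)
  fit <- km_logrank(time, event, group)$fit
  idx <- rep(seq_along(fit$strata), fit$strata)
  for (s in seq_along(fit$strata)) {
    surv <- fit$surv[idx == s]
    tms <- fit$time[idx == s]
    # non-increasing step function, bounded by 1, flat (== 1) before the
    # first event in the stratum
    expect_true(all(diff(surv) <= 1e-12))
    expect_lte(max(surv), 1)
    first_event <- suppressWarnings(min(tms[fit$n.event[idx == s] > 0]))
    if (is.finite(first_event)) {
      expect_true(all(surv[tms < first_event] == 1))
    }
  }
})

test_that("Cox estimates match a direct partial-likelihood maximization", {
  set.seed(608)
  for (i in 1:20) {
    n <- 8
    x <- rnorm(n)
    time <- rexp(n, exp(0.5 * x))
    # no ties (continuous times), all events
    fit <- cox_regression(time, rep(1, n), data.frame(x = x))
    beta_hat <- log(fit$hazard_ratios$hr)
    expect_equal(beta_hat, cox_beta_oracle(time, rep(1, n), x), tolerance = 1e-5)
  }
})

test_that("Cox regression recovers a null effect and flags separation", {
  set.seed(609)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.1) # independent of x
  event <- rbinom(n, 1, 0.7)
  fit <- cox_regression(time, event, data.frame(x = x))
  expect_gt(fit$hazard_ratios$upper, 1)
  expect_lt(fit$hazard_ratios$lower, 1)
  # complete separation: all short survivors share the covariate level
  xs <- rep(c(1, 0), each = 10)
  ts <- c(seq(0.1, 1, length.out = 10), seq(5, 14, length.out = 10))
  expect_error(cox_regression(ts, rep(1, 20), data.frame(x = xs)),
               "separation|diverged|converge")
  expect_error(cox_regression(c(1, 2), c(0, 0), data.frame(x = c(0, 1))),
               "at least one event")
})

test_that("rater concordance and manual override behave as specified", {
  auto <- c(10, 20, 30, 40)
  ic <- interrater_concordance(auto, auto)
  expect_equal(ic$concordance$statistic, 1)
  expect_equal(ic$n_overridden, 0L)
  expect_equal(ic$final_counts, auto)
  manual <- c(10, 25, 30, 40)
  ic2 <- interrater_concordance(auto, manual, qc_flags = c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(ic2$final_counts, c(10, 25, 30, 40))
  expect_equal(ic2$n_overridden, 1L)
  expect_error(interrater_concordance(1:3, 1:4), "equal length")
})

test_that("rater concordance decreases with rater noise", {
  set.seed(610)
  mean_r <- vapply(c(1, 5, 15), function(noise_sd) {
    rs <- vapply(1:40, function(i) {
      truth <- rpois(30, 50)
      manual <- truth + round(rnorm(30, 0, noise_sd))
      interrater_concordance(truth, manual)$concordance$statistic
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_r) < 0))
})

test_that("the full analysis report is deterministic and self-consistent", {
  co <- generate_cohort(cohort_sim_params(seed = 42L))
  r1 <- run_full_analysis(co)
  r2 <- run_full_analysis(co)
  expect_identical(report_pvalues(r1), report_pvalues(r2))
  pv <- report_pvalues(r1)
  expect_true(all(pv$p_value >= 0 & pv$p_value <= 1, na.rm = TRUE))
  expect_true(all(pv$n <= nrow(co), na.rm = TRUE))
  # per-test n reconciles with complete cases for the chi-square tests
  mal <- co$group %in% c("pT1", "pT4", "pN1")
  n_rec <- sum(mal & !is.na(co$event_recurrence) & !is.na(co$ido_status))
  expect_equal(pv$n[pv$test == "chi2_ido_recurrence"], n_rec)
})

test_that("missing required columns are reported by name", {
  co <- generate_cohort(cohort_sim_params(seed = 2L))
  co$treg_count <- NULL
  co$rfs_years <- NULL
  expect_error(run_full_analysis(co), "treg_count.*rfs_years|rfs_years.*treg_count")
})
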