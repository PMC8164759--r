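HISTOLOGICAL_GROUPS <- c("benign", "dysplastic", "in_situ", "pT1", "pT4", "pN1")
MALIGNANT_GROUPS <- c("pT1", "pT4", "pN1")

#' Parameters for synthetic cohort generation
#'
#' Defines a simulated lesion cohort with the structure the analysis stage
#' assumes: six histological groups (benign and dysplastic nevi, in situ
#' melanoma, thin pT1 and deep pT4 primaries, pN1 lymph-node metastases),
#' per-sample hotspot marker counts (negative binomial: overdispersed
#' non-negative counts), a semi-quantitative tumor-cell coverage category,
#' clinicopathological covariates, and recurrence/survival fields. Default
#' group sizes follow the evaluated-stainings breakdown of the motivating
#' cohort (25/27/15/36/39/41); marker means rise from benign to metastatic
#' disease and the default IDO-on-recurrence odds ratio of 4 matches the
#' direction and rough magnitude of the published association; these effect
#' values are the generator's own calibration, not published estimates.
#'
#' @param group_sizes Named integer vector over the six groups.
#' @param treg_count_means,ido_stromal_means Named per-group negative
#'   binomial means for the two hotspot markers.
#' @param count_dispersion Negative binomial size parameter (smaller = more
#'   overdispersed).
#' @param ido_coverage_probs 6 x 5 matrix (rows = groups) of probabilities
#'   over coverage categories 0-4; each row sums to 1.
#' @param effect_ido_on_recurrence Odds ratio of recurrence for IDO-positive
#'   vs IDO-negative malignant tumors (1 = no effect).
#' @param baseline_recurrence Recurrence probability for IDO-negative
#'   malignant tumors.
#' @param baseline_hazard Exponential hazard (per year) of melanoma death
#'   for non-recurrent malignant cases.
#' @param hazard_ratio_recurrence Multiplies the death hazard for recurrent
#'   cases.
#' @param censoring_rate Probability an observation is censored before the
#'   event.
#' @param missing_rate Per-covariate probability of a missing value.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(
    group_sizes = c(benign = 25L, dysplastic = 27L, in_situ = 15L,
                    pT1 = 36L, pT4 = 39L, pN1 = 41L),
    treg_count_means = c(benign = 5, dysplastic = 10, in_situ = 25,
                         pT1 = 45, pT4 = 60, pN1 = 65),
    ido_stromal_means = c(benign = 4, dysplastic = 8, in_situ = 20,
                          pT1 = 30, pT4 = 45, pN1 = 50),
    count_dispersion = 5,
    ido_coverage_probs = rbind(
      benign = c(0.95, 0.04, 0.01, 0.00, 0.00),
      dysplastic = c(0.90, 0.07, 0.02, 0.01, 0.00),
      in_situ = c(0.80, 0.10, 0.05, 0.03, 0.02),
      pT1 = c(0.70, 0.15, 0.07, 0.05, 0.03),
      pT4 = c(0.55, 0.20, 0.10, 0.08, 0.07),
      pN1 = c(0.45, 0.22, 0.13, 0.10, 0.10)
    ),
    effect_ido_on_recurrence = 4.0,
    baseline_recurrence = 0.3,
    baseline_hazard = 0.05,
    hazard_ratio_recurrence = 2.0,
    censoring_rate = 0.3,
    missing_rate = 0.02,
    seed = 1L) {
  if (length(group_sizes) == 0L) stop("group_sizes must not be empty")
  if (is.null(names(group_sizes)) ||
      !all(names(group_sizes) %in% HISTOLOGICAL_GROUPS)) {
    stop("group_sizes must be named with the six histological groups")
  }
  if (any(group_sizes < 0)) stop("group sizes must be non-negative")
  if (any(treg_count_means <= 0) || any(ido_stromal_means <= 0)) {
    stop("marker count means must be positive")
  }
  if (count_dispersion <= 0) stop("count_dispersion must be positive")
  if (any(abs(rowSums(ido_coverage_probs) - 1) > 1e-8)) {
    stop("each row of ido_coverage_probs must sum to 1")
  }
  if (effect_ido_on_recurrence < 0) stop("odds ratio must be >= 0")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (hazard_ratio_recurrence <= 0) stop("hazard_ratio_recurrence must be positive")
  if (censoring_rate < 0 || censoring_rate > 1) stop("censoring_rate in [0, 1]")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate in [0, 1]")
  structure(
    list(
      group_sizes = group_sizes,
      treg_count_means = treg_count_means,
      ido_stromal_means = ido_stromal_means,
      count_dispersion = count_dispersion,
      ido_coverage_probs = ido_coverage_probs,
      effect_ido_on_recurrence = effect_ido_on_recurrence,
      baseline_recurrence = baseline_recurrence,
      baseline_hazard = baseline_hazard,
      hazard_ratio_recurrence = hazard_ratio_recurrence,
      censoring_rate = censoring_rate,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_sim_params"
  )
}

# uniform draw inside the coverage-fraction bin of a category
.coverage_fraction_for <- function(category) {
  lo <- c(0, 0.01, 0.0501, 0.1001, 0.2001)[category + 1L]
  hi <- c(0.0099, 0.05, 0.10, 0.20, 0.60)[category + 1L]
  stats::runif(length(category), lo, hi)
}

#' Generate a synthetic lesion cohort
#'
#' Draws one sample table per `params`: hotspot marker counts from
#' group-specific negative binomials, tumor-cell coverage categories from
#' the per-group category distributions, clinicopathological covariates
#' (with Breslow depth consistent with stage: pT1 below 1 mm, pT4 above
#' 4 mm), recurrence via a logistic model with IDO-positivity odds ratio
#' `effect_ido_on_recurrence`, recurrence-free survival times, and overall
#' survival times that are exponential with the death hazard multiplied by
#' `hazard_ratio_recurrence` for recurrent cases. Covariates are masked at
#' `missing_rate` uniformly at random. The same seed reproduces the table
#' row for row.
#'
#' @param params A [cohort_sim_params()].
#' @return A data frame of class `cohort_table`; attributes `seed` and
#'   `params` record provenance.
#' @export
generate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  set.seed(params$seed)
  groups <- rep(names(params$group_sizes), params$group_sizes)
  n <- length(groups)
  if (n == 0L) stop("group_sizes sums to zero")
  group <- factor(groups, levels = HISTOLOGICAL_GROUPS)
  malignant <- group %in% MALIGNANT_GROUPS

  treg <- stats::rnbinom(n, size = params$count_dispersion,
                         mu = params$treg_count_means[groups])
  ido_stromal <- stats::rnbinom(n, size = params$count_dispersion,
                                mu = params$ido_stromal_means[groups])

  coverage_category <- unname(vapply(groups, function(g) {
    sample(0:4, 1L, prob = params$ido_coverage_probs[g, ])
  }, integer(1)))
  coverage_fraction <- .coverage_fraction_for(coverage_category)
  ido_status <- dichotomize_ido_status(coverage_category)
  intensity_category <- ifelse(
    coverage_category >= 1L,
    sample(1:3, n, replace = TRUE, prob = c(0.45, 0.35, 0.20)),
    NA_integer_
  )

  age <- round(pmin(pmax(stats::rnorm(n, 60, 16), 18), 95))
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.45, 0.55))
  breslow <- rep(NA_real_, n)
  breslow[group == "pT1"] <- round(stats::runif(sum(group == "pT1"), 0.29, 1.0), 2)
  breslow[group == "pT4"] <- round(pmin(4 + stats::rexp(sum(group == "pT4"), 1 / 4.5), 60), 2)
  breslow[group == "pN1"] <- round(pmin(exp(stats::rnorm(sum(group == "pN1"), 1.0, 1.0)), 60), 2)

  ulceration <- ifelse(malignant, stats::rbinom(n, 1, 0.40), NA_integer_)
  nodular_growth <- ifelse(malignant, stats::rbinom(n, 1, 0.45), NA_integer_)
  mitoses_present <- ifelse(malignant, stats::rbinom(n, 1, 0.65), NA_integer_)
  capsule_rupture <- ifelse(group == "pN1", stats::rbinom(n, 1, 0.45), NA_integer_)

  # recurrence: log-odds linear in IDO positivity (malignant cases only)
  lp <- stats::qlogis(params$baseline_recurrence) +
    log(params$effect_ido_on_recurrence) * (ido_status == "positive")
  recur <- ifelse(malignant, stats::rbinom(n, 1, stats::plogis(lp)), NA_integer_)
  locoregional <- ifelse(!is.na(recur) & recur == 1L, stats::rbinom(n, 1, 0.6), 0L)
  distal <- ifelse(!is.na(recur) & recur == 1L,
                   ifelse(locoregional == 1L, stats::rbinom(n, 1, 0.5), 1L), 0L)
  locoregional[!malignant] <- NA_integer_
  distal[!malignant] <- NA_integer_

  # recurrence-free survival: event time for recurrent cases, censoring else
  rfs_years <- rep(NA_real_, n)
  event_recurrence <- rep(NA_integer_, n)
  idx <- which(malignant)
  t_rec <- stats::rexp(n, rate = 0.25)
  t_cens <- stats::rexp(n, rate = 0.08)
  event_recurrence[idx] <- recur[idx]
  rfs_years[idx] <- ifelse(recur[idx] == 1L, t_rec[idx], t_cens[idx])

  # overall survival: exponential event times, hazard multiplied for
  # recurrent cases; independent exponential censoring tuned so that about
  # `censoring_rate` of baseline subjects are censored
  os_rate <- params$baseline_hazard *
    ifelse(!is.na(recur) & recur == 1L, params$hazard_ratio_recurrence, 1)
  t_death <- stats::rexp(n, rate = pmax(os_rate, 1e-12))
  cens_rate <- params$baseline_hazard * params$censoring_rate /
    max(1 - params$censoring_rate, 1e-9)
  t_cens_os <- if (params$censoring_rate > 0) {
    stats::rexp(n, rate = cens_rate)
  } else {
    rep(Inf, n)
  }
  follow_up_years <- pmin(t_death, t_cens_os)
  event_death_melanoma <- ifelse(malignant, as.integer(t_death <= t_cens_os),
                                 NA_integer_)
  follow_up_years[!malignant] <- NA_real_

  mask <- function(x) {
    x[stats::runif(n) < params$missing_rate] <- NA
    x
  }

  out <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    group = group,
    treg_count = treg,
    ido_stromal_count = ido_stromal,
    coverage_fraction = round(coverage_fraction, 4),
    coverage_category = coverage_category,
    intensity_category = intensity_category,
    ido_status = ido_status,
    sex = mask(sex),
    age = mask(age),
    breslow_mm = mask(breslow),
    ulceration = mask(ulceration),
    nodular_growth = mask(nodular_growth),
    mitoses_present = mask(mitoses_present),
    capsule_rupture = mask(capsule_rupture),
    event_recurrence = event_recurrence,
    recurrence_locoregional = locoregional,
    recurrence_distal = distal,
    rfs_years = round(rfs_years, 4),
    follow_up_years = round(follow_up_years, 4),
    event_death_melanoma = event_death_melanoma,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "seed") <- params$seed
  attr(out, "params") <- params
  class(out) <- c("cohort_table", class(out))
  out
}

#' Write a cohort table to CSV
#'
#' Deterministic plain CSV (no row names); a provenance comment records the
#' generator seed.
#'
#' @param cohort A `cohort_table` (or plain data frame).
#' @param path Output path.
#' @param provenance Write the `# seed:` header comment (default TRUE when
#'   the cohort carries one).
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, provenance = !is.null(attr(cohort, "seed"))) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (provenance) {
    writeLines(sprintf("# generator seed: %d", attr(cohort, "seed")), con)
  }
  utils::write.csv(as.data.frame(cohort), con, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path CSV path (comment lines starting with `#` are skipped).
#' @return A `cohort_table` data frame.
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if ("group" %in% names(out)) {
    out$group <- factor(out$group, levels = HISTOLOGICAL_GROUPS)
  }
  if ("ido_status" %in% names(out)) {
    out$ido_status <- factor(out$ido_status, levels = c("negative", "positive"))
  }
  class(out) <- c("cohort_table", class(out))
  out
}
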