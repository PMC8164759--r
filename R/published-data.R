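#' Published 2x2 association counts of IDO expression in melanoma
#'
#' Cross-tabulated counts from a published melanoma cohort relating the IDO
#' status of melanoma cells (negative vs positive, i.e. below vs above 1
#' percent positive tumor cells) — and, for lymph-node capsule rupture, the
#' dichotomized staining intensity (weak vs moderate-or-strong) — to
#' clinicopathological parameters, together with the p-value printed
#' alongside each table. They serve as a reference surface for the
#' uncorrected Pearson chi-square test: [pearson_chi2()] reproduces every
#' printed p-value at 3-decimal rounding.
#'
#' @return Named list, one element per clinicopathological variable, each a
#'   list with `table` (2x2 integer matrix, rows = variable strata, columns
#'   = marker levels), `comparison` (which dichotomized marker the columns
#'   hold), and `printed_p`.
#' @examples
#' tabs <- ido_association_tables()
#' pearson_chi2(tabs$capsule_rupture$table) # p rounds to 0.014
#' @export
ido_association_tables <- function() {
  path <- system.file("extdata", "ido_clinicopath_2x2.csv", package = "ihcquant",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (v in unique(raw$variable)) {
    sub <- raw[raw$variable == v, ]
    tab <- as.matrix(sub[, c("n_negative_or_weak", "n_positive_or_modstrong")])
    dimnames(tab) <- list(sub$stratum, c("negative_or_weak", "positive_or_modstrong"))
    out[[v]] <- list(
      table = tab,
      comparison = sub$comparison[1],
      printed_p = sub$printed_p[1]
    )
  }
  out
}
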