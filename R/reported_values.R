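#' Reported associations from a published epilepsy MR screen
#'
#' Odds ratios, 95% confidence intervals and p-values for immune-cell and
#' metabolite traits reported by a published two-sample MR screen against
#' epilepsy, bundled as a worked-example input for the printed-value
#' consistency checks ([recompute_wald_p()]). Rows whose printed CI bound is
#' rounded to exactly 1.000 carry too little precision for the log-scale
#' inversion and are flagged `ci_precision_ok = FALSE`.
#'
#' @return Tibble with columns `trait, trait_class, outcome, or, ci_low,
#'   ci_high, p, ci_precision_ok`.
#' @export
reported_associations <- function() {
  readr::read_tsv(system.file("extdata", "epilepsy_screen_reported.tsv",
                              package = "mrmediate"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Reported mediated proportions from a published epilepsy MR screen
#'
#' Mediated proportions (percent) with 95% CIs and p-values for
#' immune-cell/metabolite/epilepsy triples, bundled as a worked-example
#' input for [recompute_proportion_p()].
#'
#' @return Tibble with columns `immune_cell, metabolite, outcome,
#'   proportion_pct, ci_low_pct, ci_high_pct, p`.
#' @export
reported_mediation <- function() {
  readr::read_tsv(system.file("extdata", "epilepsy_mediation_reported.tsv",
                              package = "mrmediate"),
                  show_col_types = FALSE, progress = FALSE)
}
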