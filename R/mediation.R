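#' Product-of-coefficients indirect effect
#'
#' `indirect = beta1 * beta2` with the first-order (Sobel) SE
#' `sqrt(beta2^2 se1^2 + beta1^2 se2^2)`; `exact = TRUE` adds the
#' second-order term `se1^2 se2^2` to the variance. P-value is two-sided
#' normal.
#'
#' @param beta1,se1 Exposure-to-mediator estimate and SE.
#' @param beta2,se2 Mediator-to-outcome estimate and SE.
#' @param exact Include the exact-variance cross term.
#' @return List with `indirect`, `se`, `pvalue`.
#' @export
product_of_coefficients <- function(beta1, se1, beta2, se2, exact = FALSE) {
  stopifnot(se1 > 0, se2 > 0)
  v <- beta2^2 * se1^2 + beta1^2 * se2^2
  if (exact) v <- v + se1^2 * se2^2
  se <- sqrt(v)
  list(indirect = beta1 * beta2, se = se,
       pvalue = wald_p(beta1 * beta2, se))
}

#' Mediated proportion with delta-method CI
#'
#' `proportion = indirect / beta0` (reported in percent). The SE propagates
#' numerator and denominator uncertainty by the first-order delta method for
#' a ratio of independent estimates:
#' `se^2 = se_ind^2/beta0^2 + indirect^2 se0^2 / beta0^4`.
#' The 95% CI is `proportion +/- 1.959964 se`; p is two-sided normal. A
#' proportion outside \[-1, 1\] is flagged `inconsistent` (inconsistent
#' mediation, direct and indirect paths of opposite sign) but still reported.
#'
#' @param beta0,se0 Total-effect estimate and SE (`beta0 != 0`).
#' @param indirect,indirect_se Indirect-effect estimate and SE.
#' @return List with `proportion`, `se`, `ci` (length-2), `pvalue`,
#'   `inconsistent` — all on the proportion (not percent) scale.
#' @export
mediated_proportion <- function(beta0, se0, indirect, indirect_se) {
  if (beta0 == 0) stop("mediated proportion undefined for beta0 = 0", call. = FALSE)
  prop <- indirect / beta0
  se <- sqrt(indirect_se^2 / beta0^2 + indirect^2 * se0^2 / beta0^4)
  inconsistent <- abs(prop) > 1
  if (inconsistent) {
    warning("mediated proportion outside [-1, 1] (inconsistent mediation)",
            call. = FALSE)
  }
  list(proportion = prop, se = se, ci = c(prop - Z95 * se, prop + Z95 * se),
       pvalue = wald_p(prop, se), inconsistent = inconsistent)
}

#' Recompute a p-value from a printed OR and 95% CI
#'
#' Consistency check for published odds-ratio triples: the SE is recovered
#' from the CI width on the log scale and the two-sided normal p-value
#' recomputed from `log(or)/se`.
#'
#' @param or,ci_low,ci_high Printed odds ratio and bounds (vectorized).
#' @return Numeric vector of implied p-values.
#' @export
recompute_wald_p <- function(or, ci_low, ci_high) {
  se <- (log(ci_high) - log(ci_low)) / (2 * Z95)
  wald_p(log(or), se)
}

#' Recompute a p-value from a printed mediated proportion and 95% CI
#'
#' As [recompute_wald_p()] but on the (percent) proportion scale, where the
#' interval is symmetric: `se = (U - L) / (2 * 1.959964)`, `z =
#' proportion/se`. Bounds may be given in either order.
#'
#' @param proportion,ci_low,ci_high Printed values (vectorized), any
#'   consistent unit.
#' @return Numeric vector of implied p-values.
#' @export
recompute_proportion_p <- function(proportion, ci_low, ci_high) {
  se <- abs(ci_high - ci_low) / (2 * Z95)
  wald_p(proportion, se)
}

#' Two-step mediation MR
#'
#' Estimates the three paths of the mediation triangle from summary
#' statistics:
#'
#' * `beta0` (total effect, exposure to outcome) from the exposure's
#'   instruments, after excluding instruments associated with the mediator
#'   at `mediator_p_threshold`;
#' * `beta1` (exposure to mediator) from the exposure's instruments;
#' * `beta2` (mediator to outcome) from the mediator's own instruments,
#'   excluding any associated with the exposure at the same threshold so the
#'   direct exposure path cannot leak into the mediator path.
#'
#' Each path uses IVW for 2+ instruments and the Wald ratio for a single
#' instrument. The indirect effect is `beta1 * beta2`
#' ([product_of_coefficients()]), the direct effect `beta0 - beta1*beta2`,
#' and the mediated proportion `indirect / beta0`
#' ([mediated_proportion()]).
#'
#' @param exposure,mediator,outcome `sumstats` tibbles over a shared SNP
#'   universe.
#' @param ld Optional `ld_matrix`.
#' @param p_threshold Instrument threshold for every path.
#' @param mediator_p_threshold Cross-path exclusion threshold.
#' @param exclude_mediator_from_total Apply the mediator-association
#'   exclusion on the total-effect path (default `TRUE`).
#' @param exclude_exposure_from_beta2 Apply the mirrored exposure-association
#'   exclusion on the mediator-to-outcome path (default `TRUE`).
#' @param ivw_model Passed to [ivw()].
#' @param ... Further arguments to [select_instruments()].
#' @return A `mediation_result` list: per-path estimates (`beta0/se0`,
#'   `beta1/se1`, `beta2/se2` with instrument counts), `indirect`,
#'   `indirect_se`, `indirect_p`, `direct`, and `proportion` (the
#'   [mediated_proportion()] list). Errors name the failing path when a path
#'   has no usable instruments.
#' @export
run_mediation <- function(exposure, mediator, outcome, ld = NULL,
                          p_threshold = 1e-5,
                          mediator_p_threshold = p_threshold,
                          exclude_mediator_from_total = TRUE,
                          exclude_exposure_from_beta2 = TRUE,
                          ivw_model = "multiplicative_random", ...) {
  fit_path <- function(exp_tab, out_tab, path, med_excl = NULL,
                       med_excl_threshold = mediator_p_threshold) {
    sel <- select_instruments(exp_tab, ld = ld, p_threshold = p_threshold,
                              mediator = med_excl,
                              mediator_p_threshold = med_excl_threshold, ...)
    if (nrow(sel$instruments) == 0) {
      stop("no instruments survive selection on the ", path, " path",
           call. = FALSE)
    }
    h <- harmonize_pair(sel$instruments, out_tab)
    k <- nrow(h$instruments)
    if (k == 0) {
      stop("no instruments survive harmonization on the ", path, " path",
           call. = FALSE)
    }
    fit <- if (k == 1) wald_ratio(h$instruments) else
      ivw(h$instruments, model = ivw_model)
    list(beta = fit$beta, se = fit$se, pvalue = fit$pvalue, k = k,
         fit = fit, selection = sel$report)
  }

  p0 <- fit_path(exposure, outcome, "total (beta0)",
                 med_excl = if (exclude_mediator_from_total) mediator)
  p1 <- fit_path(exposure, mediator, "exposure-mediator (beta1)")
  p2 <- fit_path(mediator, outcome, "mediator-outcome (beta2)",
                 med_excl = if (exclude_exposure_from_beta2) exposure)

  ind <- product_of_coefficients(p1$beta, p1$se, p2$beta, p2$se)
  prop <- mediated_proportion(p0$beta, p0$se, ind$indirect, ind$se)

  structure(list(
    beta0 = p0$beta, se0 = p0$se, p0 = p0$pvalue, n_snp0 = p0$k,
    beta1 = p1$beta, se1 = p1$se, p1 = p1$pvalue, n_snp1 = p1$k,
    beta2 = p2$beta, se2 = p2$se, p2 = p2$pvalue, n_snp2 = p2$k,
    indirect = ind$indirect, indirect_se = ind$se, indirect_p = ind$pvalue,
    direct = p0$beta - ind$indirect,
    proportion = prop,
    paths = list(total = p0, exposure_mediator = p1, mediator_outcome = p2)),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Two-step mediation MR\n  total beta0   = %8.4f (se %.4f, p %.3g, %d SNPs)\n",
              x$beta0, x$se0, x$p0, x$n_snp0))
  cat(sprintf("  beta1 (E->M)  = %8.4f (se %.4f, p %.3g, %d SNPs)\n",
              x$beta1, x$se1, x$p1, x$n_snp1))
  cat(sprintf("  beta2 (M->O)  = %8.4f (se %.4f, p %.3g, %d SNPs)\n",
              x$beta2, x$se2, x$p2, x$n_snp2))
  cat(sprintf("  indirect      = %8.4f (se %.4f, p %.3g)\n",
              x$indirect, x$indirect_se, x$indirect_p))
  cat(sprintf("  direct        = %8.4f\n", x$direct))
  cat(sprintf("  mediated prop = %7.2f%% [%.2f%%, %.2f%%], p %.3g%s\n",
              100 * x$proportion$proportion, 100 * x$proportion$ci[1],
              100 * x$proportion$ci[2], x$proportion$pvalue,
              if (x$proportion$inconsistent) " (inconsistent)" else ""))
  invisible(x)
}
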