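#' Cochran's Q heterogeneity test
#'
#' For IVW, `Q = sum(w_j (ratio_j - b_ivw)^2)` with weights
#' `beta_exp^2/se_out^2` (algebraically the residual sum of squares of the
#' weighted through-origin regression), df `k - 1`. For MR-Egger, `Q` is the
#' weighted residual sum of squares around the Egger line, df `k - 2`.
#' The heterogeneity flag follows the screening rule used throughout the
#' pipeline: flagged when `Q` exceeds its df or when `p < 0.1`.
#'
#' @param instruments `harmonized` tibble.
#' @param method `"ivw"` (default, needs k >= 2) or `"egger"` (k >= 3).
#' @return List with `method, q, df, pvalue, flagged` and per-SNP
#'   contributions `q_contrib` (named, summing to `q`).
#' @export
cochran_q <- function(instruments, method = c("ivw", "egger")) {
  method <- match.arg(method)
  k <- nrow(instruments)
  w <- 1 / instruments$se_out^2
  if (method == "ivw") {
    if (k < 2) stop("Cochran's Q (IVW) needs at least 2 instruments", call. = FALSE)
    fit <- ivw(instruments, model = "fixed")
    contrib <- w * (instruments$beta_out - fit$beta * instruments$beta_exp)^2
    df <- k - 1
  } else {
    if (k < 3) stop("Cochran's Q (Egger) needs at least 3 instruments", call. = FALSE)
    d <- orient_positive(instruments)
    fit <- egger(instruments)
    contrib <- w * (d$beta_out - fit$extra$intercept - fit$beta * d$beta_exp)^2
    df <- k - 2
  }
  q <- sum(contrib)
  p <- pchisq(q, df = df, lower.tail = FALSE)
  list(method = method, q = q, df = df, pvalue = p,
       flagged = (q > df) || (p < 0.1),
       q_contrib = setNames(contrib, instruments$snp_id))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept of the Egger regression estimates the average pleiotropic
#' effect per exposure-increasing allele; a nonzero intercept (two-sided
#' t-test p < 0.05 by default) indicates directional horizontal pleiotropy.
#'
#' @param instruments `harmonized` tibble with at least 3 rows.
#' @param alpha Detection level (default 0.05).
#' @return List with `intercept, se, pvalue, pleiotropic`.
#' @export
egger_intercept_test <- function(instruments, alpha = 0.05) {
  fit <- egger(instruments)
  list(intercept = fit$extra$intercept, se = fit$extra$intercept_se,
       pvalue = fit$extra$intercept_p,
       pleiotropic = fit$extra$intercept_p < alpha)
}

#' Remove pleiotropy-driving SNPs and re-run
#'
#' While the Egger intercept test detects directional pleiotropy and more
#' than 3 instruments remain, removes the instrument with the largest
#' absolute studentized residual from the Egger fit and re-tests. At most
#' `k - 3` removals can occur, so termination is guaranteed.
#'
#' @param instruments `harmonized` tibble with at least 3 rows.
#' @param alpha Intercept-test level.
#' @return List with `instruments` (survivors), `removed` (snp ids in
#'   removal order) and `test` (final [egger_intercept_test()] result).
#' @export
remove_pleiotropic_snps <- function(instruments, alpha = 0.05) {
  removed <- character()
  repeat {
    test <- egger_intercept_test(instruments, alpha = alpha)
    if (!test$pleiotropic || nrow(instruments) <= 3) break
    d <- orient_positive(instruments)
    w <- 1 / d$se_out^2
    fit <- stats::lm(beta_out ~ beta_exp, data = d, weights = w)
    rs <- abs(stats::rstudent(fit))
    worst <- which.max(rs)
    removed <- c(removed, instruments$snp_id[worst])
    instruments <- instruments[-worst, ]
  }
  list(instruments = instruments, removed = removed, test = test)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates IVW excluding each instrument in turn. A SNP is flagged
#' influential when its exclusion changes the sign of the estimate or moves
#' the p-value across `alpha` relative to the all-SNP fit.
#'
#' @param instruments `harmonized` tibble with at least 3 rows.
#' @param model IVW model, see [ivw()].
#' @param alpha Significance level for the stability flag.
#' @return Tibble with `k + 1` rows (`snp_id = "<all>"` last): `snp_id,
#'   beta, se, pvalue, influential`.
#' @export
leave_one_out <- function(instruments, model = "multiplicative_random",
                          alpha = 0.05) {
  k <- nrow(instruments)
  if (k < 3) stop("leave-one-out needs at least 3 instruments", call. = FALSE)
  full <- ivw(instruments, model = model)
  rows <- lapply(seq_len(k), function(i) {
    fit <- ivw(instruments[-i, ], model = model)
    tibble::tibble(snp_id = instruments$snp_id[i], beta = fit$beta, se = fit$se,
                   pvalue = fit$pvalue)
  })
  out <- dplyr::bind_rows(rows)
  out$influential <- sign(out$beta) != sign(full$beta) |
    (out$pvalue < alpha) != (full$pvalue < alpha)
  dplyr::bind_rows(out, tibble::tibble(snp_id = "<all>", beta = full$beta,
                                       se = full$se, pvalue = full$pvalue,
                                       influential = FALSE))
}

#' Drop SNPs associated with too many traits
#'
#' Cross-trait pleiotropy screen: instruments associated with more than
#' `max_traits` traits (e.g. metabolites) are removed before re-analysis.
#'
#' @param snp_trait_assoc Tibble/data frame with columns `snp_id` and
#'   `trait_id` (long format, one row per association).
#' @param max_traits Maximum tolerated number of associated traits
#'   (default 2, i.e. "more than two" are dropped).
#' @return A `selection_report` (`dropped` reason `cross_trait_pleiotropy`).
#' @export
cross_trait_filter <- function(snp_trait_assoc, max_traits = 2) {
  stopifnot(all(c("snp_id", "trait_id") %in% names(snp_trait_assoc)))
  counts <- table(unique(tibble::as_tibble(snp_trait_assoc)[c("snp_id", "trait_id")])$snp_id)
  drop <- names(counts)[counts > max_traits]
  keep <- setdiff(names(counts), drop)
  new_selection_report(
    kept = keep,
    dropped = tibble::tibble(snp_id = drop,
                             reason = rep("cross_trait_pleiotropy", length(drop))),
    thresholds = list(max_traits = max_traits))
}

#' Reverse-direction MR
#'
#' Runs the full selection/harmonization/estimation pipeline with the roles
#' swapped: instruments are selected from the original outcome GWAS and their
#' effects on the original exposure estimated. The verdict is
#' `"no_reverse_causation"` when the primary estimate (IVW for k >= 2, Wald
#' ratio for k = 1) has `p >= alpha`, `"reverse_causation"` otherwise, and
#' `"untestable"` when no instrument passes the threshold.
#'
#' @param outcome_as_exposure Original outcome `sumstats` (instrument source).
#' @param exposure_as_outcome Original exposure `sumstats`.
#' @param ld Optional `ld_matrix`.
#' @param p_threshold,alpha Selection threshold and verdict level.
#' @param n_boot,seed Bootstrap controls for the secondary estimators.
#' @param ... Further arguments to [select_instruments()].
#' @return List with `status` (`"ok"`/`"untestable"`), `verdict`, `results`
#'   ([mr_all_methods()] tibble or `NULL`) and the selection `report`.
#' @export
reverse_mr <- function(outcome_as_exposure, exposure_as_outcome, ld = NULL,
                       p_threshold = 1e-5, alpha = 0.05, n_boot = 200,
                       seed = 1, ...) {
  sel <- select_instruments(outcome_as_exposure, ld = ld,
                            p_threshold = p_threshold, ...)
  if (nrow(sel$instruments) == 0) {
    return(list(status = "untestable", verdict = "untestable", results = NULL,
                report = sel$report))
  }
  h <- harmonize_pair(sel$instruments, exposure_as_outcome)
  if (nrow(h$instruments) == 0) {
    return(list(status = "untestable", verdict = "untestable", results = NULL,
                report = sel$report))
  }
  res <- mr_all_methods(h$instruments, n_boot = n_boot, seed = seed)
  primary <- if (nrow(h$instruments) == 1) "wald_ratio" else "ivw"
  p <- res$pvalue[res$method == primary]
  list(status = "ok",
       verdict = if (p >= alpha) "no_reverse_causation" else "reverse_causation",
       results = res, report = sel$report)
}
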