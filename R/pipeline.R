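#' Screen many exposures against one outcome
#'
#' Runs the full per-exposure pipeline — instrument selection, allele
#' harmonization, estimation, heterogeneity and pleiotropy checks, and
#' (optionally) reverse MR for significant hits. The primary method follows
#' the instrument count: Wald ratio for a single SNP, IVW otherwise; the
#' other estimators contribute a concordance flag only (weighted median
#' sign-agreeing with IVW at p < 0.05). Exposures whose screen fails (for
#' example, no instruments at the threshold) are recorded with a status and
#' never abort the batch.
#'
#' P-values are nominal by default; `p_adjust = "BH"` applies a
#' Benjamini-Hochberg correction across the batch before the significance
#' call.
#'
#' @param exposures Named list of `sumstats` tibbles.
#' @param outcome Outcome `sumstats` tibble.
#' @param ld Optional `ld_matrix` shared by all exposures.
#' @param alpha Significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param reverse Run reverse MR for significant hits (needs instruments in
#'   the outcome GWAS; default `FALSE`).
#' @param secondary Also run the bootstrap-based secondary estimators
#'   (weighted median, modes) and MR-Egger. Setting `FALSE` keeps only the
#'   primary estimate plus the heterogeneity/pleiotropy tests, which is much
#'   faster for large calibration batches; the concordance flag is then `NA`.
#' @param n_boot,seed Bootstrap controls for the secondary estimators.
#' @param ... Further arguments to [select_instruments()].
#' @return Tibble with one row per exposure: status, primary method and
#'   estimate/OR/CI/p, significance and concordance flags, instrument count,
#'   heterogeneity (Q, p) and Egger-intercept p, reverse-MR verdict, and a
#'   list column `methods` with the full [mr_all_methods()] table.
#' @export
screen <- function(exposures, outcome, ld = NULL, alpha = 0.05,
                   p_adjust = c("none", "BH"), reverse = FALSE,
                   secondary = TRUE, n_boot = 200, seed = 1, ...) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(length(exposures) >= 1)
  if (is.null(names(exposures)) || any(!nzchar(names(exposures)))) {
    names(exposures) <- paste0("exposure_", seq_along(exposures))
  }

  one <- function(exp_tab, id) {
    base <- tibble::tibble(
      exposure_id = id, status = "ok", method = NA_character_,
      n_snp = NA_integer_, beta = NA_real_, se = NA_real_, pvalue = NA_real_,
      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      f_stat = NA_real_, q = NA_real_, q_p = NA_real_,
      egger_intercept_p = NA_real_, concordant = NA,
      reverse_verdict = NA_character_, methods = list(NULL))
    sel <- select_instruments(exp_tab, ld = ld, ...)
    if (nrow(sel$instruments) == 0) {
      base$status <- "no_instruments"
      return(base)
    }
    h <- harmonize_pair(sel$instruments, outcome)
    if (nrow(h$instruments) == 0) {
      base$status <- "no_harmonized_instruments"
      return(base)
    }
    k <- nrow(h$instruments)
    primary <- if (k == 1) "wald_ratio" else "ivw"
    res <- if (secondary) {
      mr_all_methods(h$instruments, n_boot = n_boot, seed = seed)
    } else {
      fit <- if (k == 1) wald_ratio(h$instruments) else ivw(h$instruments)
      tibble::tibble(method = fit$method, n_snp = fit$n_snp, beta = fit$beta,
                     se = fit$se, pvalue = fit$pvalue, or = fit$or,
                     ci_low = fit$ci_low, ci_high = fit$ci_high,
                     egger_intercept = NA_real_)
    }
    pr <- res[res$method == primary, ]
    base$method <- primary
    base$n_snp <- k
    base[c("beta", "se", "pvalue", "or", "ci_low", "ci_high")] <-
      pr[c("beta", "se", "pvalue", "or", "ci_low", "ci_high")]
    base$f_stat <- if (!is.null(sel$strength)) sel$strength$f_stat else NA_real_
    if (k >= 2) {
      qres <- cochran_q(h$instruments, "ivw")
      base$q <- qres$q
      base$q_p <- qres$pvalue
    }
    if (k >= 3) {
      base$egger_intercept_p <- egger_intercept_test(h$instruments)$pvalue
      if (secondary) {
        wm <- res[res$method == "weighted_median", ]
        base$concordant <- sign(wm$beta) == sign(pr$beta) && wm$pvalue < 0.05
      }
    }
    base$methods <- list(res)
    base
  }

  out <- dplyr::bind_rows(lapply(names(exposures), function(id) {
    one(exposures[[id]], id)
  }))
  out$p_adjusted <- if (p_adjust == "BH") {
    stats::p.adjust(out$pvalue, method = "BH")
  } else {
    out$pvalue
  }
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha

  if (reverse) {
    for (i in which(out$significant)) {
      rv <- reverse_mr(outcome, exposures[[out$exposure_id[i]]], ld = ld)
      out$reverse_verdict[i] <- rv$verdict
    }
  }
  out
}

#' Triage exposure/mediator pairs for mediation analysis
#'
#' For every pair of a significant exposure and a significant mediator, first
#' tests the exposure-to-mediator path (beta1); pairs with a significant
#' beta1 proceed to the full [run_mediation()], the rest are reported as
#' having no mediation path.
#'
#' @param exposure_hits Named list of exposure `sumstats` (screen survivors).
#' @param mediator_hits Named list of mediator `sumstats` (screen survivors).
#' @param outcome Outcome `sumstats`.
#' @param ld Optional `ld_matrix`.
#' @param alpha Significance level for the beta1 gate.
#' @param ... Further arguments to [run_mediation()].
#' @return Tibble with one row per pair: ids, status (`"mediation"`,
#'   `"no_mediation_path"`, or `"failed: <reason>"`), beta0/beta1/beta2,
#'   indirect and direct effects, mediated proportion (percent) with CI and
#'   p, and a list column `result` holding each `mediation_result`.
#' @export
mediation_triage <- function(exposure_hits, mediator_hits, outcome, ld = NULL,
                             alpha = 0.05, ...) {
  stopifnot(length(exposure_hits) >= 1)
  if (length(mediator_hits) == 0) {
    message("empty mediator hit list; nothing to triage")
    return(tibble::tibble(exposure_id = character(), mediator_id = character(),
                          status = character()))
  }
  rows <- list()
  for (eid in names(exposure_hits)) {
    for (mid in names(mediator_hits)) {
      row <- tibble::tibble(
        exposure_id = eid, mediator_id = mid, status = NA_character_,
        beta0 = NA_real_, beta1 = NA_real_, beta1_p = NA_real_,
        beta2 = NA_real_, indirect = NA_real_, direct = NA_real_,
        proportion_pct = NA_real_, proportion_ci_low_pct = NA_real_,
        proportion_ci_high_pct = NA_real_, proportion_p = NA_real_,
        result = list(NULL))
      b1 <- tryCatch({
        sel <- select_instruments(exposure_hits[[eid]], ld = ld)
        h <- harmonize_pair(sel$instruments, mediator_hits[[mid]])
        if (nrow(h$instruments) == 1) wald_ratio(h$instruments) else
          ivw(h$instruments)
      }, error = function(e) NULL)
      if (is.null(b1)) {
        row$status <- "failed: exposure-mediator path"
      } else {
        row$beta1_p <- b1$pvalue
        if (b1$pvalue >= alpha) {
          row$status <- "no_mediation_path"
        } else {
          med <- tryCatch(
            run_mediation(exposure_hits[[eid]], mediator_hits[[mid]], outcome,
                          ld = ld, ...),
            error = function(e) e)
          if (inherits(med, "error")) {
            row$status <- paste0("failed: ", conditionMessage(med))
          } else {
            row$status <- "mediation"
            row$beta0 <- med$beta0
            row$beta1 <- med$beta1
            row$beta2 <- med$beta2
            row$indirect <- med$indirect
            row$direct <- med$direct
            row$proportion_pct <- 100 * med$proportion$proportion
            row$proportion_ci_low_pct <- 100 * med$proportion$ci[1]
            row$proportion_ci_high_pct <- 100 * med$proportion$ci[2]
            row$proportion_p <- med$proportion$pvalue
            row$result <- list(med)
          }
        }
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  dplyr::bind_rows(rows)
}

#' Write screening and mediation reports to disk
#'
#' Produces (a) a forest-table TSV with one row per exposure and method,
#' (b) a mediation TSV shaped like a published mediation table (exposure,
#' mediator, outcome, mediated proportion with CI, p), and (c) a
#' run-metadata JSON recording thresholds, seeds and counts.
#'
#' @param screen_results Output of [screen()].
#' @param mediation_results Output of [mediation_triage()] (may be `NULL`).
#' @param dir Output directory (created if absent).
#' @param outcome_id Label for the outcome column.
#' @param metadata Named list merged into the metadata JSON.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(screen_results, mediation_results = NULL, dir,
                          outcome_id = "outcome", metadata = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()

  forest <- dplyr::bind_rows(lapply(seq_len(nrow(screen_results)), function(i) {
    m <- screen_results$methods[[i]]
    if (is.null(m)) return(NULL)
    tibble::tibble(exposure = screen_results$exposure_id[i],
                   outcome = outcome_id,
                   method = m$method, nsnp = m$n_snp, b = m$beta, se = m$se,
                   pval = m$pvalue, or = m$or, or_lci95 = m$ci_low,
                   or_uci95 = m$ci_high)
  }))
  fp <- file.path(dir, "forest_table.tsv")
  readr::write_tsv(forest, fp, progress = FALSE)
  paths <- c(paths, fp)

  if (!is.null(mediation_results) && nrow(mediation_results) > 0) {
    med <- mediation_results[mediation_results$status == "mediation",
                             c("exposure_id", "mediator_id", "beta0", "indirect",
                               "direct", "proportion_pct",
                               "proportion_ci_low_pct", "proportion_ci_high_pct",
                               "proportion_p")]
    med <- tibble::add_column(med, outcome = outcome_id, .after = "mediator_id")
    mp <- file.path(dir, "mediation_table.tsv")
    readr::write_tsv(med, mp, progress = FALSE)
    paths <- c(paths, mp)
  }

  meta <- c(list(
    n_exposures = nrow(screen_results),
    n_significant = sum(screen_results$significant, na.rm = TRUE),
    status_counts = as.list(table(screen_results$status)),
    package_version = as.character(utils::packageVersion("mrmediate"))),
    metadata)
  jp <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(meta, jp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, jp)
  invisible(paths)
}
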