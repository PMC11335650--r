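new_selection_report <- function(kept, dropped, thresholds) {
  stopifnot(is.character(kept),
            all(c("snp_id", "reason") %in% names(dropped)))
  structure(list(kept = kept, dropped = tibble::as_tibble(dropped),
                 thresholds = thresholds),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Instrument selection:", length(x$kept), "kept,", nrow(x$dropped), "dropped\n")
  if (nrow(x$dropped) > 0) print(table(x$dropped$reason))
  invisible(x)
}

#' Keep SNPs below a p-value threshold
#'
#' First screening step: retains rows with `P < threshold` (default
#' 1e-5, the relaxed genome-wide threshold commonly used for molecular
#' traits with modest GWAS sample sizes).
#'
#' @param table A `sumstats` tibble.
#' @param threshold Significance threshold in (0, 1).
#' @return A `selection_report` with `kept` (snp ids) and `dropped`
#'   (reason `above_p_threshold`).
#' @export
filter_by_pvalue <- function(table, threshold = 1e-5) {
  stopifnot(threshold > 0, threshold <= 1)
  keep <- table$P < threshold
  new_selection_report(
    kept = table$SNP[keep],
    dropped = tibble::tibble(snp_id = table$SNP[!keep],
                             reason = rep("above_p_threshold", sum(!keep))),
    thresholds = list(p_threshold = threshold))
}

#' Greedy LD clumping
#'
#' Repeatedly takes the lowest-p unclaimed SNP as an index (ties broken by
#' lexicographically smaller snp_id) and discards all unclaimed SNPs on the
#' same chromosome within `window_kb` whose r-squared with the index exceeds
#' `r2_threshold`. Indices form the kept set, so all retained pairs within a
#' window have r-squared at or below the threshold. The result does not
#' depend on input row order.
#'
#' @param table A `sumstats` tibble with CHR/POS populated.
#' @param ld An `ld_matrix` covering every SNP in `table`, or `NULL` with
#'   `assume_independent = TRUE` for simulated independent SNPs.
#' @param r2_threshold Maximum r-squared between retained SNPs (default 0.001).
#' @param window_kb Clumping window in kilobases (default 10,000).
#' @param assume_independent Explicit opt-out when no LD matrix exists.
#' @return A `selection_report` (`dropped` reason `clumped`).
#' @export
ld_clump <- function(table, ld = NULL, r2_threshold = 0.001, window_kb = 10000,
                     assume_independent = FALSE) {
  if (is.null(ld)) {
    if (!assume_independent) {
      stop("no LD matrix supplied; pass assume_independent = TRUE only if ",
           "the SNPs are known to be independent", call. = FALSE)
    }
    return(new_selection_report(
      kept = table$SNP,
      dropped = tibble::tibble(snp_id = character(), reason = character()),
      thresholds = list(clump_r2 = r2_threshold, clump_kb = window_kb,
                        assume_independent = TRUE)))
  }
  missing <- setdiff(table$SNP, rownames(ld))
  if (length(missing) > 0) {
    stop("SNP(s) absent from LD matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ord <- order(table$P, table$SNP)
  snp <- table$SNP[ord]
  chr <- table$CHR[ord]
  pos <- table$POS[ord]
  state <- rep("unclaimed", length(snp))
  win <- window_kb * 1000
  for (i in seq_along(snp)) {
    if (state[i] != "unclaimed") next
    state[i] <- "index"
    near <- state == "unclaimed" & chr == chr[i] & abs(pos - pos[i]) <= win
    if (any(near)) {
      r2 <- ld[snp[i], snp[near]]
      state[near][r2 > r2_threshold] <- "clumped"
    }
  }
  kept <- snp[state == "index"]
  new_selection_report(
    kept = table$SNP[table$SNP %in% kept],
    dropped = tibble::tibble(snp_id = snp[state == "clumped"],
                             reason = rep("clumped", sum(state == "clumped"))),
    thresholds = list(clump_r2 = r2_threshold, clump_kb = window_kb,
                      assume_independent = FALSE))
}

#' Instrument-strength F statistic
#'
#' `F = R2 (N - 1 - K) / ((1 - R2) K)` where `R2` is the exposure variance
#' explained by the `K` instruments and `N` the exposure GWAS sample size.
#' Instrument sets with `F >= 10` are conventionally called strong.
#'
#' @param r2_total Variance explained, in \[0, 1).
#' @param n Sample size, must exceed `k + 1`.
#' @param k Number of instruments, at least 1.
#' @return List with `r2_total`, `n`, `k`, `f_stat` and logical `strong`
#'   (`f_stat >= 10`).
#' @export
f_statistic <- function(r2_total, n, k) {
  if (r2_total < 0 || r2_total >= 1) stop("r2_total must lie in [0, 1)", call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (n <= k + 1) stop("n must exceed k + 1", call. = FALSE)
  f <- (r2_total * (n - 1 - k)) / ((1 - r2_total) * k)
  list(r2_total = r2_total, n = n, k = k, f_stat = f, strong = f >= 10)
}

#' Per-SNP variance explained in the exposure
#'
#' SD-trait approximation `2 eaf (1 - eaf) beta^2`; the set-level `R2` is the
#' sum over instruments (capped below 1).
#'
#' @param eaf Effect-allele frequency (vectorized).
#' @param beta Per-allele effect in SD units (vectorized).
#' @return Numeric vector of per-SNP r-squared.
#' @export
per_snp_r2 <- function(eaf, beta) 2 * eaf * (1 - eaf) * beta^2

set_r2 <- function(table) min(sum(per_snp_r2(table$EAF, table$BETA)), 1 - 1e-12)

#' Drop exposure instruments associated with the mediator
#'
#' Mirrors the mediation-path screen: an exposure instrument whose mediator
#' p-value falls below `threshold` is excluded from the total-effect path so
#' the exposure-to-outcome contrast is not contaminated by the mediator
#' pathway's instruments.
#'
#' @param instruments `sumstats` tibble of selected exposure instruments.
#' @param mediator `sumstats` tibble for the mediator; must contain every
#'   instrument SNP.
#' @param threshold Mediator-association threshold (default 1e-5).
#' @return A `selection_report` (`dropped` reason `mediator_associated`).
#' @export
exclude_mediator_associated <- function(instruments, mediator, threshold = 1e-5) {
  missing <- setdiff(instruments$SNP, mediator$SNP)
  if (length(missing) > 0) {
    stop("instrument(s) absent from mediator table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  med_p <- setNames(mediator$P, mediator$SNP)[instruments$SNP]
  drop <- med_p < threshold
  new_selection_report(
    kept = instruments$SNP[!drop],
    dropped = tibble::tibble(snp_id = instruments$SNP[drop],
                             reason = rep("mediator_associated", sum(drop))),
    thresholds = list(mediator_p_threshold = threshold))
}

#' Full instrument-selection screen
#'
#' Runs, in order: p-value threshold, greedy LD clumping, set-level
#' F-statistic weak-instrument filter, and (optionally) mediator-association
#' exclusion. The F filter uses the summed per-SNP variance explained; with
#' `f_mode = "per_snp"` individual SNPs with per-SNP `F < f_min` are dropped
#' instead of the whole set.
#'
#' @param table Exposure `sumstats` tibble.
#' @param ld Optional `ld_matrix` (see [ld_clump()]).
#' @param p_threshold,r2_threshold,window_kb,f_min Screen parameters.
#' @param mediator Optional mediator `sumstats` for the final exclusion step.
#' @param mediator_p_threshold Threshold for that step.
#' @param assume_independent Passed to [ld_clump()].
#' @param f_mode `"set"` (default) or `"per_snp"`.
#' @return List with `instruments` (subset of `table`), `report`
#'   (`selection_report` pooling all stages) and `strength` (set-level
#'   [f_statistic()] of the kept instruments, `NULL` when none survive).
#' @export
select_instruments <- function(table, ld = NULL, p_threshold = 1e-5,
                               r2_threshold = 0.001, window_kb = 10000,
                               f_min = 10, mediator = NULL,
                               mediator_p_threshold = p_threshold,
                               assume_independent = is.null(ld),
                               f_mode = c("set", "per_snp")) {
  f_mode <- match.arg(f_mode)
  dropped <- list()

  rep1 <- filter_by_pvalue(table, p_threshold)
  dropped[[1]] <- rep1$dropped
  cur <- table[table$SNP %in% rep1$kept, , drop = FALSE]

  if (nrow(cur) > 0) {
    rep2 <- ld_clump(cur, ld, r2_threshold, window_kb, assume_independent)
    dropped[[2]] <- rep2$dropped
    cur <- cur[cur$SNP %in% rep2$kept, , drop = FALSE]
  }

  strength <- NULL
  if (nrow(cur) > 0) {
    if (f_mode == "per_snp") {
      f_snp <- vapply(seq_len(nrow(cur)), function(i) {
        f_statistic(min(per_snp_r2(cur$EAF[i], cur$BETA[i]), 1 - 1e-12),
                    cur$N[i], 1)$f_stat
      }, numeric(1))
      weak <- f_snp < f_min
      dropped[[3]] <- tibble::tibble(snp_id = cur$SNP[weak],
                                     reason = rep("weak_f", sum(weak)))
      cur <- cur[!weak, , drop = FALSE]
      if (nrow(cur) > 0) {
        strength <- f_statistic(set_r2(cur), cur$N[1], nrow(cur))
      }
    } else {
      strength <- f_statistic(set_r2(cur), cur$N[1], nrow(cur))
      if (strength$f_stat < f_min) {
        dropped[[3]] <- tibble::tibble(snp_id = cur$SNP,
                                       reason = rep("weak_f", nrow(cur)))
        cur <- cur[0, , drop = FALSE]
        strength <- NULL
      }
    }
  }

  if (!is.null(mediator) && nrow(cur) > 0) {
    rep4 <- exclude_mediator_associated(cur, mediator, mediator_p_threshold)
    dropped[[4]] <- rep4$dropped
    cur <- cur[cur$SNP %in% rep4$kept, , drop = FALSE]
    if (nrow(cur) > 0) strength <- f_statistic(set_r2(cur), cur$N[1], nrow(cur))
  }

  report <- new_selection_report(
    kept = cur$SNP,
    dropped = dplyr::bind_rows(dropped),
    thresholds = list(p_threshold = p_threshold, clump_r2 = r2_threshold,
                      clump_kb = window_kb, f_min = f_min, f_mode = f_mode,
                      mediator_p_threshold = if (is.null(mediator)) NA_real_ else mediator_p_threshold))
  list(instruments = cur, report = report, strength = strength)
}
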