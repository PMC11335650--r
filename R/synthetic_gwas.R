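#' Configuration for the summary-level GWAS simulator
#'
#' Defines the generative model behind [simulate_triple()]. Summary statistics
#' are simulated directly at the summary level: per-SNP true effects are drawn
#' once, then observed betas are sampled around them with the analytic
#' standard error for a standardized continuous trait,
#' `se = 1/sqrt(2 p (1 - p) n)`.
#'
#' The default sample sizes mirror the cohort scale of a typical
#' immune-cell/metabolite/epilepsy screen: a small flow-cytometry exposure
#' GWAS (n = 3,757), a mid-size metabolite GWAS (n = 8,299) and a large
#' case-control outcome GWAS (n = 44,889, i.e. 15,212 cases + 29,677
#' controls analysed on the log-odds scale).
#'
#' @param n_instruments Number of SNPs with a direct effect on the exposure.
#' @param n_med_instruments Number of SNPs with a direct effect on the
#'   mediator only (needed for an identified mediator-to-outcome path).
#' @param n_null_snps SNPs with no effect on any trait.
#' @param n_exp,n_med,n_out GWAS sample sizes.
#' @param theta True direct exposure-to-outcome effect.
#' @param beta1 True exposure-to-mediator effect.
#' @param beta2 True mediator-to-outcome effect.
#' @param gamma_sd SD of instrument-exposure effects (drawn Normal(0, sd^2)).
#' @param delta_sd SD of mediator-instrument effects.
#' @param pleio_mean,pleio_sd Mean and SD of per-instrument pleiotropic
#'   outcome effects, expressed per exposure-increasing (or
#'   mediator-increasing) allele so a nonzero mean is directional.
#' @param inside_corr Correlation between pleiotropic effects and instrument
#'   strength (an InSIDE violation when nonzero).
#' @param maf_range Interval within (0, 1) for minor-allele frequencies.
#' @param frac_palindromic Fraction of SNPs given A/T or C/G allele pairs.
#' @param frac_flipped Fraction of outcome rows reported on the opposite
#'   strand and/or with swapped allele coding.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_instruments = 20,
                       n_med_instruments = n_instruments,
                       n_null_snps = 50,
                       n_exp = 3757, n_med = 8299, n_out = 44889,
                       theta = 0.09, beta1 = 0.1, beta2 = 0.1,
                       gamma_sd = 0.15, delta_sd = gamma_sd,
                       pleio_mean = 0, pleio_sd = 0, inside_corr = 0,
                       maf_range = c(0.05, 0.5),
                       frac_palindromic = 0.16, frac_flipped = 0.1,
                       seed = NULL) {
  cfg <- list(n_instruments = n_instruments, n_med_instruments = n_med_instruments,
              n_null_snps = n_null_snps,
              n_exp = n_exp, n_med = n_med, n_out = n_out,
              theta = theta, beta1 = beta1, beta2 = beta2,
              gamma_sd = gamma_sd, delta_sd = delta_sd,
              pleio_mean = pleio_mean, pleio_sd = pleio_sd,
              inside_corr = inside_corr,
              maf_range = as.numeric(maf_range),
              frac_palindromic = frac_palindromic, frac_flipped = frac_flipped,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_instruments >= 1, cfg$n_med_instruments >= 0, cfg$n_null_snps >= 0)
  if (any(c(cfg$n_exp, cfg$n_med, cfg$n_out) < 2)) {
    stop("all sample sizes must be at least 2", call. = FALSE)
  }
  mr <- cfg$maf_range
  if (length(mr) != 2 || mr[1] <= 0 || mr[2] >= 1 || mr[1] >= mr[2]) {
    stop("maf_range must be a non-degenerate interval within (0, 1)", call. = FALSE)
  }
  if (cfg$frac_palindromic < 0 || cfg$frac_palindromic > 1 ||
      cfg$frac_flipped < 0 || cfg$frac_flipped > 1) {
    stop("frac_palindromic and frac_flipped must lie in [0, 1]", call. = FALSE)
  }
  if (abs(cfg$inside_corr) > 1) stop("inside_corr must lie in [-1, 1]", call. = FALSE)
  invisible(cfg)
}

# analytic SE of a per-allele effect on a standardized trait
se_sdtrait <- function(p, n) 1 / sqrt(2 * p * (1 - p) * n)

wald_p <- function(beta, se) 2 * pnorm(-abs(beta / se))

comp_allele <- function(a) chartr("ACGT", "TGCA", a)

# draw one allele pair per SNP; palindromic pairs are A/T or C/G
draw_alleles <- function(n_snp, frac_palindromic) {
  pal <- runif(n_snp) < frac_palindromic
  ea <- character(n_snp)
  nea <- character(n_snp)
  pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  nonpal_pairs <- list(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                       c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
  ip <- sample.int(4L, n_snp, replace = TRUE)
  inp <- sample.int(8L, n_snp, replace = TRUE)
  for (i in seq_len(n_snp)) {
    pair <- if (pal[i]) pal_pairs[[ip[i]]] else nonpal_pairs[[inp[i]]]
    ea[i] <- pair[1]
    nea[i] <- pair[2]
  }
  list(ea = ea, nea = nea, palindromic = pal)
}

#' Simulate an exposure/mediator/outcome summary-statistics triple
#'
#' Generates three aligned GWAS summary-statistics tables with known ground
#' truth. Instrument SNP `j` carries a true exposure effect `gamma_j ~
#' Normal(0, gamma_sd^2)`; the mediator inherits `beta1 * gamma_j` and has
#' its own direct instruments with effects `delta_j ~ Normal(0, delta_sd^2)`;
#' the outcome receives `(theta + beta1*beta2) * gamma_j + alpha_j` from
#' exposure instruments and `beta2 * delta_j + alpha_j` from mediator
#' instruments, where `alpha_j` is a pleiotropic effect aligned with the
#' trait-increasing allele (mean `pleio_mean`, SD `pleio_sd`, correlated with
#' instrument strength when `inside_corr != 0`). Observed betas are drawn
#' around these truths with analytic SEs; p-values are two-sided Wald. A
#' `frac_flipped` fraction of outcome rows is re-expressed on the opposite
#' strand and/or with swapped alleles, which [harmonize_pair()] must undo.
#'
#' @param config A [sim_config()].
#' @return List with `exposure`, `mediator`, `outcome` (`sumstats` tibbles
#'   sharing one snp_id set) and `truth` (theta_total, indirect, per-SNP
#'   gamma/delta/alpha vectors and SNP roles).
#' @export
simulate_triple <- function(config) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  m <- config$n_instruments
  md <- config$n_med_instruments
  n0 <- config$n_null_snps
  M <- m + md + n0
  role <- rep(c("exposure_instrument", "mediator_instrument", "null"),
              times = c(m, md, n0))

  snp <- sprintf("rs%06d", seq_len(M))
  chr <- as.character(rep_len(1:22, M))
  pos <- sample.int(2.5e8, M, replace = TRUE)
  maf <- runif(M, config$maf_range[1], config$maf_range[2])
  al <- draw_alleles(M, config$frac_palindromic)

  gamma <- c(rnorm(m, 0, config$gamma_sd), rep(0, md + n0))
  delta <- c(rep(0, m), rnorm(md, 0, config$delta_sd), rep(0, n0))

  # pleiotropy per trait-increasing allele, optionally correlated with
  # instrument strength (InSIDE violation)
  alpha <- rep(0, M)
  inst <- role != "null"
  if (config$pleio_sd > 0 || config$pleio_mean != 0) {
    k <- sum(inst)
    strength <- abs(gamma + delta)[inst]
    zs <- if (sd(strength) > 0) (strength - mean(strength)) / sd(strength) else rep(0, k)
    eps <- rnorm(k)
    mix <- config$inside_corr * zs + sqrt(1 - config$inside_corr^2) * eps
    a <- config$pleio_mean + config$pleio_sd * mix
    orient <- ifelse(gamma[inst] + delta[inst] >= 0, 1, -1)
    alpha[inst] <- orient * a
  }

  theta_total <- config$theta + config$beta1 * config$beta2
  mu_exp <- gamma
  mu_med <- config$beta1 * gamma + delta
  mu_out <- theta_total * gamma + config$beta2 * delta + alpha

  se_exp <- se_sdtrait(maf, config$n_exp)
  se_med <- se_sdtrait(maf, config$n_med)
  se_out <- se_sdtrait(maf, config$n_out)

  b_exp <- rnorm(M, mu_exp, se_exp)
  b_med <- rnorm(M, mu_med, se_med)
  b_out <- rnorm(M, mu_out, se_out)

  mk <- function(beta, se, n, trait_id) {
    as_sumstats(tibble::tibble(
      SNP = snp, CHR = chr, POS = pos, EA = al$ea, NEA = al$nea, EAF = maf,
      BETA = beta, SE = se, P = pmax(wald_p(beta, se), .Machine$double.xmin),
      N = n), trait_id = trait_id)
  }
  exposure <- mk(b_exp, se_exp, config$n_exp, "exposure")
  mediator <- mk(b_med, se_med, config$n_med, "mediator")
  outcome <- mk(b_out, se_out, config$n_out, "outcome")

  # re-express a fraction of outcome rows on the other strand and/or with
  # swapped allele coding; palindromes only ever get the swap (a strand flip
  # is textually invisible for them)
  if (config$frac_flipped > 0) {
    flip <- which(runif(M) < config$frac_flipped)
    for (i in flip) {
      do_swap <- runif(1) < 0.5 || al$palindromic[i]
      do_strand <- !al$palindromic[i] && runif(1) < 0.5
      if (!do_swap && !do_strand) do_swap <- TRUE
      if (do_swap) {
        tmp <- outcome$EA[i]
        outcome$EA[i] <- outcome$NEA[i]
        outcome$NEA[i] <- tmp
        outcome$BETA[i] <- -outcome$BETA[i]
        outcome$EAF[i] <- 1 - outcome$EAF[i]
      }
      if (do_strand) {
        outcome$EA[i] <- comp_allele(outcome$EA[i])
        outcome$NEA[i] <- comp_allele(outcome$NEA[i])
      }
    }
  }

  truth <- list(theta = config$theta, beta1 = config$beta1, beta2 = config$beta2,
                theta_total = theta_total,
                indirect = config$beta1 * config$beta2,
                gamma = setNames(gamma, snp), delta = setNames(delta, snp),
                alpha = setNames(alpha, snp), role = setNames(role, snp))
  list(exposure = exposure, mediator = mediator, outcome = outcome, truth = truth)
}

#' Simulate a block-diagonal LD matrix
#'
#' Consecutive SNPs (in the id order of [simulate_triple()]) are grouped into
#' blocks of `block_size`; r-squared is `within_r2` inside a block and 0
#' between blocks.
#'
#' @param config A [sim_config()] (determines the number and ids of SNPs).
#' @param block_size Number of SNPs per block (last block may be smaller).
#' @param within_r2 Off-diagonal r-squared within a block, in \[0, 1\].
#' @return An `ld_matrix`.
#' @export
simulate_ld_blocks <- function(config, block_size, within_r2) {
  validate_sim_config(config)
  stopifnot(block_size >= 1, within_r2 >= 0, within_r2 <= 1)
  M <- config$n_instruments + config$n_med_instruments + config$n_null_snps
  ids <- sprintf("rs%06d", seq_len(M))
  block <- (seq_len(M) - 1) %/% block_size
  m <- outer(block, block, function(a, b) ifelse(a == b, within_r2, 0))
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  as_ld_matrix(m)
}
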