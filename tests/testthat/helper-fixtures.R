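# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except the bundled reported-value tables.

# a harmonized instrument tibble straight from effect vectors
make_harmonized <- function(bx, by, sy, sx = rep(0.01, length(bx)),
                            bm = NULL, sm = NULL) {
  k <- length(bx)
  out <- tibble::tibble(
    snp_id = sprintf("rs%03d", seq_len(k)),
    chrom = rep("1", k), pos = seq_len(k) * 1e6,
    effect_allele = rep("A", k), other_allele = rep("G", k),
    beta_exp = bx, se_exp = sx, eaf_exp = rep(0.3, k),
    beta_out = by, se_out = sy, eaf_out = rep(0.3, k),
    p_exp = 2 * pnorm(-abs(bx / sx)), p_out = 2 * pnorm(-abs(by / sy)),
    n_exp = rep(10000, k), n_out = rep(20000, k))
  if (!is.null(bm)) {
    out$beta_med <- bm
    out$se_med <- sm
  }
  class(out) <- c("harmonized", class(out))
  out
}

# a small well-formed sumstats tibble
make_sumstats <- function(n = 5, p = NULL, beta = NULL, seed = 1,
                          trait_id = "trait") {
  set.seed(seed)
  eaf <- runif(n, 0.1, 0.5)
  se <- 1 / sqrt(2 * eaf * (1 - eaf) * 10000)
  if (is.null(beta)) beta <- rnorm(n, 0, 5 * mean(se))
  if (is.null(p)) p <- 2 * pnorm(-abs(beta / se))
  as_sumstats(tibble::tibble(
    SNP = sprintf("rs%03d", seq_len(n)), CHR = "1", POS = seq_len(n) * 1e6,
    EA = rep(c("A", "C"), length.out = n), NEA = rep(c("G", "T"), length.out = n),
    EAF = eaf, BETA = beta, SE = se, P = p, N = 10000), trait_id = trait_id)
}

# config used for calibration-style runs: independent non-palindromic SNPs,
# no allele hazards, so selection/harmonization never drops anything
calib_config <- function(seed, theta = 0, ...) {
  sim_config(n_instruments = 10, n_med_instruments = 0, n_null_snps = 0,
             theta = theta, beta1 = 0, beta2 = 0,
             gamma_sd = 0.3, n_exp = 1e5,
             frac_palindromic = 0, frac_flipped = 0, seed = seed, ...)
}

# quick forward pipeline: select (independent), harmonize, return instruments
pipeline_instruments <- function(sim, p_threshold = 1e-5) {
  sel <- select_instruments(sim$exposure, assume_independent = TRUE,
                            p_threshold = p_threshold)
  harmonize_pair(sel$instruments, sim$outcome)$instruments
}
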