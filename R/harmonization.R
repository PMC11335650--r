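#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' For every SNP present in both tables the outcome effect is re-expressed
#' per copy of the exposure's effect allele:
#'
#' * identical alleles: copied as-is;
#' * swapped alleles (outcome EA equals exposure NEA and vice versa): the
#'   outcome beta is negated and its EAF replaced by `1 - EAF`;
#' * strand complements: complemented, then treated as identical/swapped;
#' * palindromic SNPs (A/T or C/G pairs), for which strand is textually
#'   undecidable: excluded as ambiguous when either trait's EAF lies inside
#'   `ambiguity_band` (or always, with `strict_palindromes = TRUE`),
#'   otherwise aligned by allele frequency — if the textually aligned outcome
#'   EAF sits on the other side of 0.5 from the exposure EAF the coding is
#'   flipped;
#' * irreconcilable allele pairs: excluded.
#'
#' After alignment, SNPs whose exposure and aligned outcome EAFs differ by
#' more than `eaf_discordance` are excluded as frequency-inconsistent. The
#' report accounts for every shared SNP.
#'
#' @param exposure,outcome `sumstats` tibbles.
#' @param ambiguity_band Closed EAF interval within which a palindromic SNP
#'   is considered ambiguous (default `c(0.42, 0.58)`).
#' @param eaf_discordance Maximum tolerated |EAF difference| after alignment
#'   (default 0.2).
#' @param strict_palindromes Drop every palindromic SNP regardless of
#'   frequency.
#' @return List with `instruments` — a tibble (class `harmonized`) with
#'   columns `snp_id, effect_allele, other_allele, beta_exp, se_exp,
#'   eaf_exp, beta_out, se_out, eaf_out, p_exp, p_out, n_exp, n_out` — and
#'   `report`, a `selection_report` over the shared SNPs.
#' @export
harmonize_pair <- function(exposure, outcome, ambiguity_band = c(0.42, 0.58),
                           eaf_discordance = 0.2, strict_palindromes = FALSE) {
  shared <- intersect(exposure$SNP, outcome$SNP)
  if (length(shared) == 0) stop("no shared SNPs between tables", call. = FALSE)
  ex <- exposure[match(shared, exposure$SNP), ]
  ou <- outcome[match(shared, outcome$SNP), ]

  n <- length(shared)
  beta_out <- ou$BETA
  eaf_out <- ou$EAF
  reason <- rep(NA_character_, n)

  pal <- ex$EA == comp_allele(ex$NEA)
  ident <- ou$EA == ex$EA & ou$NEA == ex$NEA
  swapped <- ou$EA == ex$NEA & ou$NEA == ex$EA
  str_ident <- comp_allele(ou$EA) == ex$EA & comp_allele(ou$NEA) == ex$NEA
  str_swapped <- comp_allele(ou$EA) == ex$NEA & comp_allele(ou$NEA) == ex$EA

  for (i in seq_len(n)) {
    if (pal[i]) {
      # for a palindrome every textual match is strand-ambiguous
      if (!(ident[i] || swapped[i])) {
        reason[i] <- "incompatible_alleles"
        next
      }
      in_band <- function(f) f >= ambiguity_band[1] & f <= ambiguity_band[2]
      if (strict_palindromes || in_band(ex$EAF[i]) || in_band(ou$EAF[i])) {
        reason[i] <- "ambiguous_palindrome"
        next
      }
      if (swapped[i]) {
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
      # frequency alignment: disagreeing sides of 0.5 mean the apparent
      # coding is a strand artifact
      if ((ex$EAF[i] - 0.5) * (eaf_out[i] - 0.5) < 0) {
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
    } else if (ident[i] || str_ident[i]) {
      # nothing to do
    } else if (swapped[i] || str_swapped[i]) {
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
    } else {
      reason[i] <- "incompatible_alleles"
    }
  }

  ok <- is.na(reason)
  discordant <- ok & abs(ex$EAF - eaf_out) > eaf_discordance
  reason[discordant] <- "eaf_discordant"
  ok <- is.na(reason)

  instruments <- tibble::tibble(
    snp_id = shared[ok],
    chrom = ex$CHR[ok], pos = ex$POS[ok],
    effect_allele = ex$EA[ok], other_allele = ex$NEA[ok],
    beta_exp = ex$BETA[ok], se_exp = ex$SE[ok], eaf_exp = ex$EAF[ok],
    beta_out = beta_out[ok], se_out = ou$SE[ok], eaf_out = eaf_out[ok],
    p_exp = ex$P[ok], p_out = ou$P[ok],
    n_exp = ex$N[ok], n_out = ou$N[ok])
  class(instruments) <- c("harmonized", class(instruments))

  report <- new_selection_report(
    kept = shared[ok],
    dropped = tibble::tibble(snp_id = shared[!ok], reason = reason[!ok]),
    thresholds = list(ambiguity_band = ambiguity_band,
                      eaf_discordance = eaf_discordance,
                      strict_palindromes = strict_palindromes))
  list(instruments = instruments, report = report)
}

#' Attach mediator effects to a harmonized instrument set
#'
#' Aligns the mediator table to the harmonized effect alleles (same allele
#' logic as [harmonize_pair()]) and adds `beta_med`, `se_med`, `eaf_med`,
#' `p_med`, `n_med` columns. Instruments whose mediator row cannot be
#' reconciled are dropped.
#'
#' @param instruments Output of [harmonize_pair()]`$instruments`.
#' @param mediator `sumstats` tibble.
#' @inheritParams harmonize_pair
#' @return The augmented `harmonized` tibble.
#' @export
attach_mediator <- function(instruments, mediator, ambiguity_band = c(0.42, 0.58),
                            eaf_discordance = 0.2, strict_palindromes = FALSE) {
  pseudo_exp <- as_sumstats(tibble::tibble(
    SNP = instruments$snp_id, CHR = instruments$chrom, POS = instruments$pos,
    EA = instruments$effect_allele, NEA = instruments$other_allele,
    EAF = instruments$eaf_exp, BETA = instruments$beta_exp,
    SE = instruments$se_exp, P = instruments$p_exp, N = instruments$n_exp))
  h <- harmonize_pair(pseudo_exp, mediator, ambiguity_band = ambiguity_band,
                      eaf_discordance = eaf_discordance,
                      strict_palindromes = strict_palindromes)
  keep <- match(h$instruments$snp_id, instruments$snp_id)
  out <- instruments[keep, ]
  out$beta_med <- h$instruments$beta_out
  out$se_med <- h$instruments$se_out
  out$eaf_med <- h$instruments$eaf_out
  out$p_med <- h$instruments$p_out
  out$n_med <- h$instruments$n_out
  out
}
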