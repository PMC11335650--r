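---
title: "Methods: two-sample and mediation MR in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample and mediation MR in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

Two-sample Mendelian randomization treats genetic variants as instruments
for a modifiable exposure. For SNP $j$, let $\gamma_j$ be its true effect on
the exposure and $\Gamma_j$ its effect on the outcome. If the instrument
assumptions hold (relevance, independence from confounders, and exclusion —
no outcome path other than the exposure), then $\Gamma_j = \theta \gamma_j$
for a single causal effect $\theta$, and each SNP's Wald ratio
$\hat\Gamma_j/\hat\gamma_j$ estimates $\theta$. All estimators in this
package operate on summary statistics only: per-SNP effect sizes, standard
errors, allele frequencies and sample sizes from two non-overlapping GWAS.

Binary outcomes are handled on the log-odds scale, so a causal estimate
$\hat\theta$ is reported as an odds ratio $e^{\hat\theta}$ per SD of the
exposure, with a 95% CI $e^{\hat\theta \pm 1.959964\,\mathrm{se}}$.

Two-step mediation MR decomposes a total effect $\beta_0$
(exposure $\to$ outcome) into $\beta_1$ (exposure $\to$ mediator) and
$\beta_2$ (mediator $\to$ outcome): the indirect effect is the coefficient
product $\beta_1\beta_2$, the direct effect $\beta_0 - \beta_1\beta_2$, and
the mediated proportion $\beta_1\beta_2/\beta_0$. The product's SE is the
first-order (Sobel) form
$\sqrt{\beta_2^2\mathrm{se}_1^2 + \beta_1^2\mathrm{se}_2^2}$ (the exact
extra term $\mathrm{se}_1^2\mathrm{se}_2^2$ is available via `exact =
TRUE`); the proportion's SE propagates numerator and denominator by the
delta method assuming the two MR fits are independent. Published mediation
tables in this field print symmetric normal intervals on the proportion,
which is exactly what this reproduces — `recompute_proportion_p()` inverts
such an interval back to its implied p-value, and the bundled published
rows (`reported_mediation()`) agree with their printed p-values to within
0.002, i.e. to printed rounding.

## Instrument selection

The screen runs in a fixed order, each stage logged in a
`selection_report` so every input SNP lands in exactly one kept/dropped
category:

1. **Association threshold** `p_threshold = 1e-5`. Molecular-trait GWAS at
   cohort sizes of a few thousand rarely yield multiple genome-wide
   ($5\times10^{-8}$) hits, so the field's customary relaxed threshold is
   the default.
2. **LD clumping** `r2_threshold = 0.001`, `window_kb = 10000`: greedy —
   the lowest-p unclaimed SNP becomes an index, unclaimed SNPs within the
   window on the same chromosome with $r^2$ above threshold are discarded,
   repeat. Ties in p are broken by lexicographic snp_id so the result is
   row-order invariant. Without an LD matrix the function refuses to run
   unless `assume_independent = TRUE` is passed explicitly: a silent
   independence assumption would corrupt a real analysis, while simulated
   instruments are independent by construction and may say so.
3. **Weak-instrument filter** using
   $F = R^2(N-1-K)/\left((1-R^2)K\right)$ with
   $R^2 = \sum_j 2p_j(1-p_j)\beta_j^2$ (the SD-trait approximation) summed
   over the retained set; sets with $F < 10$ are dropped. The formula's $K$
   is a set-level count, so the filter is set-level by default; a
   `f_mode = "per_snp"` option instead drops individual SNPs with per-SNP
   $F < 10$, since screens in this field are described both ways.
4. **Mediator-association exclusion** (mediation total-effect path only):
   instruments with mediator p below the instrument threshold are removed,
   so the total-effect contrast is not carried by SNPs that move the
   mediator. The threshold is unstated in the published screens we mirror;
   it defaults to the instrument threshold and is configurable.

## Harmonization

Exposure and outcome rows are aligned to the exposure's effect allele:
identical pairs are copied, swapped pairs negate the outcome beta and
reflect its EAF, strand complements are complemented first. Palindromic
SNPs (A/T, C/G) are textually strand-undecidable: those with either EAF in
the ambiguity band `[0.42, 0.58]` are dropped, the rest are aligned by
allele frequency (if the aligned outcome EAF falls on the other side of 0.5
from the exposure EAF, the coding is flipped). The band is a tunable
operationalization of "ambiguous", which published pipelines rarely
quantify; `strict_palindromes = TRUE` drops every palindrome for the
conservative reading. After alignment, SNPs whose EAFs still differ by more
than `eaf_discordance = 0.2` are dropped as likely mismatches. The
harmonizer is an involution (re-harmonizing its output is the identity) and
undoes any mixture of allele swaps and strand flips exactly — the test
suite checks pipeline identity to 1e-10 between flipped and unflipped twins
of the same simulation.

## Estimators

- **IVW**: weighted through-origin regression,
  $\hat\theta = \sum w_j\hat\gamma_j\hat\Gamma_j / \sum w_j\hat\gamma_j^2$
  with $w_j = 1/\mathrm{se}(\hat\Gamma_j)^2$. The default multiplicative
  random-effects SE multiplies the fixed-effect SE by
  $\max(1, \sqrt{Q/(k-1)})$: heterogeneity widens the interval but can
  never narrow it below the fixed-effect one. P-values are normal.
- **MR-Egger**: instruments are oriented so all $\hat\gamma_j > 0$, then
  outcome effects are regressed on exposure effects *with* an intercept.
  The intercept estimates the mean directional pleiotropic effect per
  exposure-increasing allele; inference uses a $t_{k-2}$ reference, which
  is markedly more stable than the normal at the small instrument counts
  (3–30) typical here. Residual scaling is floored at 1 as for IVW.
- **Weighted median**: ratios ordered, weights
  $\hat\gamma_j^2/\mathrm{se}(\hat\Gamma_j)^2$ normalized, estimate
  interpolated from the weighted empirical CDF at 0.5. SE by seeded
  parametric bootstrap (per-SNP betas resampled from their sampling
  distributions; `n_boot = 1000` default, values below 100 warn).
- **Modes**: Gaussian-kernel density over ratios, equal weights (simple) or
  IVW weights (weighted); bandwidth is `bandwidth_factor` (default 1)
  times the modified-MAD rule $0.9\min(\mathrm{sd},\mathrm{mad})k^{-1/5}$,
  maximized on a 512-point grid spanning the ratio range $\pm 3$
  bandwidths. All-identical ratios return that ratio directly.
- **Wald ratio** for single-SNP exposures, first-order SE
  $\mathrm{se}(\hat\Gamma)/|\hat\gamma|$ by default, second-order option
  adding the exposure-noise term.

The screen's significance call uses the Wald ratio when one instrument
survives and IVW otherwise, mirroring how published screens of this kind
adjudicate single- and two-SNP traits; the remaining estimators inform a
concordance flag (weighted median sign-agreeing with IVW at p < 0.05)
rather than gating significance. Multiple-testing correction is off by
default (`p_adjust = "none"`) to mirror those screens' nominal-alpha
convention, with Benjamini–Hochberg one switch away — the choice is logged
in the run metadata.

## Sensitivity analyses

Cochran's $Q$ uses the estimator's own weights and fit (IVW: df $k-1$;
Egger: df $k-2$), with per-SNP contributions that sum to the total. The
heterogeneity *flag* follows the screening rule this pipeline mirrors —
flagged when $Q$ exceeds its df **or** p < 0.1. Note the first clause fires
for roughly half of null samples (the mean of a $\chi^2_{df}$ exceeds its
median); the calibration tests therefore check the p < 0.1 clause, which is
exact at the 10% rate. The Egger intercept test calls directional
pleiotropy at p < 0.05. (Some published descriptions phrase the rule as "a
lack of pleiotropy when p < 0.05", which contradicts both standard usage
and their own reported "no pleiotropy, p > 0.05"; this package implements
the standard rule.) When pleiotropy is detected,
`remove_pleiotropic_snps()` removes one SNP per iteration — the largest
absolute studentized residual from the Egger fit — and re-tests, bounded by
$k-3$ removals. Leave-one-out flags SNPs whose exclusion changes the IVW
estimate's sign or its significance at 0.05. The cross-trait filter drops
SNPs instrumenting more than `max_traits = 2` traits. Reverse MR swaps
roles and runs the full pipeline; its verdict is "no reverse causation"
when the primary p ≥ 0.05, and "untestable" — never a silent pass — when
the outcome GWAS yields no instruments.

## The synthetic-data generator

`simulate_triple()` simulates at the summary level: per-SNP truths are
drawn once, observed betas are sampled around them with the analytic
SD-trait SE $1/\sqrt{2p(1-p)n}$, and p-values are two-sided Wald. This is
what two-sample MR consumes, and it keeps a full calibration run at desk
scale; no individual-level genotypes are simulated. Default sample sizes
(3,757 exposure / 8,299 mediator / 44,889 outcome) mirror the cohort
scales of a typical immune-cell, metabolite and epilepsy screen; effect
scales (`gamma_sd = 0.15`, total effects around 0.1 on the log-odds scale,
mediated proportions around 10%) are chosen to resemble the magnitudes such
screens report, since the underlying trait GWAS do not publish their
effect-size distributions.

Three structural choices matter for interpretation:

- **Mediator-specific instruments.** Exposure instruments reach the
  mediator only through the exposure, so a mediator→outcome MR built on
  them would estimate $\theta_{\rm total}/\beta_1$, not $\beta_2$ — the
  mediator path is unidentified without variants acting on the mediator
  directly. The generator therefore gives the mediator its own instruments
  (`n_med_instruments`, effects `delta_sd`), and `run_mediation()`
  mirrors the mediator-association screen on the $\beta_2$ path by
  excluding mediator instruments associated with the exposure. Both
  exclusions are configurable.
- **Directional pleiotropy per trait-increasing allele.** Pleiotropic
  effects $\alpha_j \sim N(\mu, \sigma^2)$ are sign-aligned with the
  instrument's trait-increasing allele; otherwise a nonzero $\mu$ would
  average out under the sign orientation every Egger fit applies, and no
  estimator could (or should) recover it. `inside_corr` correlates
  $|\alpha_j|$-scale deviations with instrument strength to violate
  InSIDE on demand.
- **Exact allele-coding hazards.** A `frac_flipped` fraction of outcome
  rows is re-expressed by allele swap and/or strand complement (palindromes
  only ever swap — a strand flip is textually invisible for them), and
  EAFs are exact population frequencies, so harmonization can and must
  recover the unflipped analysis exactly; the acceptance suite requires
  agreement to 1e-10.

What the generator does **not** emulate: realistic LD (the block matrices
are stylized), sample overlap between the two GWAS, EAF estimation noise
(so real-data palindrome alignment is harder than simulated), binary-trait
liability-scale effects on the exposure side, and winner's-curse-corrected
discovery. Passing calibration here shows the pipeline's statistics are
right under the stated model, not that any real screen's hits are.

## Numerical choices and problem sizes

The normal 97.5% quantile is kept at full precision (1.959964…) because
printed-CI inversions are sensitive to it. Bootstrap SEs are seeded and
deterministic. The mode grid (512 points) and its ±3-bandwidth span are
fixed documented constants. Degenerate inputs have defined behaviour:
zero-MAD ratio sets return the common ratio; `beta_exp = 0` is a domain
error for the Wald ratio; proportions outside [−1, 1] are flagged as
inconsistent mediation but still reported.

Test and acceptance runs use 1,000–2,000 replicates for calibration rates
and 300 replicates for parameter-recovery grids, with 10–25 instruments per
replicate — sizes at which Monte-Carlo error is small relative to the
tolerances being checked while a full suite completes in a few minutes.
The mediation recovery grid uses an exposure GWAS of n = 20,000 rather
than the 3,757-scale default: recovery-to-truth is a strong-instrument
property, and at n ≈ 3,757 the mediator-association screen preferentially
retains weaker instruments whose regression dilution biases the total
effect by a few percent — a real feature of two-step MR at small cohort
scale that the worked examples display rather than hide.

## Known limitations

- Regression dilution (NOME violation) is not corrected; with weak
  instruments all ratio-based estimators attenuate toward zero.
- The proportion CI assumes independent numerator and denominator; with
  overlapping instrument sets on the $\beta_0$ and $\beta_1$ paths the
  delta-method SE is approximate.
- No MR-PRESSO, Steiger filtering, multivariable MR or
  contamination-mixture models; no reference-panel strand inference; no
  remote GWAS accession fetching. Interfaces are R functions plus the
  numbered analysis drivers — the workflow is not wrapped in a shell CLI.
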