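new_mr_result <- function(method, n_snp, beta, se, pvalue, extra = list()) {
  orci <- to_or(beta, se)
  structure(list(method = method, n_snp = n_snp, beta = beta, se = se,
                 pvalue = pvalue, or = orci$or, ci_low = orci$ci_low,
                 ci_high = orci$ci_high, extra = extra),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s (%d SNPs): beta = %.4f (se %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
              x$method, x$n_snp, x$beta, x$se, x$or, x$ci_low, x$ci_high, x$pvalue))
  invisible(x)
}

#' Convert a log-odds estimate to an odds ratio with 95% CI and p-value
#'
#' @param beta Log-odds causal estimate.
#' @param se Its standard error (positive).
#' @return List with `or = exp(beta)`, `ci_low`/`ci_high`
#'   (`exp(beta -/+ 1.959964 se)`) and a two-sided normal `pvalue`.
#' @export
to_or <- function(beta, se) {
  stopifnot(se > 0)
  list(or = exp(beta), ci_low = exp(beta - Z95 * se), ci_high = exp(beta + Z95 * se),
       pvalue = wald_p(beta, se))
}

#' Recover log-odds and SE from a printed OR and 95% CI
#'
#' Inverse of [to_or()]: `beta = log(or)`, `se = (log(ci_high) -
#' log(ci_low)) / (2 * 1.959964)`.
#'
#' @param or,ci_low,ci_high Odds ratio and its 95% confidence bounds.
#' @return List with `beta`, `se` and the implied two-sided normal `pvalue`.
#' @export
or_to_beta <- function(or, ci_low, ci_high) {
  se <- (log(ci_high) - log(ci_low)) / (2 * Z95)
  list(beta = log(or), se = se, pvalue = wald_p(log(or), se))
}

#' Wald ratio estimate from a single instrument
#'
#' `beta = beta_out / beta_exp`; the default SE is the first-order delta
#' approximation `se_out / |beta_exp|`, the `"second_order"` option adds the
#' exposure-uncertainty term
#' `sqrt(se_out^2/beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4)`.
#'
#' @param inst One-row `harmonized` tibble (or any list with `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`).
#' @param se_method `"first_order"` (default) or `"second_order"`.
#' @return An `mr_result`.
#' @export
wald_ratio <- function(inst, se_method = c("first_order", "second_order")) {
  se_method <- match.arg(se_method)
  bx <- inst$beta_exp[1]; by <- inst$beta_out[1]
  sx <- inst$se_exp[1]; sy <- inst$se_out[1]
  if (bx == 0) stop("Wald ratio undefined for beta_exp = 0", call. = FALSE)
  b <- by / bx
  se <- if (se_method == "first_order") sy / abs(bx) else
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  new_mr_result("wald_ratio", 1L, b, se, wald_p(b, se))
}

#' Inverse-variance weighted estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/se_out^2`:
#' `beta = sum(bx by / sy^2) / sum(bx^2 / sy^2)`. The fixed-effect SE is
#' `sqrt(1 / sum(bx^2/sy^2))`; the default multiplicative random-effects
#' model inflates it by `max(1, sqrt(Q/(k-1)))` where `Q` is Cochran's
#' statistic, so heterogeneity widens but never narrows the interval.
#' P-values are two-sided normal.
#'
#' @param instruments `harmonized` tibble with at least 2 rows.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @param allow_single Permit a one-instrument fit (which reduces exactly to
#'   the Wald ratio); off by default so single-SNP traits are routed through
#'   [wald_ratio()] deliberately.
#' @return An `mr_result`; `extra` carries `q`, `q_df` and the scaling.
#' @export
ivw <- function(instruments, model = c("multiplicative_random", "fixed"),
                allow_single = FALSE) {
  model <- match.arg(model)
  k <- nrow(instruments)
  if (k < 2 && !allow_single) {
    stop("IVW needs at least 2 instruments; use wald_ratio() for a single SNP",
         call. = FALSE)
  }
  if (k < 1) stop("no instruments", call. = FALSE)
  bx <- instruments$beta_exp; by <- instruments$beta_out
  w <- 1 / instruments$se_out^2
  b <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  q <- sum(w * (by - b * bx)^2)
  scaling <- if (model == "multiplicative_random" && k > 1) max(1, sqrt(q / (k - 1))) else 1
  se <- se_fixed * scaling
  new_mr_result("ivw", k, b, se, wald_p(b, se),
                extra = list(model = model, q = q, q_df = k - 1, scaling = scaling))
}

# orient instruments so every exposure effect is positive (joint sign flip
# leaves every ratio unchanged); required by Egger, harmless elsewhere
orient_positive <- function(instruments) {
  s <- ifelse(instruments$beta_exp < 0, -1, 1)
  instruments$beta_exp <- s * instruments$beta_exp
  instruments$beta_out <- s * instruments$beta_out
  instruments
}

#' MR-Egger regression
#'
#' Instruments are oriented so all exposure effects are positive, then
#' outcome effects are regressed on exposure effects with an intercept,
#' weights `1/se_out^2`. The slope is the pleiotropy-robust causal estimate;
#' the intercept estimates the average directional pleiotropic effect.
#' Standard errors use multiplicative residual scaling floored at 1;
#' inference uses a t distribution with `k - 2` df, which is markedly more
#' stable than the normal at the small instrument counts typical of
#' molecular-trait MR.
#'
#' @param instruments `harmonized` tibble with at least 3 rows.
#' @return An `mr_result`; `extra` holds `intercept`, `intercept_se`,
#'   `intercept_p`, the residual heterogeneity `q` (df `k - 2`) and the
#'   scaling applied.
#' @export
egger <- function(instruments) {
  k <- nrow(instruments)
  if (k < 3) stop("MR-Egger needs at least 3 instruments", call. = FALSE)
  d <- orient_positive(instruments)
  w <- 1 / d$se_out^2
  fit <- stats::lm(beta_out ~ beta_exp, data = d, weights = w)
  q <- sum(w * stats::residuals(fit)^2)
  scaling <- max(1, sqrt(q / (k - 2)))
  sm <- summary(fit)
  # lm scales coefficient SEs by the residual sd; replace by our floored one
  se_unit <- sm$coefficients[, "Std. Error"] / sm$sigma
  slope <- unname(stats::coef(fit)["beta_exp"])
  slope_se <- unname(se_unit["beta_exp"]) * scaling
  icpt <- unname(stats::coef(fit)["(Intercept)"])
  icpt_se <- unname(se_unit["(Intercept)"]) * scaling
  p_slope <- 2 * pt(-abs(slope / slope_se), df = k - 2)
  p_icpt <- 2 * pt(-abs(icpt / icpt_se), df = k - 2)
  new_mr_result("egger", k, slope, slope_se, p_slope,
                extra = list(intercept = icpt, intercept_se = icpt_se,
                             intercept_p = p_icpt, q = q, q_df = k - 2,
                             scaling = scaling))
}

weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(r[1])
  if (cum[length(cum)] <= 0.5) return(r[length(r)])
  i <- max(which(cum < 0.5))
  r[i] + (r[i + 1] - r[i]) * (0.5 - cum[i]) / (cum[i + 1] - cum[i])
}

boot_se <- function(instruments, n_boot, seed, point_fun) {
  set.seed(seed)
  k <- nrow(instruments)
  est <- vapply(seq_len(n_boot), function(b) {
    bx <- rnorm(k, instruments$beta_exp, instruments$se_exp)
    by <- rnorm(k, instruments$beta_out, instruments$se_out)
    point_fun(by / bx, bx^2 / instruments$se_out^2)
  }, numeric(1))
  sd(est)
}

#' Weighted-median estimate
#'
#' Per-SNP Wald ratios are ordered and the estimate is the linear
#' interpolation of the weighted empirical CDF at 0.5, with weights
#' `beta_exp^2 / se_out^2`. Consistent when at least half the weight comes
#' from valid instruments. The SE comes from a seeded parametric bootstrap
#' that resamples per-SNP betas from their sampling distributions.
#'
#' @param instruments `harmonized` tibble with at least 3 rows.
#' @param n_boot Bootstrap draws (default 1000; fewer than 100 draws warns).
#' @param seed Bootstrap seed (mandatory for reproducibility).
#' @return An `mr_result`.
#' @export
weighted_median <- function(instruments, n_boot = 1000, seed = 1) {
  k <- nrow(instruments)
  if (k < 3) stop("weighted median needs at least 3 instruments", call. = FALSE)
  if (n_boot < 100) warning("n_boot < 100 gives an unstable bootstrap SE")
  ratios <- instruments$beta_out / instruments$beta_exp
  weights <- instruments$beta_exp^2 / instruments$se_out^2
  b <- weighted_median_point(ratios, weights)
  se <- boot_se(instruments, n_boot, seed, weighted_median_point)
  new_mr_result("weighted_median", k, b, se, wald_p(b, se))
}

mode_point <- function(ratios, weights, bandwidth_factor = 1, grid_n = 512) {
  if (length(unique(ratios)) == 1) return(ratios[1])
  md <- mad(ratios)
  s <- 0.9 * min(sd(ratios), if (md > 0) md else sd(ratios)) * length(ratios)^(-1 / 5)
  h <- bandwidth_factor * s
  if (h <= 0) return(ratios[which.max(weights)])
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = grid_n)
  w <- weights / sum(weights)
  dens <- colSums(w * stats::dnorm(outer(ratios, grid, "-") / h))
  grid[which.max(dens)]
}

#' Mode-based estimate (simple and weighted)
#'
#' The estimate is the maximizer of a Gaussian-kernel density over the
#' per-SNP Wald ratios — equal kernel weights for the simple mode, weights
#' `beta_exp^2 / se_out^2` for the weighted mode. The bandwidth is
#' `bandwidth_factor` times a modified median-absolute-deviation rule
#' (`0.9 min(sd, mad) k^(-1/5)`); the density is maximized on a 512-point
#' grid spanning the ratio range plus 3 bandwidths. Consistent when the
#' largest group of instruments sharing a ratio is valid (ZEMPA). SE by
#' parametric bootstrap as in [weighted_median()].
#'
#' @param instruments `harmonized` tibble with at least 3 rows.
#' @param weighted Use inverse-variance weights (`TRUE`) or equal weights.
#' @param bandwidth_factor Multiplier on the bandwidth rule (default 1).
#' @param n_boot,seed Bootstrap controls.
#' @return An `mr_result` with method `simple_mode` or `weighted_mode`.
#' @export
mode_estimate <- function(instruments, weighted = TRUE, bandwidth_factor = 1,
                          n_boot = 1000, seed = 1) {
  k <- nrow(instruments)
  if (k < 3) stop("mode estimator needs at least 3 instruments", call. = FALSE)
  if (n_boot < 100) warning("n_boot < 100 gives an unstable bootstrap SE")
  ratios <- instruments$beta_out / instruments$beta_exp
  weights <- if (weighted) instruments$beta_exp^2 / instruments$se_out^2 else
    rep(1, k)
  b <- mode_point(ratios, weights, bandwidth_factor)
  pf <- if (weighted) {
    function(r, w) mode_point(r, w, bandwidth_factor)
  } else {
    function(r, w) mode_point(r, rep(1, length(r)), bandwidth_factor)
  }
  se <- boot_se(instruments, n_boot, seed, pf)
  new_mr_result(if (weighted) "weighted_mode" else "simple_mode", k, b, se,
                wald_p(b, se))
}

#' Run every applicable MR estimator on an instrument set
#'
#' Applies the Wald ratio for a single instrument, IVW from 2 instruments,
#' and additionally MR-Egger, weighted median and both modes from 3.
#'
#' @param instruments `harmonized` tibble.
#' @param ivw_model Passed to [ivw()].
#' @param n_boot,seed Bootstrap controls for median/mode.
#' @return Tibble with one row per method: `method, n_snp, beta, se, pvalue,
#'   or, ci_low, ci_high` plus an `egger_intercept` column (NA elsewhere).
#' @export
mr_all_methods <- function(instruments, ivw_model = "multiplicative_random",
                           n_boot = 1000, seed = 1) {
  k <- nrow(instruments)
  if (k == 0) stop("no instruments", call. = FALSE)
  res <- list()
  if (k == 1) {
    res$wald <- wald_ratio(instruments)
  } else {
    res$ivw <- ivw(instruments, model = ivw_model)
    if (k >= 3) {
      res$egger <- egger(instruments)
      res$wm <- weighted_median(instruments, n_boot = n_boot, seed = seed)
      res$sm <- mode_estimate(instruments, weighted = FALSE, n_boot = n_boot,
                              seed = seed + 1)
      res$wmode <- mode_estimate(instruments, weighted = TRUE, n_boot = n_boot,
                                 seed = seed + 2)
    }
  }
  dplyr::bind_rows(lapply(res, function(r) {
    tibble::tibble(method = r$method, n_snp = r$n_snp, beta = r$beta, se = r$se,
                   pvalue = r$pvalue, or = r$or, ci_low = r$ci_low,
                   ci_high = r$ci_high,
                   egger_intercept = if (r$method == "egger") r$extra$intercept else NA_real_)
  }))
}
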