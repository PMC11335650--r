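test_that("Wald ratio matches the delta formula and handles edge cases", {
  inst <- make_harmonized(bx = 0.1, by = 0.05, sy = 0.02, sx = 0.01)
  w <- wald_ratio(inst)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.2)

  null <- wald_ratio(make_harmonized(0.1, 0, 0.02))
  expect_equal(null$beta, 0)
  expect_equal(null$or, 1)

  expect_error(wald_ratio(make_harmonized(0, 0.05, 0.02)), "beta_exp = 0")
})

test_that("second-order Wald SE agrees with a parametric bootstrap on strong instruments", {
  inst <- make_harmonized(bx = 0.2, by = 0.08, sy = 0.01, sx = 0.005)
  w2 <- wald_ratio(inst, se_method = "second_order")
  set.seed(99)
  draws <- rnorm(2e5, 0.08, 0.01) / rnorm(2e5, 0.2, 0.005)
  expect_lt(abs(w2$se - sd(draws)) / sd(draws), 0.05)
})

test_that("IVW reproduces the closed-form hand computation", {
  inst <- make_harmonized(bx = c(0.1, 0.2, 0.4), by = c(0.05, 0.10, 0.20),
                          sy = rep(0.02, 3))
  fixed <- ivw(inst, model = "fixed")
  re <- ivw(inst, model = "multiplicative_random")
  expect_equal(fixed$beta, 0.5)
  expect_equal(fixed$se, sqrt(1 / 525))
  expect_equal(fixed$se, 0.04364358, tolerance = 1e-7)
  expect_equal(re$extra$q, 0)        # exact fit, both models agree
  expect_equal(re$se, fixed$se)
})

test_that("IVW equals a single shared ratio exactly and matches GWLS algebra", {
  inst <- make_harmonized(bx = c(0.1, 0.3, 0.7), by = 0.37 * c(0.1, 0.3, 0.7),
                          sy = c(0.01, 0.03, 0.02))
  expect_equal(ivw(inst)$beta, 0.37, tolerance = 1e-14)

  set.seed(101)
  for (i in 1:100) {
    k <- sample(2:12, 1)
    inst <- make_harmonized(bx = rnorm(k, 0, 0.3), by = rnorm(k, 0, 0.1),
                            sy = runif(k, 0.01, 0.1))
    w <- 1 / inst$se_out^2
    x <- inst$beta_exp
    oracle_b <- solve(t(x) %*% (w * x), t(x) %*% (w * inst$beta_out))[1, 1]
    oracle_se <- sqrt(solve(t(x) %*% (w * x))[1, 1])
    fit <- ivw(inst, model = "fixed")
    expect_equal(fit$beta, oracle_b, tolerance = 1e-10)
    expect_equal(fit$se, oracle_se, tolerance = 1e-10)
  }
})

test_that("a forced single-instrument IVW reduces to the Wald ratio", {
  inst <- make_harmonized(bx = 0.15, by = 0.06, sy = 0.02)
  expect_error(ivw(inst), "wald_ratio")
  forced <- ivw(inst, allow_single = TRUE)
  w <- wald_ratio(inst)
  expect_equal(forced$beta, w$beta)
  expect_equal(forced$se, w$se)
})

test_that("Egger recovers slope and intercept exactly on an exact-fit construction", {
  bx <- c(0.1, 0.25, 0.4)
  inst <- make_harmonized(bx = bx, by = 0.01 + 0.4 * bx,
                          sy = c(0.02, 0.05, 0.03))
  fit <- egger(inst)
  expect_equal(fit$beta, 0.4, tolerance = 1e-12)
  expect_equal(fit$extra$intercept, 0.01, tolerance = 1e-12)
  expect_equal(fit$extra$q, 0, tolerance = 1e-20)
  expect_error(egger(inst[1:2, ]), "at least 3")
})

test_that("Egger intercept is calibrated at zero and recovers directional pleiotropy", {
  run_mean_intercept <- function(pleio_mean, n_rep, seed0) {
    est <- vapply(seq_len(n_rep), function(r) {
      cfg <- calib_config(seed = seed0 + r, theta = 0.1)
      cfg$n_instruments <- 20
      cfg$pleio_mean <- pleio_mean
      cfg$pleio_sd <- 0.01
      sim <- simulate_triple(cfg)
      egger(pipeline_instruments(sim))$extra$intercept
    }, numeric(1))
    c(mean = mean(est), mc_se = sd(est) / sqrt(n_rep))
  }
  null <- run_mean_intercept(0, 300, 60000)
  expect_lt(abs(null["mean"]), 3 * null["mc_se"])
  dir <- run_mean_intercept(0.02, 300, 70000)
  expect_lt(abs(dir["mean"] - 0.02), 3 * dir["mc_se"])
})

test_that("weighted median interpolates the weighted CDF at one half", {
  inst <- make_harmonized(bx = c(0.1, 0.1, 0.1),
                          by = 0.1 * c(0.4, 0.5, 0.6), sy = rep(0.02, 3))
  fit <- weighted_median(inst, n_boot = 200, seed = 5)
  expect_equal(fit$beta, 0.5, tolerance = 1e-12)

  again <- weighted_median(inst, n_boot = 200, seed = 5)
  expect_identical(fit$se, again$se)  # seeded bootstrap is deterministic
  expect_warning(weighted_median(inst, n_boot = 50, seed = 5), "n_boot")
})

test_that("weighted median resists up to half invalid instruments", {
  # 6 valid instruments at ratio 0.3 holding the weight majority, 4 invalid
  # with large balanced pleiotropy (the median's validity condition)
  hits <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    set.seed(3000 + r)
    bx <- rep(0.2, 10)
    by <- 0.3 * bx
    by[7:8] <- by[7:8] + 0.15   # pleiotropic shifts, both directions
    by[9:10] <- by[9:10] - 0.15
    sy <- rep(0.01, 10)
    inst <- make_harmonized(bx = bx, by = rnorm(10, by, sy), sy = sy)
    fit <- weighted_median(inst, n_boot = 200, seed = r)
    ci <- c(fit$beta - 1.959964 * fit$se, fit$beta + 1.959964 * fit$se)
    if (ci[1] <= 0.3 && 0.3 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("mode estimators find the plurality cluster", {
  inst0 <- make_harmonized(bx = rep(0.2, 4), by = rep(0.2 * 0.3, 4),
                           sy = rep(0.02, 4))
  expect_equal(mode_estimate(inst0, n_boot = 150, seed = 1)$beta, 0.3)

  bx <- rep(0.2, 8)
  ratios <- c(rep(0.5, 6), rep(2.0, 2))
  inst <- make_harmonized(bx = bx, by = ratios * bx, sy = rep(0.02, 8))
  sm <- mode_estimate(inst, weighted = FALSE, n_boot = 150, seed = 2)
  expect_lt(abs(sm$beta - 0.5), 0.1)

  # equal weights make the weighted and simple modes coincide
  wm <- mode_estimate(inst, weighted = TRUE, n_boot = 150, seed = 2)
  expect_equal(wm$beta, sm$beta)
})

test_that("OR conversion round-trips and honours its invariants", {
  res <- to_or(0, 0.1)
  expect_equal(res$or, 1)
  expect_equal(res$pvalue, 1)

  conv <- to_or(-0.23, 0.07)
  back <- or_to_beta(conv$or, conv$ci_low, conv$ci_high)
  expect_equal(back$beta, -0.23, tolerance = 1e-12)
  expect_equal(back$se, 0.07, tolerance = 1e-12)
  expect_true(conv$ci_low < conv$or && conv$or < conv$ci_high)
})

test_that("all estimators are equivariant under joint per-SNP sign flips", {
  set.seed(77)
  bx <- rnorm(8, 0, 0.3)
  by <- 0.25 * bx + rnorm(8, 0, 0.02)
  sy <- runif(8, 0.01, 0.04)
  inst <- make_harmonized(bx = bx, by = by, sy = sy)
  s <- sample(c(-1, 1), 8, replace = TRUE)
  flipped <- inst
  flipped$beta_exp <- s * bx
  flipped$beta_out <- s * by

  expect_equal(ivw(flipped)$beta, ivw(inst)$beta, tolerance = 1e-12)
  expect_equal(egger(flipped)$beta, egger(inst)$beta, tolerance = 1e-12)
  expect_equal(weighted_median(flipped, n_boot = 100, seed = 1)$beta,
               weighted_median(inst, n_boot = 100, seed = 1)$beta,
               tolerance = 1e-12)
  expect_equal(mode_estimate(flipped, n_boot = 100, seed = 1)$beta,
               mode_estimate(inst, n_boot = 100, seed = 1)$beta,
               tolerance = 1e-9)
})

test_that("fixed-effects IVW SE never exceeds the multiplicative-random SE", {
  set.seed(88)
  for (i in 1:50) {
    k <- sample(2:15, 1)
    inst <- make_harmonized(bx = rnorm(k, 0, 0.3),
                            by = rnorm(k, 0, 0.05), sy = runif(k, 0.01, 0.05))
    expect_lte(ivw(inst, "fixed")$se, ivw(inst, "multiplicative_random")$se)
  }
})

test_that("all six estimators recover the true effect on strong clean instruments", {
  n_rep <- 300
  theta <- 0.15
  methods <- c("ivw", "egger", "weighted_median", "simple_mode", "weighted_mode")
  est <- matrix(NA_real_, n_rep, length(methods) + 1,
                dimnames = list(NULL, c(methods, "wald_ratio")))
  for (r in seq_len(n_rep)) {
    cfg <- calib_config(seed = 80000 + r, theta = theta)
    cfg$n_instruments <- 12
    sim <- simulate_triple(cfg)
    inst <- pipeline_instruments(sim)
    res <- mr_all_methods(inst, n_boot = 100, seed = r)
    est[r, res$method] <- res$beta
    est[r, "wald_ratio"] <- wald_ratio(inst[1, ])$beta
  }
  for (m in colnames(est)) {
    mc_se <- sd(est[, m]) / sqrt(n_rep)
    expect_lt(abs(mean(est[, m]) - theta), 3 * mc_se,
              label = paste("bias of", m, "exceeds 3 MC SEs"))
  }
})
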