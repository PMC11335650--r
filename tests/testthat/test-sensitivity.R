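test_that("Cochran's Q is zero for homogeneous ratios and follows the flag rule", {
  inst <- make_harmonized(bx = c(0.1, 0.2, 0.3), by = 0.4 * c(0.1, 0.2, 0.3),
                          sy = c(0.01, 0.02, 0.015))
  q <- cochran_q(inst, "ivw")
  expect_equal(q$q, 0, tolerance = 1e-20)
  expect_equal(q$df, 2)
  expect_false(q$flagged)

  set.seed(21)
  for (i in 1:20) {
    k <- sample(3:10, 1)
    rnd <- make_harmonized(bx = rnorm(k, 0, 0.3), by = rnorm(k, 0, 0.05),
                           sy = runif(k, 0.01, 0.05))
    for (m in c("ivw", "egger")) {
      qq <- cochran_q(rnd, m)
      expect_identical(qq$flagged, (qq$q > qq$df) || (qq$pvalue < 0.1))
      expect_equal(qq$df, k - if (m == "ivw") 1 else 2)
      # per-SNP contributions decompose the total
      expect_equal(sum(qq$q_contrib), qq$q, tolerance = 1e-10)
    }
  }
})

test_that("Q needs enough instruments", {
  inst <- make_harmonized(bx = 0.1, by = 0.05, sy = 0.02)
  expect_error(cochran_q(inst, "ivw"), "at least 2")
  expect_error(cochran_q(make_harmonized(c(0.1, 0.2), c(0.05, 0.1), c(0.02, 0.02)),
                         "egger"), "at least 3")
})

test_that("Egger intercept test is null on exact zero-intercept fits", {
  bx <- c(0.1, 0.2, 0.35, 0.5)
  inst <- make_harmonized(bx = bx, by = 0.3 * bx, sy = rep(0.02, 4))
  t0 <- egger_intercept_test(inst)
  expect_equal(t0$intercept, 0, tolerance = 1e-12)
  expect_false(t0$pleiotropic)
})

test_that("directional pleiotropy is detected in a majority of replicates", {
  n_rep <- 150
  detected <- vapply(seq_len(n_rep), function(r) {
    cfg <- calib_config(seed = 90000 + r, theta = 0.1)
    cfg$n_instruments <- 20
    cfg$pleio_mean <- 0.05
    cfg$pleio_sd <- 0.01
    sim <- simulate_triple(cfg)
    egger_intercept_test(pipeline_instruments(sim))$pleiotropic
  }, logical(1))
  expect_gt(mean(detected), 0.5)
})

test_that("pleiotropic-SNP removal terminates within k - 3 removals", {
  set.seed(31)
  bx <- runif(10, 0.1, 0.4)
  by <- 0.3 * bx + rnorm(10, 0, 0.005)
  by[1:3] <- by[1:3] + 0.2  # planted outliers driving the intercept
  inst <- make_harmonized(bx = bx, by = by, sy = rep(0.01, 10))
  res <- remove_pleiotropic_snps(inst)
  expect_lte(length(res$removed), 10 - 3)
  expect_equal(nrow(res$instruments) + length(res$removed), 10)
  expect_true(!res$test$pleiotropic || nrow(res$instruments) == 3)
})

test_that("leave-one-out has k + 1 rows and matches direct IVW refits", {
  inst <- make_harmonized(bx = c(0.1, 0.2, 0.3), by = c(0.04, 0.09, 0.12),
                          sy = c(0.01, 0.02, 0.015))
  loo <- leave_one_out(inst)
  expect_equal(nrow(loo), 4)
  expect_identical(loo$snp_id[4], "<all>")
  for (i in 1:3) {
    direct <- ivw(inst[-i, ])
    expect_equal(loo$beta[i], direct$beta, tolerance = 1e-14)
    expect_equal(loo$se[i], direct$se, tolerance = 1e-14)
  }
  expect_error(leave_one_out(inst[1:2, ]), "at least 3")
})

test_that("leave-one-out flags only the planted influential SNP", {
  # three concordant instruments plus one outlier that flips the pooled sign
  inst <- make_harmonized(bx = c(0.2, 0.25, 0.3, 0.22),
                          by = c(0.004, 0.005, 0.006, -0.30),
                          sy = rep(0.01, 4))
  loo <- leave_one_out(inst)
  expect_true(loo$influential[loo$snp_id == "rs004"])
  expect_false(any(loo$influential[loo$snp_id %in% c("rs001", "rs002", "rs003")]))

  homog <- make_harmonized(bx = c(0.1, 0.2, 0.3), by = 0.4 * c(0.1, 0.2, 0.3),
                           sy = rep(0.02, 3))
  loo2 <- leave_one_out(homog)
  expect_equal(loo2$beta, rep(0.4, 4), tolerance = 1e-12)
})

test_that("cross-trait filter drops SNPs tied to more than max_traits traits", {
  assoc <- tibble::tibble(
    snp_id = c("rs1", "rs1", "rs1", "rs2", "rs2", "rs3"),
    trait_id = c("m1", "m2", "m3", "m1", "m2", "m1"))
  rep <- cross_trait_filter(assoc, max_traits = 2)
  expect_identical(rep$dropped$snp_id, "rs1")     # 3 metabolites: dropped
  expect_setequal(rep$kept, c("rs2", "rs3"))      # 2 and 1: kept

  set.seed(41)
  for (i in 1:5) {
    rnd <- tibble::tibble(snp_id = sample(sprintf("rs%d", 1:30), 200, TRUE),
                          trait_id = sample(sprintf("m%d", 1:15), 200, TRUE))
    rep_r <- cross_trait_filter(rnd, max_traits = 3)
    counts <- tapply(rnd$trait_id, rnd$snp_id, function(x) length(unique(x)))
    expect_setequal(rep_r$dropped$snp_id, names(counts)[counts > 3])
  }
})

test_that("cross-trait filtering commutes with instrument selection", {
  sim <- simulate_triple(sim_config(n_instruments = 15, seed = 44,
                                    gamma_sd = 0.3))
  assoc <- tibble::tibble(
    snp_id = rep(sim$exposure$SNP[1:6], times = c(3, 3, 1, 1, 4, 2)),
    trait_id = sprintf("m%d", c(1:3, 1:3, 1, 1, 1:4, 1:2)))
  keep_ids <- function(tab) tab$SNP

  a <- select_instruments(sim$exposure, assume_independent = TRUE)$instruments
  a <- a[!(a$SNP %in% cross_trait_filter(assoc)$dropped$snp_id), ]

  pre <- sim$exposure[!(sim$exposure$SNP %in% cross_trait_filter(assoc)$dropped$snp_id), ]
  b <- select_instruments(pre, assume_independent = TRUE)$instruments
  expect_identical(keep_ids(a), keep_ids(b))
})

test_that("reverse MR reports untestable outcomes and calibrated null verdicts", {
  # an outcome GWAS with no signal cannot be tested for reverse causation
  null_tab <- make_sumstats(20, p = runif(20, 0.2, 1), seed = 51)
  expo <- make_sumstats(20, seed = 52)
  rv <- reverse_mr(null_tab, expo, assume_independent = TRUE)
  expect_identical(rv$status, "untestable")

  # with a truly null reverse effect the verdict is "no reverse causation"
  # at roughly the nominal rate
  n_rep <- 100
  verdicts <- vapply(seq_len(n_rep), function(r) {
    sim <- simulate_triple(calib_config(seed = 100000 + r))
    reverse_mr(sim$exposure, sim$outcome, assume_independent = TRUE)$verdict
  }, character(1))
  expect_gte(mean(verdicts == "no_reverse_causation"), 0.88)
})

test_that("reverse MR detects a true reverse effect", {
  n_rep <- 30
  detected <- vapply(seq_len(n_rep), function(r) {
    sim <- simulate_triple(calib_config(seed = 110000 + r, theta = 0.3))
    reverse_mr(sim$exposure, sim$outcome,
               assume_independent = TRUE)$verdict == "reverse_causation"
  }, logical(1))
  expect_gt(mean(detected), 0.5)
})
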