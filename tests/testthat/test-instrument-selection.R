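test_that("p-value filter keeps exactly the sub-threshold rows", {
  tab <- make_sumstats(2, p = c(5e-6, 2e-5))
  rep <- filter_by_pvalue(tab, 1e-5)
  expect_identical(rep$kept, "rs001")
  expect_identical(rep$dropped$snp_id, "rs002")
  expect_identical(rep$dropped$reason, "above_p_threshold")

  expect_length(filter_by_pvalue(tab, 1)$kept, 2)  # everything sub-threshold

  # brute-force agreement on a large random table
  big <- make_sumstats(1000, p = runif(1000), seed = 42)
  thr <- 0.3
  rep2 <- filter_by_pvalue(big, thr)
  expect_identical(rep2$kept, big$SNP[big$P < thr])
  expect_setequal(c(rep2$kept, rep2$dropped$snp_id), big$SNP)
})

test_that("greedy clumping follows the hand-traced execution", {
  tab <- make_sumstats(3, p = c(1e-8, 1e-7, 1e-6))
  tab$POS <- c(1e6, 1e6 + 10e3, 5e7)  # rs2 sits 10 kb from rs1
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.5
  dimnames(m) <- list(tab$SNP, tab$SNP)
  rep <- ld_clump(tab, as_ld_matrix(m), r2_threshold = 0.001, window_kb = 10000)
  expect_setequal(rep$kept, c("rs001", "rs003"))
  expect_identical(rep$dropped$snp_id, "rs002")
  expect_identical(rep$dropped$reason, "clumped")
})

test_that("clumping respects the window and an identity LD matrix keeps all", {
  tab <- make_sumstats(2, p = c(1e-8, 1e-7))
  tab$POS <- c(1e6, 1e6 + 20000e3)  # 20,000 kb apart
  m <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(tab$SNP, tab$SNP))
  rep <- ld_clump(tab, as_ld_matrix(m), r2_threshold = 0.001, window_kb = 10000)
  expect_setequal(rep$kept, tab$SNP)  # correlated but outside the window

  tab2 <- make_sumstats(6, seed = 9)
  ident <- diag(6)
  dimnames(ident) <- list(tab2$SNP, tab2$SNP)
  expect_setequal(ld_clump(tab2, as_ld_matrix(ident))$kept, tab2$SNP)
})

test_that("clumping is row-order invariant and breaks p ties lexicographically", {
  tab <- make_sumstats(4, p = c(1e-8, 1e-8, 1e-6, 1e-7))
  tab$POS <- c(1e6, 1.5e6, 2e6, 2.5e6)
  m <- matrix(0.9, 4, 4); diag(m) <- 1
  dimnames(m) <- list(tab$SNP, tab$SNP)
  ld <- as_ld_matrix(m)
  rep_fwd <- ld_clump(tab, ld)
  shuffled <- tab[c(3, 1, 4, 2), ]
  rep_shuf <- ld_clump(shuffled, ld)
  expect_setequal(rep_fwd$kept, rep_shuf$kept)
  expect_identical(rep_fwd$kept, "rs001")  # tie with rs002 broken by id
})

test_that("clumping refuses silent independence assumptions", {
  tab <- make_sumstats(3)
  expect_error(ld_clump(tab, NULL), "assume_independent")
  expect_setequal(ld_clump(tab, NULL, assume_independent = TRUE)$kept, tab$SNP)
  ld <- as_ld_matrix(structure(diag(2), dimnames = list(tab$SNP[1:2], tab$SNP[1:2])))
  expect_error(ld_clump(tab, ld), "rs003")
})

test_that("the F statistic matches the printed formula and flags weakness", {
  f1 <- f_statistic(0.02, 10000, 10)
  expect_equal(f1$f_stat, 0.02 * 9989 / (0.98 * 10))
  expect_equal(f1$f_stat, 20.38571, tolerance = 1e-6)
  expect_true(f1$strong)

  f2 <- f_statistic(0.05, 461, 5)
  expect_equal(f2$f_stat, 0.05 * 455 / (0.95 * 5), tolerance = 1e-12)
  expect_equal(f2$f_stat, 4.789474, tolerance = 1e-6)
  expect_false(f2$strong)

  expect_equal(f_statistic(0, 100, 3)$f_stat, 0)
  expect_error(f_statistic(1, 100, 3), "r2_total")
  expect_error(f_statistic(0.1, 4, 3), "exceed")
})

test_that("F is monotone: increasing in r2 and n, decreasing in k", {
  r2 <- seq(0.01, 0.5, by = 0.05)
  f_r2 <- vapply(r2, function(x) f_statistic(x, 5000, 10)$f_stat, numeric(1))
  expect_true(all(diff(f_r2) > 0))
  ns <- seq(100, 5000, by = 250)
  f_n <- vapply(ns, function(x) f_statistic(0.05, x, 10)$f_stat, numeric(1))
  expect_true(all(diff(f_n) > 0))
  ks <- 1:20
  f_k <- vapply(ks, function(x) f_statistic(0.05, 5000, x)$f_stat, numeric(1))
  expect_true(all(diff(f_k) < 0))
})

test_that("per-SNP r2 matches the SD-trait formula and the generative variance", {
  expect_equal(per_snp_r2(0.5, 0), 0)
  expect_equal(per_snp_r2(0.5, 0.1), 0.005)

  # summed r2 over strong instruments approximates the variance the
  # generator actually assigned (2 p (1-p) gamma^2)
  cfg <- sim_config(n_instruments = 40, n_med_instruments = 0, n_null_snps = 0,
                    gamma_sd = 0.3, n_exp = 2e5, frac_palindromic = 0,
                    frac_flipped = 0, seed = 6)
  sim <- simulate_triple(cfg)
  est <- sum(per_snp_r2(sim$exposure$EAF, sim$exposure$BETA))
  true_r2 <- sum(2 * sim$exposure$EAF * (1 - sim$exposure$EAF) * sim$truth$gamma^2)
  expect_lt(abs(est - true_r2) / true_r2, 0.1)
})

test_that("mediator-associated instruments are excluded, missing ones error", {
  inst <- make_sumstats(3)
  med <- make_sumstats(3, p = c(1e-6, 0.5, 0.2))
  rep <- exclude_mediator_associated(inst, med, threshold = 1e-5)
  expect_identical(rep$dropped$snp_id, "rs001")
  expect_identical(rep$dropped$reason, "mediator_associated")
  expect_setequal(rep$kept, c("rs002", "rs003"))

  expect_error(exclude_mediator_associated(inst, med[1:2, ]), "rs003")

  # brute-force agreement on random fixtures
  for (s in 1:5) {
    inst_r <- make_sumstats(50, seed = s)
    med_r <- make_sumstats(50, p = runif(50), seed = s + 100)
    rep_r <- exclude_mediator_associated(inst_r, med_r, threshold = 0.3)
    expect_setequal(rep_r$kept, inst_r$SNP[med_r$P[match(inst_r$SNP, med_r$SNP)] >= 0.3])
  }
})

test_that("set-level F filtering drops weak sets; per-SNP mode drops weak SNPs", {
  weak <- make_sumstats(3, beta = c(0.01, 0.012, 0.009), seed = 3)
  weak$P <- rep(1e-6, 3)  # pass the p screen, fail the F screen
  res <- select_instruments(weak, assume_independent = TRUE)
  expect_equal(nrow(res$instruments), 0)
  expect_true(all(res$report$dropped$reason[res$report$dropped$snp_id %in% weak$SNP]
                  == "weak_f"))

  mixed <- make_sumstats(4, beta = c(0.3, 0.25, 0.01, 0.3), seed = 4)
  mixed$P <- rep(1e-8, 4)
  res2 <- select_instruments(mixed, assume_independent = TRUE, f_mode = "per_snp")
  expect_false("rs003" %in% res2$instruments$SNP)
  expect_equal(nrow(res2$instruments), 3)
})

test_that("the selection pipeline is idempotent", {
  sim <- simulate_triple(sim_config(n_instruments = 12, seed = 8,
                                    gamma_sd = 0.25))
  first <- select_instruments(sim$exposure, assume_independent = TRUE)
  second <- select_instruments(first$instruments, assume_independent = TRUE)
  expect_identical(second$instruments$SNP, first$instruments$SNP)
  expect_equal(nrow(second$report$dropped), 0)
})

test_that("selection reports partition the input SNP set", {
  sim <- simulate_triple(sim_config(n_instruments = 10, seed = 9))
  res <- select_instruments(sim$exposure, mediator = sim$mediator,
                            assume_independent = TRUE)
  accounted <- c(res$report$kept, res$report$dropped$snp_id)
  expect_setequal(accounted, sim$exposure$SNP)
  expect_equal(anyDuplicated(accounted), 0)
})
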