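#!/usr/bin/env Rscript

# Step 1: build the synthetic study.
#
# We emulate the data situation of an immune-cell / metabolite / epilepsy
# screen at the published cohort scales (exposure GWAS n = 3,757, mediator
# GWAS n = 8,299, outcome GWAS n = 44,889): a batch of candidate exposures,
# two of which truly affect the outcome, one of those partly through a
# mediator. Everything is written as plain TSV under results/data/ together
# with a ground-truth sidecar, so later steps (and any reader) can rerun the
# analysis from files alone.

suppressPackageStartupMessages(library(mrmediate))

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed0 <- 20240901

n_exposures <- 12
effect_idx <- c(1, 2)     # exposures with a real effect on the outcome
theta_effect <- 0.25      # direct effect, log-odds per SD

truth <- list()
for (i in seq_len(n_exposures)) {
  has_effect <- i %in% effect_idx
  cfg <- sim_config(
    n_instruments = 15, n_med_instruments = 15, n_null_snps = 30,
    theta = if (has_effect) theta_effect else 0,
    beta1 = if (i == 1) 0.3 else 0,   # exposure 1 acts partly via the mediator
    beta2 = if (i == 1) 0.4 else 0,
    gamma_sd = 0.25, seed = seed0 + i)
  sim <- simulate_triple(cfg)
  id <- sprintf("trait_%02d", i)
  write_sumstats(sim$exposure, file.path(out_dir, paste0(id, "_exposure.tsv")))
  write_sumstats(sim$mediator, file.path(out_dir, paste0(id, "_mediator.tsv")))
  write_sumstats(sim$outcome, file.path(out_dir, paste0(id, "_outcome.tsv")))
  truth[[id]] <- list(theta = cfg$theta, beta1 = cfg$beta1, beta2 = cfg$beta2,
                      theta_total = sim$truth$theta_total,
                      mediated_proportion =
                        if (sim$truth$theta_total != 0)
                          sim$truth$indirect / sim$truth$theta_total else 0)
}

ld <- simulate_ld_blocks(sim_config(n_instruments = 15, n_med_instruments = 15,
                                    n_null_snps = 30, seed = seed0),
                         block_size = 1, within_r2 = 0)
write_ld_matrix(ld, file.path(out_dir, "ld_matrix.tsv"))

jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)

cat("Simulated", n_exposures, "exposure/mediator/outcome triples;",
    length(effect_idx), "carry a true total effect of", theta_effect,
    "(trait_01 with 37.5% of it mediated).\n")
cat("Wrote summary statistics, an LD matrix and truth.json to", out_dir, "\n")
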