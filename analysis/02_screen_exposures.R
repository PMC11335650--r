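#!/usr/bin/env Rscript

# Step 2: two-sample MR screen of every candidate exposure against the
# outcome. Each exposure goes through the full screen — p < 1e-5 instrument
# threshold, LD clumping (the simulated SNPs are independent, which the
# bundled identity LD matrix encodes), set-level F >= 10 filter, allele
# harmonization with palindrome handling — and is estimated with the method
# its instrument count dictates (Wald ratio for one SNP, IVW otherwise),
# with the remaining estimators reported alongside.

suppressPackageStartupMessages(library(mrmediate))

data_dir <- "results/data"
stopifnot(dir.exists(data_dir))  # run analysis/01_simulate_cohorts.R first
truth <- jsonlite::read_json(file.path(data_dir, "truth.json"))
ld <- read_ld_matrix(file.path(data_dir, "ld_matrix.tsv"))

rows <- list()
for (id in names(truth)) {
  exposure <- read_sumstats(file.path(data_dir, paste0(id, "_exposure.tsv")),
                            trait_id = id)
  outcome <- read_sumstats(file.path(data_dir, paste0(id, "_outcome.tsv")),
                           trait_id = "epilepsy")
  rows[[id]] <- screen(setNames(list(exposure), id), outcome, ld = ld, seed = 1)
}
res <- dplyr::bind_rows(rows)

render_report(res, NULL, "results/screen", outcome_id = "epilepsy",
              metadata = list(p_threshold = 1e-5, clump_r2 = 0.001,
                              clump_kb = 10000, f_min = 10, alpha = 0.05,
                              seed = 1))

hits <- res$exposure_id[res$significant]
true_pos <- names(truth)[vapply(truth, function(t) t$theta_total != 0, logical(1))]
cat("Screened", nrow(res), "exposures;", length(hits), "significant at IVW p < 0.05:",
    paste(hits, collapse = ", "), "\n")
cat("Planted effects:", paste(true_pos, collapse = ", "), "\n")
missed <- setdiff(true_pos, hits)
fps <- setdiff(hits, true_pos)
if (length(missed)) cat("Missed:", paste(missed, collapse = ", "), "\n")
if (length(fps)) {
  cat("Nominally significant without a planted effect (expected at the",
      "uncorrected alpha = 0.05 the screen mirrors):",
      paste(fps, collapse = ", "), "\n")
}
cat("Forest table and run metadata written to results/screen/\n")
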