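#!/usr/bin/env Rscript
# Stability analysis of the synthetic scenarios written by 02_simulate_qpcr.R:
# the four algorithms, the comprehensive geometric-mean ranking, the geNorm
# pairwise-variation series, and the recommended reference-gene set per
# scenario. Run after analysis/02_simulate_qpcr.R.

library(rgstab)
in_dir <- file.path("results", "synthetic")
out_dir <- file.path("results", "stability")
stopifnot(dir.exists(in_dir))

for (preset in c("corm_growth", "tissues", "drought", "all")) {
  ct <- read_ct_table(file.path(in_dir, paste0(preset, "_ct.tsv")))
  truth <- jsonlite::read_json(file.path(in_dir, paste0(preset, "_truth.json")))
  res <- run_full_pipeline(ct, out_dir = out_dir)
  r <- res$all
  comp <- r$comprehensive
  cat("\n==", preset, "==\n")
  cat("comprehensive ranking:", paste(comp$gene_id, collapse = " > "), "\n")
  cat("geNorm V series:",
      paste(sprintf("V%s/%d=%.3f", names(r$genorm$v_series),
                    as.integer(names(r$genorm$v_series)) + 1,
                    r$genorm$v_series), collapse = "  "), "\n")
  cat("optimal number of RGs:",
      if (is.na(r$optimal_n)) "undetermined" else r$optimal_n,
      "-> recommended:", paste(r$recommended, collapse = ", "), "\n")
  cat("designed least stable:", truth$designed_order[[10]],
      "| found least stable:", comp$gene_id[nrow(comp)], "\n")
  conc <- compare_methods(r$stability)
  cat("method concordance (Spearman), min off-diagonal:",
      round(min(conc$spearman[upper.tri(conc$spearman)]), 3), "\n")
  file.rename(file.path(out_dir, "all"), file.path(out_dir, preset))
}
cat("\nper-scenario tables under", out_dir, "\n")
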