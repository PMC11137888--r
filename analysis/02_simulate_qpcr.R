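#!/usr/bin/env Rscript
# Generate the four synthetic qPCR scenarios (corm growth stages, tissues,
# drought, and their union) with known ground truth, and write them as the
# same wide TSV tables the readers consume. Ten genes each: eight stable,
# one systematically regulated across conditions (bTUB_like), one with high
# assay scatter (EF1A_like).

library(rgstab)
out_dir <- file.path("results", "synthetic")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

seed0 <- 2301
for (preset in c("corm_growth", "tissues", "drought", "all")) {
  seed0 <- seed0 + 1
  sim <- simulate_ct_dataset(synthetic_preset(preset, seed = seed0))
  path <- file.path(out_dir, paste0(preset, "_ct.tsv"))
  write_ct_table(sim$ct, path)
  jsonlite::write_json(
    list(preset = preset, seed = seed0,
         designed_order = sim$truth$designed_order,
         designed_score = as.list(round(sim$truth$designed_score, 4)),
         groups = as.list(table(sim$ct$groups))),
    file.path(out_dir, paste0(preset, "_truth.json")),
    auto_unbox = TRUE, pretty = TRUE)
  cat(sprintf("%-12s %2d genes x %2d samples -> %s (least stable by design: %s)\n",
              preset, nrow(sim$ct$values), ncol(sim$ct$values), path,
              tail(sim$truth$designed_order, 1)))
}
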