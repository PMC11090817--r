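#!/usr/bin/env Rscript
## Classify gene ubiquity (extended core >= 90%, cloud <= 15%, species with
## >= 10 genomes) and test whether transferred gene families are
## cloud-enriched and core-depleted by two-sided Fisher's exact tests.

source("analysis/00_config.R")

world <- dataset_as_world(load_dataset(WORLD_DIR), config = study_config())
res <- run_pipeline(world, stages = c("events", "ubiquity"))

for (cls in names(res$ubiquity)) {
  u <- res$ubiquity[[cls]]
  cat(sprintf("%s: odds ratio %.2f (Fisher p = %.3g)\n",
              cls, u$odds_ratio, u$p))
  print(u$table)
}

summary <- data.frame(
  class = names(res$ubiquity),
  odds_ratio = vapply(res$ubiquity, function(u) u$odds_ratio, 0),
  p = vapply(res$ubiquity, function(u) u$p, 0))
write.table(summary, file.path(RESULTS_DIR, "ubiquity_fisher.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
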