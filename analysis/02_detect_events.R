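#!/usr/bin/env Rscript
## Aggregate reconciliation replicates into well-supported transfer events
## (>= 80% of pooled samples, >= 0.5 minimum branch support, families with
## more than 50 optimal roots excluded) and summarise per-species
## transferred-gene fractions.

source("analysis/00_config.R")

world <- dataset_as_world(load_dataset(WORLD_DIR), config = study_config())
res <- run_pipeline(world, stages = "events")

cat("Retained events:", nrow(res$events), "\n")
cat("Gene families with >= 1 transfer:",
    length(res$transferred_families), "of",
    length(unique(world$recon_meta$gene_family_id)),
    sprintf("(%.1f%%)\n", res$pct_families_with_transfer))
sf <- res$species_fraction
cat(sprintf("Per-species transferred-gene fraction: mean %.3f (IQR %.3f-%.3f)\n",
            mean(sf$fraction), quantile(sf$fraction, 0.25),
            quantile(sf$fraction, 0.75)))

write.table(res$events, file.path(RESULTS_DIR, "retained_events.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$counts, file.path(RESULTS_DIR, "pair_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sf, file.path(RESULTS_DIR, "species_transfer_fraction.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
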