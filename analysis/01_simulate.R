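#!/usr/bin/env Rscript
## Generate the synthetic study community and persist it as plain text.
## Every downstream script reads from results/world, so the whole analysis
## can be re-run stage by stage.

source("analysis/00_config.R")

cfg <- study_config()
cat("Simulating world:", cfg$n_species, "species,", cfg$n_samples,
    "samples,", cfg$n_gene_families, "gene families,",
    cfg$n_reconciliations, "reconciliation replicates\n")

world <- simulate_world(cfg)
write_world(world, WORLD_DIR)

cat("Planted transfer events:", nrow(world$transfers$events), "\n")
cat("OTU pairs with >= 1 transfer:", nrow(world$transfers$counts), "\n")
cat("Specialist OTUs:", sum(world$abundance$truth$specialist), "\n")
cat("World written to", WORLD_DIR, "\n")
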