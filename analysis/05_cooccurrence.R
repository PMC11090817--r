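#!/usr/bin/env Rscript
## Co-occurrence analysis: presence at >= 0.01% relative abundance,
## co-occurrence conditional on the rarer OTU, the power-law fit
## CO = k * PD^a, and per-focal-OTU Spearman correlations of transfer
## counts with raw and phylogenetically corrected co-occurrence, compared
## against a count-shuffled background.

source("analysis/00_config.R")

world <- dataset_as_world(load_dataset(WORLD_DIR), config = study_config())
res <- run_pipeline(world, stages = c("events", "cooccurrence"),
                    n_shuffles = 1)

## community-wide power-law fit (per-OTU fits are inside the correlation
## analysis)
pres <- presence_matrix(world$abundance$abundance)
com <- co_occurrence_matrix(pres)
otus <- world$species_tree$tip.label
pdm <- patristic_matrix(world$species_tree)
ut <- upper.tri(pdm)
ok <- is.finite(com[otus, otus][ut])
fit <- fit_power_law(pdm[ut][ok], com[otus, otus][ut][ok])
cat(sprintf("Community power law: CO = %.3f * PD^%.3f\n", fit$k, fit$a))

rca <- res$cooccurrence
cat("Focal OTUs analysed:", nrow(rca$per_otu), "\n")
cat(sprintf("Median rho pre/post correction: %.3f / %.3f (background %.3f)\n",
            median(rca$per_otu$rho_pre), median(rca$per_otu$rho_post),
            median(rca$background)))
cat(sprintf("Post-correction vs background, two-sided MWU p = %.3g\n",
            rca$mwu_post_vs_background$p))
cat("Multi-transfer cutoff (80%-quantile of positive counts):",
    res$multi_threshold, "\n")

write.table(rca$per_otu, file.path(RESULTS_DIR, "cooccurrence_rho.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(k = fit$k, a = fit$a,
                          mwu_p = rca$mwu_post_vs_background$p,
                          multi_threshold = res$multi_threshold),
                     file.path(RESULTS_DIR, "powerlaw_fit.json"),
                     auto_unbox = TRUE, digits = NA)
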