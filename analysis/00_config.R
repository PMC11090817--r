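## Shared settings for the numbered analysis scripts.  Each script is a
## thin driver over the hgtecology package: run them in order from the
## repository root, e.g.  Rscript analysis/01_simulate.R
##
## The study community: 300 OTUs across four environments, 2,000 samples,
## 5,000 gene families with 100 reconciliation replicates each.

library(hgtecology)

WORLD_DIR <- "results/world"
RESULTS_DIR <- "results"

study_config <- function(seed = 20240301) {
  world_config(seed = seed)
}
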