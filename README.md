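# hgtecology

Eco-evolutionary analysis of horizontal gene transfer (HGT) in prokaryotic
communities.

Successful gene transfer needs both opportunity and retention: donor and
recipient must meet, and the transferred gene must persist in the recipient
lineage. This package implements an integrated analysis of those two sides
for anyone studying HGT at the community scale. It takes transfer events
called from gene-tree/species-tree reconciliation and relates them to (i)
the ubiquity of the transferred families within pangenomes, (ii) their
functional categories as a function of time since transfer, and (iii) the
ecology of the exchanging taxa — co-occurrence across environmental samples,
relative abundance, and habitat generalism.

## What it computes

- **Transfer-event detection** — aggregates reconciliation replicates
  (pooled across optimal roots) and retains gene-tree nodes called a
  transfer in ≥ 80% of samples, with ≥ 0.5 minimum branch support; families
  with more than 50 optimal roots are excluded, and multifurcations
  containing identical cross-species genes count as transfers regardless of
  support.
- **Pangenome ubiquity** — gene ubiquity `u = genomes_with_gene /
  genomes_total`, classified as extended core (u ≥ 0.90), shell, or cloud
  (u ≤ 0.15) for species with ≥ 10 genomes; transferred vs non-transferred
  composition tested with two-sided Fisher's exact tests (cross-product
  odds ratio).
- **Functional enrichment** — each event placed on a species-distance ×
  gene-distance grid (species bins 1–3 spanning 0.08–2.00; nested gene bins
  a–e, with d ⊂ c and e ⊂ d picking out recent transfers); each
  (cell, category) tested with a two-sided binomial test against the
  pipeline-wide background fraction, Holm–Šidák adjusted.
- **Co-occurrence correction** — co-occurrence
  `CO = |samples with both| / |samples with the rarer OTU|`, modelled
  against patristic distance with the power law `CO ≈ k · PD^a` (nonlinear
  least squares, log–log initialisation); per focal OTU, Spearman
  correlations of transfer counts with raw CO and with model residuals,
  compared to a count-shuffled background by Mann–Whitney U.
- **Abundance and generalism** — preferred habitats (argmax of mean
  abundance over animal/aquatic/plant/soil), 80%/20% abundance tiers,
  transfer-fraction curves with Bernoulli error bands
  `sqrt(p(1−p)/n)`, the Shannon-entropy generalism index, and
  inter-environment transfer-rate matrices on distance-equalised subsamples
  with Z-scores against a resampled background.
- **Matched subsampling** — the covariate-normalisation primitive used
  throughout: equal-width binning (up to 80 × 80 for two covariates) with
  per-bin downsampling of the larger group.
- **A synthetic community generator** — plants every one of these effects
  with known parameters (power-law exponent, cloud odds ratio, rate
  coefficients, per-cell enrichment factors, reconciliation support noise)
  so each stage can be validated against ground truth.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
community (300 OTUs, 2,000 samples, 5,000 gene families, 100 reconciliation
replicates per family):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_detect_events.R
Rscript analysis/05_cooccurrence.R
```

which prints, among other things:

```
Gene families with >= 1 transfer: 3000 of 5000 (60.0%)
Community power law: CO = 0.159 * PD^-0.502
Median rho pre/post correction: 0.134 / 0.047 (background -0.003)
Post-correction vs background, two-sided MWU p = 5.4e-05
```

The community was generated with `CO = 0.15 · PD^−0.5`, so the fitted power
law recovers the planted decay; the per-OTU correlation between transfer
counts and co-occurrence stays positive after removing the phylogenetic
signal (median ρ 0.047 against a shuffled background centred on zero),
which is the planted co-occurrence effect on transfer rates. The pangenome
stage (`analysis/03_pangenome_ubiquity.R`) recovers the planted cloud
enrichment of transferred families (odds ratio 1.93 against a planted 2.0),
and the ecology stage (`analysis/06_abundance_generalism.R`) shows the
planted ordering of abundance tiers and the specialist/generalist contrast
(specialists: higher mean and s.d. of inter-environment transfer rates;
generalists: lower spread).

Library use mirrors the scripts:

```r
library(hgtecology)
cfg <- world_config(n_species = 150, n_samples = 800, seed = 1)
world <- simulate_world(cfg)
res <- run_pipeline(world)
res$ubiquity$cloud$odds_ratio   # planted at cfg$cloud_odds_ratio = 2
```

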