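test_that("species tree simulation honours its contract", {
  t2 <- simulate_species_tree(2, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  expect_gt(patristic_distance(t2, t2$tip.label[1], t2$tip.label[2]), 0)
  expect_error(simulate_species_tree(1), "n_species")

  ta <- simulate_species_tree(50, seed = 7)
  tb <- simulate_species_tree(50, seed = 7)
  expect_identical(ape::write.tree(ta), ape::write.tree(tb))
  tc <- simulate_species_tree(50, seed = 8)
  expect_false(ape::write.tree(ta) == ape::write.tree(tc))
  expect_true(all(ta$edge.length > 0))
  expect_true(ape::is.rooted(ta))
  expect_equal(max(patristic_matrix(ta)), 2, tolerance = 0.05)
})

test_that("identical configurations give bit-identical worlds", {
  cfg <- world_config(n_species = 40, n_samples = 200,
                      n_gene_families = 300, n_reconciliations = 10,
                      seed = 5)
  w1 <- simulate_world(cfg)
  w2 <- simulate_world(cfg)
  expect_identical(serialize(w1, NULL, version = 2),
                   serialize(w2, NULL, version = 2))
})

test_that("abundance columns are sub-compositional and non-negative", {
  w <- small_world()
  ab <- w$abundance$abundance
  expect_true(all(ab >= 0))
  expect_true(all(colSums(ab) <= 1 + 1e-12))
  expect_equal(sort(rownames(ab)), sort(w$species_tree$tip.label))
  expect_length(w$abundance$sample_env, ncol(ab))
})

test_that("pure specialist communities have near-zero entropy profiles", {
  cfg <- world_config(n_species = 50, n_samples = 400,
                      n_gene_families = 300, n_reconciliations = 10,
                      specialist_fraction = 1, seed = 17)
  w <- simulate_world(cfg)
  prof <- habitat_profiles(w$abundance$abundance, w$abundance$sample_env)
  expect_lt(median(prof$entropy, na.rm = TRUE), 0.15)
  ## preferred environments recover the planted ones
  agree <- mean(prof$preferred_env == w$abundance$truth$preferred_env,
                na.rm = TRUE)
  expect_gt(agree, 0.95)
})

test_that("a flat co-occurrence exponent removes the distance correlation", {
  rhos <- vapply(1:8, function(i) {
    cfg <- world_config(n_species = 120, n_samples = 800,
                        n_gene_families = 300, n_reconciliations = 10,
                        cooccur_a = 0, cooccur_k = 0.3,
                        seed = 200 + i)
    tree <- simulate_species_tree(cfg$n_species, seed = 200 + i)
    ab <- simulate_abundance_matrix(tree, cfg)
    pres <- presence_matrix(ab$abundance)
    co <- co_occurrence_matrix(pres)[tree$tip.label, tree$tip.label]
    pd <- patristic_matrix(tree)
    ut <- upper.tri(co)
    ok <- is.finite(co[ut])
    cor(co[ut][ok], pd[ut][ok], method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("the planted power-law exponent is recovered from realized data", {
  errs <- vapply(1:3, function(i) {
    cfg <- world_config(n_species = 200, n_samples = 1500,
                        n_gene_families = 300, n_reconciliations = 10,
                        seed = 300 + i)
    tree <- simulate_species_tree(cfg$n_species, seed = 300 + i)
    ab <- simulate_abundance_matrix(tree, cfg)
    pres <- presence_matrix(ab$abundance)
    co <- co_occurrence_matrix(pres)[tree$tip.label, tree$tip.label]
    pd <- patristic_matrix(tree)
    ut <- upper.tri(co)
    ok <- is.finite(co[ut])
    fit_power_law(pd[ut][ok], co[ut][ok])$a - cfg$cooccur_a
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.15)
})

test_that("transfer simulation respects degenerate configurations", {
  cfg0 <- world_config(n_species = 30, n_samples = 200,
                       n_gene_families = 100, n_reconciliations = 10,
                       hgt_base_rate = 0, seed = 23)
  tree <- simulate_species_tree(30, seed = 23)
  ab <- simulate_abundance_matrix(tree, cfg0)
  tt <- simulate_transfers(tree, ab, cfg0)
  expect_equal(nrow(tt$events), 0L)
  expect_equal(nrow(tt$counts), 0L)
  ## OTU set mismatch is rejected
  tree2 <- simulate_species_tree(31, seed = 24)
  expect_error(simulate_transfers(tree2, ab, cfg0), "OTU sets differ")
})

test_that("a positive residual effect shows up in per-OTU correlations", {
  cfg <- world_config(n_species = 100, n_samples = 800,
                      n_gene_families = 2000, n_reconciliations = 10,
                      beta_residual = 4, specialist_boost = 0,
                      beta_abundance = 0, rate_dispersion = 0,
                      seed = 31)
  tree <- simulate_species_tree(cfg$n_species, seed = 31)
  ab <- simulate_abundance_matrix(tree, cfg)
  tt <- simulate_transfers(tree, ab, cfg)
  tr <- tt$truth
  rhos <- vapply(unique(c(tr$otu_a)), function(o) {
    sub <- tr[tr$otu_a == o | tr$otu_b == o, ]
    if (length(unique(sub$n_events)) < 2) return(NA_real_)
    cor(sub$residual, sub$n_events, method = "spearman")
  }, numeric(1))
  expect_gt(median(rhos, na.rm = TRUE), 0)
})

test_that("world invariants: counts symmetric structure and truth recorded", {
  w <- small_world()
  cnt <- w$transfers$counts
  expect_true(all(cnt$otu_a < cnt$otu_b))
  expect_true(all(cnt$count >= 1))
  ## counts match an independent recount from the event list
  cnt2 <- pairwise_transfer_counts(
    w$transfers$events,
    stats::setNames(w$species_tree$tip.label, w$species_tree$tip.label))
  expect_equal(cnt[c("otu_a", "otu_b", "count")],
               cnt2[c("otu_a", "otu_b", "count")])
  expect_true(all(c("preferred_env", "specialist", "prevalence") %in%
                    names(w$abundance$truth)))
  ## reconciliation meta covers every family
  expect_equal(sort(unique(w$recon_meta$gene_family_id)),
               sprintf("F%06d", seq_len(w$config$n_gene_families)))
})

test_that("gene distances populate every gene bin component", {
  w <- small_world()
  comp <- table(w$transfers$events$gene_bin_component)
  expect_setequal(names(comp), c("a", "b", "c", "d", "e"))
  gd <- w$transfers$events$mean_gene_distance
  expect_true(all(gd > 0 & gd <= 0.75))
})
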