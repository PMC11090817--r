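test_that("patristic distances are path sums, symmetric, zero on identity", {
  tr <- abc_tree()
  expect_equal(patristic_distance(tr, "A", "B"), 0.3)
  expect_equal(patristic_distance(tr, "A", "C"), 0.45)
  expect_equal(patristic_distance(tr, "B", "C"), 0.55)
  expect_equal(patristic_distance(tr, "C", "A"), 0.45)
  expect_equal(patristic_distance(tr, "A", "A"), 0)
  expect_error(patristic_distance(tr, "A", "Z"), "unknown leaf")
})

test_that("patristic distance satisfies the triangle inequality", {
  for (seed in 1:5) {
    tree <- simulate_species_tree(15, seed = seed)
    d <- patristic_matrix(tree)
    tips <- tree$tip.label
    trip <- t(utils::combn(tips, 3))
    for (i in seq_len(nrow(trip))) {
      a <- trip[i, 1]; b <- trip[i, 2]; c <- trip[i, 3]
      expect_lte(d[a, c], d[a, b] + d[b, c] + 1e-12)
    }
  }
})

make_samples <- function(n_flagged, n_total, node = "T1",
                         donor = "X", recipient = "Y") {
  flagged <- data.frame(root_id = 1L, replicate = seq_len(n_flagged),
                        node_id = node, event_type = "transfer",
                        donor = donor, recipient = recipient,
                        stringsAsFactors = FALSE)
  rest <- data.frame(root_id = 1L,
                     replicate = seq_len(n_total - n_flagged) + n_flagged,
                     node_id = node, event_type = "speciation",
                     donor = donor, recipient = NA_character_,
                     stringsAsFactors = FALSE)
  rbind(flagged, rest)
}

test_that("support aggregation applies the 80% threshold inclusively", {
  ev <- aggregate_transfer_events(make_samples(412, 500),
                                  node_support = c(T1 = 0.9))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$support_fraction, 0.824)
  expect_false(ev$via_multifurcation_rule)

  ev <- aggregate_transfer_events(make_samples(399, 500),
                                  node_support = c(T1 = 0.9))
  expect_equal(nrow(ev), 0L)

  ev <- aggregate_transfer_events(make_samples(400, 500),
                                  node_support = c(T1 = 0.9))
  expect_equal(nrow(ev), 1L)  # exactly 0.8 is retained
})

test_that("branch support filter and multifurcation override behave as stated", {
  s <- make_samples(450, 500)
  expect_equal(nrow(aggregate_transfer_events(s, c(T1 = 0.49))), 0L)
  expect_equal(nrow(aggregate_transfer_events(s, c(T1 = 0.5))), 1L)
  ## low support but satisfies the identical-gene multifurcation rule
  ev <- aggregate_transfer_events(make_samples(10, 500), c(T1 = 0.9),
                                  multifurcation_nodes = "T1")
  expect_equal(nrow(ev), 1L)
  expect_true(ev$via_multifurcation_rule)
  expect_equal(ev$support_fraction, 0.02)
})

test_that("families with more than 50 optimal roots are excluded", {
  s51 <- do.call(rbind, lapply(1:51, function(r) {
    data.frame(root_id = r, replicate = 1:2, node_id = "T1",
               event_type = "transfer", donor = "X", recipient = "Y",
               stringsAsFactors = FALSE)
  }))
  ev <- aggregate_transfer_events(s51)
  expect_equal(nrow(ev), 0L)
  expect_equal(attr(ev, "excluded"), "max_roots")
  s50 <- s51[s51$root_id <= 50, ]
  expect_equal(nrow(aggregate_transfer_events(s50)), 1L)
  expect_error(aggregate_transfer_events(s51[0, ]), "empty")
})

test_that("aggregation equals a brute-force recount on random replicate sets", {
  set.seed(31)
  for (rep in 1:20) {
    n_total <- sample(20:60, 1)
    nodes <- paste0("n", 1:4)
    samples <- do.call(rbind, lapply(seq_len(n_total), function(r) {
      flag <- runif(4) < 0.5
      data.frame(root_id = 1L, replicate = r, node_id = nodes,
                 event_type = ifelse(flag, "transfer", "speciation"),
                 donor = "X", recipient = ifelse(flag, "Y", NA),
                 stringsAsFactors = FALSE)
    }))
    sup <- stats::setNames(runif(4), nodes)
    ev <- aggregate_transfer_events(samples, sup, min_support = 0.5)
    ## independent recount
    for (nd in nodes) {
      flags <- sum(samples$node_id == nd & samples$event_type == "transfer")
      expected <- flags / n_total >= 0.5 && sup[nd] >= 0.5
      expect_equal(nd %in% ev$node_id, unname(expected))
      if (expected)
        expect_equal(ev$support_fraction[ev$node_id == nd],
                     unname(flags / n_total))
    }
  }
})

test_that("event mean distances equal brute-force pair means", {
  sp <- abc_tree()
  gt <- ape::read.tree(text = "(((gA:0.02,gB:0.08):0.01,gC:0.1):0.02,(gD:0.05,gE:0.07):0.03);")
  map <- c(gA = "A", gB = "A", gC = "B", gD = "C", gE = "C")
  left <- c("gA", "gB", "gC"); right <- c("gD", "gE")
  got <- event_mean_distances(left, right, gt, sp, map)
  gd <- patristic_matrix(gt); sd_ <- patristic_matrix(sp)
  acc_g <- c(); acc_s <- c()
  for (l in left) for (r in right) {
    acc_g <- c(acc_g, gd[l, r])
    acc_s <- c(acc_s, sd_[map[l], map[r]])
  }
  expect_equal(got$mean_gene_distance, mean(acc_g))
  expect_equal(got$mean_species_distance, mean(acc_s))

  ## single-leaf sets reduce to the single pairwise distances
  got1 <- event_mean_distances("gA", "gD", gt, sp, map)
  expect_equal(got1$mean_gene_distance, gd["gA", "gD"])
  expect_equal(got1$mean_species_distance, sd_["A", "C"])

  ## overlap filter applies to the gene distance only
  ov <- stats::setNames(c(0.4), hgtecology:::pair_key("gA", "gD"))
  got2 <- event_mean_distances("gA", "gD", gt, sp, map, overlap = ov)
  expect_true(is.na(got2$mean_gene_distance))
  expect_equal(got2$mean_species_distance, sd_["A", "C"])
})

test_that("per-species transfer fractions average over genomes", {
  assessed <- list(g1 = paste0("F", 1:10), g2 = paste0("F", 1:10),
                   g3 = paste0("F", 1:5))
  gs <- c(g1 = "sp1", g2 = "sp1", g3 = "sp2")
  tf <- paste0("F", 1:4)   # g1: 4/10, g2: 4/10, g3: 4/5
  out <- per_species_transfer_fraction(tf, assessed, gs)
  expect_equal(out$fraction[out$species == "sp1"], 0.4)
  expect_equal(out$fraction[out$species == "sp2"], 0.8)
  ## species mean over genomes at 0.2 and 0.4
  out2 <- per_species_transfer_fraction(paste0("F", 1:2),
                                        list(a = paste0("F", 1:10),
                                             b = paste0("F", c(1, 11:15))),
                                        c(a = "s", b = "s"))
  expect_equal(out2$fraction, mean(c(0.2, 1 / 6)))
  ## no events
  out3 <- per_species_transfer_fraction(character(0), assessed, gs)
  expect_true(all(out3$fraction == 0))
  expect_warning(per_species_transfer_fraction(tf, c(assessed,
                                                     list(g4 = character(0))),
                                               c(gs, g4 = "sp3")),
                 "no assessed genes")
})

test_that("pairwise counts deduplicate by family and stay symmetric", {
  ev <- data.frame(
    gene_family_id = c("F1", "F1", "F2", "F3"),
    donor_leaves = c("X", "X", "Y", "X"),
    recipient_leaves = c("Y", "Y", "X", "X"),
    stringsAsFactors = FALSE)
  map <- c(X = "oX", Y = "oY")
  cnt <- pairwise_transfer_counts(ev, map)
  ## F1 counted once despite two events; F2 same pair opposite direction;
  ## F3 is within one species and dropped
  expect_equal(nrow(cnt), 1L)
  expect_equal(cnt$count, 2L)
  expect_equal(sort(c(cnt$otu_a, cnt$otu_b)), c("oX", "oY"))
  m <- hgt_count_matrix(cnt)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 0))
  ## total counts invariant under OTU relabelling
  cnt2 <- pairwise_transfer_counts(ev, c(X = "z9", Y = "a1"))
  expect_equal(sum(cnt2$count), sum(cnt$count))
  ## unmapped species skipped with a logged count
  cnt3 <- pairwise_transfer_counts(ev, c(X = "oX"))
  expect_equal(nrow(cnt3), 0L)
  expect_gt(attr(cnt3, "n_unmapped"), 0L)
})

test_that("retained events equal planted events when replicates are noiseless", {
  cfg <- world_config(n_species = 40, n_samples = 300,
                      n_gene_families = 400, n_reconciliations = 20,
                      support_noise = 0, seed = 77)
  w <- simulate_world(cfg)
  ev <- hgtecology:::detect_events_stage(w)
  planted <- w$transfers$events
  expect_equal(nrow(ev), nrow(planted))
  expect_setequal(paste(ev$gene_family_id, ev$node_id),
                  paste(planted$gene_family_id, planted$event_node))
  expect_true(all(ev$support_fraction == 1))
  ## and the recomputed pair counts equal the planted count matrix
  cnt <- pairwise_transfer_counts(
    ev, stats::setNames(w$species_tree$tip.label, w$species_tree$tip.label))
  expect_equal(cnt[c("otu_a", "otu_b", "count")],
               w$transfers$counts[c("otu_a", "otu_b", "count")])
})

test_that("gene pair table applies support/overlap filters and transfer flags", {
  sp <- abc_tree()
  gt <- ape::read.tree(text = "((gA:0.1,gB:0.1):0.05,(gC:0.1,gD:0.1):0.05);")
  map <- c(gA = "A", gB = "B", gC = "C", gD = "C")
  k <- function(a, b) hgtecology:::pair_key(a, b)
  sup <- stats::setNames(c(0.4, 0.5), c(k("gA", "gB"), k("gA", "gC")))
  ov <- stats::setNames(0.4, k("gB", "gC"))
  events <- data.frame(gene_family_id = "F1", donor_leaves = "A",
                       recipient_leaves = "C", stringsAsFactors = FALSE)
  tab <- build_gene_pair_table(gt, sp, map, events = events,
                               pair_support = sup, overlap = ov)
  keys <- k(tab$gene_a, tab$gene_b)
  expect_false(k("gA", "gB") %in% keys)  # support 0.4 < 0.5
  expect_true(k("gA", "gC") %in% keys)   # support exactly 0.5 kept
  expect_false(k("gB", "gC") %in% keys)  # overlap 0.4 < 0.5
  expect_false(k("gC", "gD") %in% keys)  # same species
  expect_true(all(tab$has_transfer[tab$species_a == "A" &
                                     tab$species_b == "C"]))
  expect_false(any(tab$has_transfer[tab$species_a == "B"]))
})

test_that("transferred family percentage reproduces a printed worked ratio", {
  expect_equal(round(transferred_family_percentage(634352, 961821)), 66)
  expect_equal(transferred_family_percentage(1, 2), 50)
  expect_error(transferred_family_percentage(1, 0), "positive")
})
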