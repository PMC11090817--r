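#' Configuration for the synthetic community generator
#'
#' Bundles every planted parameter of the synthetic world: community size,
#' environment composition, the co-occurrence/phylogenetic-distance power law
#' (`co = cooccur_k * pd^cooccur_a`), the log-linear transfer-rate model
#' (baseline, co-occurrence-residual effect, abundance-tier effect,
#' same-habitat specialist boost, distance decay), the cloud-gene odds ratio
#' planted for transferred families, functional-annotation enrichments, and
#' the reconciliation replicate noise.
#'
#' @param n_species,n_samples community dimensions (counts >= 2).
#' @param env_fractions 4 proportions (animal, aquatic, plant, soil) summing
#'   to 1: sample environment composition.
#' @param cooccur_k,cooccur_a planted power-law parameters.
#' @param co_max saturation ceiling for the planted co-occurrence.
#' @param hgt_base_rate baseline Poisson rate of transferred gene families
#'   per OTU pair.
#' @param beta_residual effect of the co-occurrence residual
#'   (`co - k * pd^a`, natural scale) on the log transfer rate.
#' @param beta_abundance effect per high-abundance OTU in the pair on the
#'   log rate (mid tier counts half).
#' @param specialist_boost extra log rate for pairs of same-habitat
#'   specialists.
#' @param pd_decay exponential decay of the transfer rate with phylogenetic
#'   distance.
#' @param rate_dispersion standard deviation (log scale) of a mean-one
#'   lognormal frailty multiplying each pair's transfer rate; produces the
#'   overdispersed, heavy-tailed pair counts seen in real transfer data.
#' @param specialist_fraction fraction of OTUs that are habitat specialists.
#' @param prevalence_range uniform range of per-OTU presence probability.
#' @param cloud_odds_ratio planted odds ratio of transferred vs
#'   non-transferred families falling in the cloud ubiquity class.
#' @param cloud_base cloud probability for non-transferred families.
#' @param n_gene_families,n_reconciliations,support_noise reconciliation
#'   replicate structure: families simulated, replicates per family, and the
#'   probability of a miscalled event per replicate.
#' @param categories functional category vocabulary.
#' @param annotation_background per-category annotation probability.
#' @param planted_enrichments list of `list(category, species_bin, gene_bin,
#'   factor)` entries multiplying the annotation probability for events in
#'   that grid cell.
#' @param gene_bin_weights mixture weights over the five (disjoint
#'   components of the) gene-distance bins for planted event gene distances.
#' @param mean_genomes mean genomes per species (min 10).
#' @param multi_root_prob probability that a family has two optimal roots.
#' @param seed master seed; every stage derives its own stream from it.
#' @return validated list of class `world_config`.
#' @export
world_config <- function(n_species = 300, n_samples = 2000,
                         env_fractions = c(animal = 0.4, aquatic = 0.3,
                                           plant = 0.15, soil = 0.15),
                         cooccur_k = 0.15, cooccur_a = -0.5, co_max = 0.9,
                         hgt_base_rate = 0.6, beta_residual = 3,
                         beta_abundance = 0.5, specialist_boost = 1,
                         pd_decay = 1, rate_dispersion = 0.8,
                         specialist_fraction = 0.5,
                         prevalence_range = c(0.04, 0.07),
                         cloud_odds_ratio = 2, cloud_base = 0.35,
                         n_gene_families = 5000, n_reconciliations = 100,
                         support_noise = 0.05,
                         categories = c("C", "E", "G", "J", "K", "L", "M",
                                        "P", "T", "V"),
                         annotation_background = 0.12,
                         planted_enrichments = list(),
                         gene_bin_weights = c(a = 0.20, b = 0.20, c = 0.25,
                                              d = 0.20, e = 0.15),
                         mean_genomes = 25, multi_root_prob = 0.1,
                         seed = 1) {
  cfg <- as.list(environment())
  if (n_species < 2 || n_samples < 2 || n_gene_families < 2 ||
      n_reconciliations < 2)
    stop_invalid("world_config: all counts must be >= 2")
  if (length(env_fractions) != 4 || abs(sum(env_fractions) - 1) > 1e-9)
    stop_invalid("world_config: env_fractions must be 4 proportions summing to 1")
  if (cooccur_k <= 0 || hgt_base_rate < 0 || cloud_odds_ratio <= 0)
    stop_invalid("world_config: rate parameters must be positive")
  if (support_noise < 0 || support_noise > 1 || cloud_base <= 0 ||
      cloud_base >= 1)
    stop_invalid("world_config: probabilities must lie in [0, 1]")
  names(cfg$env_fractions) <- ENVIRONMENTS
  structure(cfg, class = "world_config")
}

#' Simulate a species tree
#'
#' Pure-birth (Yule) tree with `n_species` leaves, rescaled so the maximum
#' patristic distance equals `span` (default 2, matching the range of the
#' species-distance bin grid).
#'
#' @param n_species number of leaves (>= 2).
#' @param seed integer seed.
#' @param span target maximum patristic distance.
#' @param min_edge floor on branch lengths after rescaling, so no two
#'   leaves are arbitrarily close (keeps the planted co-occurrence curve
#'   below saturation at the closest pairs).
#' @return an [ape::phylo] with uniquely named leaves (`S0001`, ...) and
#'   strictly positive branch lengths.
#' @export
simulate_species_tree <- function(n_species, seed = 1, span = 2,
                                  min_edge = 0.02) {
  if (n_species < 2) stop_invalid("simulate_species_tree: n_species >= 2")
  with_seed(seed, {
    tree <- ape::rphylo(n_species, birth = 1, death = 0)
    tree$tip.label <- sprintf("S%04d", seq_len(n_species))
    for (i in 1:2) {
      tree$edge.length <- pmax(tree$edge.length, min_edge)
      d <- max(stats::cophenetic(tree))
      tree$edge.length <- tree$edge.length * (span / d)
    }
    tree$edge.length <- pmax(tree$edge.length, min_edge)
    tree$node.label <- NULL
    tree
  })
}

#' Simulate an environment-structured abundance matrix
#'
#' Presence patterns are drawn from a Gaussian copula whose per-pair latent
#' correlation is calibrated (by bisection on the bivariate normal CDF) so
#' the expected co-occurrence of each OTU pair equals the planted power law
#' `min(co_max, k * pd^a)`.  Each OTU has a phylogenetically clustered
#' preferred environment (Brownian trait split by environment fractions) and
#' is a specialist or a generalist: specialists carry near-zero abundance
#' (just above the presence threshold) outside their home environment, so
#' their abundance mass - and hence their entropy and habitat preference -
#' concentrates at home while presence structure, which drives
#' co-occurrence, remains copula-governed.
#'
#' @param tree species tree from [simulate_species_tree()]; leaves are OTUs.
#' @param config a [world_config()].
#' @param seed integer seed (defaults to the config seed).
#' @return list of class `abundance_matrix`: `abundance` (OTU x sample
#'   matrix), `sample_env`, and `truth` (per-OTU preferred environment,
#'   specialist flag, prevalence).
#' @export
simulate_abundance_matrix <- function(tree, config, seed = config$seed) {
  otus <- tree$tip.label
  n <- length(otus)
  m <- config$n_samples
  pd <- stats::cophenetic(tree)[otus, otus]
  seeds <- derive_seeds(seed, 5)

  sample_env <- with_seed(seeds[1],
    sample(ENVIRONMENTS, m, replace = TRUE, prob = config$env_fractions))

  truth <- with_seed(seeds[2], {
    trait <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    br <- stats::quantile(trait, cumsum(config$env_fractions))
    pref <- ENVIRONMENTS[findInterval(trait, c(-Inf, br[1:3]),
                                      left.open = TRUE)]
    data.frame(otu = otus, preferred_env = pref,
               specialist = stats::runif(n) < config$specialist_fraction,
               prevalence = stats::runif(n, config$prevalence_range[1],
                                         config$prevalence_range[2]),
               scale = stats::rlnorm(n, log(0.02), 0.6),
               stringsAsFactors = FALSE)
  })

  ## calibrate the latent correlation of every pair to the planted CO
  ut <- upper.tri(pd)
  co_target <- pmin(config$co_max, config$cooccur_k * pd[ut]^config$cooccur_a)
  p <- truth$prevalence
  pi_ <- matrix(p, n, n)[ut]
  pj_ <- matrix(p, n, n, byrow = TRUE)[ut]
  joint <- co_target * pmin(pi_, pj_)
  ## Calibrate per-pair latent correlations, then smooth them into a PSD
  ## kernel of patristic distance (see fit_monotone_psd_rho).  The kernel
  ## smoothing slightly biases the implied joint probabilities, so the
  ## joint targets are corrected over a few fixed-point iterations.
  rho_target <- calibrate_latent_rho(joint, pi_, pj_, iterations = 45)
  rho_fitted <- rho_target
  for (it in 1:3) {
    rho_fitted <- fit_monotone_psd_rho(pd[ut], rho_target)$fitted
    j_implied <- pbvnorm(stats::qnorm(pi_), stats::qnorm(pj_), rho_fitted)
    j_adj <- pmin(joint * (joint / pmax(j_implied, 1e-12)),
                  pmin(pi_, pj_) * 0.999)
    rho_target <- calibrate_latent_rho(j_adj, pi_, pj_, iterations = 45)
  }
  rho_fitted <- fit_monotone_psd_rho(pd[ut], rho_target)$fitted
  R <- diag(n)
  R[ut] <- rho_fitted
  R <- R + t(R) - diag(n)

  presence <- with_seed(seeds[3], {
    L <- chol(R + diag(1e-8, n))
    Z <- crossprod(L, matrix(stats::rnorm(n * m), n, m))
    Z <= stats::qnorm(p)
  })

  abundance <- with_seed(seeds[4], {
    ab <- matrix(0, n, m, dimnames = list(otus, NULL))
    home <- outer(truth$preferred_env, sample_env, "==")
    full <- home | !truth$specialist
    n_pres <- sum(presence)
    vals <- truth$scale[row(ab)[presence]] *
      stats::rlnorm(n_pres, 0, 0.5)
    away <- 1.5e-4 * stats::rlnorm(n_pres, 0, 0.1)
    ab[presence] <- ifelse(full[presence], vals, away)
    ## keep columns sub-compositional and presence intact
    cs <- colSums(ab)
    ab <- sweep(ab, 2, pmax(1, cs / 0.95), "/")
    ab[presence] <- pmax(ab[presence], 1.2e-4)
    ab
  })
  colnames(abundance) <- sprintf("sample%05d", seq_len(m))

  structure(list(abundance = abundance, sample_env = sample_env,
                 truth = truth),
            class = "abundance_matrix")
}

#' Simulate pairwise transfer counts and transfer events
#'
#' Pair counts are Poisson with a log-linear rate: baseline, co-occurrence
#' residual (realised co-occurrence minus the planted power-law curve),
#' abundance-tier score of the two OTUs, a same-habitat specialist
#' indicator, and exponential decay with phylogenetic distance.  One event
#' is emitted per transferred gene family (so the pairwise family counts
#' equal the planted counts exactly); each event carries a gene distance
#' drawn from a mixture over the gene-distance bins so every grid cell is
#' populated.
#'
#' @param tree species tree.
#' @param ab an `abundance_matrix` from [simulate_abundance_matrix()].
#' @param config a [world_config()].
#' @param seed integer seed.
#' @return list: `counts` (`hgt_counts` data.frame), `events` (data.frame
#'   with `gene_family_id`, `donor_leaves`, `recipient_leaves`,
#'   `mean_species_distance`, `mean_gene_distance`, `gene_bin_component`),
#'   and `truth` (per-pair rates and covariates).
#' @export
simulate_transfers <- function(tree, ab, config, seed = config$seed) {
  otus <- tree$tip.label
  if (!identical(sort(rownames(ab$abundance)), sort(otus)))
    stop_invalid("simulate_transfers: abundance and tree OTU sets differ")
  pd <- stats::cophenetic(tree)[otus, otus]
  pres <- presence_matrix(ab$abundance)
  co <- co_occurrence_matrix(pres)[otus, otus]

  profiles <- abundance_tiers(habitat_profiles(ab$abundance, ab$sample_env))
  tier_score <- ifelse(is.na(profiles$tier), 0.5,
                       c(high = 1, mid = 0.5, low = 0)[profiles$tier])
  names(tier_score) <- profiles$otu
  tr <- ab$truth

  ut <- which(upper.tri(pd), arr.ind = TRUE)
  ia <- ut[, 1]; ib <- ut[, 2]
  resid <- co[ut] - config$cooccur_k * pd[ut]^config$cooccur_a
  resid[is.na(resid)] <- 0
  same_spec <- tr$specialist[ia] & tr$specialist[ib] &
    tr$preferred_env[ia] == tr$preferred_env[ib]
  log_rate <- log(config$hgt_base_rate) +
    config$beta_residual * resid +
    config$beta_abundance * (tier_score[otus[ia]] + tier_score[otus[ib]]) +
    config$specialist_boost * same_spec -
    config$pd_decay * pd[ut]
  rate <- if (config$hgt_base_rate == 0) rep(0, length(log_rate))
          else exp(log_rate)

  seeds <- derive_seeds(seed, 2)
  n_events <- with_seed(seeds[1], {
    s2 <- config$rate_dispersion^2
    frailty <- stats::rlnorm(length(rate), -s2 / 2, config$rate_dispersion)
    stats::rpois(length(rate), rate * frailty)
  })

  comp_edges <- list(a = c(0.50, 0.75), b = c(0.25, 0.50), c = c(0.05, 0.25),
                     d = c(0.01, 0.05), e = c(0.00, 0.01))
  events <- with_seed(seeds[2], {
    idx <- rep(seq_along(n_events), n_events)
    k <- length(idx)
    if (k == 0L) {
      data.frame(gene_family_id = character(), event_node = character(),
                 donor_leaves = character(), recipient_leaves = character(),
                 mean_species_distance = numeric(),
                 mean_gene_distance = numeric(),
                 gene_bin_component = character(), stringsAsFactors = FALSE)
    } else {
      ## events are spread round-robin over a 60% subset of families, so a
      ## family can host several transfer events (distinct gene-tree nodes)
      n_fam_used <- max(1L, min(floor(0.6 * config$n_gene_families), k))
      fam_idx <- ((seq_len(k) - 1L) %% n_fam_used) + 1L
      fam <- sprintf("F%06d", fam_idx)
      node <- paste0("T", ((seq_len(k) - 1L) %/% n_fam_used) + 1L)
      comp <- sample(names(comp_edges), k, replace = TRUE,
                     prob = config$gene_bin_weights[names(comp_edges)])
      lo <- vapply(comp_edges[comp], `[`, 0, 1)
      hi <- vapply(comp_edges[comp], `[`, 0, 2)
      gdist <- stats::runif(k, lo, hi)
      a_first <- stats::runif(k) < 0.5
      donor <- ifelse(a_first, otus[ia[idx]], otus[ib[idx]])
      recip <- ifelse(a_first, otus[ib[idx]], otus[ia[idx]])
      data.frame(gene_family_id = fam, event_node = node,
                 donor_leaves = donor, recipient_leaves = recip,
                 mean_species_distance = pd[ut][idx],
                 mean_gene_distance = gdist, gene_bin_component = comp,
                 stringsAsFactors = FALSE)
    }
  })

  counts <- pairwise_transfer_counts(
    events, stats::setNames(otus, otus))
  truth <- data.frame(otu_a = otus[ia], otu_b = otus[ib], pd = pd[ut],
                      co = co[ut], residual = resid,
                      same_habitat_specialists = same_spec, rate = rate,
                      n_events = n_events, stringsAsFactors = FALSE)
  list(counts = counts, events = events, truth = truth)
}

#' Simulate pangenomes, annotations and reconciliation replicates
#'
#' Transferred families receive cloud-class ubiquity with odds
#' `cloud_odds_ratio` times those of non-transferred families; annotations
#' are multi-label with per-cell planted enrichment factors; reconciliation
#' replicate sets flag each true transfer with probability
#' `1 - support_noise` and each background node spuriously with probability
#' `support_noise`.
#'
#' @param config a [world_config()].
#' @param transfers output of [simulate_transfers()].
#' @param species character vector of species identifiers.
#' @param seed integer seed.
#' @return list: `pangenome` (species_id, gene_family_id, genomes_with_gene,
#'   genomes_total), `annotations` (named list per family),
#'   `reconciliations` (data.frame of transfer-flagged samples with
#'   `gene_family_id`, `root_id`, `replicate`, `node_id`, `event_type`,
#'   `donor`, `recipient`), `recon_meta` (per family: `n_roots`,
#'   `n_samples_total`, `true_node`), `node_support` (per family x node),
#'   `genomes` (named list of assessed family sets) and `genome_species`.
#' @export
simulate_gene_families <- function(config, transfers, species,
                                   seed = config$seed) {
  events <- transfers$events
  n_ev <- nrow(events)
  ev_fams <- unique(events$gene_family_id)
  if (length(ev_fams) > config$n_gene_families)
    stop_invalid("more transferred families than gene families")
  fams <- sprintf("F%06d", seq_len(config$n_gene_families))
  transferred <- fams %in% ev_fams
  seeds <- derive_seeds(seed, 4)

  ## --- pangenome -----------------------------------------------------
  pangenome <- with_seed(seeds[1], {
    genomes_total <- stats::setNames(
      10L + stats::rpois(length(species), max(config$mean_genomes - 10, 0)),
      species)
    ## every family lives in a host pangenome; transferred families appear
    ## in both recipient and donor species (one row per species x family)
    host <- sample(species, config$n_gene_families, replace = TRUE)
    sp <- c(host, events$recipient_leaves, events$donor_leaves)
    fam <- c(fams, events$gene_family_id, events$gene_family_id)
    tr <- c(transferred, rep(TRUE, 2L * n_ev))
    dup <- duplicated(paste(sp, fam))
    sp <- sp[!dup]; fam <- fam[!dup]; tr <- tr[!dup]
    p0 <- config$cloud_base
    odds1 <- config$cloud_odds_ratio * p0 / (1 - p0)
    p1 <- odds1 / (1 + odds1)
    p_cloud <- ifelse(tr, p1, p0)
    u <- stats::runif(length(sp))
    shell_share <- 0.75
    cls <- ifelse(u < p_cloud, "cloud",
                  ifelse(u < p_cloud + (1 - p_cloud) * shell_share,
                         "shell", "extended_core"))
    tot <- genomes_total[sp]
    lo <- ifelse(cls == "cloud", 1L,
                 ifelse(cls == "shell", floor(0.15 * tot) + 1L,
                        ceiling(0.9 * tot)))
    hi <- ifelse(cls == "cloud", pmax(1L, floor(0.15 * tot)),
                 ifelse(cls == "shell", ceiling(0.9 * tot) - 1L, tot))
    cnt <- lo + floor(stats::runif(length(sp)) * (hi - lo + 1))
    data.frame(species_id = sp, gene_family_id = fam,
               genomes_with_gene = as.integer(pmin(cnt, tot)),
               genomes_total = as.integer(tot), stringsAsFactors = FALSE)
  })

  ## --- annotations ---------------------------------------------------
  annotations <- with_seed(seeds[2], {
    prob <- matrix(config$annotation_background, config$n_gene_families,
                   length(config$categories),
                   dimnames = list(fams, config$categories))
    for (pl in config$planted_enrichments) {
      hit <- vapply(seq_len(n_ev), function(i) {
        b <- assign_bins(events$mean_species_distance[i],
                         events$mean_gene_distance[i])
        !is.na(b$species_bin) && b$species_bin == pl$species_bin &&
          pl$gene_bin %in% b$gene_bins
      }, logical(1))
      prob[unique(events$gene_family_id[hit]), pl$category] <-
        pmin(1, pl$factor * config$annotation_background)
    }
    draw <- matrix(stats::runif(length(prob)), nrow(prob)) < prob
    lapply(stats::setNames(seq_along(fams), fams), function(i)
      config$categories[draw[i, ]])
  })

  ## --- reconciliation replicates (vectorised over events) -------------
  recon <- with_seed(seeds[3], {
    if (n_ev == 0L) {
      list(samples = data.frame(), meta = data.frame(),
           support = data.frame())
    } else {
      ## replicate sets exist for every family; only transferred families
      ## carry a true event node, the rest have background nodes only
      n_roots_fam <- stats::setNames(
        1L + (stats::runif(length(fams)) < config$multi_root_prob),
        fams)
      n_rec <- config$n_reconciliations
      total_fam <- n_roots_fam * n_rec       # pooled samples per family
      ## true transfer rows: event x replicate grid, kept w.p. 1 - noise
      tot_ev <- unname(total_fam[events$gene_family_id])
      ev_rep <- rep(seq_len(n_ev), tot_ev)   # event index per (event, sample)
      samp_i <- sequence(tot_ev)             # pooled sample index 1..total
      keep <- stats::runif(length(ev_rep)) < (1 - config$support_noise)
      root <- ((samp_i - 1L) %/% n_rec) + 1L
      repl <- ((samp_i - 1L) %% n_rec) + 1L
      true_rows <- data.frame(
        gene_family_id = events$gene_family_id[ev_rep][keep],
        root_id = root[keep], replicate = repl[keep],
        node_id = events$event_node[ev_rep][keep], event_type = "transfer",
        donor = events$donor_leaves[ev_rep][keep],
        recipient = events$recipient_leaves[ev_rep][keep],
        stringsAsFactors = FALSE)
      ## spurious transfer rows on background nodes (all families)
      n_bg_nodes <- 4L
      per_node_tot <- rep(unname(total_fam), each = n_bg_nodes)
      fam_rep <- rep(rep(fams, each = n_bg_nodes), per_node_tot)
      grid_n <- length(fam_rep)
      samp_b <- sequence(per_node_tot)
      node_b <- rep(rep(paste0("N", seq_len(n_bg_nodes)), length(fams)),
                    per_node_tot)
      sp_keep <- stats::runif(grid_n) < config$support_noise
      sp_rows <- if (any(sp_keep)) data.frame(
        gene_family_id = fam_rep[sp_keep],
        root_id = ((samp_b[sp_keep] - 1L) %/% n_rec) + 1L,
        replicate = ((samp_b[sp_keep] - 1L) %% n_rec) + 1L,
        node_id = node_b[sp_keep], event_type = "transfer",
        donor = sample(species, sum(sp_keep), replace = TRUE),
        recipient = sample(species, sum(sp_keep), replace = TRUE),
        stringsAsFactors = FALSE) else NULL
      samples <- rbind(true_rows, sp_rows)
      samples <- samples[order(samples$gene_family_id, samples$root_id,
                               samples$replicate, samples$node_id), ]
      rownames(samples) <- NULL
      meta <- data.frame(gene_family_id = fams,
                         n_roots = unname(n_roots_fam),
                         n_samples_total = unname(total_fam),
                         stringsAsFactors = FALSE)
      ## per-node branch supports: true nodes pass the filter, background
      ## nodes span it
      ev_support <- data.frame(
        gene_family_id = events$gene_family_id,
        node_id = events$event_node,
        min_branch_support = stats::runif(n_ev, 0.55, 0.99),
        stringsAsFactors = FALSE)
      bg_support <- data.frame(
        gene_family_id = rep(fams, each = n_bg_nodes),
        node_id = rep(paste0("N", seq_len(n_bg_nodes)), length(fams)),
        min_branch_support = stats::runif(length(fams) * n_bg_nodes,
                                          0.2, 0.95),
        stringsAsFactors = FALSE)
      list(samples = samples, meta = meta,
           support = rbind(ev_support, bg_support))
    }
  })

  ## --- genome gene content (assessed sets) ---------------------------
  genomes <- with_seed(seeds[4], {
    fam_by_sp <- split(seq_len(nrow(pangenome)), pangenome$species_id)
    g_list <- list(); g_sp <- character(0)
    for (sp in names(fam_by_sp)) {
      rows_sp <- fam_by_sp[[sp]]
      ubiq <- pangenome$genomes_with_gene[rows_sp] /
        pangenome$genomes_total[rows_sp]
      for (g in 1:3) {
        gid <- paste0(sp, ".g", g)
        keep <- stats::runif(length(rows_sp)) < ubiq
        if (!any(keep)) keep[sample(length(rows_sp), 1)] <- TRUE
        g_list[[gid]] <- pangenome$gene_family_id[rows_sp[keep]]
        g_sp <- c(g_sp, stats::setNames(sp, gid))
      }
    }
    list(assessed = g_list, genome_species = g_sp)
  })

  list(pangenome = pangenome, annotations = annotations,
       reconciliations = recon$samples, recon_meta = recon$meta,
       node_support = recon$support, genomes = genomes$assessed,
       genome_species = genomes$genome_species)
}

#' Simulate a complete synthetic world
#'
#' Runs the full generator: species tree, abundance matrix, planted transfer
#' counts/events, pangenomes, annotations and reconciliation replicate sets.
#' Identical configurations (including the seed) give bit-identical worlds.
#'
#' @param config a [world_config()].
#' @return list of class `synthetic_world` with components `config`,
#'   `species_tree`, `abundance` (the `abundance_matrix` object),
#'   `transfers` (counts/events/truth), and the [simulate_gene_families()]
#'   components.
#' @export
simulate_world <- function(config = world_config()) {
  seeds <- derive_seeds(config$seed, 4)
  tree <- simulate_species_tree(config$n_species, seed = seeds[1])
  ab <- simulate_abundance_matrix(tree, config, seed = seeds[2])
  transfers <- simulate_transfers(tree, ab, config, seed = seeds[3])
  gf <- simulate_gene_families(config, transfers, tree$tip.label,
                               seed = seeds[4])
  structure(c(list(config = config, species_tree = tree, abundance = ab,
                   transfers = transfers), gf),
            class = "synthetic_world")
}
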