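#' Patristic distance between two leaves
#'
#' Sum of branch lengths along the tree path between two leaves.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param leaf_a,leaf_b leaf (tip) labels.
#' @return non-negative numeric distance.
#' @export
patristic_distance <- function(tree, leaf_a, leaf_b) {
  ia <- match(leaf_a, tree$tip.label)
  ib <- match(leaf_b, tree$tip.label)
  if (is.na(ia) || is.na(ib))
    stop_invalid("patristic_distance: unknown leaf '",
                 if (is.na(ia)) leaf_a else leaf_b, "'")
  if (ia == ib) return(0)
  d <- ape::dist.nodes(tree)
  unname(d[ia, ib])
}

#' Full leaf-to-leaf patristic distance matrix
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return symmetric matrix with leaf labels as dimnames.
#' @export
patristic_matrix <- function(tree) {
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Aggregate reconciliation replicates into supported transfer events
#'
#' Pools reconciliation samples across replicates and optimal roots of one
#' gene family and retains, as transfer events, the gene-tree nodes labelled
#' as transfers in at least `min_support` of all pooled samples.  Nodes whose
#' minimum branch support (over the gene-tree branches subtending the
#' transferred clade) is below `min_branch_support` are dropped.  Families
#' with more than `max_roots` optimal roots are excluded entirely (recorded
#' in the `excluded` attribute).  Multifurcating nodes containing 100%
#' identical genes from different species are always emitted as events
#' (`via_multifurcation_rule = TRUE`), regardless of support.
#'
#' @param samples data.frame of reconciliation samples with columns
#'   `root_id`, `replicate`, `node_id`, `event_type`
#'   (`"speciation"`/`"duplication"`/`"transfer"`), `donor`, `recipient`
#'   (recipient `NA` unless a transfer).  All rows must belong to one family.
#' @param node_support named numeric vector: per gene-tree node, the minimum
#'   branch support of the gene pairs subtended by the node (in `[0, 1]`).
#'   Nodes absent from the vector are treated as support 1.
#' @param multifurcation_nodes character vector of node ids that satisfy the
#'   identical-genes multifurcation rule (see
#'   [multifurcation_identity_nodes()]).
#' @param min_support minimum fraction of pooled samples calling the node a
#'   transfer (default 0.8, inclusive).
#' @param min_branch_support minimum branch support (default 0.5, inclusive).
#' @param max_roots families with more optimal roots than this are excluded
#'   (default 50).
#' @param total_samples pooled number of reconciliation samples (roots x
#'   replicates).  Defaults to the number of distinct (root, replicate)
#'   pairs seen in `samples`; pass it explicitly when `samples` only lists
#'   transfer-flagged rows and some replicates flagged nothing.
#' @return data.frame with one row per retained event: `node_id`,
#'   `support_fraction`, `min_branch_support`, `donor`, `recipient` (the modal
#'   donor/recipient mapping over the samples calling the transfer), and
#'   `via_multifurcation_rule`.  Attribute `excluded` carries the exclusion
#'   reason (`"max_roots"`) when the family was dropped.
#' @export
aggregate_transfer_events <- function(samples, node_support = NULL,
                                      multifurcation_nodes = character(),
                                      min_support = 0.8,
                                      min_branch_support = 0.5,
                                      max_roots = 50,
                                      total_samples = NULL) {
  if (is.null(samples) || nrow(samples) == 0L)
    stop_invalid("aggregate_transfer_events: empty sample list")
  n_roots <- length(unique(samples$root_id))
  empty <- data.frame(node_id = character(), support_fraction = numeric(),
                      min_branch_support = numeric(), donor = character(),
                      recipient = character(),
                      via_multifurcation_rule = logical(),
                      stringsAsFactors = FALSE)
  if (n_roots > max_roots) {
    attr(empty, "excluded") <- "max_roots"
    return(empty)
  }
  total <- total_samples %||%
    nrow(unique(samples[c("root_id", "replicate")]))
  tr <- samples[samples$event_type == "transfer", , drop = FALSE]
  if (nrow(tr) == 0L && length(multifurcation_nodes) == 0L) return(empty)

  flags <- table(tr$node_id)
  support_of <- function(node) {
    if (is.null(node_support) || !node %in% names(node_support)) 1
    else unname(node_support[node])
  }
  modal_map <- function(node) {
    sub <- tr[tr$node_id == node, , drop = FALSE]
    if (nrow(sub) == 0L) return(c(NA_character_, NA_character_))
    key <- paste(sub$donor, sub$recipient, sep = "\r")
    best <- names(sort(table(key), decreasing = TRUE))[1]
    strsplit(best, "\r", fixed = TRUE)[[1]]
  }

  nodes <- union(names(flags), multifurcation_nodes)
  rows <- lapply(nodes, function(node) {
    sf <- if (node %in% names(flags)) unname(flags[[node]]) / total else 0
    bs <- support_of(node)
    via_mf <- node %in% multifurcation_nodes
    keep <- via_mf || (sf >= min_support && bs >= min_branch_support)
    if (!keep) return(NULL)
    dm <- modal_map(node)
    data.frame(node_id = node, support_fraction = sf,
               min_branch_support = bs, donor = dm[1], recipient = dm[2],
               via_multifurcation_rule = via_mf, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$node_id), , drop = FALSE]
}

#' Minimum branch support subtended by each internal node
#'
#' For a gene tree whose internal node labels carry branch supports (the
#' common Newick dialect written by FastTree), returns for each internal node
#' the minimum support over all branches in the clade it subtends, i.e. the
#' minimum branch support over the gene pairs joined at that node.
#'
#' @param gene_tree an [ape::phylo] with numeric `node.label` supports in
#'   `[0, 1]` (missing/empty labels count as support 1).
#' @return named numeric vector over internal node labels or node numbers.
#' @export
node_min_branch_support <- function(gene_tree) {
  n_tip <- length(gene_tree$tip.label)
  n_node <- gene_tree$Nnode
  supports <- suppressWarnings(as.numeric(gene_tree$node.label))
  supports[is.na(supports)] <- 1
  ids <- if (!is.null(gene_tree$node.label) &&
             any(nzchar(gene_tree$node.label))) {
    lab <- gene_tree$node.label
    lab[!nzchar(lab)] <- paste0("node", seq_len(n_node))[!nzchar(lab)]
    lab
  } else paste0("node", seq_len(n_node))
  ## children of each internal node
  out <- numeric(n_node)
  for (i in seq_len(n_node)) {
    node <- n_tip + i
    desc <- descendant_internal_nodes(gene_tree, node)
    out[i] <- min(supports[desc - n_tip])
  }
  names(out) <- ids
  out
}

## all internal nodes in the clade rooted at `node` (including itself)
descendant_internal_nodes <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  acc <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (cur > n_tip) {
      acc <- c(acc, cur)
      stack <- c(stack, tree$edge[tree$edge[, 1] == cur, 2])
    }
  }
  acc
}

#' Multifurcations containing identical cross-species genes
#'
#' Identifies gene-tree nodes that are multifurcating (more than two
#' children) and whose subtended leaves include at least one pair of 100%
#' identical genes from different species.  Sequence identity is supplied as
#' a precomputed pair set (identity computation happens upstream).
#'
#' @param gene_tree an [ape::phylo].
#' @param identity_pairs data.frame with columns `gene_a`, `gene_b` listing
#'   100%-identical cross-species gene pairs (leaf labels).
#' @return character vector of node ids (node labels where present).
#' @export
multifurcation_identity_nodes <- function(gene_tree, identity_pairs) {
  if (is.null(identity_pairs) || nrow(identity_pairs) == 0L)
    return(character())
  n_tip <- length(gene_tree$tip.label)
  counts <- tabulate(gene_tree$edge[, 1])
  multi <- which(counts > 2)
  multi <- multi[multi > n_tip]
  if (length(multi) == 0L) return(character())
  keys <- pair_key(identity_pairs$gene_a, identity_pairs$gene_b)
  lab <- gene_tree$node.label
  hits <- character(0)
  for (node in multi) {
    tips <- gene_tree$tip.label[clade_tips(gene_tree, node)]
    if (length(tips) < 2) next
    cmb <- utils::combn(sort(tips), 2)
    if (any(pair_key(cmb[1, ], cmb[2, ]) %in% keys)) {
      id <- if (!is.null(lab) && nzchar(lab[node - n_tip])) lab[node - n_tip]
            else paste0("node", node - n_tip)
      hits <- c(hits, id)
    }
  }
  hits
}

## tip indices in the clade rooted at `node`
clade_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  acc <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (cur <= n_tip) acc <- c(acc, cur)
    else stack <- c(stack, tree$edge[tree$edge[, 1] == cur, 2])
  }
  sort(acc)
}

#' Mean gene and species distances of a transfer event
#'
#' Averages the patristic distances between all (left-descendant,
#' right-descendant) pairs of the event, in the gene tree and in the species
#' tree.  Gene pairs whose alignment overlap is below `min_overlap` are
#' excluded from the gene-distance mean only.
#'
#' @param left_genes,right_genes leaf labels of the two descendant sets in
#'   the gene tree.
#' @param gene_tree,species_tree [ape::phylo] trees.
#' @param gene_to_species named character vector mapping gene leaves to
#'   species leaves.
#' @param overlap optional named numeric vector over `pair_key(gene_a,
#'   gene_b)` giving alignment overlap fractions; pairs absent from the
#'   vector count as overlap 1.
#' @param min_overlap minimum overlap for the gene-distance mean
#'   (default 0.5, inclusive).
#' @return list with `mean_gene_distance` (NA if every gene pair was
#'   filtered out) and `mean_species_distance`.
#' @export
event_mean_distances <- function(left_genes, right_genes, gene_tree,
                                 species_tree, gene_to_species,
                                 overlap = NULL, min_overlap = 0.5) {
  gd <- patristic_matrix(gene_tree)
  sd_ <- patristic_matrix(species_tree)
  pairs <- expand.grid(l = left_genes, r = right_genes,
                       stringsAsFactors = FALSE)
  gvals <- gd[cbind(pairs$l, pairs$r)]
  if (!is.null(overlap)) {
    keys <- pair_key(pairs$l, pairs$r)
    ov <- ifelse(keys %in% names(overlap), overlap[keys], 1)
    gvals <- gvals[ov >= min_overlap]
  }
  sl <- gene_to_species[pairs$l]
  sr <- gene_to_species[pairs$r]
  svals <- sd_[cbind(sl, sr)]
  list(mean_gene_distance = if (length(gvals)) mean(gvals) else NA_real_,
       mean_species_distance = mean(svals))
}

#' Per-species mean fraction of transferred genes
#'
#' For each genome, the fraction of its assessed genes whose representative
#' gene family participated in any retained transfer event; per species, the
#' mean over its genomes.
#'
#' @param transferred_families character vector of gene families involved in
#'   at least one retained transfer event.
#' @param assessed named list: per genome, the character vector of assessed
#'   representative families.
#' @param genome_species named character vector mapping genomes to species.
#' @return data.frame with `species`, `fraction` (mean over genomes), and
#'   `n_genomes`.  Genomes with zero assessed genes are dropped with a
#'   warning.
#' @export
per_species_transfer_fraction <- function(transferred_families, assessed,
                                          genome_species) {
  sizes <- lengths(assessed)
  if (any(sizes == 0L)) {
    warning("excluding ", sum(sizes == 0L), " genome(s) with no assessed genes")
    assessed <- assessed[sizes > 0L]
  }
  if (length(assessed) == 0L)
    return(data.frame(species = character(), fraction = numeric(),
                      n_genomes = integer()))
  frac <- vapply(assessed, function(fams)
    mean(fams %in% transferred_families), numeric(1))
  sp <- genome_species[names(assessed)]
  agg <- tapply(frac, sp, mean)
  data.frame(species = names(agg), fraction = as.numeric(agg),
             n_genomes = as.integer(table(sp)[names(agg)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise transferred-gene-family counts
#'
#' Builds the symmetric OTU-pair count matrix of transferred gene families.
#' For each event, every (donor leaf, recipient leaf) species pair is mapped
#' to OTUs; a pair is counted at most once per gene family, however many
#' events of that family link it (prevents double counting of nested calls).
#'
#' @param events data.frame with columns `gene_family_id`, `donor_leaves`,
#'   `recipient_leaves` (the leaf columns are `;`-separated species sets).
#' @param species_to_otu named character vector; species missing from it are
#'   skipped (count of skips recorded in attribute `n_unmapped`).
#' @return an `hgt_counts` object: data.frame `otu_a`, `otu_b`, `count`
#'   (canonical order `otu_a < otu_b`, no zero rows, zero diagonal implied).
#' @export
pairwise_transfer_counts <- function(events, species_to_otu) {
  n_unmapped <- 0L
  keys <- character(0)
  if (nrow(events) > 0L) {
    per_event <- lapply(seq_len(nrow(events)), function(i) {
      dl <- strsplit(events$donor_leaves[i], ";", fixed = TRUE)[[1]]
      rl <- strsplit(events$recipient_leaves[i], ";", fixed = TRUE)[[1]]
      grid <- expand.grid(d = dl, r = rl, stringsAsFactors = FALSE)
      grid <- grid[grid$d != grid$r, , drop = FALSE]
      oa <- species_to_otu[grid$d]
      ob <- species_to_otu[grid$r]
      bad <- is.na(oa) | is.na(ob)
      n_unmapped <<- n_unmapped + sum(bad)
      if (all(bad)) return(character(0))
      same <- oa == ob & !bad
      keep <- !bad & !same
      unique(paste(events$gene_family_id[i],
                   pair_key(oa[keep], ob[keep]), sep = "\r"))
    })
    keys <- unique(unlist(per_event))
  }
  if (length(keys) == 0L) {
    out <- data.frame(otu_a = character(), otu_b = character(),
                      count = integer(), stringsAsFactors = FALSE)
  } else {
    pair_part <- sub("^[^\r]*\r", "", keys)
    tab <- table(pair_part)
    halves <- strsplit(names(tab), "|", fixed = TRUE)
    out <- data.frame(otu_a = vapply(halves, `[`, "", 1),
                      otu_b = vapply(halves, `[`, "", 2),
                      count = as.integer(tab), row.names = NULL,
                      stringsAsFactors = FALSE)
    out <- out[order(out$otu_a, out$otu_b), ]
    rownames(out) <- NULL
  }
  attr(out, "n_unmapped") <- n_unmapped
  class(out) <- c("hgt_counts", class(out))
  out
}

#' Dense symmetric matrix form of pairwise transfer counts
#'
#' @param counts an `hgt_counts` data.frame (see
#'   [pairwise_transfer_counts()]).
#' @param otus optional OTU universe to use for rows/columns.
#' @return symmetric integer matrix with zero diagonal.
#' @export
hgt_count_matrix <- function(counts, otus = NULL) {
  otus <- otus %||% sort(unique(c(counts$otu_a, counts$otu_b)))
  m <- matrix(0L, length(otus), length(otus), dimnames = list(otus, otus))
  if (nrow(counts)) {
    m[cbind(counts$otu_a, counts$otu_b)] <- counts$count
    m[cbind(counts$otu_b, counts$otu_a)] <- counts$count
  }
  m
}

#' Cross-species gene-pair table for one gene family
#'
#' Enumerates cross-species gene pairs of a family, applying the branch
#' support and alignment overlap filters, and flags pairs spanning a retained
#' transfer event's donor and recipient sets.
#'
#' @param gene_tree [ape::phylo] for the family.
#' @param species_tree [ape::phylo].
#' @param gene_to_species named character vector.
#' @param events retained events for this family (data.frame with
#'   `donor_leaves`, `recipient_leaves`, `;`-separated species sets); may be
#'   empty.
#' @param pair_support optional named numeric over `pair_key(gene_a, gene_b)`
#'   with minimum branch support along the path between the pair (absent
#'   pairs count as 1).
#' @param overlap optional named numeric over pair keys with alignment
#'   overlap (absent pairs count as 1).
#' @param min_branch_support,min_overlap inclusive filters (defaults 0.5).
#' @return data.frame: `gene_a`, `gene_b`, `species_a`, `species_b`,
#'   `gene_distance`, `species_distance`, `has_transfer`,
#'   `min_branch_support`, `overlap_fraction`.
#' @export
build_gene_pair_table <- function(gene_tree, species_tree, gene_to_species,
                                  events = NULL, pair_support = NULL,
                                  overlap = NULL, min_branch_support = 0.5,
                                  min_overlap = 0.5) {
  tips <- gene_tree$tip.label
  if (length(tips) < 2)
    return(data.frame())
  cmb <- utils::combn(tips, 2)
  ga <- cmb[1, ]; gb <- cmb[2, ]
  sa <- unname(gene_to_species[ga]); sb <- unname(gene_to_species[gb])
  keep <- sa != sb
  ga <- ga[keep]; gb <- gb[keep]; sa <- sa[keep]; sb <- sb[keep]
  keys <- pair_key(ga, gb)
  bs <- if (is.null(pair_support)) rep(1, length(keys)) else
    ifelse(keys %in% names(pair_support), pair_support[keys], 1)
  ov <- if (is.null(overlap)) rep(1, length(keys)) else
    ifelse(keys %in% names(overlap), overlap[keys], 1)
  keep <- bs >= min_branch_support & ov >= min_overlap
  ga <- ga[keep]; gb <- gb[keep]; sa <- sa[keep]; sb <- sb[keep]
  bs <- bs[keep]; ov <- ov[keep]
  if (length(ga) == 0L) return(data.frame())
  gd <- patristic_matrix(gene_tree)
  sdm <- patristic_matrix(species_tree)
  has_transfer <- rep(FALSE, length(ga))
  if (!is.null(events) && nrow(events) > 0L) {
    for (i in seq_len(nrow(events))) {
      dl <- strsplit(events$donor_leaves[i], ";", fixed = TRUE)[[1]]
      rl <- strsplit(events$recipient_leaves[i], ";", fixed = TRUE)[[1]]
      has_transfer <- has_transfer |
        (sa %in% dl & sb %in% rl) | (sa %in% rl & sb %in% dl)
    }
  }
  data.frame(gene_a = ga, gene_b = gb, species_a = sa, species_b = sb,
             gene_distance = gd[cbind(ga, gb)],
             species_distance = sdm[cbind(sa, sb)],
             has_transfer = has_transfer,
             min_branch_support = unname(bs), overlap_fraction = unname(ov),
             stringsAsFactors = FALSE)
}

#' Fraction of gene families with at least one transfer
#'
#' @param n_with_transfer number of gene families (gene trees) in which at
#'   least one well-supported transfer event was detected.
#' @param n_total total number of gene families assessed.
#' @return percentage in `[0, 100]`.
#' @export
transferred_family_percentage <- function(n_with_transfer, n_total) {
  if (n_total <= 0) stop_invalid("n_total must be positive")
  100 * n_with_transfer / n_total
}
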