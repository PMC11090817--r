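## On-disk formats: Newick for trees, headered TSV for tables, JSON for
## scalar summaries.  Every table starts with a provenance comment line
## ("# hgtecology <version> config=<hash> seed=<seed>") which readers skip.

pkg_version <- function() {
  tryCatch(as.character(utils::packageVersion("hgtecology")),
           error = function(e) "0.0.0.dev")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[order(names(config))]), f)
  unname(tools::md5sum(f))
}

provenance_line <- function(config) {
  paste0("# hgtecology ", pkg_version(), " config=", config_hash(config),
         " seed=", config$seed)
}

write_table <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a synthetic world to a directory
#'
#' Serialises every component as plain text: the species tree as Newick,
#' all tables as provenance-headered TSV.
#'
#' @param world a `synthetic_world` from [simulate_world()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- world$config
  ape::write.tree(world$species_tree, file.path(dir, "species_tree.nwk"))
  ab <- world$abundance$abundance
  ab_df <- data.frame(otu = rownames(ab), signif(ab, 12),
                      check.names = FALSE, stringsAsFactors = FALSE)
  write_table(ab_df, file.path(dir, "abundance.tsv"), cfg)
  write_table(data.frame(sample = colnames(ab),
                         environment = world$abundance$sample_env),
              file.path(dir, "sample_env.tsv"), cfg)
  cnt <- world$transfers$counts
  names(cnt)[names(cnt) == "count"] <- "n_genes"
  write_table(cnt, file.path(dir, "transfer_counts.tsv"), cfg)
  write_table(world$transfers$events, file.path(dir, "events.tsv"), cfg)
  write_table(world$pangenome, file.path(dir, "pangenome.tsv"), cfg)
  ann <- data.frame(gene_family_id = names(world$annotations),
                    categories = vapply(world$annotations, paste,
                                        "", collapse = ","),
                    stringsAsFactors = FALSE)
  write_table(ann, file.path(dir, "annotations.tsv"), cfg)
  write_table(world$reconciliations, file.path(dir, "reconciliations.tsv"),
              cfg)
  write_table(world$recon_meta, file.path(dir, "recon_meta.tsv"), cfg)
  write_table(world$node_support, file.path(dir, "node_support.tsv"), cfg)
  gen <- data.frame(genome = names(world$genomes),
                    species = unname(world$genome_species[names(world$genomes)]),
                    families = vapply(world$genomes, paste, "",
                                      collapse = ","),
                    stringsAsFactors = FALSE)
  write_table(gen, file.path(dir, "genomes.tsv"), cfg)
  jsonlite::write_json(world$config[!vapply(world$config, is.list,
                                            logical(1))],
                       file.path(dir, "world_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a dataset directory
#'
#' Reads the files written by [write_world()] and validates cross-file
#' consistency: abundance values in `[0, 1]`, known environment labels, and
#' agreement between tree leaves and abundance OTUs.
#'
#' @param dir dataset directory.
#' @return list with the same table components as a `synthetic_world`
#'   (minus the planted truth).
#' @export
load_dataset <- function(dir) {
  need <- file.path(dir, c("species_tree.nwk", "abundance.tsv",
                           "sample_env.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop_invalid("load_dataset: missing file(s): ",
                 paste(missing, collapse = ", "))
  tree <- ape::read.tree(file.path(dir, "species_tree.nwk"))
  ab_df <- read_table(file.path(dir, "abundance.tsv"))
  ab <- as.matrix(ab_df[, -1, drop = FALSE])
  rownames(ab) <- ab_df$otu
  if (any(!is.finite(ab)))
    stop_invalid("load_dataset: non-numeric abundance values")
  bad <- which(ab < 0 | ab > 1, arr.ind = TRUE)
  if (nrow(bad))
    stop_invalid("load_dataset: abundance outside [0, 1] at OTU '",
                 rownames(ab)[bad[1, 1]], "', sample '",
                 colnames(ab)[bad[1, 2]], "'",
                 if (nrow(bad) > 1) paste0(" (and ", nrow(bad) - 1, " more)"))
  env <- read_table(file.path(dir, "sample_env.tsv"))
  unknown <- setdiff(unique(env$environment), c(ENVIRONMENTS, "none"))
  if (length(unknown))
    stop_invalid("load_dataset: unknown environment label(s): ",
                 paste(unknown, collapse = ", "))
  orphan <- setdiff(tree$tip.label, rownames(ab))
  if (length(orphan))
    warning("load_dataset: ", length(orphan),
            " tree leaf/leaves absent from abundance table: ",
            paste(utils::head(orphan, 5), collapse = ", "))
  out <- list(species_tree = tree, abundance = ab,
              sample_env = env$environment[match(colnames(ab), env$sample)],
              excluded_leaves = orphan)
  opt <- function(name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    if (file.exists(p)) read_table(p) else NULL
  }
  out$counts <- opt("transfer_counts")
  if (!is.null(out$counts))
    names(out$counts)[names(out$counts) == "n_genes"] <- "count"
  out$events <- opt("events")
  out$pangenome <- opt("pangenome")
  ann <- opt("annotations")
  if (!is.null(ann)) {
    cats <- strsplit(ifelse(is.na(ann$categories), "", ann$categories), ",")
    out$annotations <- stats::setNames(
      lapply(cats, function(x) x[nzchar(x)]), ann$gene_family_id)
  }
  out$reconciliations <- opt("reconciliations")
  out$recon_meta <- opt("recon_meta")
  out$node_support <- opt("node_support")
  gen <- opt("genomes")
  if (!is.null(gen)) {
    out$genomes <- stats::setNames(strsplit(gen$families, ","), gen$genome)
    out$genome_species <- stats::setNames(gen$species, gen$genome)
  }
  out$config_path <- file.path(dir, "world_config.json")
  out
}

#' Wrap a loaded dataset into the structure the pipeline expects
#'
#' [load_dataset()] returns flat tables; the pipeline operates on the
#' nested `synthetic_world` layout.  This adapter rebuilds that layout
#' (without any planted truth) so on-disk datasets and in-memory worlds are
#' interchangeable.
#'
#' @param ds a list from [load_dataset()].
#' @param config optional `world_config`; defaults to the serialised
#'   configuration in `world_config.json` next to the dataset, if present.
#' @return a list usable by [run_pipeline()].
#' @export
dataset_as_world <- function(ds, config = NULL) {
  if (is.null(config) && !is.null(ds$config_path) &&
      file.exists(ds$config_path)) {
    config <- jsonlite::read_json(ds$config_path, simplifyVector = TRUE)
  }
  list(config = config %||% list(seed = 1L),
       species_tree = ds$species_tree,
       abundance = list(abundance = ds$abundance,
                        sample_env = ds$sample_env),
       transfers = list(events = ds$events, counts = ds$counts),
       pangenome = ds$pangenome, annotations = ds$annotations,
       reconciliations = ds$reconciliations, recon_meta = ds$recon_meta,
       node_support = ds$node_support, genomes = ds$genomes,
       genome_species = ds$genome_species)
}

## stage 1: aggregate reconciliation replicates into retained events
detect_events_stage <- function(world, min_support = 0.8,
                                min_branch_support = 0.5, max_roots = 50) {
  recs <- world$reconciliations
  meta <- world$recon_meta
  if (is.null(recs) || nrow(recs) == 0L)
    return(data.frame())
  by_fam <- split(seq_len(nrow(recs)), recs$gene_family_id)
  sup_by_fam <- split(world$node_support, world$node_support$gene_family_id)
  totals <- stats::setNames(meta$n_samples_total, meta$gene_family_id)
  out <- vector("list", length(by_fam))
  for (i in seq_along(by_fam)) {
    fam <- names(by_fam)[i]
    sub <- recs[by_fam[[i]], , drop = FALSE]
    sup <- sup_by_fam[[fam]]
    ns <- stats::setNames(sup$min_branch_support, sup$node_id)
    ev <- aggregate_transfer_events(sub, node_support = ns,
                                    min_support = min_support,
                                    min_branch_support = min_branch_support,
                                    max_roots = max_roots,
                                    total_samples = unname(totals[fam]))
    if (nrow(ev)) ev$gene_family_id <- fam
    out[[i]] <- ev
  }
  out <- out[vapply(out, nrow, 0L) > 0]
  if (!length(out)) return(data.frame())
  ev <- do.call(rbind, out)
  ## attach planted mean distances where the (family, node) matches a
  ## generated event; spurious survivors fall back to the species tree
  key <- paste(ev$gene_family_id, ev$node_id)
  pk <- paste(world$transfers$events$gene_family_id,
              world$transfers$events$event_node)
  m <- match(key, pk)
  ev$mean_gene_distance <- world$transfers$events$mean_gene_distance[m]
  ev$mean_species_distance <- world$transfers$events$mean_species_distance[m]
  pdm <- stats::cophenetic(world$species_tree)
  miss <- is.na(m) & ev$donor %in% rownames(pdm) &
    ev$recipient %in% rownames(pdm)
  ev$mean_species_distance[miss] <- pdm[cbind(ev$donor[miss],
                                              ev$recipient[miss])]
  ev$donor_leaves <- ev$donor
  ev$recipient_leaves <- ev$recipient
  rownames(ev) <- NULL
  ev
}

## build the all-pairs table used by the ecology stages
build_pair_table <- function(world, counts) {
  otus <- world$species_tree$tip.label
  pd <- stats::cophenetic(world$species_tree)[otus, otus]
  ut <- which(upper.tri(pd), arr.ind = TRUE)
  pairs <- data.frame(otu_a = otus[ut[, 1]], otu_b = otus[ut[, 2]],
                      pd = pd[ut], stringsAsFactors = FALSE)
  key <- pair_key(pairs$otu_a, pairs$otu_b)
  ck <- pair_key(counts$otu_a, counts$otu_b)
  cnt <- counts$count[match(key, ck)]
  pairs$count <- ifelse(is.na(cnt), 0L, cnt)
  pairs$transferred <- pairs$count >= 1
  pairs
}

#' Run the full analysis pipeline on a synthetic world
#'
#' Executes the stages in order: event detection (reconciliation
#' aggregation), pairwise counts and per-species transfer fractions,
#' pangenome ubiquity with Fisher tests, grid functional enrichment,
#' co-occurrence power-law correction with shuffled background, and the
#' abundance/generalism ecology analyses.  All stochastic steps derive
#' their seeds from `config$seed`.
#'
#' @param world a `synthetic_world`.
#' @param out_dir optional directory for TSV/JSON outputs and the run
#'   manifest.
#' @param n_background background subsamples for the ecology Z-scores.
#' @param n_shuffles shuffled replicates per focal OTU in the
#'   co-occurrence stage.
#' @param n_per_env generalist/specialist selection size per environment.
#' @param min_support,min_branch_support,max_roots event filters.
#' @param stages character subset of
#'   `c("events", "ubiquity", "enrichment", "cooccurrence", "ecology")`.
#' @return list of stage results (and manifest when `out_dir` is given).
#' @export
run_pipeline <- function(world, out_dir = NULL, n_background = 200,
                         n_shuffles = 1, n_per_env = 200,
                         min_support = 0.8, min_branch_support = 0.5,
                         max_roots = 50,
                         stages = c("events", "ubiquity", "enrichment",
                                    "cooccurrence", "ecology")) {
  cfg <- world$config
  seeds <- derive_seeds(cfg$seed + 1L, 4)
  res <- list(config = cfg)

  ## events ------------------------------------------------------------
  events <- detect_events_stage(world, min_support, min_branch_support,
                                max_roots)
  res$events <- events
  counts <- pairwise_transfer_counts(
    events, stats::setNames(world$species_tree$tip.label,
                            world$species_tree$tip.label))
  res$counts <- counts
  res$transferred_families <- unique(events$gene_family_id)
  n_fam_recon <- length(unique(world$recon_meta$gene_family_id))
  res$pct_families_with_transfer <- if (n_fam_recon > 0)
    transferred_family_percentage(length(res$transferred_families),
                                  n_fam_recon) else NA_real_
  res$species_fraction <- per_species_transfer_fraction(
    res$transferred_families, world$genomes, world$genome_species)

  ## ubiquity ----------------------------------------------------------
  if ("ubiquity" %in% stages &&
      length(res$transferred_families) > 0) {
    tab_cloud <- transfer_ubiquity_table(world$pangenome,
                                         res$transferred_families, "cloud")
    tab_core <- transfer_ubiquity_table(world$pangenome,
                                        res$transferred_families,
                                        "extended_core")
    res$ubiquity <- list(cloud = c(fisher_odds_ratio(tab_cloud),
                                   list(table = tab_cloud)),
                         extended_core = c(fisher_odds_ratio(tab_core),
                                           list(table = tab_core)))
  }

  ## enrichment --------------------------------------------------------
  if ("enrichment" %in% stages && nrow(events)) {
    res$enrichment <- enrichment_grid(
      events[!is.na(events$mean_species_distance), , drop = FALSE],
      world$annotations, assessed_families = names(world$annotations),
      categories = cfg$categories)
  }

  ## co-occurrence -----------------------------------------------------
  pres <- presence_matrix(world$abundance$abundance)
  if ("cooccurrence" %in% stages) {
    com <- co_occurrence_matrix(pres)
    elig <- eligibility_filter(counts, pres)
    cc <- counts[elig$pair_ok, , drop = FALSE]
    recs <- rbind(
      data.frame(focal_otu = cc$otu_a, partner_otu = cc$otu_b,
                 stringsAsFactors = FALSE),
      data.frame(focal_otu = cc$otu_b, partner_otu = cc$otu_a,
                 stringsAsFactors = FALSE))
    recs$count <- c(cc$count, cc$count)
    recs <- recs[recs$focal_otu %in% elig$focal_otus, , drop = FALSE]
    pdm <- stats::cophenetic(world$species_tree)
    recs$pd <- pdm[cbind(recs$focal_otu, recs$partner_otu)]
    recs$co <- com[cbind(recs$focal_otu, recs$partner_otu)]
    res$cooccurrence <- residual_correlation_analysis(
      recs, n_shuffles = n_shuffles, seed = seeds[1])
    res$multi_threshold <- tryCatch(multi_transfer_threshold(counts),
                                    error = function(e) NA_integer_)
  }

  ## ecology -----------------------------------------------------------
  if ("ecology" %in% stages) {
    profiles <- select_generalists_specialists(
      abundance_tiers(habitat_profiles(world$abundance$abundance,
                                       world$abundance$sample_env)),
      n_per_env = n_per_env)
    res$profiles <- profiles
    pairs <- build_pair_table(world, counts)
    pi_ <- match(pairs$otu_a, profiles$otu)
    pj_ <- match(pairs$otu_b, profiles$otu)
    pairs$env_a <- profiles$preferred_env[pi_]
    pairs$env_b <- profiles$preferred_env[pj_]
    pairs$tier_a <- profiles$tier[pi_]
    pairs$tier_b <- profiles$tier[pj_]
    pairs$class_a <- profiles$class[pi_]
    pairs$class_b <- profiles$class[pj_]
    same_env <- !is.na(pairs$env_a) & !is.na(pairs$env_b) &
      pairs$env_a == pairs$env_b
    tier_pairs <- pairs[same_env, , drop = FALSE]
    tier_pairs$env <- tier_pairs$env_a
    res$tier_curves <- tier_transfer_curves(tier_pairs)
    res$env_zscores <- tryCatch(
      env_transfer_zscores(pairs, n_background = n_background,
                           seed = seeds[2]),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "pipeline_stage_error"))
  }

  ## outputs -----------------------------------------------------------
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (nrow(events))
      write_table(events, file.path(out_dir, "retained_events.tsv"), cfg)
    write_table(counts, file.path(out_dir, "pair_counts.tsv"), cfg)
    if (!is.null(res$species_fraction))
      write_table(res$species_fraction,
                  file.path(out_dir, "species_transfer_fraction.tsv"), cfg)
    if (!is.null(res$enrichment))
      write_table(res$enrichment, file.path(out_dir, "enrichment.tsv"), cfg)
    if (!is.null(res$cooccurrence) && nrow(res$cooccurrence$per_otu))
      write_table(res$cooccurrence$per_otu,
                  file.path(out_dir, "cooccurrence_rho.tsv"), cfg)
    if (!is.null(res$profiles))
      write_table(res$profiles, file.path(out_dir, "habitat_profiles.tsv"),
                  cfg)
    if (!is.null(res$tier_curves) && nrow(res$tier_curves$curves))
      write_table(res$tier_curves$curves,
                  file.path(out_dir, "tier_curves.tsv"), cfg)
    if (!is.null(res$env_zscores$zscores))
      write_table(res$env_zscores$zscores,
                  file.path(out_dir, "env_zscores.tsv"), cfg)
    files <- list.files(out_dir, full.names = TRUE)
    manifest <- list(
      package_version = pkg_version(),
      config_hash = config_hash(cfg), seed = cfg$seed,
      parameters = list(n_background = n_background,
                        n_shuffles = n_shuffles, n_per_env = n_per_env,
                        min_support = min_support,
                        min_branch_support = min_branch_support,
                        max_roots = max_roots),
      files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    res$manifest <- manifest
  }
  res
}
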