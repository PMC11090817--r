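#' Default species-distance by gene-distance bin grid
#'
#' Three equal-width species-distance bins spanning 0.08-2.00 and five gene
#' distance bins: a (0.50-0.75], b (0.25-0.50], c (0.00-0.25], with d
#' (0.00-0.05] nested in c and e (0.00-0.01] nested in d, so very recent
#' transfers contribute to every bin containing their gene distance.
#'
#' @return list with `species_edges` and `gene_bins` (named list of
#'   `(lower, upper]` intervals).
#' @export
default_bin_grid <- function() {
  list(species_edges = c(0.08, 0.72, 1.36, 2.00),
       gene_bins = list(a = c(0.50, 0.75), b = c(0.25, 0.50),
                        c = c(0.00, 0.25), d = c(0.00, 0.05),
                        e = c(0.00, 0.01)))
}

#' Assign a transfer event to grid bins
#'
#' @param mean_species_distance,mean_gene_distance event mean distances
#'   (gene distance may be `NA`).
#' @param grid a bin grid (see [default_bin_grid()]).
#' @return list with `species_bin` (integer 1..3 or `NA` when outside the
#'   grid) and `gene_bins` (character subset of the nested bin labels; empty
#'   when outside all bins or gene distance missing).
#' @export
assign_bins <- function(mean_species_distance, mean_gene_distance,
                        grid = default_bin_grid()) {
  se <- grid$species_edges
  sb <- findInterval(mean_species_distance, se, rightmost.closed = TRUE)
  if (is.na(sb) || sb < 1 || sb > length(se) - 1) sb <- NA_integer_
  gb <- character(0)
  if (!is.na(mean_gene_distance)) {
    for (nm in names(grid$gene_bins)) {
      iv <- grid$gene_bins[[nm]]
      if (mean_gene_distance > iv[1] && mean_gene_distance <= iv[2])
        gb <- c(gb, nm)
    }
  }
  list(species_bin = as.integer(sb), gene_bins = gb)
}

#' Background annotation fraction of a category
#'
#' Fraction of all gene families that passed the pipeline annotated to the
#' category; the null expectation for every per-cell binomial test.
#'
#' @param annotations named list: gene family -> character vector of
#'   categories (may be empty).
#' @param assessed_families character vector of families that passed the
#'   pipeline.
#' @param category category label.
#' @return fraction in `[0, 1]`.
#' @export
background_fraction <- function(annotations, assessed_families, category) {
  if (length(assessed_families) == 0L)
    stop_invalid("background_fraction: empty assessed set")
  hit <- vapply(assessed_families, function(f)
    category %in% (annotations[[f]] %||% character(0)), logical(1))
  mean(hit)
}

#' Per-cell functional enrichment test
#'
#' Two-sided exact binomial test of the observed fraction of events in a
#' grid cell annotated to a category against the pipeline-wide background
#' fraction.
#'
#' @param event_families character vector: the gene family of each event in
#'   the cell.
#' @param annotations named list of category vectors per family.
#' @param category category label.
#' @param background background fraction (see [background_fraction()]).
#' @return one-row data.frame: `n_events_in_cell`, `n_annotated`,
#'   `observed_fraction`, `expected_fraction`, `direction`, `p_raw`.
#' @export
cell_enrichment <- function(event_families, annotations, category,
                            background) {
  n <- length(event_families)
  if (n < 1) stop_invalid("cell_enrichment: empty cell")
  k <- sum(vapply(event_families, function(f)
    category %in% (annotations[[f]] %||% character(0)), logical(1)))
  if ((background <= 0 && k == 0) || (background >= 1 && k == n)) {
    p <- 1
  } else {
    p <- stats::binom.test(k, n, p = min(max(background, 0), 1))$p.value
  }
  obs <- k / n
  direction <- if (obs > background) "enriched"
               else if (obs < background) "depleted" else "none"
  data.frame(n_events_in_cell = n, n_annotated = k, observed_fraction = obs,
             expected_fraction = background, direction = direction,
             p_raw = p, stringsAsFactors = FALSE)
}

#' Holm-Sidak step-down multiple-testing adjustment
#'
#' Sorts p-values ascending and sets the i-th adjusted value to
#' `max_{j <= i} (1 - (1 - p_(j))^(m - j + 1))`, clipped to 1, returned in
#' input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
holm_sidak_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_invalid("holm_sidak_adjust: p-values must be in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, cummax(1 - (1 - ps)^(m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Enrichment analysis over the full bin grid
#'
#' Places each event on the species-distance x gene-distance grid and tests
#' every (species bin, gene bin, category) cell against the pipeline-wide
#' background fraction, adjusting over the chosen multiple-testing family.
#'
#' @param events data.frame with columns `gene_family_id`,
#'   `mean_species_distance`, `mean_gene_distance`.
#' @param annotations named list of category vectors per family.
#' @param assessed_families families that passed the pipeline (background
#'   universe); defaults to all annotated families.
#' @param categories categories to test; defaults to all labels seen.
#' @param grid a bin grid (see [default_bin_grid()]).
#' @param adjust_family `"global"` (one family over all cell x category
#'   tests, the default) or `"per_cell"`.
#' @return long data.frame with one row per (species_bin, gene_bin,
#'   category): the [cell_enrichment()] columns plus `p_adjusted`.
#' @export
enrichment_grid <- function(events, annotations, assessed_families = NULL,
                            categories = NULL, grid = default_bin_grid(),
                            adjust_family = c("global", "per_cell")) {
  adjust_family <- match.arg(adjust_family)
  assessed_families <- assessed_families %||% names(annotations)
  categories <- categories %||% sort(unique(unlist(annotations)))
  bins <- lapply(seq_len(nrow(events)), function(i)
    assign_bins(events$mean_species_distance[i],
                events$mean_gene_distance[i], grid))
  sb <- vapply(bins, `[[`, integer(1), "species_bin")

  bg <- vapply(categories, function(cat)
    background_fraction(annotations, assessed_families, cat), numeric(1))

  rows <- list()
  for (s in seq_len(length(grid$species_edges) - 1)) {
    for (g in names(grid$gene_bins)) {
      in_cell <- !is.na(sb) & sb == s &
        vapply(bins, function(b) g %in% b$gene_bins, logical(1))
      if (!any(in_cell)) next
      fams <- events$gene_family_id[in_cell]
      for (cat in categories) {
        cell <- cell_enrichment(fams, annotations, cat, bg[[cat]])
        cell$species_bin <- s
        cell$gene_bin <- g
        cell$category <- cat
        rows[[length(rows) + 1L]] <- cell
      }
    }
  }
  if (length(rows) == 0L) return(data.frame())
  out <- do.call(rbind, rows)
  if (adjust_family == "global") {
    out$p_adjusted <- holm_sidak_adjust(out$p_raw)
  } else {
    out$p_adjusted <- NA_real_
    for (key in unique(paste(out$species_bin, out$gene_bin))) {
      idx <- paste(out$species_bin, out$gene_bin) == key
      out$p_adjusted[idx] <- holm_sidak_adjust(out$p_raw[idx])
    }
  }
  out[c("species_bin", "gene_bin", "category", "n_events_in_cell",
        "n_annotated", "observed_fraction", "expected_fraction",
        "direction", "p_raw", "p_adjusted")]
}
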