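#' Classify gene ubiquity into extended core / shell / cloud
#'
#' Gene ubiquity is the fraction of a species' genomes carrying the gene
#' family.  Families at >= `core_min` ubiquity are extended core, <=
#' `cloud_max` are cloud, the rest shell.  Species with fewer than
#' `min_genomes` genomes are excluded (returned as `NA`).
#'
#' @param genomes_with_gene,genomes_total integer vectors (recycled).
#' @param min_genomes minimum genomes per species (default 10).
#' @param core_min,cloud_max class thresholds (defaults 0.90 and 0.15, both
#'   inclusive).
#' @return factor with levels `extended_core`, `shell`, `cloud`; `NA` for
#'   excluded species.
#' @export
classify_ubiquity <- function(genomes_with_gene, genomes_total,
                              min_genomes = 10, core_min = 0.90,
                              cloud_max = 0.15) {
  if (any(genomes_with_gene <= 0 | genomes_with_gene > genomes_total))
    stop_invalid("classify_ubiquity: need 0 < genomes_with_gene <= genomes_total")
  frac <- genomes_with_gene / genomes_total
  cls <- ifelse(frac >= core_min, "extended_core",
                ifelse(frac <= cloud_max, "cloud", "shell"))
  cls[genomes_total < min_genomes] <- NA
  factor(cls, levels = c("extended_core", "shell", "cloud"))
}

#' Label putative donor and recipient by gene ubiquity
#'
#' In a species pair participating in a transfer, the species with the
#' higher ubiquity of the transferred family is labelled the putative donor.
#' Equal or missing ubiquities leave the pair unassigned.
#'
#' @param ubiquity_a,ubiquity_b numeric ubiquity fractions (may be `NA`).
#' @return list with `donor` and `recipient` in `{"a", "b", NA}` and a
#'   `reason` when unassigned.
#' @export
assign_donor_recipient <- function(ubiquity_a, ubiquity_b) {
  if (is.na(ubiquity_a) || is.na(ubiquity_b))
    return(list(donor = NA_character_, recipient = NA_character_,
                reason = "missing ubiquity"))
  if (ubiquity_a == ubiquity_b)
    return(list(donor = NA_character_, recipient = NA_character_,
                reason = "tie"))
  if (ubiquity_a > ubiquity_b) list(donor = "a", recipient = "b",
                                    reason = NA_character_)
  else list(donor = "b", recipient = "a", reason = NA_character_)
}

#' Fisher's exact test with cross-product odds ratio
#'
#' Two-sided exact test on a 2x2 table.  Unlike the conditional-MLE odds
#' ratio, the reported odds ratio is the sample cross-product
#' `(n11 * n22) / (n12 * n21)` (with an `Inf`/`0` sentinel when a cell is
#' zero); the p-value is the exact two-sided Fisher p (sum of hypergeometric
#' probabilities at most that of the observed table).
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_odds_ratio <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)))
    stop_invalid("fisher_odds_ratio: need a 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_invalid("fisher_odds_ratio: zero marginal")
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p = p)
}

#' Transferred-vs-cloud contingency table
#'
#' Cross-tabulates pangenome rows by transfer status of the gene family and
#' membership in the requested ubiquity class, for the Fisher comparison of
#' transferred and non-transferred gene composition.
#'
#' @param pangenome data.frame with `species_id`, `gene_family_id`,
#'   `genomes_with_gene`, `genomes_total`.
#' @param transferred_families character vector of families in retained
#'   transfer events.
#' @param class_of_interest `"cloud"` (default) or `"extended_core"`.
#' @param ... passed to [classify_ubiquity()].
#' @return 2x2 matrix: rows transferred/non-transferred, columns in-class /
#'   not-in-class (excluded species dropped).
#' @export
transfer_ubiquity_table <- function(pangenome, transferred_families,
                                    class_of_interest = "cloud", ...) {
  cls <- classify_ubiquity(pangenome$genomes_with_gene,
                           pangenome$genomes_total, ...)
  keep <- !is.na(cls)
  in_class <- cls[keep] == class_of_interest
  transferred <- pangenome$gene_family_id[keep] %in% transferred_families
  m <- matrix(c(sum(transferred & in_class), sum(transferred & !in_class),
                sum(!transferred & in_class), sum(!transferred & !in_class)),
              2, 2, byrow = TRUE,
              dimnames = list(c("transferred", "non_transferred"),
                              c(class_of_interest,
                                paste0("not_", class_of_interest))))
  m
}
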