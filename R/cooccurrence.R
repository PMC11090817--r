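#' Presence/absence matrix from relative abundances
#'
#' An OTU is present in a sample if its relative abundance is at least
#' `threshold` (default 0.01%).
#'
#' @param abundance numeric matrix, OTUs x samples, values in `[0, 1]`.
#' @param threshold inclusive presence threshold (default `1e-4`).
#' @return logical matrix of the same shape.
#' @export
presence_matrix <- function(abundance, threshold = 1e-4) {
  if (any(abundance < 0)) stop_invalid("presence_matrix: negative abundance")
  abundance >= threshold
}

#' Co-occurrence of two OTUs
#'
#' Number of samples in which both OTUs are present, divided by the number
#' of samples in which the less prevalent OTU is present (a conditional
#' prevalence in `[0, 1]`).
#'
#' @param presence logical matrix, OTUs x samples.
#' @param otu_a,otu_b OTU row names.
#' @return co-occurrence in `[0, 1]`; `NA` if either OTU is never present.
#' @export
co_occurrence <- function(presence, otu_a, otu_b) {
  pa <- presence[otu_a, ]; pb <- presence[otu_b, ]
  na <- sum(pa); nb <- sum(pb)
  if (na == 0L || nb == 0L) return(NA_real_)
  sum(pa & pb) / min(na, nb)
}

#' All-pairs co-occurrence matrix
#'
#' Vectorised co-occurrence over every OTU pair (shared-sample counts via a
#' cross-product of the presence matrix).
#'
#' @param presence logical matrix, OTUs x samples.
#' @return symmetric matrix of co-occurrence values (`NA` where an OTU is
#'   never present; diagonal 1 for present OTUs).
#' @export
co_occurrence_matrix <- function(presence) {
  m <- presence * 1
  joint <- tcrossprod(m)
  n <- rowSums(m)
  mins <- outer(n, n, pmin)
  out <- joint / mins
  out[mins == 0] <- NA_real_
  out
}

#' Eligibility filter for the co-occurrence analysis
#'
#' Focal OTUs must have exchanged at least one gene with `min_partners`
#' other OTUs; a pair enters the analysis only if both OTUs are present in
#' at least `min_samples` samples.
#'
#' @param counts `hgt_counts` data.frame (`otu_a`, `otu_b`, `count`).
#' @param presence logical matrix, OTUs x samples.
#' @param min_partners minimum HGT partners for a focal OTU (default 30,
#'   inclusive).
#' @param min_samples minimum samples per OTU in a pair (default 20,
#'   inclusive).
#' @return list with `focal_otus` (character) and `pair_ok` (logical over
#'   the rows of `counts`).
#' @export
eligibility_filter <- function(counts, presence, min_partners = 30,
                               min_samples = 20) {
  with_transfer <- counts[counts$count >= 1, , drop = FALSE]
  partners <- table(c(with_transfer$otu_a, with_transfer$otu_b))
  focal <- names(partners)[partners >= min_partners]
  n_samp <- rowSums(presence)
  ok_a <- counts$otu_a %in% rownames(presence) &
    n_samp[counts$otu_a] >= min_samples
  ok_b <- counts$otu_b %in% rownames(presence) &
    n_samp[counts$otu_b] >= min_samples
  list(focal_otus = focal, pair_ok = unname(ok_a & ok_b))
}

#' Fit the co-occurrence power law CO = k * PD^a
#'
#' Nonlinear least squares on the natural scale, initialised from the
#' ordinary least-squares fit of log CO on log PD over pairs with positive
#' co-occurrence.  Pairs with PD = 0 are excluded.
#'
#' @param pd,co numeric vectors (phylogenetic distance, co-occurrence).
#' @return list of class `power_law_fit`: `k`, `a`, `residuals`
#'   (`co - k * pd^a`, same length/order as input, `NA` where excluded),
#'   `converged`.
#' @export
fit_power_law <- function(pd, co) {
  keep <- is.finite(pd) & is.finite(co) & pd > 0
  if (sum(keep) < 3)
    stop_invalid("fit_power_law: need at least 3 pairs with PD > 0")
  x <- pd[keep]; y <- co[keep]
  pos <- y > 0
  if (sum(pos) >= 2) {
    ols <- stats::lm(log(y[pos]) ~ log(x[pos]))
    start <- list(k = exp(unname(stats::coef(ols)[1])),
                  a = unname(stats::coef(ols)[2]))
  } else {
    start <- list(k = max(mean(y), 1e-6), a = 0)
  }
  sse_start <- mean((y - start$k * x^start$a)^2)
  if (sse_start < 1e-20 * max(1, mean(y)^2)) {
    ## the log-log initial estimate already fits exactly (noiseless or
    ## constant data); the Levenberg-Marquardt gradient is singular there
    cf <- c(k = start$k, a = start$a)
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ k * x^a, start = start,
                        lower = c(k = 1e-12, a = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e)
        stop_invalid("fit_power_law failed to converge (log-log estimate: k=",
                     signif(start$k, 4), ", a=", signif(start$a, 4), "): ",
                     conditionMessage(e)))
    cf <- stats::coef(fit)
  }
  res <- rep(NA_real_, length(pd))
  res[keep] <- co[keep] - cf[["k"]] * pd[keep]^cf[["a"]]
  structure(list(k = cf[["k"]], a = cf[["a"]], residuals = res,
                 converged = TRUE),
            class = "power_law_fit")
}

#' Per-OTU correlation of (corrected) co-occurrence with transfer counts
#'
#' For each focal OTU and its HGT partners: fits the co-occurrence-vs-PD
#' power law over the partners, then computes Spearman correlations of the
#' number of genes transferred with raw co-occurrence (`rho_pre`) and with
#' the model residuals (`rho_post`).  A background distribution is built by
#' shuffling the transfer counts across each OTU's partners before
#' correlating; the observed and background correlation distributions are
#' compared with a two-sided Mann-Whitney U test.
#'
#' @param records data.frame with `focal_otu`, `partner_otu`, `pd`, `co`,
#'   `count` (one row per eligible focal-partner pair; a pair may appear
#'   under both of its OTUs as focal).
#' @param n_shuffles shuffled replicates per focal OTU (default 1).
#' @param seed integer seed.
#' @param min_partners_fit skip OTUs with fewer usable partners (default 3).
#' @return list: `per_otu` data.frame (`focal_otu`, `n_partners`, `k`, `a`,
#'   `rho_pre`, `rho_post`), `background` numeric vector of shuffled
#'   correlations, `mwu_post_vs_background` (list `U`, `p`), and
#'   `mwu_pre_vs_background`.
#' @export
residual_correlation_analysis <- function(records, n_shuffles = 1,
                                          seed = NULL,
                                          min_partners_fit = 3) {
  stopifnot(all(c("focal_otu", "partner_otu", "pd", "co", "count") %in%
                  names(records)))
  with_seed(seed, {
    per <- list()
    bg <- numeric(0)
    for (otu in unique(records$focal_otu)) {
      sub <- records[records$focal_otu == otu & records$pd > 0 &
                       is.finite(records$co), , drop = FALSE]
      if (nrow(sub) < min_partners_fit) next
      if (length(unique(sub$count)) < 2) next  # rho undefined
      fit <- tryCatch(fit_power_law(sub$pd, sub$co), error = function(e) NULL)
      if (is.null(fit)) next
      rho_pre <- stats::cor(sub$co, sub$count, method = "spearman")
      rho_post <- stats::cor(fit$residuals, sub$count, method = "spearman")
      for (s in seq_len(n_shuffles)) {
        bg <- c(bg, stats::cor(fit$residuals, sample(sub$count),
                               method = "spearman"))
      }
      per[[length(per) + 1L]] <- data.frame(
        focal_otu = otu, n_partners = nrow(sub), k = fit$k, a = fit$a,
        rho_pre = rho_pre, rho_post = rho_post, stringsAsFactors = FALSE)
    }
    per_otu <- if (length(per)) do.call(rbind, per) else data.frame()
    res <- list(per_otu = per_otu, background = bg)
    if (nrow(per_otu) > 0 && length(bg) > 0) {
      res$mwu_post_vs_background <- mwu_compare(per_otu$rho_post, bg)
      res$mwu_pre_vs_background <- mwu_compare(per_otu$rho_pre, bg)
    }
    res
  })
}

#' Multi-transfer count cutoff
#'
#' The nearest-rank 80% quantile of pairwise transfer counts restricted to
#' pairs with at least one gene transferred; pairs at or above the cutoff
#' count as "multiple transfers".
#'
#' @param counts integer vector of pairwise transfer counts (or an
#'   `hgt_counts` data.frame).
#' @param q quantile (default 0.8).
#' @return integer cutoff.
#' @export
multi_transfer_threshold <- function(counts, q = 0.8) {
  if (is.data.frame(counts)) counts <- counts$count
  counts <- counts[counts >= 1]
  if (length(counts) == 0L)
    stop_invalid("multi_transfer_threshold: no pairs with >= 1 transfer")
  as.integer(ceiling(nearest_rank_quantile(counts, q)))
}

#' Interaction enrichment between multi-transfer and low-transfer pairs
#'
#' Fold enrichment of predicted ecological interactions among OTU pairs with
#' multiple genes transferred relative to pairs with at most one gene
#' transferred, after the two groups have been matched on phylogenetic
#' distance and co-occurrence.
#'
#' @param n_interacting_multi,n_interacting_low interacting-pair counts in
#'   the matched multi-transfer and low-transfer sets.
#' @return list with `fold` (`NA` when the denominator is zero) and the two
#'   counts.
#' @export
interaction_enrichment <- function(n_interacting_multi, n_interacting_low) {
  fold <- if (n_interacting_low > 0) n_interacting_multi / n_interacting_low
          else NA_real_
  list(fold = fold, n_multi = n_interacting_multi, n_low = n_interacting_low)
}

#' Matched interaction analysis from an edge list
#'
#' Splits OTU pairs into multi-transfer (count >= `threshold`) and
#' low-transfer (count <= 1) groups, matches the groups simultaneously on
#' phylogenetic distance and co-occurrence (an `n_bins` x `n_bins` grid),
#' and counts interacting pairs (edge score > 0) in each matched set.
#'
#' @param pairs data.frame with `otu_a`, `otu_b`, `pd`, `co`, `count`.
#' @param edges data.frame with `otu_a`, `otu_b`, `score`; pairs absent from
#'   the edge list are non-interacting.
#' @param threshold multi-transfer cutoff (default 7; see
#'   [multi_transfer_threshold()]).
#' @param n_bins bins per covariate for the matching (default 80).
#' @param seed integer seed for the matching.
#' @return the [interaction_enrichment()] list plus matched group sizes.
#' @export
interaction_analysis <- function(pairs, edges, threshold = 7, n_bins = 80,
                                 seed = NULL) {
  key <- pair_key(pairs$otu_a, pairs$otu_b)
  inter_keys <- if (nrow(edges)) {
    ek <- pair_key(edges$otu_a, edges$otu_b)
    ek[edges$score > 0]
  } else character(0)
  interacting <- key %in% inter_keys
  multi <- pairs$count >= threshold
  low <- pairs$count <= 1
  ma <- pairs[multi, c("pd", "co")]
  mb <- pairs[low, c("pd", "co")]
  m <- matched_subsample(ma, mb, n_bins = n_bins, seed = seed)
  ia <- which(multi)[m$idx_a]
  ib <- which(low)[m$idx_b]
  out <- interaction_enrichment(sum(interacting[ia]), sum(interacting[ib]))
  out$n_matched_per_group <- length(ia)
  out
}
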