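#' Distribution-matched subsampling of two groups
#'
#' Equalises the distribution of one or two covariates between two groups by
#' per-bin downsampling: the covariate range (pooled over both groups) is cut
#' into `n_bins` equal-width bins (a bin grid of `n_bins x n_bins` cells when
#' two covariates are given), and within each bin the larger group is randomly
#' downsampled without replacement to the size of the smaller group.  After
#' matching, the per-bin counts of the two selections are identical, so the
#' matched covariate distributions coincide up to bin resolution.  This is the
#' normalisation used before all nonparametric two-group comparisons in the
#' pipeline (e.g. comparing species-distance distributions of gene pairs with
#' and without transfers at equalised gene distance, or comparing co-occurrence
#' at equalised phylogenetic distance).
#'
#' @param covariates_a,covariates_b numeric vector (one covariate) or
#'   two-column matrix/data.frame (two covariates, matched simultaneously)
#'   for each group.
#' @param n_bins number of equal-width bins per covariate (default 80).
#' @param seed integer seed for the random downsampling; `NULL` uses the
#'   current RNG state.
#' @param edges optional list of per-covariate bin edge vectors (as returned
#'   in the `edges` component) to reuse a previously computed binning;
#'   re-matching an already matched pair of groups under the same edges is a
#'   no-op because all per-bin counts are already equal.
#' @return list with integer index vectors `idx_a` and `idx_b` into the two
#'   groups, `bins` (the per-group bin-cell assignments, for diagnostics)
#'   and `edges`.
#' @examples
#' a <- data.frame(x = runif(500))
#' b <- data.frame(x = rbeta(500, 2, 1))
#' m <- matched_subsample(a$x, b$x, n_bins = 20, seed = 1)
#' length(m$idx_a) == length(m$idx_b)
#' @export
matched_subsample <- function(covariates_a, covariates_b, n_bins = 80,
                              seed = NULL, edges = NULL) {
  ca <- as.matrix(covariates_a)
  cb <- as.matrix(covariates_b)
  if (nrow(ca) == 0L || nrow(cb) == 0L)
    stop_invalid("matched_subsample: both groups must be non-empty")
  if (ncol(ca) != ncol(cb))
    stop_invalid("matched_subsample: groups must have the same covariates")
  if (!ncol(ca) %in% 1:2)
    stop_invalid("matched_subsample: one or two covariates supported")
  if (any(!is.finite(ca)) || any(!is.finite(cb)))
    stop_invalid("matched_subsample: covariates must be finite")
  if (is.null(edges)) edges <- list(NULL, NULL)

  bin_one <- function(xa, xb, e) {
    if (is.null(e)) {
      rng <- range(c(xa, xb))
      e <- if (rng[1] == rng[2]) rng[1] + c(0, 1e-9)
           else seq(rng[1], rng[2], length.out = n_bins + 1L)
    }
    nb <- length(e) - 1L
    # right-open bins except the last (closed) one
    f <- function(x) pmin(pmax(findInterval(x, e,
                                            rightmost.closed = TRUE), 1L),
                          nb)
    list(a = f(xa), b = f(xb), edges = e)
  }

  b1 <- bin_one(ca[, 1], cb[, 1], edges[[1]])
  if (ncol(ca) == 2L) {
    b2 <- bin_one(ca[, 2], cb[, 2], edges[[2]])
    nb2 <- length(b2$edges) - 1L
    cell_a <- (b1$a - 1L) * nb2 + b2$a
    cell_b <- (b1$b - 1L) * nb2 + b2$b
    out_edges <- list(b1$edges, b2$edges)
  } else {
    cell_a <- b1$a
    cell_b <- b1$b
    out_edges <- list(b1$edges)
  }

  idx <- with_seed(seed, {
    ia <- integer(0); ib <- integer(0)
    shared <- intersect(unique(cell_a), unique(cell_b))
    for (cell in shared) {
      wa <- which(cell_a == cell)
      wb <- which(cell_b == cell)
      n <- min(length(wa), length(wb))
      ia <- c(ia, if (length(wa) > n) sample(wa, n) else wa)
      ib <- c(ib, if (length(wb) > n) sample(wb, n) else wb)
    }
    list(a = sort(ia), b = sort(ib))
  })
  if (length(idx$a) == 0L)
    warning("matched_subsample: covariate supports do not overlap; ",
            "empty selection")
  list(idx_a = idx$a, idx_b = idx$b,
       bins = list(a = cell_a, b = cell_b), edges = out_edges)
}

#' Mann-Whitney U test wrapper
#'
#' Two-sample rank test comparing the distributions of `values_a` and
#' `values_b`.  Uses the exact null distribution when the product of sample
#' sizes is at most 10,000 and there are no ties; otherwise the normal
#' approximation with tie correction.
#'
#' @param values_a,values_b numeric vectors (non-empty).
#' @param alternative one of `"two.sided"`, `"less"`, `"greater"` (alternative
#'   refers to `values_a` relative to `values_b`).
#' @return list with elements `U` (the Mann-Whitney U statistic for group a)
#'   and `p` (the p-value).
#' @export
mwu_compare <- function(values_a, values_b,
                        alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop_invalid("mwu_compare: both groups must be non-empty")
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  n_ab <- as.double(length(values_a)) * length(values_b)
  if (all(values_a == values_a[1]) && all(values_b == values_a[1])) {
    return(list(U = n_ab / 2, p = 1))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = alternative,
                       exact = (!ties && n_ab <= 10000), correct = FALSE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}
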