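ENVIRONMENTS <- c("animal", "aquatic", "plant", "soil")

#' Per-OTU habitat profiles
#'
#' For each OTU, the mean relative abundance over the samples of each of the
#' four major environments, the preferred environment (argmax of the four
#' means; ties and all-zero profiles are excluded with a reason), and the
#' generalism entropy of the profile.
#'
#' @param abundance numeric matrix, OTUs x samples.
#' @param sample_env character vector of environment labels per sample
#'   (values in `animal`, `aquatic`, `plant`, `soil`; other labels ignored).
#' @return data.frame: `otu`, one `mean_<env>` column per environment,
#'   `preferred_env` (`NA` when excluded), `exclusion_reason`, `entropy`,
#'   `entropy_normalized` (entropy / log 4).
#' @export
habitat_profiles <- function(abundance, sample_env) {
  stopifnot(ncol(abundance) == length(sample_env))
  means <- sapply(ENVIRONMENTS, function(e) {
    idx <- which(sample_env == e)
    if (length(idx) == 0L) rep(NA_real_, nrow(abundance))
    else rowMeans(abundance[, idx, drop = FALSE])
  })
  rownames(means) <- rownames(abundance)
  pref <- character(nrow(means)); reason <- rep(NA_character_, nrow(means))
  for (i in seq_len(nrow(means))) {
    v <- means[i, ]
    v[is.na(v)] <- 0
    if (all(v == 0)) {
      pref[i] <- NA; reason[i] <- "all zero"
    } else if (sum(v == max(v)) > 1) {
      pref[i] <- NA; reason[i] <- "tie"
    } else {
      pref[i] <- ENVIRONMENTS[which.max(v)]
    }
  }
  ent <- apply(means, 1, function(v) {
    v[is.na(v)] <- 0
    generalism_entropy(v)
  })
  out <- data.frame(otu = rownames(means), means,
                    preferred_env = pref, exclusion_reason = reason,
                    entropy = ent, entropy_normalized = ent / log(4),
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[2:5] <- paste0("mean_", ENVIRONMENTS)
  out
}

#' Generalism entropy of an abundance profile
#'
#' Shannon entropy (natural log) of the four environment mean abundances
#' after normalising them to sum to one; 0 for a single-environment
#' specialist, `log(4)` for a perfectly even generalist.
#'
#' @param means numeric vector of 4 per-environment mean abundances.
#' @return entropy in `[0, log(4)]`; `NA` when all means are zero.
#' @export
generalism_entropy <- function(means) {
  s <- sum(means)
  if (!is.finite(s) || s <= 0) return(NA_real_)
  q <- means / s
  q <- q[q > 0]
  -sum(q * log(q))
}

#' Abundance tiers within preferred environments
#'
#' Within each environment, OTUs preferring it are split on the 80% and 20%
#' quantiles of their mean abundance in that environment: strictly above the
#' upper quantile is `high`, strictly below the lower quantile is `low`,
#' everything else `mid`.
#'
#' @param profiles output of [habitat_profiles()].
#' @param q_high,q_low quantile cutpoints (defaults 0.8 / 0.2).
#' @return `profiles` with added columns `abundance_in_pref` and `tier`
#'   (`NA` for OTUs without a preferred environment).
#' @export
abundance_tiers <- function(profiles, q_high = 0.8, q_low = 0.2) {
  profiles$abundance_in_pref <- NA_real_
  profiles$tier <- NA_character_
  for (e in ENVIRONMENTS) {
    idx <- which(!is.na(profiles$preferred_env) & profiles$preferred_env == e)
    if (length(idx) == 0L) next
    ab <- profiles[[paste0("mean_", e)]][idx]
    profiles$abundance_in_pref[idx] <- ab
    hi <- stats::quantile(ab, q_high, names = FALSE)
    lo <- stats::quantile(ab, q_low, names = FALSE)
    profiles$tier[idx] <- ifelse(ab > hi, "high",
                                 ifelse(ab < lo, "low", "mid"))
  }
  profiles
}

#' Transfer-fraction curves by abundance tier
#'
#' For OTU pairs sharing a preferred environment, computes per phylogenetic
#' distance bin the fraction of pairs with at least one transfer, separately
#' for the high-high, high-low and low-low tier groups, with Bernoulli
#' standard-error bands `sqrt(p(1-p)/n)`.  Group curves are compared with
#' one-sided Wilcoxon rank-sum tests on the per-bin fractions (testing the
#' ordering high-high > high-low > low-low) and Benjamini-Hochberg adjusted
#' across all comparisons and environments.
#'
#' @param pairs data.frame with `pd`, `transferred` (logical), `env`
#'   (shared preferred environment), `tier_a`, `tier_b`.
#' @param n_bins equal-count distance bins per environment (default 20).
#' @return list: `curves` (env, group, bin, pd_mid, fraction, band, n) and
#'   `tests` (env, comparison, p_raw, p_adjusted).
#' @export
tier_transfer_curves <- function(pairs, n_bins = 20) {
  grp <- function(a, b) {
    t <- sort(c(a, b))
    if (all(t == "high")) "high-high"
    else if (all(t == "low")) "low-low"
    else if (t[1] == "high" && t[2] == "low") "high-low"
    else NA_character_
  }
  pairs$group <- mapply(grp, pairs$tier_a, pairs$tier_b)
  pairs <- pairs[!is.na(pairs$group), , drop = FALSE]
  curves <- list(); tests <- list()
  for (e in intersect(ENVIRONMENTS, unique(pairs$env))) {
    sub <- pairs[pairs$env == e, , drop = FALSE]
    if (nrow(sub) < n_bins) next
    edges <- unique(stats::quantile(sub$pd, probs = seq(0, 1,
                                                        length.out = n_bins + 1)))
    sub$bin <- cut(sub$pd, edges, include.lowest = TRUE, labels = FALSE)
    frac_by <- list()
    for (g in c("high-high", "high-low", "low-low")) {
      gsub <- sub[sub$group == g, , drop = FALSE]
      if (nrow(gsub) == 0L) next
      for (b in sort(unique(gsub$bin))) {
        bs <- gsub[gsub$bin == b, , drop = FALSE]
        p_hat <- mean(bs$transferred)
        curves[[length(curves) + 1L]] <- data.frame(
          env = e, group = g, bin = b,
          pd_mid = stats::median(bs$pd), fraction = p_hat,
          band = sqrt(p_hat * (1 - p_hat) / nrow(bs)), n = nrow(bs),
          stringsAsFactors = FALSE)
        frac_by[[g]] <- c(frac_by[[g]], p_hat)
      }
    }
    cmp <- list(c("high-high", "high-low"), c("high-high", "low-low"),
                c("high-low", "low-low"))
    for (cm in cmp) {
      if (is.null(frac_by[[cm[1]]]) || is.null(frac_by[[cm[2]]])) next
      p <- suppressWarnings(stats::wilcox.test(frac_by[[cm[1]]],
                                               frac_by[[cm[2]]],
                                               alternative = "greater"))$p.value
      tests[[length(tests) + 1L]] <- data.frame(
        env = e, comparison = paste(cm, collapse = " > "), p_raw = p,
        stringsAsFactors = FALSE)
    }
  }
  curves <- if (length(curves)) do.call(rbind, curves) else data.frame()
  tests <- if (length(tests)) do.call(rbind, tests) else data.frame()
  if (nrow(tests)) tests$p_adjusted <- stats::p.adjust(tests$p_raw, "BH")
  list(curves = curves, tests = tests)
}

#' Select generalists and specialists by entropy
#'
#' Per preferred environment, the `n_per_env` OTUs with the highest entropy
#' are classed generalists and the `n_per_env` with the lowest entropy
#' specialists (deterministic tie-break on OTU identifier).  When an
#' environment holds fewer than `2 * n_per_env` OTUs, `n_per_env` is clipped
#' with a warning.
#'
#' @param profiles output of [habitat_profiles()].
#' @param n_per_env OTUs per class per environment (default 200).
#' @return `profiles` with added column `class` in
#'   `{generalist, specialist, neither}` (`NA` preferred env stays `NA`).
#' @export
select_generalists_specialists <- function(profiles, n_per_env = 200) {
  profiles$class <- ifelse(is.na(profiles$preferred_env), NA, "neither")
  for (e in intersect(ENVIRONMENTS, unique(profiles$preferred_env))) {
    idx <- which(!is.na(profiles$preferred_env) &
                   profiles$preferred_env == e & !is.na(profiles$entropy))
    n <- n_per_env
    if (length(idx) < 2 * n) {
      n <- floor(length(idx) / 2)
      warning("environment '", e, "': only ", length(idx),
              " OTUs; n_per_env clipped to ", n)
    }
    if (n == 0L) next
    ord <- idx[order(profiles$entropy[idx], profiles$otu[idx])]
    profiles$class[utils::tail(ord, n)] <- "generalist"
    profiles$class[utils::head(ord, n)] <- "specialist"
  }
  profiles
}

#' Inter-environment transfer-rate matrices and resampled Z-scores
#'
#' For each group (all species, generalists, specialists) and each unordered
#' pair of the four environments, computes the fraction of OTU pairs with at
#' least one transfer on subsamples equalised to a common phylogenetic
#' distance distribution.  Summary statistics over the ten environment-pair
#' cells (mean, s.d., range) are compared with a background distribution
#' obtained by drawing `n_background` equally-matched subsamples of
#' all-species pairs at the same cell sizes; a normal distribution is fitted
#' to each background and Z-scores reported.
#'
#' The PD equalisation draws per-bin hypergeometric success counts, which is
#' distributionally identical to index-level matched subsampling of the
#' transfer flags and allows thousands of background replicates.
#'
#' @param pairs data.frame with `pd`, `transferred` (logical), `env_a`,
#'   `env_b` (preferred environments) and `class_a`, `class_b`
#'   (`generalist`/`specialist`/`neither`).
#' @param n_background background replicates (default 1000).
#' @param n_bins equal-count PD bins for the matching (default 20).
#' @param seed integer seed.
#' @return list: `fractions` (4x4 mirrored matrix per group), `zscores`
#'   data.frame (group, statistic, observed, background_mean,
#'   background_sd, z), `cell_sizes`.
#' @export
env_transfer_zscores <- function(pairs, n_background = 1000, n_bins = 20,
                                 seed = NULL) {
  keep <- pairs$env_a %in% ENVIRONMENTS & pairs$env_b %in% ENVIRONMENTS &
    is.finite(pairs$pd)
  pairs <- pairs[keep, , drop = FALSE]
  edges <- unique(stats::quantile(pairs$pd,
                                  probs = seq(0, 1, length.out = n_bins + 1)))
  pairs$bin <- cut(pairs$pd, edges, include.lowest = TRUE, labels = FALSE)
  B <- length(edges) - 1L
  pairs$cell <- pair_key(pairs$env_a, pairs$env_b)
  cells <- sort(unique(pairs$cell))

  groups <- list(
    all = rep(TRUE, nrow(pairs)),
    generalist = pairs$class_a == "generalist" &
      pairs$class_b == "generalist",
    specialist = pairs$class_a == "specialist" &
      pairs$class_b == "specialist")
  groups <- groups[vapply(groups, function(g) any(g, na.rm = TRUE),
                          logical(1))]
  groups <- lapply(groups, function(g) !is.na(g) & g)

  ## per cell x bin totals and successes, per group and for the background
  tab <- function(mask) {
    n <- matrix(0L, length(cells), B, dimnames = list(cells, NULL))
    k <- n
    sub <- pairs[mask, , drop = FALSE]
    if (nrow(sub)) {
      tn <- table(factor(sub$cell, cells), factor(sub$bin, seq_len(B)))
      tk <- table(factor(sub$cell[sub$transferred], cells),
                  factor(sub$bin[sub$transferred], seq_len(B)))
      n[] <- tn; k[] <- tk
    }
    list(n = n, k = k)
  }
  bg_tab <- tab(rep(TRUE, nrow(pairs)))

  stat3 <- function(fr) c(mean = mean(fr), sd = stats::sd(fr),
                          range = max(fr) - min(fr))

  with_seed(seed, {
    ## the common PD target is supported only on bins populated in every
    ## group x cell combination (environments are phylogenetically
    ## clustered, so extreme-distance bins can be structurally empty for
    ## some environment pairs); within that support each cell is
    ## downsampled to equal per-bin counts, equalising the distance
    ## distribution across cells and groups
    tabs <- lapply(groups, tab)
    support <- which(Reduce(`&`, lapply(tabs, function(tt)
      apply(tt$n >= 1, 2, all))))
    if (length(support) == 0L)
      stop_invalid("env_transfer_zscores: no phylogenetic distance bin is ",
                   "populated in every environment-pair cell of every group")
    fractions <- list(); zrows <- list(); cell_sizes <- list()
    for (gname in names(groups)) {
      gt <- tabs[[gname]]
      ## matched per-bin draw size in each cell = min bin count of the cell
      t_draw <- apply(gt$n[, support, drop = FALSE], 1, min)
      empty <- names(t_draw)[t_draw == 0]
      if (length(empty))
        stop_invalid("env_transfer_zscores: environment-pair cell(s) empty ",
                     "after matching for group '", gname, "': ",
                     paste(empty, collapse = ", "))
      nb <- length(support)
      obs_fr <- numeric(length(cells)); names(obs_fr) <- cells
      bg_stats <- matrix(0, n_background, 3,
                         dimnames = list(NULL, c("mean", "sd", "range")))
      bg_fr <- matrix(0, n_background, length(cells))
      for (ci in seq_along(cells)) {
        tt <- t_draw[ci]
        kk <- gt$k[ci, support]; nn <- gt$n[ci, support]
        s_obs <- stats::rhyper(nb, kk, nn - kk, tt)
        obs_fr[ci] <- sum(s_obs) / (nb * tt)
        ## background: all-species pairs of the same cell, same draw sizes
        kb <- bg_tab$k[ci, support]; nb_ <- bg_tab$n[ci, support]
        s_bg <- matrix(stats::rhyper(nb * n_background,
                                     rep(kb, each = n_background),
                                     rep(nb_ - kb, each = n_background),
                                     tt),
                       n_background, nb)
        bg_fr[, ci] <- rowSums(s_bg) / (nb * tt)
      }
      for (r in seq_len(n_background)) bg_stats[r, ] <- stat3(bg_fr[r, ])
      obs_stats <- stat3(obs_fr)
      for (s in colnames(bg_stats)) {
        fitn <- MASS::fitdistr(bg_stats[, s], "normal")$estimate
        zrows[[length(zrows) + 1L]] <- data.frame(
          group = gname, statistic = s, observed = unname(obs_stats[s]),
          background_mean = unname(fitn["mean"]),
          background_sd = unname(fitn["sd"]),
          z = unname((obs_stats[s] - fitn["mean"]) / fitn["sd"]),
          stringsAsFactors = FALSE)
      }
      m <- matrix(NA_real_, 4, 4, dimnames = list(ENVIRONMENTS, ENVIRONMENTS))
      for (ci in seq_along(cells)) {
        ee <- strsplit(cells[ci], "|", fixed = TRUE)[[1]]
        m[ee[1], ee[2]] <- obs_fr[ci]
        m[ee[2], ee[1]] <- obs_fr[ci]
      }
      fractions[[gname]] <- m
      cell_sizes[[gname]] <- t_draw * length(support)
    }
    list(fractions = fractions, zscores = do.call(rbind, zrows),
         cell_sizes = cell_sizes)
  })
}
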