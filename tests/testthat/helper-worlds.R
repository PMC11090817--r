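## Shared fixture worlds, built once per test run and memoised.

.world_cache <- new.env(parent = emptyenv())

cached_world <- function(name, config) {
  if (!exists(name, envir = .world_cache)) {
    assign(name, simulate_world(config), envir = .world_cache)
  }
  get(name, envir = .world_cache)
}

## a small but fully featured world used by several test files
small_world <- function() {
  cached_world("small", world_config(
    n_species = 120, n_samples = 600, n_gene_families = 1500,
    n_reconciliations = 30, seed = 101))
}

## hand-built three-leaf tree: ((A:0.1,B:0.2):0.05,C:0.3);
abc_tree <- function() {
  ape::read.tree(text = "((A:0.1,B:0.2)ab:0.05,C:0.3)r;")
}

## brute-force Mann-Whitney p by enumeration over rank assignments
enumerate_mwu <- function(a, b, alternative = "two.sided") {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  u_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(ix) {
    aa <- pooled[ix]; bb <- pooled[-ix]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  })
  switch(alternative,
         two.sided = mean(abs(us - n * m / 2) >= abs(u_obs - n * m / 2)),
         greater = mean(us >= u_obs),
         less = mean(us <= u_obs))
}

## brute-force two-sided Fisher p: enumerate all tables with fixed margins
enumerate_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x)
    stats::dhyper(x, c1, n - c1, r1), numeric(1))
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
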