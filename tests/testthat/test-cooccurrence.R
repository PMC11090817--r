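test_that("presence threshold is inclusive at 0.01%", {
  m <- matrix(c(1e-4, 9e-5, 0, 0.2), 2, 2,
              dimnames = list(c("o1", "o2"), c("s1", "s2")))
  p <- presence_matrix(m)
  expect_true(p["o1", "s1"])
  expect_false(p["o2", "s1"])
  expect_false(p["o1", "s2"])
  expect_error(presence_matrix(-m), "negative")
})

test_that("co-occurrence is shared samples over the rarer OTU's samples", {
  pres <- matrix(FALSE, 2, 5, dimnames = list(c("a", "b"), paste0("s", 1:5)))
  pres["a", c("s1", "s2", "s3")] <- TRUE
  pres["b", c("s2", "s3", "s4", "s5")] <- TRUE
  expect_equal(co_occurrence(pres, "a", "b"), 2 / 3)
  expect_equal(co_occurrence(pres, "b", "a"), 2 / 3)
  pres2 <- rbind(pres, c = pres["a", ])
  expect_equal(co_occurrence(pres2, "a", "c"), 1)
  pres3 <- rbind(pres2, d = !pres["a", ])
  expect_equal(co_occurrence(pres3, "a", "d"), 0)
  ## matrix form agrees with the pairwise definition and is symmetric
  cm <- co_occurrence_matrix(pres3)
  expect_true(isSymmetric(cm))
  expect_equal(cm["a", "b"], 2 / 3)
  ## invariant under sample permutation
  perm <- sample(ncol(pres3))
  expect_equal(co_occurrence_matrix(pres3[, perm]), cm)
})

test_that("eligibility thresholds are inclusive", {
  counts <- do.call(rbind, lapply(1:30, function(i)
    data.frame(otu_a = "hub", otu_b = paste0("p", i), count = 1L)))
  counts2 <- rbind(counts, data.frame(otu_a = "weak",
                                      otu_b = paste0("p", 1:29), count = 1L))
  pres <- matrix(TRUE, 32, 20,
                 dimnames = list(c("hub", "weak", paste0("p", 1:30)),
                                 paste0("s", 1:20)))
  el <- eligibility_filter(counts2, pres)
  expect_true("hub" %in% el$focal_otus)     # exactly 30 partners
  expect_false("weak" %in% el$focal_otus)   # 29 partners
  expect_true(all(el$pair_ok))              # exactly 20 samples each
  pres19 <- pres; pres19["hub", 20] <- FALSE
  el2 <- eligibility_filter(counts2, pres19)
  expect_false(any(el2$pair_ok[counts2$otu_a == "hub"]))
})

test_that("power-law fit recovers noiseless parameters exactly", {
  pd <- c(0.25, 0.49, 1.0, 4.0)
  co <- 0.5 * pd^-0.5
  fit <- fit_power_law(pd, co)
  expect_equal(fit$k, 0.5, tolerance = 1e-6)
  expect_equal(fit$a, -0.5, tolerance = 1e-6)
  expect_equal(fit$residuals, rep(0, 4), tolerance = 1e-8)

  flat <- fit_power_law(seq(0.1, 2, length.out = 20), rep(0.4, 20))
  expect_equal(flat$a, 0, tolerance = 1e-6)
  expect_error(fit_power_law(c(0, 0, 0), c(1, 1, 1)), "PD > 0")
})

test_that("power-law exponent is recovered under lognormal noise", {
  set.seed(51)
  errs <- vapply(1:50, function(i) {
    pd <- runif(500, 0.05, 2)
    co <- 0.3 * pd^-0.5 * rlnorm(500, 0, 0.2)
    fit_power_law(pd, co)$a - (-0.5)
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.1)
})

test_that("multi-transfer cutoff uses the nearest-rank 80% quantile", {
  nearest_rank_oracle <- function(x, p) sort(x)[ceiling(p * length(x))]
  expect_equal(multi_transfer_threshold(rep(1, 10)), 1L)
  expect_equal(multi_transfer_threshold(1:10),
               as.integer(nearest_rank_oracle(1:10, 0.8)))
  expect_equal(multi_transfer_threshold(1:10), 8L)
  set.seed(52)
  for (i in 1:10) {
    x <- rpois(50, 3) + 1L
    expect_equal(multi_transfer_threshold(x),
                 as.integer(nearest_rank_oracle(x, 0.8)))
  }
  ## zero-count pairs are excluded from the quantile
  df <- data.frame(otu_a = "a", otu_b = letters[2:11],
                   count = c(rep(0L, 5), rep(2L, 5)))
  expect_equal(multi_transfer_threshold(df), 2L)
  expect_error(multi_transfer_threshold(rep(0, 5)), "no pairs")
})

test_that("interaction enrichment reproduces the printed fold changes", {
  expect_equal(round(interaction_enrichment(1012, 571)$fold, 1), 1.8)
  expect_equal(round(interaction_enrichment(12525, 10071)$fold, 1), 1.2)
  expect_equal(interaction_enrichment(50, 50)$fold, 1)
  expect_true(is.na(interaction_enrichment(10, 0)$fold))
})

test_that("matched interaction analysis counts interacting pairs per group", {
  set.seed(53)
  n <- 2000
  pairs <- data.frame(otu_a = paste0("x", 1:n), otu_b = paste0("y", 1:n),
                      pd = runif(n, 0, 2), co = runif(n),
                      count = sample(c(0, 1, 8, 10), n, replace = TRUE),
                      stringsAsFactors = FALSE)
  ## interactions planted preferentially in multi-transfer pairs
  inter <- pairs$count >= 7 & runif(n) < 0.4 |
    pairs$count <= 1 & runif(n) < 0.2
  edges <- data.frame(otu_a = pairs$otu_a[inter], otu_b = pairs$otu_b[inter],
                      score = 1)
  out <- interaction_analysis(pairs, edges, threshold = 7, n_bins = 10,
                              seed = 1)
  expect_gt(out$fold, 1)
  expect_equal(out$n_multi + out$n_low <= sum(inter), TRUE)
})

test_that("residual correlation: perfect monotone counts give rho_post 1", {
  set.seed(54)
  pd <- runif(40, 0.1, 2)
  co <- 0.3 * pd^-0.5
  resid_true <- rnorm(40, 0, 0.02)
  rec <- data.frame(focal_otu = "f", partner_otu = paste0("p", 1:40),
                    pd = pd, co = co + resid_true,
                    count = rank(resid_true), stringsAsFactors = FALSE)
  out <- residual_correlation_analysis(rec, n_shuffles = 2, seed = 9)
  expect_equal(out$per_otu$rho_post, 1, tolerance = 0.05)
  ## constant counts -> OTU skipped
  rec$count <- 3
  out2 <- residual_correlation_analysis(rec, seed = 9)
  expect_equal(nrow(out2$per_otu), 0L)
})

test_that("rank correlations are invariant to monotone count rescaling", {
  set.seed(55)
  pd <- runif(30, 0.1, 2)
  rec <- data.frame(focal_otu = "f", partner_otu = paste0("p", 1:30),
                    pd = pd, co = 0.3 * pd^-0.5 * rlnorm(30, 0, 0.1),
                    count = rpois(30, 3) + 1, stringsAsFactors = FALSE)
  out1 <- residual_correlation_analysis(rec, seed = 7)
  rec2 <- rec; rec2$count <- rec$count^3 + 10
  out2 <- residual_correlation_analysis(rec2, seed = 7)
  expect_equal(out1$per_otu$rho_pre, out2$per_otu$rho_pre)
  expect_equal(out1$per_otu$rho_post, out2$per_otu$rho_post)
})
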