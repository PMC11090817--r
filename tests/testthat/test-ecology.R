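test_that("generalism entropy has the stated extremes and invariances", {
  expect_equal(generalism_entropy(c(0.25, 0.25, 0.25, 0.25)), log(4))
  expect_equal(generalism_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(generalism_entropy(c(0.5, 0.5, 0, 0)), log(2))
  ## scale and permutation invariance; uniform is the unique maximum
  expect_equal(generalism_entropy(c(2, 2, 2, 2)), log(4))
  v <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(generalism_entropy(v), generalism_entropy(rev(v)))
  expect_lt(generalism_entropy(v), log(4))
  expect_true(is.na(generalism_entropy(c(0, 0, 0, 0))))
})

test_that("preferred habitat is the argmax of environment means", {
  ab <- rbind(o1 = c(0.02, 0.02, 0.001, 0.0005, 0.0002, 0.0002),
              o2 = c(0.001, 0.001, 0.05, 0.04, 0.001, 0.001),
              o3 = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01),
              o4 = c(0, 0, 0, 0, 0, 0))
  env <- c("animal", "animal", "aquatic", "aquatic", "plant", "soil")
  prof <- habitat_profiles(ab, env)
  expect_equal(prof$preferred_env[prof$otu == "o1"], "animal")
  expect_equal(prof$preferred_env[prof$otu == "o2"], "aquatic")
  ## exact tie across all four -> excluded with reason
  expect_true(is.na(prof$preferred_env[prof$otu == "o3"]))
  expect_equal(prof$exclusion_reason[prof$otu == "o3"], "tie")
  expect_equal(prof$exclusion_reason[prof$otu == "o4"], "all zero")
})

test_that("abundance tiers use strict quantile inequalities per environment", {
  ## 10 OTUs with distinct abundances -> exactly 2 high and 2 low
  prof <- data.frame(otu = paste0("o", 1:10),
                     mean_animal = seq(0.01, 0.1, length.out = 10),
                     mean_aquatic = 0, mean_plant = 0, mean_soil = 0,
                     preferred_env = "animal", stringsAsFactors = FALSE)
  t1 <- abundance_tiers(prof)
  expect_equal(sum(t1$tier == "high"), 2)
  expect_equal(sum(t1$tier == "low"), 2)
  ## all equal -> everything mid
  prof2 <- prof; prof2$mean_animal <- 0.05
  t2 <- abundance_tiers(prof2)
  expect_true(all(t2$tier == "mid"))
  ## invariant to monotone rescaling within an environment
  prof3 <- prof; prof3$mean_animal <- prof$mean_animal^2 * 10
  expect_equal(abundance_tiers(prof3)$tier, t1$tier)
  ## independent computation per environment
  prof4 <- prof
  prof4$preferred_env <- rep(c("animal", "soil"), each = 5)
  prof4$mean_soil <- prof4$mean_animal
  t4 <- abundance_tiers(prof4)
  expect_equal(sum(t4$tier == "high"), 2)  # 1 per environment
})

test_that("error bands equal the binomial standard error", {
  set.seed(71)
  pairs <- data.frame(pd = runif(2000, 0, 2),
                      transferred = runif(2000) < 0.3,
                      env = "animal",
                      tier_a = sample(c("high", "low"), 2000, TRUE),
                      tier_b = sample(c("high", "low"), 2000, TRUE),
                      stringsAsFactors = FALSE)
  out <- tier_transfer_curves(pairs, n_bins = 5)
  expect_true(all(abs(out$curves$band -
                        sqrt(out$curves$fraction *
                               (1 - out$curves$fraction) /
                               out$curves$n)) < 1e-12))
  ## spot values: p = 0.1, n = 100 -> band 0.03; all transferred -> band 0
  expect_equal(sqrt(0.1 * 0.9 / 100), 0.03)
  allt <- pairs; allt$transferred <- TRUE
  outt <- tier_transfer_curves(allt, n_bins = 5)
  expect_true(all(outt$curves$fraction == 1))
  expect_true(all(outt$curves$band == 0))
})

test_that("generalist/specialist selection counts and tie-breaks are exact", {
  prof <- data.frame(otu = sprintf("o%03d", 1:500),
                     preferred_env = "animal",
                     entropy = runif(500), stringsAsFactors = FALSE)
  out <- select_generalists_specialists(prof, n_per_env = 200)
  expect_equal(sum(out$class == "generalist"), 200)
  expect_equal(sum(out$class == "specialist"), 200)
  expect_equal(sum(out$class == "neither"), 100)
  ## clipping with warning
  expect_warning(out2 <- select_generalists_specialists(prof[1:100, ],
                                                        n_per_env = 200),
                 "clipped")
  expect_equal(sum(out2$class == "generalist"), 50)
  ## deterministic lexicographic tie-break at an entropy tie
  prof3 <- data.frame(otu = c("b", "a", "c", "d"), preferred_env = "animal",
                      entropy = c(0.5, 0.5, 0.9, 0.1),
                      stringsAsFactors = FALSE)
  out3 <- select_generalists_specialists(prof3, n_per_env = 1)
  expect_equal(out3$class[out3$otu == "c"], "generalist")
  expect_equal(out3$class[out3$otu == "d"], "specialist")
  out3b <- select_generalists_specialists(prof3[c(2, 1, 3, 4), ],
                                          n_per_env = 1)
  expect_equal(out3b$class[out3b$otu == "c"], "generalist")
})

test_that("Z-score matches its definition and self-background is calibrated", {
  ## observed 0.10 against background N(0.05, 0.005) -> Z = 10
  z <- (0.10 - 0.05) / 0.005
  expect_equal(z, 10)
  ## synthetic pair table: all-group Z against its own background should be
  ## approximately standard normal over repetitions
  set.seed(72)
  n <- 4000
  envs <- sample(ENVIRONMENTS, 2 * n, TRUE)
  pairs <- data.frame(pd = runif(n, 0, 2),
                      env_a = envs[1:n], env_b = envs[(n + 1):(2 * n)],
                      transferred = runif(n) < 0.25,
                      class_a = "neither", class_b = "neither",
                      stringsAsFactors = FALSE)
  zs <- vapply(1:60, function(i) {
    out <- env_transfer_zscores(pairs, n_background = 120, n_bins = 6,
                                seed = 1000 + i)
    out$zscores$z[out$zscores$group == "all" &
                    out$zscores$statistic == "sd"]
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.4)
  expect_gt(sd(zs), 0.6)
  expect_lt(sd(zs), 1.6)
})

test_that("environment-pair fraction matrices are symmetric with 10 cells", {
  set.seed(73)
  n <- 3000
  envs <- sample(ENVIRONMENTS, 2 * n, TRUE)
  cls <- sample(c("generalist", "specialist", "neither"), 2 * n, TRUE)
  pairs <- data.frame(pd = runif(n, 0, 2),
                      env_a = envs[1:n], env_b = envs[(n + 1):(2 * n)],
                      transferred = runif(n) < 0.3,
                      class_a = cls[1:n], class_b = cls[(n + 1):(2 * n)],
                      stringsAsFactors = FALSE)
  out <- env_transfer_zscores(pairs, n_background = 50, n_bins = 5, seed = 2)
  for (g in names(out$fractions)) {
    m <- out$fractions[[g]]
    expect_true(isSymmetric(m))
    expect_equal(dim(m), c(4, 4))
    expect_true(all(m >= 0 & m <= 1, na.rm = TRUE))
  }
  expect_equal(nrow(out$zscores), 9)
})
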