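test_that("site frequencies respect the MAF window and seed", {
  f <- simulate_site_frequencies(500, c(0.4, 0.5), seed = 2)
  maf <- pmin(f, 1 - f)
  expect_true(all(maf > 0.4 & maf <= 0.5))
  expect_true(any(f > 0.5) && any(f < 0.5)) # B minor or major with equal chance
  expect_identical(simulate_site_frequencies(500, c(0.4, 0.5), seed = 2), f)
  low <- simulate_site_frequencies(500, c(0.0, 0.1), seed = 3)
  expect_true(all(low > 0 & low < 1))
  expect_error(simulate_site_frequencies(10, c(0.3, 0.3)), "min < max")
})

test_that("source genotypes share within groups and follow HWE", {
  L <- 4000
  freqs <- rep(0.5, L)
  truth <- simulate_source_genotypes(c(1L, 1L, 1L), freqs, seed = 4)
  expect_identical(ncol(truth$source_genotypes), 1L) # one distinct source
  counts <- tabulate(truth$source_genotypes + 1L, 3L) / L
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / L)
  expect_true(all(abs(counts - c(0.25, 0.5, 0.25)) < 3 * se))
  # two distinct sources collide at a site with probability sum(p_g^2) = 0.375
  truth2 <- simulate_source_genotypes(c(1L, 2L), freqs, seed = 5)
  frac_diff <- mean(truth2$source_genotypes[, 1] != truth2$source_genotypes[, 2])
  expect_lt(abs(frac_diff - 0.625), 3 * sqrt(0.625 * 0.375 / L))
})

test_that("contamination selects the exact half-up-rounded site count", {
  freqs <- simulate_site_frequencies(1000, c(0.3, 0.5), seed = 6)
  truth <- simulate_source_genotypes(c(1L, 1L), freqs, seed = 6)
  for (p in c(0, 0.1, 0.5)) {
    out <- inject_contamination(truth, 2L, p, seed = 7)
    expect_identical(sum(out$contamination$mask), as.integer(p * 1000))
  }
  # half-up: 0.0025 * 1000 = 2.5 rounds to 3; banker's round() would give 2
  out <- inject_contamination(truth, 2L, 0.0025, seed = 7)
  expect_identical(sum(out$contamination$mask), 3L)
  expect_error(inject_contamination(truth, 5L, 0.1), "1..2")
  expect_error(inject_contamination(truth, 1L, 1.2), "\\[0, 1\\]")
})

test_that("read simulation matches the binomial observation model", {
  L <- 3000
  freqs <- rep(0.5, L)
  cfg <- sim_config(1L, L = L, lambda = 15, error_rate = 0.01, seed = 8)
  truth <- simulate_source_genotypes(1L, freqs, seed = 8)
  truth$source_genotypes[] <- 2L # force BB everywhere
  data <- simulate_allele_depths(truth, cfg, seed = 9)
  frac_B <- sum(data$n_B) / sum(data$n_A + data$n_B)
  expect_lt(abs(frac_B - 0.99), 3 * sqrt(0.99 * 0.01 / (15 * L)))
  # near-zero depth leaves a valid dataset full of (0,0)
  thin <- simulate_replicates(sim_config(c(1L, 2L), L = 200, lambda = 0.1,
                                         seed = 10))
  expect_gt(mean(thin$dataset$n_A + thin$dataset$n_B == 0), 0.8)
  expect_s3_class(thin$dataset, "replicate_dataset")
})

test_that("the whole simulation is a pure function of config and seed", {
  cfg <- sim_config(c(1L, 2L, 1L), L = 300, lambda = c(1, 2, 4),
                    contamination = list(sample = 2, p = 0.2), seed = 11)
  a <- simulate_replicates(cfg)
  b <- simulate_replicates(cfg)
  expect_identical(a$dataset$n_A, b$dataset$n_A)
  expect_identical(a$dataset$n_B, b$dataset$n_B)
  expect_identical(a$truth$contamination$mask, b$truth$contamination$mask)
})

test_that("at high depth the true genotype dominates the likelihood", {
  sim <- simulate_replicates(sim_config(1L, L = 500, lambda = 15,
                                        maf_window = c(0.3, 0.5), seed = 12))
  g_true <- sim$truth$source_genotypes[, 1]
  ll <- vapply(0:2, function(g) {
    genotype_log_likelihood(sim$dataset$n_A[, 1], sim$dataset$n_B[, 1], g)
  }, numeric(500))
  mean_true <- mean(ll[cbind(seq_len(500), g_true + 1L)])
  for (g in 0:2) {
    wrong <- g_true != g
    expect_gt(mean_true, mean(ll[wrong, g + 1L]))
  }
})

test_that("full contamination at high depth breaks the replicate call", {
  cfg <- sim_config(c(1L, 1L), L = 1000, lambda = 15,
                    maf_window = c(0.4, 0.5),
                    contamination = list(sample = 2, p = 1), seed = 13)
  res <- joint_posterior(simulate_replicates(cfg)$dataset)
  expect_lt(res$posterior[match("1,1", res$labels)], 0.5)
})

test_that("config validation catches malformed inputs", {
  expect_error(sim_config(c(2L, 1L)), "restricted-growth")
  expect_error(sim_config(c(1L, 2L), lambda = c(1, 2, 3)), "length 1 or k")
  expect_error(sim_config(c(1L, 2L), maf_window = c(0.2, 0.6)), "max <= 0.5")
  expect_error(sim_config(c(1L, 2L), contamination = list(sample = 3, p = 0.1)),
               "contamination")
  expect_error(simulate_allele_depths(
    simulate_source_genotypes(1L, rep(0.5, 5), seed = 1),
    sim_config(c(1L, 1L), L = 5)), "disagree")
})
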