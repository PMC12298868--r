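test_that("phenotype simulation hits target moments exactly and rejects bad correlation", {
  traits <- data.frame(trait = c("a", "b", "c"),
                       mean = c(10, 0, 1547), sd = c(2, 1, 875.683))
  tm <- simulate_phenotypes(pheno_sim_config(traits, n_accessions = 50,
                                             seed = 3))
  expect_equal(unname(colMeans(tm$values)), traits$mean, tolerance = 1e-12)
  expect_equal(unname(apply(tm$values, 2, sd)), traits$sd, tolerance = 1e-12)

  # degenerate scale: sd 0 gives constant columns at the mean
  traits0 <- data.frame(trait = "k", mean = 5, sd = 0)
  tm0 <- simulate_phenotypes(pheno_sim_config(traits0, n_accessions = 10,
                                              seed = 1))
  expect_true(all(tm0$values == 5))

  bad <- matrix(c(1, 2, 2, 1), 2)   # correlation > 1 off-diagonal, not PSD
  expect_error(pheno_sim_config(traits[1:2, ], correlation = bad),
               "positive semi-definite")
})

test_that("identity-correlation phenotypes have near-zero inter-trait correlation", {
  traits <- data.frame(trait = paste0("t", 1:4), mean = 0, sd = 1)
  tm <- simulate_phenotypes(pheno_sim_config(traits, n_accessions = 10000,
                                             seed = 11))
  r <- cor(tm$values)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
})

test_that("phenotype simulation respects a supplied correlation matrix", {
  R <- matrix(0.6, 3, 3); diag(R) <- 1
  traits <- data.frame(trait = paste0("t", 1:3), mean = 0, sd = 1)
  tm <- simulate_phenotypes(pheno_sim_config(traits, n_accessions = 5000,
                                             correlation = R, seed = 4))
  r <- cor(tm$values)
  expect_equal(r[upper.tri(r)], rep(0.6, 3), tolerance = 0.05)
})

test_that("genotype simulation is reproducible and respects call codes", {
  cfg <- geno_sim_config(n_accessions = 40, n_loci = 1000,
                         chrom_sizes = rep(100, 10), seed = 9)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$calls, g2$calls)
  expect_true(all(g1$calls %in% c(0L, 1L, 2L) | is.na(g1$calls)))
  # missing fraction within half a percentage point of the configured rate
  expect_equal(mean(is.na(g1$calls)), cfg$missing_rate, tolerance = 0.005)
})

test_that("zero residual heterozygosity gives Ho = 0; near-zero Fst collapses subpop frequencies", {
  g <- simulate_genotypes(geno_sim_config(
    n_accessions = 30, n_loci = 500, residual_het_rate = 0,
    missing_rate = 0, chrom_sizes = rep(50, 10), seed = 2))
  expect_identical(sum(g$calls == 1L), 0L)
  expect_equal(unname(diversity_stats(g)$panel["ho"]), 0)

  # with F -> 0 every subpopulation's model frequency collapses onto the
  # ancestral frequency
  g0 <- simulate_genotypes(geno_sim_config(
    n_accessions = 60, n_loci = 500, fst = 1e-6, residual_het_rate = 0,
    missing_rate = 0, chrom_sizes = rep(50, 10), seed = 5))
  P0 <- attr(g0, "subpop_freq")
  expect_lt(max(apply(P0, 2L, function(f) max(f) - min(f))), 0.01)
  g_hi <- simulate_genotypes(geno_sim_config(
    n_accessions = 60, n_loci = 500, fst = 0.3, residual_het_rate = 0,
    missing_rate = 0, chrom_sizes = rep(50, 10), seed = 5))
  P_hi <- attr(g_hi, "subpop_freq")
  expect_gt(mean(apply(P_hi, 2L, function(f) max(f) - min(f))), 0.1)
})

test_that("default genotype panel is calibrated to the emulated inbred panel", {
  g <- simulate_genotypes(geno_sim_config(n_accessions = 200, n_loci = 2000,
                                          seed = 1))
  panel <- diversity_stats(filter_loci(g))$panel
  expect_lt(abs(panel["ho"] - 0.03), 0.01)
  expect_lt(abs(panel["he"] - 0.40), 0.05)
})

test_that("germination simulation reproduces configured group structure", {
  cfg <- stress_sim_config(noise_sd = 0, seed = 6)
  sim <- simulate_germination(cfg)
  # noise 0: all rows within a group identical
  for (gr in 1:5) {
    rows <- sim$indicators$values[sim$groups == gr, , drop = FALSE]
    expect_equal(max(apply(rows, 2, function(x) diff(range(x)))), 0)
  }
  # exact proportions of the 172-accession core yield the exact counts
  expect_equal(unname(table(sim$groups)), c(4L, 14L, 47L, 64L, 43L),
               ignore_attr = TRUE)
  expect_error(stress_sim_config(noise_sd = -1), "noise_sd")
  expect_error(stress_sim_config(group_proportions = c(0.5, 0.5, 0, 0, 0.1)),
               "sum to 1")
})

test_that("structure likelihood tables place the delta-K optimum at the built-in kink", {
  tab <- simulate_structure_likelihoods(true_k = 6, noise_sd = 0.001,
                                        seed = 1)
  expect_equal(evanno_delta_k(tab)$best_k, 6)
  expect_error(simulate_structure_likelihoods(true_k = 3, reps = 2),
               "reps")
  # kink at K = 3 with modest noise recovered across seeds
  hits <- sum(vapply(1:100, function(s)
    evanno_delta_k(simulate_structure_likelihoods(
      true_k = 3, k_range = c(1, 8), noise_sd = 30, seed = s))$best_k == 3,
    logical(1L)))
  expect_gte(hits, 95)
})
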