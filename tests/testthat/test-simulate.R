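test_that("the same seed reproduces the panel byte-for-byte", {
  sc <- sim_scenario(n_chromosomes = 2, loci_per_chr = 60,
                     chr_length_cm = 0.3,
                     demography = list(type = "constant", ne = 100),
                     sample_n = 30, seed = 61)
  s1 <- sim_wright_fisher(sc)
  s2 <- sim_wright_fisher(sc)
  expect_identical(s1$genotypes$dosages, s2$genotypes$dosages)
  dir <- withr::local_tempdir()
  write_plink(s1$genotypes, file.path(dir, "a"))
  write_plink(s2$genotypes, file.path(dir, "b"))
  expect_identical(readBin(file.path(dir, "a.bed"), "raw", 1e6),
                   readBin(file.path(dir, "b.bed"), "raw", 1e6))
  s3 <- sim_wright_fisher(sim_scenario(
    n_chromosomes = 2, loci_per_chr = 60, chr_length_cm = 0.3,
    demography = list(type = "constant", ne = 100), sample_n = 30, seed = 62))
  expect_false(identical(s1$genotypes$dosages, s3$genotypes$dosages))
})

test_that("scenario validation rejects impossible plans", {
  expect_error(sim_scenario(demography = list(type = "constant", ne = 0)))
  expect_error(sim_scenario(demography = list(type = "constant", ne = 50),
                            sample_n = 100), "final population")
  expect_error(sim_scenario(demography = list(type = "oscillating")), "type")
})

test_that("an unlinked chromosome shows no LD beyond the sampling floor", {
  # 50 cM between adjacent loci: recombination probability 0.5 per interval,
  # i.e. free recombination
  sc <- sim_scenario(n_chromosomes = 1, loci_per_chr = 20,
                     chr_length_cm = 50 * 20,
                     demography = list(type = "constant", ne = 200),
                     sample_n = 100, seed = 63)
  sim <- sim_wright_fisher(sc)
  qc <- apply_qc(sim$genotypes, maf_min = 0.05)
  d <- qc$genotypes$dosages
  r2 <- suppressWarnings(cor(d)^2)
  obs <- mean(r2[upper.tri(r2)], na.rm = TRUE)
  # permutation baseline: break any association, keep allele frequencies
  base <- replicate(60, {
    dp <- apply(d, 2, sample)
    r2p <- suppressWarnings(cor(dp)^2)
    mean(r2p[upper.tri(r2p)], na.rm = TRUE)
  })
  expect_lt(abs(obs - mean(base)), 3 * sd(base) + 3 * sd(base) / sqrt(60))
})

test_that("a non-recombining chromosome carries far more LD than unlinked loci", {
  sc <- sim_scenario(n_chromosomes = 2, loci_per_chr = 25,
                     chr_length_cm = 1e-9, mutation = FALSE, burn_in = 150,
                     demography = list(type = "constant", ne = 150),
                     sample_n = 80, seed = 64)
  sim <- sim_wright_fisher(sc)
  qc <- apply_qc(sim$genotypes, maf_min = 0.05)
  g <- qc$genotypes
  r2 <- suppressWarnings(cor(g$dosages)^2)
  same_chr <- outer(g$sites$chrom, g$sites$chrom, "==") & upper.tri(r2)
  diff_chr <- !outer(g$sites$chrom, g$sites$chrom, "==") & upper.tri(r2)
  expect_gt(mean(r2[same_chr], na.rm = TRUE),
            5 * mean(r2[diff_chr], na.rm = TRUE))
})

test_that("per-generation drift variance scales as p(1-p)/(2Ne)", {
  ne <- 2000
  sim <- sim_split_drift(branch_ne = ne, t_split = 1, n_loci = 50000,
                         sample_n = 2, seed = 65)
  p0 <- sim$truth$freq_ancestral
  dev2 <- (sim$truth$freq_a - p0)^2 / (p0 * (1 - p0))
  expect_equal(mean(dev2), 1 / (2 * ne), tolerance = 0.05)
})

test_that("drift accrues the expected FST-scale divergence over many loci", {
  sim <- sim_split_drift(branch_ne = 500, t_split = 50, n_loci = 30000,
                         sample_n = 2, seed = 66)
  f_true <- sim$truth$expected_fst
  p0 <- sim$truth$freq_ancestral
  dev2 <- (sim$truth$freq_a - p0)^2 / (p0 * (1 - p0))
  expect_equal(mean(dev2), f_true, tolerance = 0.05)
})

test_that("a split at time zero leaves the populations indistinguishable", {
  sim <- sim_split_drift(branch_ne = 1000, t_split = 0, n_loci = 10000,
                         sample_n = 50, seed = 67)
  expect_equal(sim$truth$expected_fst, 0)
  expect_lt(abs(as.numeric(wc_pair_fst(sim$genotypes, "A", "B"))), 0.005)
})

test_that("LD decays with recombination distance on constant-Ne panels", {
  trend <- vapply(c(68, 69, 70), function(seed) {
    sim <- sim_wright_fisher(sim_scenario(
      n_chromosomes = 3, loci_per_chr = 200, chr_length_cm = 1,
      demography = list(type = "constant", ne = 300), sample_n = 80,
      seed = seed))
    qc <- apply_qc(sim$genotypes, maf_min = 0.05)
    st <- bin_r2_profile(qc$genotypes, make_bins())
    ok <- st$n_pairs > 10
    cor(st$c_mid[ok], st$mean_r2[ok], method = "kendall")
  }, numeric(1))
  expect_true(all(trend < -0.5))
})

test_that("piecewise demography changes the population size over epochs", {
  sc <- sim_scenario(
    n_chromosomes = 1, loci_per_chr = 30, chr_length_cm = 0.2,
    demography = list(type = "piecewise",
                      epochs = data.frame(ne = c(200, 40),
                                          generations = c(10, 10))),
    sample_n = 40, burn_in = 50, seed = 71)
  sim <- sim_wright_fisher(sc)
  expect_identical(n_samples(sim$genotypes), 40L)
  expect_identical(sim$truth$generations_simulated, 70L)
})
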