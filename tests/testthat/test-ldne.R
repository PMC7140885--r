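test_that("default binning yields 250 overlapping categories", {
  b <- make_bins()
  expect_identical(nrow(b), 250L)
  expect_equal(b$c_high, seq(0.001, 0.25, by = 0.001))
  expect_equal(b$c_low, pmax(0, b$c_high - 0.005))
  expect_true(all(diff(b$c_mid) > 0))
})

test_that("disjoint bins are produced when width equals step", {
  b <- make_bins(c_min = 0.005, c_max = 0.01, step = 0.005, width = 0.005)
  expect_identical(nrow(b), 2L)
  expect_equal(b$c_low, c(0, 0.005))
  expect_equal(b$c_high, c(0.005, 0.01))
  expect_error(make_bins(step = 0), "positive")
})

test_that("distance-to-time mapping gives 200 generations at 0.25 cM", {
  expect_equal(cm_to_generations(0.25), 200)
  # doubling the distance halves the time depth exactly
  c <- runif(20, 0.001, 0.3)
  expect_equal(cm_to_generations(2 * c), cm_to_generations(c) / 2)
})

test_that("pair r2 equals the hand-computed squared Pearson correlation", {
  expect_equal(pair_r2(c(0, 1, 2, 2), c(0, 1, 1, 2)), 8 / 11)
  x <- c(0, 1, 2, 1, 0, 2)
  expect_equal(pair_r2(x, x), 1)
  # pairwise-complete handling: the NA pair is excluded
  expect_equal(pair_r2(c(0, 1, 2, 2, NA), c(0, 1, 1, 2, 0)), 8 / 11)
  # monomorphic on the complete subset -> undefined
  expect_true(is.na(pair_r2(c(0, 0, 0, NA), c(0, 1, 2, 1))))
})

test_that("r2 between independent loci sits at the 1/n sampling floor", {
  set.seed(21)
  n <- 200
  x <- rbinom(n, 2, 0.4)
  y <- rbinom(n, 2, 0.3)
  perm <- replicate(300, pair_r2(x, sample(y)))
  # E[r2] for independent vectors is 1/(n-1); both the permutation oracle
  # and the observed pair should sit on that scale
  expect_gt(mean(perm), 0.5 / n)
  expect_lt(mean(perm), 2 / n)
  expect_lt(pair_r2(x, y), 10 / n)
})

test_that("a single SNP pair lands in the covering bins only", {
  g <- toy_geno(rbind(c(0L, 0L), c(1L, 1L), c(2L, 1L), c(2L, 2L)),
                cm = c(0.10, 0.20))
  bins <- make_bins()
  st <- bin_r2_profile(g, bins)
  covered <- bins$c_low <= 0.1 & bins$c_high >= 0.1
  expect_identical(unname(st$n_pairs[covered]), rep(1L, sum(covered)))
  expect_identical(unname(st$n_pairs[!covered]), rep(0L, sum(!covered)))
  expect_equal(st$mean_r2[covered],
               rep(pair_r2(g$dosages[, 1], g$dosages[, 2]), sum(covered)))
})

test_that("a distance on a shared edge enters both adjacent bins", {
  g <- toy_geno(rbind(c(0L, 0L), c(1L, 1L), c(2L, 1L), c(2L, 2L)),
                cm = c(0.005, 0.010))
  bins <- make_bins(c_min = 0.005, c_max = 0.01, step = 0.005, width = 0.005)
  st <- bin_r2_profile(g, bins)   # distance 0.005 = upper edge of bin 1
  expect_identical(unname(st$n_pairs), c(1L, 1L))
})

test_that("profiling requires genetic positions and some usable pair", {
  g <- toy_geno(rbind(c(0L, 0L), c(1L, 1L), c(2L, 1L)))
  expect_error(bin_r2_profile(g, make_bins()), "attach_genetic_map")
  g2 <- toy_geno(rbind(c(0L, 0L), c(1L, 1L), c(2L, 1L)), cm = c(1, 2))
  expect_error(bin_r2_profile(g2, make_bins()), "wider bins")
})

test_that("Sved inversion matches hand evaluation and round-trips exactly", {
  # alpha 1, c = 0.001 M, adjusted r2 = 0.2 -> 250 * (5 - 1) = 1000
  n <- 1e9   # make 1/n negligible for the hand-evaluated case
  expect_equal(ne_from_r2(0.2 + 1 / n, c = 0.001, n_samples = n, alpha = 1),
               1000, tolerance = 1e-6)
  for (ne in c(5404, 500, 123.4)) {
    for (alpha in c(1, 2)) {
      r2 <- r2_from_ne(ne, c = 0.0025, n_samples = 100, alpha = alpha)
      expect_equal(ne_from_r2(r2, c = 0.0025, n_samples = 100, alpha = alpha),
                   ne, tolerance = 1e-9)
    }
  }
  # boundary: adjusted r2 = 1/alpha -> Ne = 0
  expect_equal(ne_from_r2(0.5 + 0.01, c = 0.001, n_samples = 100, alpha = 2),
               0)
  # no signal: r2 at or below the sampling floor -> undefined
  expect_true(is.na(ne_from_r2(0.01, c = 0.001, n_samples = 100)))
})

test_that("Sved inversion is strictly decreasing in r2", {
  r2 <- seq(0.02, 0.9, by = 0.01)
  ne <- ne_from_r2(r2, c = 0.001, n_samples = 100)
  expect_true(all(diff(ne[!is.na(ne) & ne > 0]) < 0))
})

test_that("identical chromosomes give zero-width jackknife intervals", {
  set.seed(22)
  block <- matrix(rep(rbinom(40, 2L, 0.4), 10), nrow = 40)
  g <- toy_geno(cbind(block, block, block),
                chrom = rep(c("1", "2", "3"), each = 10),
                bp = rep(seq_len(10) * 1000L, 3),
                cm = rep(seq_len(10) * 0.02, 3))
  tr <- ne_trajectory(bin_r2_profile(g, make_bins()))
  usable <- !is.na(tr$ne_hat) & !is.na(tr$ci_low)
  expect_gt(sum(usable), 0)
  expect_equal(tr$ci_low[usable], tr$ne_hat[usable])
  expect_equal(tr$ci_high[usable], tr$ne_hat[usable])
})

test_that("time depths scale with the generation length", {
  g <- random_geno(n = 50, m = 20, seed = 23)
  g$sites$cm <- seq_len(20) * 0.02
  tr <- ne_trajectory(bin_r2_profile(g, make_bins()), generation_years = 25)
  expect_equal(tr$t_years, tr$t_gen * 25)
  expect_equal(tr$t_gen[which.max(tr$c_mid)],
               cm_to_generations(max(tr$c_mid)))
})

test_that("confidence bounds bracket the point estimate", {
  sim <- sim_wright_fisher(sim_scenario(
    n_chromosomes = 4, loci_per_chr = 80, chr_length_cm = 0.4,
    demography = list(type = "constant", ne = 100), sample_n = 50, seed = 24))
  tr <- ne_trajectory(bin_r2_profile(sim$genotypes, make_bins()))
  ok <- !is.na(tr$ne_hat) & !is.na(tr$ci_low)
  expect_gt(sum(ok), 0)
  expect_true(all(tr$ci_low[ok] <= tr$ne_hat[ok] + 1e-9))
  expect_true(all(tr$ci_high[ok] >= tr$ne_hat[ok] - 1e-9))
})

test_that("harmonic mean matches hand values and the AM-HM inequality", {
  expect_equal(harmonic_mean(c(2, 3, 6)), 3)
  expect_equal(harmonic_mean(rep(7.5, 10)), 7.5)
  set.seed(25)
  for (i in 1:20) {
    x <- runif(10, 0.1, 100)
    expect_lte(harmonic_mean(x), mean(x))
  }
  expect_error(harmonic_mean(c(1, 0)), "positive")
})

test_that("long-term Ne summarises usable bins and excludes zeros", {
  traj <- data.frame(ne_hat = c(2, 3, 6, NA, 0),
                     ci_low = c(1, 2, 4, NA, 0),
                     ci_high = c(4, 5, 9, NA, 0))
  class(traj) <- c("ne_trajectory", "data.frame")
  expect_warning(lt <- long_term_ne(traj), "Ne = 0")
  expect_equal(lt$ne_harmonic, 3)
  expect_identical(lt$n_bins_used, 3L)
  expect_equal(lt$ci_low, harmonic_mean(c(1, 2, 4)))
  expect_equal(lt$ci_high, harmonic_mean(c(4, 5, 9)))
  # bounded by the extreme bins
  expect_gte(lt$ne_harmonic, 2)
  expect_lte(lt$ne_harmonic, 6)
})

test_that("trajectory TSV round-trips", {
  g <- random_geno(n = 50, m = 20, seed = 26)
  g$sites$cm <- seq_len(20) * 0.02
  tr <- ne_trajectory(bin_r2_profile(g, make_bins()))
  path <- file.path(withr::local_tempdir(), "traj.tsv")
  write_trajectory(tr, path)
  tr2 <- read_trajectory(path)
  expect_equal(tr2$ne_hat, tr$ne_hat)
  expect_equal(tr2$mean_r2, tr$mean_r2)
})
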