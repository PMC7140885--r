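test_that("PLINK round-trip preserves dosages, sites and samples exactly", {
  g <- random_geno(n = 13, m = 21, miss = 0.1, pop = c("P1", "P2"), seed = 3)
  prefix <- file.path(withr::local_tempdir(), "rt")
  write_plink(g, prefix)
  g2 <- read_plink(prefix)
  expect_identical(unname(g2$dosages), unname(g$dosages))
  expect_equal(g2$sites[c("chrom", "bp", "id", "a1", "a2")],
               g$sites[c("chrom", "bp", "id", "a1", "a2")])
  expect_identical(g2$samples$id, g$samples$id)
  expect_identical(g2$samples$population, g$samples$population)
})

test_that("hand-built .bed bytes decode to the expected dosages", {
  # 3 samples x 2 SNPs, SNP-major. Codes (2 bits, sample 1 in the low bits):
  # SNP1 dosages (0, 2, 1) -> codes 11,00,10 -> 0b00100011 = 0x23
  # SNP2 dosages (1, NA, 0) -> codes 10,01,11 -> 0b00110110 = 0x36
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "hand")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x23, 0x36)), paste0(prefix, ".bed"))
  writeLines(c("1\ts1\t0\t100\tA\tG", "1\ts2\t0\t200\tC\tT"),
             paste0(prefix, ".bim"))
  writeLines(c("F1 i1 0 0 0 -9", "F1 i2 0 0 0 -9", "F1 i3 0 0 0 -9"),
             paste0(prefix, ".fam"))
  g <- read_plink(prefix)
  expect_identical(unname(g$dosages),
                   matrix(c(0L, 2L, 1L, 1L, NA, 0L), nrow = 3))
})

test_that("malformed PLINK input is rejected with the file named", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "bad")
  expect_error(read_plink(prefix), "not found")
  writeLines("1\ts1\t0\t100\tA\tG", paste0(prefix, ".bim"))
  writeLines("F1 i1 0 0 0 -9", paste0(prefix, ".fam"))
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0x00)), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "magic")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "truncated")
})

test_that("non-autosomal sites are dropped on read", {
  g <- toy_geno(matrix(c(0L, 1L, 2L, 1L), 2), chrom = c("1", "X"))
  prefix <- file.path(withr::local_tempdir(), "auto")
  write_plink(g, prefix)
  expect_message(g2 <- read_plink(prefix), "non-autosomal")
  expect_identical(g2$sites$chrom, "1")
  expect_identical(ncol(g2$dosages), 1L)
})

test_that("genetic-map interpolation is linear with clamped extrapolation", {
  m <- genetic_map(chrom = c("1", "1"), bp = c(0, 1e6), cm = c(0, 1))
  g <- toy_geno(matrix(0:2, 3, 4), bp = c(5e5, 1e6, 2e6, 3e6))
  ga <- attach_genetic_map(g, m)
  expect_equal(ga$sites$cm, c(0.5, 1, 1, 1))   # midpoint, anchor, clamp x2
  expect_error(attach_genetic_map(g, m, policy = "error"), "outside")
  g_chr2 <- toy_geno(matrix(0:2, 3, 2), chrom = "2")
  expect_error(attach_genetic_map(g_chr2, m), "absent.*2")
})

test_that("attached cM positions are monotone when the map is monotone", {
  m <- genetic_map(chrom = rep("1", 4), bp = c(1, 1e5, 5e5, 1e6),
                   cm = c(0, 0.2, 0.2, 1.4))
  set.seed(9)
  g <- toy_geno(matrix(0L, 2, 30), bp = sort(sample.int(2e6, 30)))
  ga <- attach_genetic_map(g, m)
  expect_false(is.unsorted(ga$sites$cm))
})

test_that("self-merge doubles samples and keeps the site set", {
  g <- random_geno(n = 8, m = 12, pop = "P", seed = 5)
  gm <- merge_datasets(g, g)
  expect_identical(gm$sites$id, g$sites$id)
  expect_identical(nrow(gm$dosages), 2L * nrow(g$dosages))
  expect_identical(unname(gm$dosages), unname(rbind(g$dosages, g$dosages)))
})

test_that("merge flips dosages where A1/A2 are swapped", {
  a <- toy_geno(matrix(c(0L, 1L, 2L, 2L, 1L, 0L), 3), a1 = "A", a2 = "G")
  b <- a
  b$sites$a1[2] <- "G"; b$sites$a2[2] <- "A"
  b$dosages[, 2] <- 2L - b$dosages[, 2]   # same genotypes, other allele counted
  gm <- merge_datasets(a, b)
  expect_identical(unname(gm$dosages),
                   unname(rbind(a$dosages, a$dosages)))
})

test_that("merge handles strand flips and drops ambiguous discordant sites", {
  a <- toy_geno(matrix(c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 1L, 0L), 3),
                a1 = c("A", "A", "A"), a2 = c("G", "G", "T"))
  b <- a
  # site 1: strand-flipped, same orientation (A/G -> T/C): dosages unchanged
  b$sites$a1[1] <- "T"; b$sites$a2[1] <- "C"
  # site 2: strand-flipped and swapped (A/G -> C/T): dosages flip
  b$sites$a1[2] <- "C"; b$sites$a2[2] <- "T"
  b$dosages[, 2] <- 2L - b$dosages[, 2]
  # site 3: ambiguous A/T with swapped coding: must be dropped
  b$sites$a1[3] <- "T"; b$sites$a2[3] <- "A"
  expect_message(gm <- merge_datasets(a, b), "dropping 1")
  expect_identical(gm$sites$id, a$sites$id[1:2])
  expect_identical(unname(gm$dosages),
                   unname(rbind(a$dosages[, 1:2], a$dosages[, 1:2])))
})

test_that("merge errors on a disjoint marker set and is symmetric in sites", {
  a <- random_geno(n = 4, m = 6, seed = 1)
  b <- random_geno(n = 4, m = 6, seed = 2)
  b$sites$id <- paste0("other_", b$sites$id)
  expect_error(merge_datasets(a, b), "no shared")
  bsub <- subset_genotypes(a, sites = 2:4)
  expect_identical(sort(merge_datasets(a, bsub)$sites$id),
                   sort(merge_datasets(bsub, a)$sites$id))
})

test_that("sites are kept sorted by chromosome and position", {
  sites <- data.frame(chrom = c("2", "1"), bp = c(50L, 100L),
                      id = c("b", "a"), a1 = "A", a2 = "G")
  samples <- data.frame(id = c("i1", "i2"))
  g <- genotype_matrix(matrix(c(0L, 1L, 2L, 0L), 2), sites, samples)
  expect_identical(g$sites$id, c("a", "b"))
  expect_identical(unname(g$dosages[, 1]), c(2L, 0L))
})
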