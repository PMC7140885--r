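#' Weir-Cockerham (1984) pairwise FST
#'
#' Two-population multilocus FST from the 1984 variance components: for
#' each biallelic locus, the among-population (a), among-individual-
#' within-population (b) and within-individual (c) components are formed
#' from sample sizes, allele frequencies and observed heterozygote
#' proportions (no Hardy-Weinberg assumption), and the multilocus estimate
#' is the ratio of sums `sum(a) / sum(a + b + c)` over loci with a defined,
#' nonzero denominator. Loci monomorphic across the pooled pair are
#' skipped.
#'
#' @param g a [genotype_matrix()] with population labels.
#' @param pop_a,pop_b population labels present in `g$samples$population`.
#' @return multilocus FST (may be slightly negative by sampling noise),
#'   with attribute `n_loci` giving the number of loci used.
#' @export
wc_pair_fst <- function(g, pop_a, pop_b) {
  stopifnot(inherits(g, "genotype_matrix"))
  ia <- which(g$samples$population == pop_a)
  ib <- which(g$samples$population == pop_b)
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("both populations need >= 2 individuals: ", pop_a, ", ", pop_b)
  }
  comp <- wc_components(g$dosages[ia, , drop = FALSE],
                        g$dosages[ib, , drop = FALSE])
  ok <- is.finite(comp$a) & is.finite(comp$den) & comp$den > 0
  if (!any(ok)) {
    stop("no polymorphic shared locus between ", pop_a, " and ", pop_b)
  }
  fst <- sum(comp$a[ok]) / sum(comp$den[ok])
  attr(fst, "n_loci") <- sum(ok)
  fst
}

# Per-locus Weir-Cockerham variance components for two populations.
# Returns a (among-population component) and den = a + b + c.
wc_components <- function(da, db) {
  r <- 2
  n1 <- colSums(!is.na(da)); n2 <- colSums(!is.na(db))
  # allele frequency of A1 and observed heterozygote proportion, per pop
  p1 <- colMeans(da, na.rm = TRUE) / 2
  p2 <- colMeans(db, na.rm = TRUE) / 2
  h1 <- colMeans(da == 1L, na.rm = TRUE)
  h2 <- colMeans(db == 1L, na.rm = TRUE)

  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r -
       hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  usable <- n1 >= 2 & n2 >= 2 & pbar > 0 & pbar < 1
  a[!usable] <- NA_real_
  den <- a + b + cc
  den[!usable] <- NA_real_
  list(a = a, den = den)
}

#' Pairwise FST matrix over labelled populations
#'
#' All population pairs via [wc_pair_fst()]. Negative multilocus estimates
#' (possible for weakly differentiated pairs) are preserved in the matrix
#' and flagged in the `negative_pairs` attribute.
#'
#' @param g a [genotype_matrix()] with >= 2 population labels.
#' @return an `fst_matrix`: symmetric numeric matrix with zero diagonal,
#'   population labels as dimnames; attributes `n_loci` (matrix of locus
#'   counts) and `negative_pairs` (character matrix of flagged pairs).
#' @export
fst_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  pops <- sort(unique(g$samples$population[!is.na(g$samples$population)]))
  if (length(pops) < 2L) stop("need >= 2 labelled populations")
  k <- length(pops)
  fst <- matrix(0, k, k, dimnames = list(pops, pops))
  nl <- matrix(0L, k, k, dimnames = list(pops, pops))
  neg <- character(0)
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      v <- tryCatch(wc_pair_fst(g, pops[i], pops[j]), error = function(e) {
        stop("fst_matrix failed for pair (", pops[i], ", ", pops[j], "): ",
             conditionMessage(e))
      })
      fst[i, j] <- fst[j, i] <- as.numeric(v)
      nl[i, j] <- nl[j, i] <- attr(v, "n_loci")
      if (v < 0) neg <- c(neg, paste(pops[i], pops[j], sep = "-"))
    }
  }
  structure(fst, class = c("fst_matrix", "matrix"),
            n_loci = nl, negative_pairs = neg)
}

#' Write / read a square labelled matrix as TSV
#'
#' Square TSV with a header row and a leading label column; used for FST
#' and divergence matrices.
#'
#' @param m labelled square matrix.
#' @param path file path.
#' @return `path` (write) or a plain labelled matrix (read).
#' @export
write_square_tsv <- function(m, path) {
  tab <- data.frame(label = rownames(m), as.data.frame(unclass(m)),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_square_tsv
#' @export
read_square_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}
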