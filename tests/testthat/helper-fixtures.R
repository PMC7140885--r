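# Small in-code fixtures shared across test files.

# Genotype matrix from a plain dosage matrix; metadata filled with defaults.
toy_geno <- function(dos, chrom = "1", bp = NULL, cm = NULL, pop = NULL,
                     a1 = "A", a2 = "G") {
  dos <- as.matrix(dos)
  m <- ncol(dos)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  sites <- data.frame(chrom = rep(chrom, length.out = m), bp = bp,
                      id = sprintf("s%d", seq_len(m)),
                      a1 = rep(a1, length.out = m),
                      a2 = rep(a2, length.out = m),
                      cm = if (is.null(cm)) NA_real_ else cm,
                      stringsAsFactors = FALSE)
  samples <- data.frame(id = sprintf("i%d", seq_len(nrow(dos))),
                        population = if (is.null(pop)) NA_character_ else
                          rep(pop, length.out = nrow(dos)),
                        stringsAsFactors = FALSE)
  genotype_matrix(dos, sites, samples)
}

# A clean random genotype panel in Hardy-Weinberg proportions.
random_geno <- function(n = 30, m = 50, maf_range = c(0.2, 0.5),
                        miss = 0, pop = NULL, seed = 1) {
  set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])
  dos <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
  if (miss > 0) dos[runif(n * m) < miss] <- NA_integer_
  toy_geno(dos, pop = pop)
}
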