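#' Genotype matrix container
#'
#' A `genotype_matrix` holds diploid biallelic genotypes as allele-dosage
#' counts together with per-sample and per-site metadata. Dosages count copies
#' of the A1 allele (the fifth column of a PLINK `.bim` file), so values are
#' 0, 1, 2 or `NA` for missing. Sites are kept sorted by (chromosome,
#' physical position).
#'
#' @param dosages integer matrix, samples in rows and sites in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param sites data.frame with columns `chrom`, `bp`, `id`, `a1`, `a2` and
#'   optionally `cm` (genetic position in centiMorgans; `NA` until a map is
#'   attached).
#' @param samples data.frame with columns `id` and `population` (population
#'   label; may be `NA`).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `sites`, `samples`.
#' @export
genotype_matrix <- function(dosages, sites, samples) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (is.null(dim(dosages)) || nrow(dosages) < 1L || ncol(dosages) < 1L) {
    stop("dosages must be a matrix with at least one sample and one site")
  }
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need_site <- c("chrom", "bp", "id", "a1", "a2")
  if (!all(need_site %in% names(sites))) {
    stop("sites must have columns: ", paste(need_site, collapse = ", "))
  }
  if (!"cm" %in% names(sites)) sites$cm <- NA_real_
  if (!"id" %in% names(samples)) stop("samples must have an 'id' column")
  if (!"population" %in% names(samples)) samples$population <- NA_character_
  if (nrow(samples) != nrow(dosages)) {
    stop("nrow(samples) must equal nrow(dosages)")
  }
  if (nrow(sites) != ncol(dosages)) {
    stop("nrow(sites) must equal ncol(dosages)")
  }
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("dosages must be in {0, 1, 2, NA}")
  }
  if (any(sites$bp < 1, na.rm = TRUE)) stop("site bp positions must be >= 1")
  if (any(sites$a1 == sites$a2)) stop("a1 and a2 must differ at every site")
  ord <- order(sites$chrom, sites$bp)
  if (is.unsorted(ord, strictly = FALSE) || any(ord != seq_along(ord))) {
    sites <- sites[ord, , drop = FALSE]
    dosages <- dosages[, ord, drop = FALSE]
  }
  rownames(sites) <- NULL
  rownames(samples) <- NULL
  dimnames(dosages) <- list(samples$id, sites$id)
  structure(
    list(dosages = dosages, sites = sites, samples = samples),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_pop <- length(unique(x$samples$population[!is.na(x$samples$population)]))
  cat(sprintf(
    "genotype_matrix: %d samples x %d sites (%d chromosome%s%s)\n",
    nrow(x$dosages), ncol(x$dosages),
    length(unique(x$sites$chrom)),
    if (length(unique(x$sites$chrom)) == 1L) "" else "s",
    if (n_pop > 0L) sprintf(", %d population label%s", n_pop,
                            if (n_pop == 1L) "" else "s") else ""
  ))
  cat(sprintf("  genetic map attached: %s\n",
              if (all(!is.na(x$sites$cm))) "yes" else "no"))
  invisible(x)
}

#' Number of samples / sites
#' @param g a `genotype_matrix`
#' @return integer count.
#' @export
n_samples <- function(g) nrow(g$dosages)

#' @rdname n_samples
#' @export
n_sites <- function(g) ncol(g$dosages)

#' Subset a genotype matrix
#'
#' @param g a `genotype_matrix`.
#' @param samples logical/integer/character index over samples (optional).
#' @param sites logical/integer/character index over sites (optional).
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(g, samples = NULL, sites = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  si <- if (is.null(samples)) seq_len(n_samples(g)) else samples
  vi <- if (is.null(sites)) seq_len(n_sites(g)) else sites
  if (is.character(si)) si <- match(si, g$samples$id)
  if (is.character(vi)) vi <- match(vi, g$sites$id)
  genotype_matrix(
    g$dosages[si, vi, drop = FALSE],
    g$sites[vi, , drop = FALSE],
    g$samples[si, , drop = FALSE]
  )
}

#' Split a genotype matrix by population label
#' @param g a `genotype_matrix`.
#' @return named list of `genotype_matrix`, one per population label.
#' @export
split_by_population <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  labs <- g$samples$population
  labs[is.na(labs)] <- "<unlabelled>"
  out <- lapply(sort(unique(labs)), function(p) {
    subset_genotypes(g, samples = which(labs == p))
  })
  names(out) <- sort(unique(labs))
  out
}
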