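#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square goodness-of-fit test of observed
#' genotype counts against the Hardy-Weinberg proportions implied by the
#' sample allele frequency. No continuity correction is applied. A
#' monomorphic site carries no information and returns p = 1.
#'
#' @param hom1 count of A1/A1 homozygotes.
#' @param het count of heterozygotes.
#' @param hom2 count of A2/A2 homozygotes.
#' @return two-sided p-value in (0, 1].
#' @export
hwe_test <- function(hom1, het, hom2) {
  stopifnot(hom1 >= 0, het >= 0, hom2 >= 0)
  n <- hom1 + het + hom2
  if (n < 1) stop("hwe_test: all genotype counts are zero")
  p <- (2 * hom1 + het) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((c(hom1, het, hom2) - expd)^2 / expd)
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Per-site genotype statistics
#'
#' @param g a [genotype_matrix()].
#' @return data.frame with one row per site: `id`, `n_called`, `miss_frac`,
#'   `maf` (minor allele frequency from called genotypes), genotype counts
#'   `hom1_obs`, `het_obs`, `hom2_obs`, and `hwe_p`.
#' @export
site_stats <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  n <- nrow(d)
  n_called <- n - colSums(is.na(d))
  hom1 <- colSums(d == 2L, na.rm = TRUE)
  het  <- colSums(d == 1L, na.rm = TRUE)
  hom2 <- colSums(d == 0L, na.rm = TRUE)
  p1 <- ifelse(n_called > 0, (2 * hom1 + het) / (2 * n_called), NA_real_)
  maf <- pmin(p1, 1 - p1)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    if (n_called[j] == 0L) return(NA_real_)
    hwe_test(hom1[j], het[j], hom2[j])
  }, numeric(1))
  data.frame(id = g$sites$id, n_called = n_called,
             miss_frac = 1 - n_called / n, maf = maf,
             hom1_obs = hom1, het_obs = het, hom2_obs = hom2,
             hwe_p = hwe_p, stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply array quality-control filters
#'
#' Standard array QC in a fixed, documented order: (1) individuals with a
#' missing-genotype fraction above `mind` are removed; (2) site statistics
#' are recomputed on the remaining individuals; (3) sites are removed for,
#' in order, missingness above `geno`, minor allele frequency below
#' `maf_min`, and Hardy-Weinberg p-value below `hwe_alpha`. MAF and the HWE
#' test use called genotypes only. Defaults match common array practice:
#' 10% missingness, MAF < 0.01, HWE p < 1e-4.
#'
#' @param g a [genotype_matrix()].
#' @param mind maximum per-individual missing fraction.
#' @param geno maximum per-site missing fraction.
#' @param maf_min minimum minor allele frequency (sites strictly below are
#'   removed).
#' @param hwe_alpha HWE p-value threshold (sites strictly below are removed).
#' @return list with elements `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (a `qc_report`: data.frames `individuals_removed` and
#'   `sites_removed` with columns id/reason/value/threshold, plus the
#'   thresholds used).
#' @export
apply_qc <- function(g, mind = 0.1, geno = 0.1, maf_min = 0.01,
                     hwe_alpha = 1e-4) {
  stopifnot(inherits(g, "genotype_matrix"),
            mind >= 0, mind <= 1, geno >= 0, geno <= 1,
            maf_min >= 0, maf_min <= 1, hwe_alpha >= 0, hwe_alpha <= 1)
  miss_ind <- rowMeans(is.na(g$dosages))
  drop_ind <- which(miss_ind > mind)
  ind_removed <- data.frame(
    id = g$samples$id[drop_ind], reason = rep("mind", length(drop_ind)),
    value = miss_ind[drop_ind], threshold = rep(mind, length(drop_ind)),
    stringsAsFactors = FALSE
  )
  if (length(drop_ind) == n_samples(g)) {
    stop("apply_qc: all individuals removed by missingness filter")
  }
  if (length(drop_ind)) g <- subset_genotypes(g, samples = -drop_ind)

  st <- site_stats(g)
  reason <- rep(NA_character_, nrow(st))
  value <- rep(NA_real_, nrow(st))
  thr <- rep(NA_real_, nrow(st))
  hit <- function(cond, why, val, t) {
    new <- is.na(reason) & cond
    reason[new] <<- why; value[new] <<- val[new]; thr[new] <<- t
  }
  hit(st$miss_frac > geno, "geno", st$miss_frac, geno)
  hit(is.na(st$maf) | st$maf < maf_min, "maf", st$maf, maf_min)
  hit(!is.na(st$hwe_p) & st$hwe_p < hwe_alpha, "hwe", st$hwe_p, hwe_alpha)
  drop_site <- which(!is.na(reason))
  site_removed <- data.frame(
    id = st$id[drop_site], reason = reason[drop_site],
    value = value[drop_site], threshold = thr[drop_site],
    stringsAsFactors = FALSE
  )
  if (length(drop_site) == n_sites(g)) {
    stop("apply_qc: all sites removed by site filters")
  }
  if (length(drop_site)) g <- subset_genotypes(g, sites = -drop_site)

  report <- structure(
    list(individuals_removed = ind_removed, sites_removed = site_removed,
         thresholds = list(mind = mind, geno = geno, maf = maf_min,
                           hwe = hwe_alpha)),
    class = "qc_report"
  )
  list(genotypes = g, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d individual(s) and %d site(s) removed\n",
              nrow(x$individuals_removed), nrow(x$sites_removed)))
  if (nrow(x$sites_removed)) {
    print(table(x$sites_removed$reason))
  }
  invisible(x)
}

#' Write a QC report to disk
#'
#' Writes a TSV of removals (id, reason, value, threshold) and a JSON
#' summary with counts per reason and the thresholds used.
#'
#' @param report a `qc_report` from [apply_qc()].
#' @param tsv_path,json_path output paths.
#' @return invisibly, the JSON summary as a list.
#' @export
write_qc_report <- function(report, tsv_path, json_path) {
  stopifnot(inherits(report, "qc_report"))
  both <- rbind(
    cbind(what = rep("individual", nrow(report$individuals_removed)),
          report$individuals_removed),
    cbind(what = rep("site", nrow(report$sites_removed)),
          report$sites_removed)
  )
  utils::write.table(both, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- list(
    thresholds = report$thresholds,
    individuals_removed = nrow(report$individuals_removed),
    sites_removed_by_reason = as.list(table(report$sites_removed$reason))
  )
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}
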