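#' Recombination-distance categories for LD-based Ne estimation
#'
#' Builds overlapping sliding windows over recombination distance. Windows
#' of width `width` advance by `step`; upper edges run from `step` to
#' `c_max` inclusive and lower edges are truncated at 0. With the defaults
#' (step 0.001 cM, window width 0.005 cM, maximum distance 0.25 cM) this
#' yields exactly 250 categories spanning pair distances up to 0.25 cM.
#' Each bin carries its midpoint `c_mid` and the time depth
#' `t_gen = 1/(2 c)` generations (with `c` in Morgans) at which LD at that
#' distance is informative about Ne.
#'
#' @param c_min smallest window width in cM; also the default `width`.
#' @param c_max largest upper edge in cM.
#' @param step window advance in cM.
#' @param width window width in cM (defaults to `c_min`).
#' @return a `distance_bins` data.frame with columns `c_low`, `c_high`,
#'   `c_mid` (cM) and `t_gen` (generations before present).
#' @export
make_bins <- function(c_min = 0.005, c_max = 0.25, step = 0.001,
                      width = c_min) {
  if (step <= 0) stop("step must be positive")
  if (width < step) stop("width must be >= step")
  if (c_min >= c_max) stop("c_min must be < c_max")
  upper <- seq(step, c_max, by = step)
  lower <- pmax(0, upper - width)
  mid <- (lower + upper) / 2
  structure(
    data.frame(c_low = lower, c_high = upper, c_mid = mid,
               t_gen = cm_to_generations(mid)),
    class = c("distance_bins", "data.frame")
  )
}

#' Map a recombination distance to a time depth
#'
#' LD between loci `c` Morgans apart reflects effective population size
#' roughly `1/(2c)` generations ago; with `c` given in cM this is
#' `50 / c_cm` generations.
#'
#' @param c_cm recombination distance in centiMorgans (> 0).
#' @return time depth in generations before present.
#' @export
cm_to_generations <- function(c_cm) {
  stopifnot(all(c_cm > 0))
  1 / (2 * c_cm / 100)
}

#' Squared dosage correlation between two loci
#'
#' Composite (Rogers-Huff style) linkage disequilibrium for unphased
#' genotypes: the squared Pearson correlation of allele dosages over
#' pairwise-complete samples. Returns `NA` when fewer than two complete
#' pairs remain or either locus is monomorphic on the complete subset.
#'
#' @param x,y dosage vectors of equal length (values 0/1/2/NA).
#' @return r-squared in \[0, 1\], or `NA` if undefined.
#' @export
pair_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Mean pairwise r-squared per recombination-distance category
#'
#' For every intrachromosomal pair of sites whose cM distance falls inside
#' a bin (closed interval: a distance on a shared edge enters both
#' overlapping bins) the composite dosage r-squared is computed, pooled
#' across chromosomes, and averaged per bin. Pairs undefined because a
#' locus is monomorphic on the pairwise-complete subset are skipped and
#' counted. Per-chromosome sums are retained for the jackknife in
#' [ne_trajectory()].
#'
#' @param g a [genotype_matrix()] with genetic positions attached.
#' @param bins a `distance_bins` object from [make_bins()].
#' @param max_pairs optional cap on pairs per bin; when set, a uniform
#'   subsample of that size is drawn with `seed`.
#' @param seed RNG seed used only when `max_pairs` is set.
#' @return a `bin_ld_stats` data.frame: bin columns plus `n_pairs` and
#'   `mean_r2`. Attributes: `n_samples`, `n_skipped` (monomorphic pairs),
#'   `chrom_sums` (per-chromosome r-squared sums and pair counts per bin).
#' @export
bin_r2_profile <- function(g, bins = make_bins(), max_pairs = NULL,
                           seed = NULL) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(bins, "distance_bins"))
  if (anyNA(g$sites$cm)) {
    stop("genetic positions (cm) must be attached before LD profiling; ",
         "see attach_genetic_map()")
  }
  d_max <- max(bins$c_high)
  chroms <- unique(g$sites$chrom)
  dist_all <- numeric(0); r2_all <- numeric(0); chr_all <- character(0)
  n_skipped <- 0L
  for (ch in chroms) {
    idx <- which(g$sites$chrom == ch)
    if (length(idx) < 2L) next
    cm <- g$sites$cm[idx]
    dmat <- abs(outer(cm, cm, "-"))
    ut <- which(upper.tri(dmat) & dmat <= d_max, arr.ind = TRUE)
    if (!nrow(ut)) next
    r2m <- suppressWarnings(
      stats::cor(g$dosages[, idx, drop = FALSE],
                 use = "pairwise.complete.obs")^2
    )
    r2 <- r2m[ut]
    bad <- is.na(r2)
    n_skipped <- n_skipped + sum(bad)
    dist_all <- c(dist_all, dmat[ut][!bad])
    r2_all <- c(r2_all, r2[!bad])
    chr_all <- c(chr_all, rep(ch, sum(!bad)))
  }
  if (!length(r2_all)) {
    stop("no SNP pairs fall in any distance bin; ",
         "use wider bins or a denser marker map")
  }
  if (!is.null(max_pairs) && !is.null(seed)) set.seed(seed)

  n_bins <- nrow(bins)
  chrom_levels <- chroms
  sum_mat <- matrix(0, nrow = length(chrom_levels), ncol = n_bins,
                    dimnames = list(chrom_levels, NULL))
  cnt_mat <- sum_mat
  n_pairs <- integer(n_bins)
  mean_r2 <- rep(NA_real_, n_bins)
  chr_f <- factor(chr_all, levels = chrom_levels)
  for (b in seq_len(n_bins)) {
    in_bin <- which(dist_all >= bins$c_low[b] & dist_all <= bins$c_high[b])
    if (!is.null(max_pairs) && length(in_bin) > max_pairs) {
      in_bin <- sample(in_bin, max_pairs)
    }
    if (!length(in_bin)) next
    n_pairs[b] <- length(in_bin)
    mean_r2[b] <- mean(r2_all[in_bin])
    s <- tapply(r2_all[in_bin], chr_f[in_bin], sum)
    k <- tapply(rep(1, length(in_bin)), chr_f[in_bin], sum)
    sum_mat[, b] <- ifelse(is.na(s), 0, s)
    cnt_mat[, b] <- ifelse(is.na(k), 0, k)
  }
  if (all(n_pairs == 0L)) {
    stop("no SNP pairs fall in any distance bin; ",
         "use wider bins or a denser marker map")
  }
  out <- cbind(bins, n_pairs = n_pairs, mean_r2 = mean_r2)
  class(out) <- c("bin_ld_stats", "data.frame")
  attr(out, "n_samples") <- n_samples(g)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "chrom_sums") <- list(sum = sum_mat, n = cnt_mat)
  out
}

#' Invert the Sved relationship: Ne from mean r-squared
#'
#' Under the drift-recombination relationship
#' `E[r2] = 1/(alpha + 4 Ne c) + 1/n`, the effective population size is
#' `Ne = (1/(4c)) * (1/(r2 - 1/n) - alpha)`. The `1/n` term corrects for
#' sampling noise with `n` the number of individuals (composite dosage
#' estimator); `alpha` is 2 for the mutation-adjusted variant (default)
#' or 1 for the classic form. A bin whose adjusted r-squared is
#' non-positive carries no signal and returns `NA`; a negative inversion
#' is clamped to 0.
#'
#' @param mean_r2 mean r-squared (vectorised).
#' @param c recombination distance in Morgans (> 0).
#' @param n_samples number of individuals behind `mean_r2`.
#' @param alpha structural constant, 1 or 2.
#' @return Ne estimate(s), `NA` where undefined.
#' @export
ne_from_r2 <- function(mean_r2, c, n_samples, alpha = 2) {
  stopifnot(all(c > 0), n_samples >= 2, alpha %in% c(1, 2))
  adj <- mean_r2 - 1 / n_samples
  ne <- ifelse(adj > 0, (1 / (4 * c)) * (1 / adj - alpha), NA_real_)
  pmax(ne, 0)
}

#' Expected r-squared under the Sved relationship
#'
#' Forward form `E[r2] = 1/(alpha + 4 Ne c) + 1/n`; exact inverse of
#' [ne_from_r2()].
#'
#' @param ne effective population size (> 0).
#' @inheritParams ne_from_r2
#' @return expected mean r-squared.
#' @export
r2_from_ne <- function(ne, c, n_samples, alpha = 2) {
  stopifnot(all(ne > 0), all(c > 0))
  1 / (alpha + 4 * ne * c) + 1 / n_samples
}

#' Ne trajectory through time from a binned LD profile
#'
#' Inverts the per-bin mean r-squared to Ne at the bin's representative
#' distance, and attaches 95% confidence intervals from a
#' leave-one-chromosome-out jackknife: each chromosome's pairs are removed
#' in turn, the bin mean recomputed and re-inverted, and the 2.5/97.5
#' percentiles of the resulting Ne values taken (widened minimally to
#' bracket the point estimate). Time depths are `t_gen = 1/(2c)`
#' generations and `t_years = t_gen * generation_years`.
#'
#' @param stats a `bin_ld_stats` object from [bin_r2_profile()].
#' @param alpha structural constant of the Sved relationship (1 or 2).
#' @param generation_years years per generation (default 25).
#' @return an `ne_trajectory` data.frame: `c_low`, `c_high`, `c_mid`,
#'   `t_gen`, `t_years`, `n_pairs`, `mean_r2`, `ne_hat`, `ci_low`,
#'   `ci_high`.
#' @export
ne_trajectory <- function(stats, alpha = 2, generation_years = 25) {
  stopifnot(inherits(stats, "bin_ld_stats"))
  n <- attr(stats, "n_samples")
  cs <- attr(stats, "chrom_sums")
  c_morgans <- stats$c_mid / 100
  ne_hat <- ne_from_r2(stats$mean_r2, c_morgans, n, alpha)
  n_chrom <- nrow(cs$sum)
  ci_low <- rep(NA_real_, nrow(stats))
  ci_high <- ci_low
  if (n_chrom >= 2L) {
    tot_s <- colSums(cs$sum)
    tot_n <- colSums(cs$n)
    for (b in seq_len(nrow(stats))) {
      if (stats$n_pairs[b] == 0L) next
      loo_n <- tot_n[b] - cs$n[, b]
      usable <- loo_n > 0
      if (sum(usable) < 2L) next
      loo_r2 <- (tot_s[b] - cs$sum[usable, b]) / loo_n[usable]
      loo_ne <- ne_from_r2(loo_r2, c_morgans[b], n, alpha)
      if (all(is.na(loo_ne))) next
      q <- stats::quantile(loo_ne, c(0.025, 0.975), na.rm = TRUE,
                           names = FALSE)
      ci_low[b] <- min(q[1], ne_hat[b], na.rm = TRUE)
      ci_high[b] <- max(q[2], ne_hat[b], na.rm = TRUE)
    }
  }
  out <- data.frame(
    c_low = stats$c_low, c_high = stats$c_high, c_mid = stats$c_mid,
    t_gen = stats$t_gen, t_years = stats$t_gen * generation_years,
    n_pairs = stats$n_pairs, mean_r2 = stats$mean_r2,
    ne_hat = ne_hat, ci_low = ci_low, ci_high = ci_high
  )
  class(out) <- c("ne_trajectory", "data.frame")
  attr(out, "generation_years") <- generation_years
  attr(out, "alpha") <- alpha
  attr(out, "n_samples") <- n
  out
}

#' Harmonic mean
#'
#' `1 / mean(1/x)`; the natural long-term average for effective population
#' sizes, dominated by the smallest epochs.
#'
#' @param x positive values; `NA`s removed.
#' @return the harmonic mean.
#' @export
harmonic_mean <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  if (any(x <= 0)) stop("harmonic mean requires strictly positive values")
  length(x) / sum(1 / x)
}

#' Long-term Ne as the harmonic mean over the trajectory
#'
#' Summarises an [ne_trajectory()] as the harmonic mean of the usable
#' per-bin estimates; bins with undefined Ne are excluded, and bins with
#' Ne = 0 are excluded with a warning (the harmonic mean is undefined at
#' 0). Confidence bounds are the harmonic means of the per-bin CI bounds.
#'
#' @param traj an `ne_trajectory`.
#' @return a `long_term_ne` list: `ne_harmonic`, `ci_low`, `ci_high`,
#'   `n_bins_used`.
#' @export
long_term_ne <- function(traj) {
  stopifnot(inherits(traj, "ne_trajectory"))
  usable <- !is.na(traj$ne_hat)
  if (!any(usable)) stop("no usable bins: every Ne estimate is undefined")
  zero <- usable & traj$ne_hat == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " bin(s) with Ne = 0 from harmonic mean")
    usable <- usable & !zero
  }
  if (!any(usable)) stop("no usable bins after excluding Ne = 0")
  ci_l <- traj$ci_low[usable]
  ci_h <- traj$ci_high[usable]
  structure(
    list(
      ne_harmonic = harmonic_mean(traj$ne_hat[usable]),
      ci_low = if (all(is.na(ci_l)) || any(ci_l <= 0, na.rm = TRUE))
        NA_real_ else harmonic_mean(ci_l),
      ci_high = if (all(is.na(ci_h))) NA_real_ else harmonic_mean(ci_h),
      n_bins_used = sum(usable)
    ),
    class = "long_term_ne"
  )
}

#' @export
print.long_term_ne <- function(x, ...) {
  cat(sprintf("long-term Ne (harmonic mean over %d bins): %.1f",
              x$n_bins_used, x$ne_harmonic))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  95%% CI (%.1f-%.1f)", x$ci_low, x$ci_high))
  }
  cat("\n")
  invisible(x)
}

#' Write / read an Ne trajectory as TSV
#'
#' @param traj an `ne_trajectory`.
#' @param path file path.
#' @return `path` (write) or an `ne_trajectory` data.frame (read).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ne_trajectory"))
  utils::write.table(as.data.frame(traj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t")
  class(out) <- c("ne_trajectory", "data.frame")
  out
}
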