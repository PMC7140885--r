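#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided comparison of two independent samples (here, Ne series from
#' two regions). Mode `"auto"` uses the exact null distribution of the
#' Mann-Whitney U statistic when `n1 + n2 <= 20` and the data contain no
#' ties, and otherwise the normal approximation with tie-corrected
#' variance and continuity correction. Forcing `mode = "exact"` on tied
#' data falls back to full enumeration of all `choose(n1 + n2, n1)`
#' group assignments.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return a `rank_sum_result` list: `U` (Mann-Whitney U for `x`),
#'   `p_value` (two-sided), `n1`, `n2`, `method`.
#' @export
rank_sum_test <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- switch(mode,
                      auto = (n1 + n2 <= 20) && !ties,
                      exact = TRUE,
                      approx = FALSE)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (use_exact && !ties) {
    p <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value
    method <- "exact"
  } else if (use_exact) {
    p <- .rank_sum_enumerate(x, y)
    method <- "exact-enumeration"
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    method <- "normal-approximation-with-tie-correction"
  }
  structure(list(U = u, p_value = min(p, 1), n1 = n1, n2 = n2,
                 method = method),
            class = "rank_sum_result")
}

# Exact two-sided p by enumeration of all C(n1+n2, n1) assignments of the
# pooled values to group 1; p = fraction of assignments whose U is at least
# as far from n1*n2/2 as the observed U. Feasible for n1+n2 <= ~20.
.rank_sum_enumerate <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  dev_obs <- abs(u_obs - n1 * n2 / 2)
  idx <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(u_all - n1 * n2 / 2) >= dev_obs - 1e-12)
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("rank-sum test: U = %g (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' Compare two Ne series between regions
#'
#' Convenience wrapper for the region comparison: reads two trajectory
#' TSVs (or accepts `ne_trajectory` objects), extracts the usable per-bin
#' Ne values, runs [rank_sum_test()], and reports the decision at `alpha`.
#'
#' @param a,b `ne_trajectory` objects or paths to trajectory TSVs.
#' @param alpha significance threshold (default 0.001).
#' @param value column to compare (default `"ne_hat"`).
#' @return a `region_comparison` list: the `rank_sum_result`, `alpha`,
#'   `significant`, and the two series' summaries.
#' @export
compare_regions <- function(a, b, alpha = 0.001, value = "ne_hat") {
  grab <- function(z) {
    if (is.character(z)) z <- read_trajectory(z)
    v <- z[[value]]
    v[!is.na(v) & v > 0]
  }
  va <- grab(a); vb <- grab(b)
  res <- rank_sum_test(va, vb)
  structure(
    list(test = res, alpha = alpha, significant = res$p_value < alpha,
         summary_a = summary(va), summary_b = summary(vb)),
    class = "region_comparison"
  )
}
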