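#' Divergence time from FST under pure drift
#'
#' Under drift alone, differentiation accrues as
#' `FST(T) = 1 - (1 - 1/(2 Ne))^T`, inverted here as
#' `T = ln(1 - FST) / ln(1 - 1/(2 Ne))` generations since the split.
#' Negative FST estimates (sampling noise around zero) give T = 0.
#'
#' @param fst pairwise FST in \[0, 1); values <= 0 map to 0.
#' @param ne effective population size per branch (> 0.5). Vectorised.
#' @return divergence time in generations.
#' @export
divergence_time <- function(fst, ne) {
  stopifnot(all(ne > 0.5))
  if (any(fst >= 1)) stop("fst >= 1 implies infinite divergence time")
  fst <- pmax(fst, 0)
  log(1 - fst) / log(1 - 1 / (2 * ne))
}

#' Expected FST accrued by drift
#'
#' Forward form `FST = 1 - (1 - 1/(2 Ne))^T`; exact inverse of
#' [divergence_time()].
#'
#' @param t_gen generations since the split.
#' @param ne per-branch effective population size.
#' @return expected FST.
#' @export
fst_from_divergence <- function(t_gen, ne) {
  stopifnot(all(t_gen >= 0), all(ne > 0.5))
  1 - (1 - 1 / (2 * ne))^t_gen
}

#' Divergence-time matrices from FST and long-term Ne
#'
#' Converts a pairwise FST matrix into divergence times. The Ne entering
#' the drift equation for each pair is, by default, the harmonic mean of
#' the two populations' long-term Ne (configurable to the minimum or a
#' fixed value). Negative FST entries are clamped to 0 and listed in the
#' `clamped_pairs` attribute. When the long-term Ne estimates carry
#' confidence intervals, CI matrices are produced by re-evaluating the
#' formula at the lower and upper Ne bounds (FST uncertainty is not
#' propagated).
#'
#' @param fst an `fst_matrix` (or plain labelled symmetric matrix).
#' @param ne_by_pop named list mapping each population label to a
#'   `long_term_ne` (or a single number).
#' @param generation_years years per generation (default 25).
#' @param pair_ne_rule `"harmonic"` (default), `"min"`, or `"fixed"`.
#' @param fixed_ne pair Ne when `pair_ne_rule = "fixed"`.
#' @return a `divergence_matrix` list: `generations`, `years` (= generations
#'   x `generation_years`), optional `ci_low_years` / `ci_high_years`,
#'   `generation_years`, and `clamped_pairs`.
#' @export
divergence_matrix <- function(fst, ne_by_pop, generation_years = 25,
                              pair_ne_rule = c("harmonic", "min", "fixed"),
                              fixed_ne = NULL) {
  pair_ne_rule <- match.arg(pair_ne_rule)
  labels <- rownames(fst)
  if (is.null(labels) || !identical(labels, colnames(fst))) {
    stop("fst must be a labelled square matrix")
  }
  missing_lab <- setdiff(labels, names(ne_by_pop))
  if (pair_ne_rule != "fixed" && length(missing_lab)) {
    stop("no Ne estimate for population(s): ",
         paste(missing_lab, collapse = ", "))
  }
  get_field <- function(lab, field) {
    x <- ne_by_pop[[lab]]
    if (inherits(x, "long_term_ne")) {
      switch(field, est = x$ne_harmonic, low = x$ci_low, high = x$ci_high)
    } else if (field == "est") as.numeric(x) else NA_real_
  }
  pair_ne <- function(na, nb) {
    switch(pair_ne_rule,
           harmonic = harmonic_mean(c(na, nb)),
           min = min(na, nb),
           fixed = fixed_ne)
  }
  k <- length(labels)
  gen <- matrix(0, k, k, dimnames = list(labels, labels))
  lo <- hi <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  diag(lo) <- diag(hi) <- 0
  clamped <- character(0)
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      f <- fst[i, j]
      if (f < 0) clamped <- c(clamped, paste(labels[i], labels[j], sep = "-"))
      ne <- pair_ne(get_field(labels[i], "est"), get_field(labels[j], "est"))
      gen[i, j] <- gen[j, i] <- divergence_time(f, ne)
      ne_lo <- pair_ne(get_field(labels[i], "low"), get_field(labels[j], "low"))
      ne_hi <- pair_ne(get_field(labels[i], "high"),
                       get_field(labels[j], "high"))
      if (pair_ne_rule != "fixed" && !is.na(ne_lo) && !is.na(ne_hi)) {
        lo[i, j] <- lo[j, i] <- divergence_time(f, ne_lo)
        hi[i, j] <- hi[j, i] <- divergence_time(f, ne_hi)
      }
    }
  }
  structure(
    list(generations = gen, years = gen * generation_years,
         ci_low_years = lo * generation_years,
         ci_high_years = hi * generation_years,
         generation_years = generation_years, clamped_pairs = clamped),
    class = "divergence_matrix"
  )
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat(sprintf("divergence_matrix: %d populations, %g years/generation\n",
              nrow(x$generations), x$generation_years))
  print(round(x$years))
  invisible(x)
}
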