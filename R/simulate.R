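#' Define a Wright-Fisher simulation scenario
#'
#' Describes the demographic truth behind a synthetic genotype panel:
#' number of chromosomes, marker density, genetic-map length, the Ne plan,
#' and sample size. Defaults emulate a dense genotyping array: markers
#' every 0.005 cM (OmniExpress-like density) on several independent
#' chromosomes, initial standing variation with allele frequencies uniform
#' on \[0.05, 0.95\], recurrent symmetric mutation maintaining the site
#' frequency spectrum, and a burn-in of `4 * Ne` generations so LD is near
#' mutation-drift-recombination equilibrium before sampling. Without
#' mutation (`mutation = FALSE`) there is no LD equilibrium: tightly
#' linked variation collapses onto few haplotypes and r-squared keeps
#' rising, so the drift-only mode is meant for linkage-structure tests,
#' not Ne recovery.
#'
#' @param n_chromosomes number of independently segregating chromosomes.
#' @param loci_per_chr markers per chromosome.
#' @param chr_length_cm genetic-map length of each chromosome in cM.
#' @param demography either `list(type = "constant", ne = N)` or
#'   `list(type = "piecewise", epochs = data.frame(ne, generations))`,
#'   epochs ordered oldest first (the first epoch also sets the founder
#'   pool and burn-in length).
#' @param sample_n diploid individuals genotyped at the end.
#' @param burn_in generations before the epoch schedule; default
#'   `4 * ne` of the first epoch.
#' @param mutation logical; simulate recurrent symmetric allele-flip
#'   mutation (default `TRUE`). `FALSE` gives pure drift.
#' @param mutation_rate per-locus flip probability per transmitted gamete;
#'   default scales with the founding size so that the population-scaled
#'   rate is `4 * Ne * mu = 0.1` per locus, enough to hold a stationary
#'   polymorphism spectrum at desk scale.
#' @param seed RNG seed; the same seed reproduces the panel exactly.
#' @return a `sim_scenario` list.
#' @export
sim_scenario <- function(n_chromosomes = 5, loci_per_chr = 300,
                         chr_length_cm = 1.5,
                         demography = list(type = "constant", ne = 500),
                         sample_n = 100, burn_in = NULL, mutation = TRUE,
                         mutation_rate = NULL, seed = 1) {
  stopifnot(n_chromosomes >= 1, loci_per_chr >= 2, chr_length_cm > 0,
            sample_n >= 1)
  epochs <- switch(
    demography$type,
    constant = data.frame(ne = demography$ne, generations = 0),
    piecewise = as.data.frame(demography$epochs),
    stop("demography$type must be 'constant' or 'piecewise'")
  )
  stopifnot(all(epochs$ne >= 1), all(epochs$generations >= 0))
  if (is.null(burn_in)) burn_in <- 4 * epochs$ne[1]
  if (sample_n > epochs$ne[nrow(epochs)]) {
    stop("sample_n cannot exceed the final population size")
  }
  if (!mutation) {
    mutation_rate <- 0
  } else if (is.null(mutation_rate)) {
    mutation_rate <- 0.1 / (4 * epochs$ne[1])
  }
  stopifnot(mutation_rate >= 0, mutation_rate < 0.5)
  structure(
    list(n_chromosomes = n_chromosomes, loci_per_chr = loci_per_chr,
         chr_length_cm = chr_length_cm, epochs = epochs,
         sample_n = sample_n, burn_in = burn_in,
         mutation_rate = mutation_rate, seed = seed),
    class = "sim_scenario"
  )
}

#' Forward Wright-Fisher genotype simulation
#'
#' Simulates discrete, non-overlapping generations of a random-mating
#' diploid population per chromosome: recombination between adjacent
#' markers with probability `d_cM / 100` per meiosis (small-interval
#' approximation), binomially founded standing variation, and (by default)
#' recurrent symmetric mutation at the scenario's per-locus rate.
#' After the burn-in and any demographic epochs, `sample_n` individuals
#' are drawn and their allele dosages returned with genetic positions
#' already attached (uniform marker spacing).
#'
#' @param scenario a [sim_scenario()].
#' @return list with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (scenario parameters plus the Ne plan actually simulated).
#' @export
sim_wright_fisher <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  L <- scenario$loci_per_chr
  spacing_cm <- scenario$chr_length_cm / L
  rec <- rep(spacing_cm / 100, L - 1)
  ep <- scenario$epochs
  ne_path <- c(rep(ep$ne[1], scenario$burn_in),
               rep(ep$ne, ep$generations))
  if (!length(ne_path)) stop("scenario simulates zero generations")
  ne0 <- ep$ne[1]
  ne_last <- ne_path[length(ne_path)]

  dos_list <- vector("list", scenario$n_chromosomes)
  for (ch in seq_len(scenario$n_chromosomes)) {
    p0 <- stats::runif(L, 0.05, 0.95)
    haps <- matrix(stats::rbinom(L * 2 * ne0, 1L, p0), nrow = L)
    final <- wf_evolve(haps, as.integer(ne_path), rec,
                       mu = scenario$mutation_rate)
    ids <- sample.int(ne_last, scenario$sample_n)
    dos_list[[ch]] <- t(final[, 2 * ids - 1L, drop = FALSE] +
                          final[, 2 * ids, drop = FALSE])
  }
  cm <- seq_len(L) * spacing_cm
  sites <- do.call(rbind, lapply(seq_len(scenario$n_chromosomes), function(ch) {
    data.frame(chrom = as.character(ch), bp = pmax(1, round(cm * 1e6)),
               id = sprintf("snp%d_%d", ch, seq_len(L)),
               a1 = "A", a2 = "G", cm = cm, stringsAsFactors = FALSE)
  }))
  samples <- data.frame(id = sprintf("ind%03d", seq_len(scenario$sample_n)),
                        population = "SIM", stringsAsFactors = FALSE)
  g <- genotype_matrix(do.call(cbind, dos_list), sites, samples)
  truth <- list(scenario = scenario,
                ne_plan = data.frame(ne = unique(ne_path)),
                generations_simulated = length(ne_path))
  list(genotypes = g, truth = truth)
}

#' Two-population drift split simulation
#'
#' Per-locus ancestral allele frequencies are drawn uniform on
#' \[0.05, 0.95\]; two descendant branches then drift independently by
#' binomial resampling of `2 * branch_ne` gametes per generation for
#' `t_split` generations, and `sample_n` diploid genotypes per branch are
#' sampled binomially from the final frequencies (loci unlinked). The
#' truth record carries the drift expectation
#' `FST = 1 - (1 - 1/(2 Ne))^T` that [divergence_time()] inverts.
#'
#' @param ancestral_ne effective size of the ancestral population (source
#'   of the standing variation; the drift epoch itself uses `branch_ne`).
#' @param branch_ne per-branch effective size after the split.
#' @param t_split generations since the split.
#' @param n_loci unlinked biallelic loci.
#' @param sample_n diploid individuals sampled per branch.
#' @param seed RNG seed.
#' @return list with `genotypes` (populations labelled "A" and "B") and
#'   `truth` (parameters plus `expected_fst`).
#' @export
sim_split_drift <- function(ancestral_ne = 1000, branch_ne = 1000,
                            t_split = 100, n_loci = 20000, sample_n = 50,
                            seed = 1) {
  stopifnot(ancestral_ne >= 1, branch_ne >= 1, t_split >= 0, n_loci >= 1,
            sample_n >= 2)
  set.seed(seed)
  p0 <- stats::runif(n_loci, 0.05, 0.95)
  drift <- function(p) {
    for (t in seq_len(t_split)) {
      p <- stats::rbinom(n_loci, 2L * branch_ne, p) / (2 * branch_ne)
    }
    p
  }
  pa <- drift(p0)
  pb <- drift(p0)
  geno <- function(p) {
    matrix(stats::rbinom(sample_n * n_loci, 2L, rep(p, each = sample_n)),
           nrow = sample_n)
  }
  dos <- rbind(geno(pa), geno(pb))
  sites <- data.frame(chrom = "1", bp = seq_len(n_loci) * 1000L,
                      id = sprintf("snp%d", seq_len(n_loci)),
                      a1 = "A", a2 = "G", cm = NA_real_,
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    id = sprintf("%s%03d", rep(c("A", "B"), each = sample_n),
                 rep(seq_len(sample_n), 2)),
    population = rep(c("A", "B"), each = sample_n),
    stringsAsFactors = FALSE
  )
  truth <- list(ancestral_ne = ancestral_ne, branch_ne = branch_ne,
                t_split = t_split, n_loci = n_loci, sample_n = sample_n,
                seed = seed,
                expected_fst = fst_from_divergence(t_split, branch_ne),
                freq_ancestral = p0, freq_a = pa, freq_b = pb)
  list(genotypes = genotype_matrix(dos, sites, samples), truth = truth)
}
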