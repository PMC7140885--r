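#' Run the full demographic-inference pipeline
#'
#' Orchestrates the stages on one configuration: load (or simulate)
#' genotypes, quality control, per-population LD-based Ne trajectory and
#' long-term Ne, pairwise Weir-Cockerham FST, drift divergence times, the
#' UPGMA tree, and (optionally) a rank-sum comparison of two populations'
#' Ne series. Every stage writes a self-describing plain-text artifact
#' (TSV/JSON/Newick) into `out_dir`, so any single stage can be re-run
#' standalone on external data, and a run manifest records parameters and
#' seeds.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   * `bfile` — PLINK prefix to load, or `scenario` — a [sim_scenario()]
#'     (or its argument list) to simulate, or `split` — an argument list
#'     for [sim_split_drift()];
#'   * `map` — genetic-map file path (optional if cM already present);
#'   * `qc` — list of thresholds for [apply_qc()] (optional);
#'   * `alpha` — Sved constant (default 2);
#'   * `generation_years` — default 25;
#'   * `fixed_ne` — pair Ne for divergence when no LD-based long-term Ne is
#'     available (e.g. unlinked split data without a genetic map);
#'   * `compare` — character vector of two population labels (optional);
#'   * `seed` — integer seed recorded and applied.
#' @param out_dir output directory, created if missing.
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  gy <- if (is.null(config$generation_years)) 25 else config$generation_years
  alpha <- if (is.null(config$alpha)) 2 else config$alpha
  manifest <- list(started = format(Sys.time(), tz = "UTC"),
                   package_version = as.character(utils::packageVersion("ldne")),
                   seed = seed, generation_years = gy, alpha = alpha)

  # --- stage: genotypes ---------------------------------------------------
  if (!is.null(config$scenario)) {
    sc <- config$scenario
    if (!inherits(sc, "sim_scenario")) {
      sc$seed <- if (is.null(sc$seed)) seed else sc$seed
      sc <- do.call(sim_scenario, sc)
    }
    sim <- sim_wright_fisher(sc)
    g <- sim$genotypes
    write_plink(g, file.path(out_dir, "simulated"))
    jsonlite::write_json(sim$truth["scenario"],
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    manifest$input <- "simulated"
  } else if (!is.null(config$split)) {
    sa <- config$split
    if (is.null(sa$seed)) sa$seed <- seed
    sim <- do.call(sim_split_drift, sa)
    g <- sim$genotypes
    write_plink(g, file.path(out_dir, "simulated"))
    jsonlite::write_json(
      sim$truth[c("branch_ne", "t_split", "n_loci", "sample_n", "seed",
                  "expected_fst")],
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE
    )
    manifest$input <- "simulated-split"
  } else if (!is.null(config$bfile)) {
    g <- read_plink(config$bfile)
    manifest$input <- normalizePath(paste0(config$bfile, ".bed"))
    manifest$input_md5 <- unname(tools::md5sum(manifest$input))
  } else {
    stop("config must provide either 'bfile' or 'scenario'")
  }
  if (!is.null(config$map)) {
    g <- attach_genetic_map(g, read_genetic_map(config$map))
  }

  # --- stage: qc ----------------------------------------------------------
  qc_args <- config$qc
  if (is.null(qc_args)) qc_args <- list()
  qc <- do.call(apply_qc, c(list(g), qc_args))
  g <- qc$genotypes
  write_qc_report(qc$report, file.path(out_dir, "qc_removals.tsv"),
                  file.path(out_dir, "qc_summary.json"))

  # --- stage: per-population Ne trajectory (needs genetic positions) ------
  pops <- split_by_population(g)
  ne_by_pop <- list()
  trajs <- list()
  if (!anyNA(g$sites$cm)) {
    bins <- make_bins()
    for (p in names(pops)) {
      st <- bin_r2_profile(pops[[p]], bins)
      tr <- ne_trajectory(st, alpha = alpha, generation_years = gy)
      trajs[[p]] <- tr
      ne_by_pop[[p]] <- long_term_ne(tr)
      write_trajectory(tr, file.path(out_dir,
                                     sprintf("ne_trajectory_%s.tsv", p)))
    }
    jsonlite::write_json(
      lapply(ne_by_pop, function(x) x[c("ne_harmonic", "ci_low", "ci_high")]),
      file.path(out_dir, "long_term_ne.json"),
      auto_unbox = TRUE, pretty = TRUE, na = "null"
    )
  }

  # --- stages needing >= 2 populations ------------------------------------
  fst <- div <- tree <- NULL
  if (length(pops) >= 2L) {
    fst <- fst_matrix(g)
    write_square_tsv(fst, file.path(out_dir, "fst.tsv"))
    if (length(ne_by_pop)) {
      div <- divergence_matrix(fst, ne_by_pop, generation_years = gy)
    } else if (!is.null(config$fixed_ne)) {
      div <- divergence_matrix(fst, list(), generation_years = gy,
                               pair_ne_rule = "fixed",
                               fixed_ne = config$fixed_ne)
    }
    if (!is.null(div)) {
      write_square_tsv(div$generations,
                       file.path(out_dir, "divergence_generations.tsv"))
      write_square_tsv(div$years, file.path(out_dir, "divergence_years.tsv"))
      tree <- upgma_tree(div)
      to_newick(tree, file.path(out_dir, "divergence_upgma.nwk"))
    }
  }

  # --- stage: region comparison -------------------------------------------
  comparison <- NULL
  if (!is.null(config$compare)) {
    stopifnot(length(config$compare) == 2L,
              all(config$compare %in% names(trajs)))
    comparison <- compare_regions(trajs[[config$compare[1]]],
                                  trajs[[config$compare[2]]],
                                  alpha = if (is.null(config$compare_alpha))
                                    0.001 else config$compare_alpha)
    jsonlite::write_json(
      c(comparison$test[c("U", "p_value", "n1", "n2", "method")],
        list(alpha = comparison$alpha, significant = comparison$significant)),
      file.path(out_dir, "region_comparison.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }

  manifest$finished <- format(Sys.time(), tz = "UTC")
  manifest$artifacts <- list.files(out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(genotypes = g, qc = qc$report, trajectories = trajs,
                 long_term_ne = ne_by_pop, fst = fst, divergence = div,
                 tree = tree, comparison = comparison))
}
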