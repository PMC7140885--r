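#' Read a PLINK binary fileset
#'
#' Reads a PLINK 1 binary trio (`.bed`/`.bim`/`.fam`) into a
#' [genotype_matrix()]. Only the SNP-major `.bed` layout (the PLINK 1.9
#' default) is supported. Dosages count copies of the A1 allele (`.bim`
#' column 5): the 2-bit codes 00/10/11 decode to dosage 2/1/0 and 01 to
#' missing. Non-autosomal sites (chromosome codes X, Y, XY, MT, 0 and
#' 23--26) are dropped with a message, since all downstream analyses are
#' autosomal.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return a [genotype_matrix()]. The population label is taken from the
#'   family ID column of the `.fam` file when it differs from the
#'   individual ID, otherwise left `NA`.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) {
    if (!file.exists(p)) stop("PLINK file not found: ", p)
  }
  fam <- utils::read.table(paths[3], header = FALSE,
                           colClasses = "character")
  if (ncol(fam) < 2L) stop("malformed .fam file: ", paths[3])
  bim <- utils::read.table(paths[2], header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "numeric", "character", "character"))
  bim$V4 <- as.integer(round(bim$V4))
  if (ncol(bim) != 6L) stop("malformed .bim file (expected 6 columns): ",
                            paths[2])
  n <- nrow(fam)
  m <- nrow(bim)

  bed <- readBin(paths[1], what = "raw",
                 n = file.info(paths[1])$size)
  if (length(bed) < 3L || bed[1] != as.raw(0x6c) || bed[2] != as.raw(0x1b)) {
    stop("not a PLINK .bed file (bad magic number): ", paths[1])
  }
  if (bed[3] != as.raw(0x01)) {
    stop("only SNP-major .bed files are supported: ", paths[1])
  }
  bps <- ceiling(n / 4)          # bytes per SNP
  if (length(bed) - 3L != bps * m) {
    stop("truncated or oversized .bed file: ", paths[1],
         " (expected ", bps * m, " data bytes, found ", length(bed) - 3L, ")")
  }
  b <- matrix(as.integer(bed[-(1:3)]), nrow = bps, ncol = m)
  codes <- array(0L, dim = c(4L, bps, m))
  for (k in 0:3) codes[k + 1L, , ] <- (b %/% (4L^k)) %% 4L
  dim(codes) <- c(4L * bps, m)
  # 2-bit genotype code -> A1 dosage: 00->2, 01->missing, 10->1, 11->0
  lut <- c(2L, NA_integer_, 1L, 0L)
  dos <- matrix(lut[codes[seq_len(n), , drop = FALSE] + 1L], nrow = n)

  sites <- data.frame(chrom = bim$V1, bp = bim$V4, id = bim$V2,
                      a1 = bim$V5, a2 = bim$V6,
                      cm = ifelse(bim$V3 == 0, NA_real_, bim$V3),
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    id = fam$V2,
    population = ifelse(fam$V1 == fam$V2, NA_character_, fam$V1),
    stringsAsFactors = FALSE
  )
  non_auto <- !sites$chrom %in% as.character(1:22)
  if (any(non_auto)) {
    message("read_plink: dropping ", sum(non_auto), " non-autosomal site(s)")
    if (all(non_auto)) stop("no autosomal sites in ", paths[2])
    dos <- dos[, !non_auto, drop = FALSE]
    sites <- sites[!non_auto, , drop = FALSE]
  }
  genotype_matrix(dos, sites, samples)
}

#' Write a PLINK binary fileset
#'
#' Inverse of [read_plink()]: writes SNP-major `.bed` plus `.bim`/`.fam`.
#' The family ID column is the population label (the sample ID when the
#' label is missing).
#'
#' @param g a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- n_samples(g); m <- n_sites(g)
  fam <- data.frame(
    fid = ifelse(is.na(g$samples$population), g$samples$id,
                 g$samples$population),
    iid = g$samples$id, pat = 0L, mat = 0L, sex = 0L, pheno = -9L
  )
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(
    chrom = g$sites$chrom, id = g$sites$id,
    cm = ifelse(is.na(g$sites$cm), 0, g$sites$cm),
    bp = format(g$sites$bp, scientific = FALSE, trim = TRUE),
    a1 = g$sites$a1, a2 = g$sites$a2
  )
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")

  # A1 dosage -> 2-bit code: 2->00, missing->01, 1->10, 0->11
  code <- matrix(3L, nrow = n, ncol = m)
  d <- g$dosages
  code[!is.na(d) & d == 2L] <- 0L
  code[is.na(d)] <- 1L
  code[!is.na(d) & d == 1L] <- 2L
  bps <- ceiling(n / 4)
  pad <- 4L * bps - n
  if (pad > 0L) code <- rbind(code, matrix(0L, nrow = pad, ncol = m))
  dim(code) <- c(4L, bps, m)
  bytes <- code[1L, , ] + 4L * code[2L, , ] + 16L * code[3L, , ] +
    64L * code[4L, , ]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read a genetic map file
#'
#' Whitespace-delimited text with a header line and three columns:
#' chromosome, physical position (bp), genetic position (cM). Within each
#' chromosome, positions must be strictly increasing and cM nondecreasing.
#'
#' @param path map file path.
#' @return a `genetic_map`: named list (one entry per chromosome) of
#'   data.frames with columns `bp`, `cm`.
#' @export
read_genetic_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE)
  if (ncol(tab) < 3L) stop("genetic map needs 3 columns: chromosome, bp, cM")
  genetic_map(chrom = as.character(tab[[1]]), bp = as.numeric(tab[[2]]),
              cm = as.numeric(tab[[3]]))
}

#' Construct a genetic map from anchor points
#'
#' @param chrom chromosome label per anchor.
#' @param bp physical position per anchor (strictly increasing within each
#'   chromosome).
#' @param cm genetic position in cM per anchor (nondecreasing within each
#'   chromosome).
#' @return a `genetic_map` (see [read_genetic_map()]).
#' @export
genetic_map <- function(chrom, bp, cm) {
  stopifnot(length(chrom) == length(bp), length(bp) == length(cm))
  parts <- split(data.frame(bp = bp, cm = cm), as.character(chrom))
  parts <- lapply(parts, function(d) {
    d <- d[order(d$bp), , drop = FALSE]
    if (anyDuplicated(d$bp)) stop("duplicate bp anchors within a chromosome")
    if (is.unsorted(d$cm)) stop("cM must be nondecreasing in bp")
    rownames(d) <- NULL
    d
  })
  structure(parts, class = "genetic_map")
}

#' Write a genetic map file
#' @param m a `genetic_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(m, path) {
  stopifnot(inherits(m, "genetic_map"))
  tab <- do.call(rbind, lapply(names(m), function(ch) {
    data.frame(chromosome = ch, position = m[[ch]]$bp, cM = m[[ch]]$cm)
  }))
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Attach genetic-map positions to a genotype matrix
#'
#' Sets the cM coordinate of every site by linear interpolation in physical
#' position between the flanking map anchors of its chromosome. Sites
#' outside the anchor range are handled per `policy`: `"clamp"` (default)
#' assigns the terminal anchor's cM; `"error"` fails.
#'
#' @param g a [genotype_matrix()].
#' @param m a `genetic_map` covering every chromosome in `g`.
#' @param policy extrapolation policy, `"clamp"` or `"error"`.
#' @return `g` with `sites$cm` filled in.
#' @export
attach_genetic_map <- function(g, m, policy = c("clamp", "error")) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(m, "genetic_map"))
  policy <- match.arg(policy)
  missing_chr <- setdiff(unique(g$sites$chrom), names(m))
  if (length(missing_chr)) {
    stop("chromosome(s) absent from genetic map: ",
         paste(missing_chr, collapse = ", "))
  }
  cm <- numeric(n_sites(g))
  for (ch in unique(g$sites$chrom)) {
    idx <- which(g$sites$chrom == ch)
    anchors <- m[[ch]]
    x <- g$sites$bp[idx]
    if (policy == "error" &&
        (min(x) < anchors$bp[1] || max(x) > anchors$bp[nrow(anchors)])) {
      stop("site(s) on chromosome ", ch, " outside genetic-map anchor range")
    }
    if (nrow(anchors) == 1L) {
      cm[idx] <- anchors$cm
    } else {
      cm[idx] <- stats::approx(anchors$bp, anchors$cm, xout = x,
                               rule = 2, ties = "ordered")$y
    }
  }
  g$sites$cm <- cm
  g
}

.strand_complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Merge two genotype datasets on shared markers
#'
#' Intersects marker IDs and reconciles allele coding: sites where `b` has
#' A1/A2 swapped relative to `a` get their dosages flipped (`2 - d`);
#' non-ambiguous strand flips are complemented and then matched; strand-
#' ambiguous sites (A/T, C/G) whose alleles do not match `a` exactly are
#' dropped, as are sites with irreconcilable alleles. Samples are
#' concatenated with population labels preserved.
#'
#' @param a,b [genotype_matrix()] objects with allele codes per site.
#' @return a merged [genotype_matrix()] on the reconciled shared sites.
#' @export
merge_datasets <- function(a, b) {
  stopifnot(inherits(a, "genotype_matrix"), inherits(b, "genotype_matrix"))
  shared <- intersect(a$sites$id, b$sites$id)
  if (!length(shared)) stop("no shared marker IDs between datasets")
  ai <- match(shared, a$sites$id)
  bi <- match(shared, b$sites$id)
  a1a <- toupper(a$sites$a1[ai]); a2a <- toupper(a$sites$a2[ai])
  a1b <- toupper(b$sites$a1[bi]); a2b <- toupper(b$sites$a2[bi])
  ambiguous <- (a1a == .strand_complement[a2a]) & !is.na(.strand_complement[a2a])

  same  <- a1b == a1a & a2b == a2a
  swap  <- a1b == a2a & a2b == a1a
  c1b <- .strand_complement[a1b]; c2b <- .strand_complement[a2b]
  flip_same <- !is.na(c1b) & !is.na(c2b) & c1b == a1a & c2b == a2a
  flip_swap <- !is.na(c1b) & !is.na(c2b) & c1b == a2a & c2b == a1a

  keep_asis <- same | (!ambiguous & flip_same & !same & !swap)
  keep_swap <- (!same & swap & !ambiguous) |
    (!ambiguous & flip_swap & !same & !swap & !flip_same)
  keep <- keep_asis | keep_swap
  n_drop <- sum(!keep)
  if (n_drop) {
    message("merge_datasets: dropping ", n_drop,
            " site(s) with irreconcilable or strand-ambiguous alleles")
  }
  if (!any(keep)) stop("no shared markers with reconcilable alleles")

  ai <- ai[keep]; bi <- bi[keep]
  bd <- b$dosages[, bi, drop = FALSE]
  fl <- keep_swap[keep]
  if (any(fl)) bd[, fl] <- 2L - bd[, fl, drop = FALSE]
  genotype_matrix(
    rbind(a$dosages[, ai, drop = FALSE], bd),
    a$sites[ai, , drop = FALSE],
    rbind(a$samples, b$samples)
  )
}
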