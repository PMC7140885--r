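#' UPGMA tree from a divergence-time matrix
#'
#' Classic unweighted pair-group (average-linkage) clustering: the closest
#' pair of clusters is merged at height d/2 and distances to the merged
#' cluster are size-weighted averages, producing an ultrametric rooted
#' tree whose leaves sit at height 0. Labels are sorted lexicographically
#' before clustering so ties in the minimum distance break
#' deterministically. Heights are in the units of the input matrix (years,
#' when given a [divergence_matrix()]).
#'
#' @param d a `divergence_matrix` (its `years` matrix is used) or a plain
#'   labelled symmetric matrix of nonnegative distances.
#' @return an ultrametric `ape` tree of class
#'   `c("ultrametric_tree", "phylo")` with branch lengths in input units.
#' @export
upgma_tree <- function(d) {
  if (inherits(d, "divergence_matrix")) d <- d$years
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d))) {
    stop("distance matrix must have matching row/column labels")
  }
  if (nrow(d) < 2L) stop("need >= 2 labels to build a tree")
  if (anyNA(d)) {
    bad <- which(is.na(d), arr.ind = TRUE)[1, ]
    stop("NaN/NA distance for pair (", rownames(d)[bad[1]], ", ",
         colnames(d)[bad[2]], ")")
  }
  if (!isSymmetric(unname(as.matrix(d)), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  if (any(d < 0)) stop("distances must be nonnegative")
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # as.phylo halves hclust merge heights, i.e. node height = d/2
  tr <- ape::as.phylo(hc)
  class(tr) <- c("ultrametric_tree", "phylo")
  tr
}

#' Serialise a tree to Newick
#'
#' Standard single-line Newick with branch lengths, ";"-terminated;
#' labels containing Newick metacharacters are quoted by the writer.
#'
#' @param tree a `phylo` tree.
#' @param path optional output file; when `NULL` the string is returned.
#' @param precision significant digits for branch lengths.
#' @return the Newick string, invisibly when written to a file.
#' @export
to_newick <- function(tree, path = NULL, precision = 10) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = precision)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Root-to-leaf depths of a rooted tree
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return named vector of root-to-leaf path lengths, one per tip.
#' @export
tree_leaf_depths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  depths <- ape::node.depth.edgelength(tree)
  stats::setNames(depths[seq_len(ape::Ntip(tree))], tree$tip.label)
}
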