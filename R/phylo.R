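# Ultrametric family phylogenies: patristic matrices, UPGMA trees and the
# Brownian-motion covariance.

#' Patristic distances from divergence node ages
#'
#' On an ultrametric tree the patristic (tip-to-tip path) distance between
#' two families equals twice the age of their divergence node.
#'
#' @param node_ages symmetric non-negative matrix of pairwise divergence node
#'   ages (Ma), labeled by family.
#' @return symmetric patristic matrix (Ma) with zero diagonal.
#' @export
patristic_from_node_ages <- function(node_ages) {
  node_ages <- as.matrix(node_ages)
  if (any(node_ages < 0)) stop("negative node age")
  if (!isSymmetric(unname(node_ages), tol = 1e-8))
    stop("node-age matrix must be symmetric")
  d <- 2 * node_ages
  diag(d) <- 0
  d
}

#' UPGMA tree from a patristic distance matrix
#'
#' Average-linkage agglomeration; node heights are half the merge distance so
#' that an ultrametric input is reproduced exactly. Ties are resolved
#' deterministically (lexicographic tip order, as in `hclust`).
#'
#' @param d symmetric distance matrix with zero diagonal, or a `dist`.
#' @return an ultrametric `phylo` tree with branch lengths in the units of
#'   `d` / 2 per unit height (Ma for patristic input).
#' @export
upgma_tree <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d), tol = 1e-8))
      stop("distance matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  phangorn::upgma(d)
}

# Depth (root-to-tip path length) of an ultrametric tree, with tolerance
# check: all root-to-tip paths must agree to rel_tol * depth.
tree_depth <- function(tree, rel_tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  depth <- max(depths)
  if (depth > 0 && diff(range(depths)) > rel_tol * depth)
    stop("tree is not ultrametric within tolerance")
  depth
}

#' Brownian-motion covariance matrix of a tree
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j; the
#' diagonal is the root-to-tip depth. For an ultrametric tree this equals
#' depth minus the divergence node age.
#'
#' @param tree a `phylo` object.
#' @return symmetric positive-semidefinite matrix over tips (Ma).
#' @export
bm_covariance <- function(tree) {
  ape::vcv(tree)
}

#' Tip-to-tip patristic distance matrix of a tree
#'
#' @param tree a `phylo` object.
#' @return symmetric matrix of path lengths between tips.
#' @export
patristic_matrix <- function(tree) {
  stats::cophenetic(tree)
}
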