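#' Simulate an ultrametric species tree
#'
#' Grows a rooted binary tree under a pure-birth (Yule) process and rescales
#' it so the root-to-tip depth is exactly 1.0 time unit. Downstream stages
#' (family-count simulation, the relatedness matrix) only require
#' ultrametricity, not a realistic diversification history.
#'
#' @param n_species number of tips (>= 2).
#' @param seed integer seed; the same seed always yields the same tree.
#' @param depth depth to rescale the tree to (default 1.0).
#' @return an [ape::phylo] ultrametric rooted binary tree with tip labels
#'   `sp01, sp02, ...`.
#' @examples
#' tr <- simulate_species_tree(10, seed = 1)
#' max(ape::node.depth.edgelength(tr))  # 1
#' @export
simulate_species_tree <- function(n_species, seed, depth = 1.0) {
  if (!is.numeric(n_species) || n_species < 2)
    stop("`n_species` must be at least 2", call. = FALSE)
  n_species <- as.integer(n_species)
  tr <- with_seed(seed, ape::rphylo(n_species, birth = 1, death = 0))
  tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
  d <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / d * depth
  tr
}

#' Phylogenetic relatedness matrix from an ultrametric tree
#'
#' Computes the species-by-species matrix `A` with `A[i, j]` equal to the
#' shared root-to-MRCA path length of species `i` and `j`, divided by the
#' tree depth, so the diagonal is exactly 1. This is the (Gram, hence
#' positive-semidefinite) matrix that scales the covariance of the
#' species-level random effect in [fit_hierarchical_model()].
#'
#' @param tree a rooted ultrametric [ape::phylo] tree.
#' @param tol maximum allowed spread of root-to-tip depths (default 1e-6).
#' @return a symmetric matrix with unit diagonal, dimnames = tip labels.
#' @export
tree_to_relatedness <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object", call. = FALSE)
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (diff(range(depths)) > tol)
    stop("tree is not ultrametric (tip-depth spread ",
         format(diff(range(depths))), " > ", tol, ")", call. = FALSE)
  A <- ape::vcv.phylo(tree) / max(depths)
  diag(A) <- 1
  A[]
}
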