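#' Read a time-calibrated phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()] with the validation the downstream
#' phylogenetic regression requires: exactly one tree, branch lengths on
#' every edge, and unique tip labels. Tip order is the file order.
#'
#' @param path Newick file containing a single tree.
#' @return An [ape::phylo] object.
#' @seealso [phylo_cov()] for the derived covariance matrix.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) {
    stop("'", path, "' contains more than one tree", call. = FALSE)
  }
  if (is.null(tree)) stop("could not parse Newick in '", path, "'",
                          call. = FALSE)
  validate_tree(tree)
}

#' @rdname read_newick
#' @param text Newick string (alternative to a file).
#' @export
read_newick_text <- function(text) {
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick string", call. = FALSE)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    stop("tree is missing branch lengths on one or more edges",
         call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate taxon label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  tree
}

#' Phylogenetic variance-covariance matrix of a tree
#'
#' Under a Brownian-motion model of trait evolution the covariance of two
#' taxa is the shared root-to-tip path length (the depth of their most
#' recent common ancestor), and the variance of a taxon is its root-to-tip
#' distance. For an ultrametric (time-calibrated) tree the diagonal is
#' constant.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @return Symmetric positive semi-definite matrix with taxa as row and
#'   column names, in the tree's tip order.
#' @export
phylo_cov <- function(tree) {
  validate_tree(tree)
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label, drop = FALSE]
}
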