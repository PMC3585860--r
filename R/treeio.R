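#' Read a rooted phylogenetic tree from newick text
#'
#' Parses a newick string (or a file containing one) into an [ape::read.tree()]
#' `"phylo"` object and validates the invariants every downstream analysis
#' relies on: unique tip labels and non-negative branch lengths. Quoted labels,
#' polytomies and internal (support) labels are accepted; internal labels are
#' retained but ignored by all computations.
#'
#' @param text Newick string. Exactly one of `text`/`file` must be given.
#' @param file Path to a newick file.
#' @return An object of class `"phylo"`.
#' @examples
#' tr <- read_newick("((A:1,B:1):0.5,C:1.5);")
#' tree_height(tr)
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) {
    if (!file.exists(file)) stop("tree file not found: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  if (!nzchar(gsub("\\s", "", text))) stop("empty newick input")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop(sprintf(
      "malformed newick: %d '(' vs %d ')' (first imbalance near character %d)",
      n_open, n_close, nchar(text)))
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error: unparseable string")
  validate_tree(tr)
  tr
}

#' Write a tree as newick text
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  validate_tree(tree)
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# Structural invariants shared by every stage.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  invisible(tree)
}

#' Tree height (maximum root-to-tip path length)
#' @param tree A `"phylo"` object with branch lengths.
#' @return Numeric scalar.
#' @export
tree_height <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}

#' Root on an outgroup and remove it
#'
#' Roots the tree on the branch leading to `outgroup`, then prunes the
#' outgroup tip; the degree-2 node left behind is collapsed with its two
#' incident branch lengths summed, so total path lengths through the pruned
#' node are preserved.
#'
#' @param tree A `"phylo"` object.
#' @param outgroup A tip label present in the tree.
#' @return The rooted, pruned `"phylo"` object.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  validate_tree(tree)
  if (length(outgroup) != 1L || !outgroup %in% tree$tip.label)
    stop("outgroup tip not found: ", paste(outgroup, collapse = ", "))
  if (ape::Ntip(tree) < 3L)
    stop("pruning the outgroup would leave fewer than 2 tips")
  tr <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  tr <- ape::drop.tip(tr, outgroup, collapse.singles = TRUE)
  validate_tree(tr)
  tr
}

#' Node times before present on an ultrametric tree
#'
#' Returns the time-before-present of every node (tips at 0, root largest),
#' after checking ultrametricity: all root-to-tip path lengths must agree
#' within `tol * height`.
#'
#' @param tree Ultrametric `"phylo"` object.
#' @param tol Relative ultrametricity tolerance (default `1e-5` of tree
#'   height; chronograms from posterior samplers carry rounding noise).
#' @return Named numeric vector over all nodes (tip labels, then internal node
#'   numbers as names), in `ape` node order.
#' @export
node_times <- function(tree, tol = 1e-5) {
  validate_tree(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  depth <- ape::node.depth.edgelength(tree)
  ntip <- ape::Ntip(tree)
  h <- max(depth[seq_len(ntip)])
  tipd <- depth[seq_len(ntip)]
  if (h > 0 && (max(tipd) - min(tipd)) > tol * h) {
    worst <- c(which.min(tipd), which.max(tipd))
    stop(sprintf(
      "tree is not ultrametric within tolerance: tips '%s' (depth %.8g) and '%s' (depth %.8g) differ by %.3g x height",
      tree$tip.label[worst[1]], tipd[worst[1]],
      tree$tip.label[worst[2]], tipd[worst[2]],
      (max(tipd) - min(tipd)) / h))
  }
  times <- h - depth
  times[seq_len(ntip)] <- 0  # absorb sub-tolerance jitter
  names(times) <- c(tree$tip.label, seq.int(ntip + 1L, ntip + tree$Nnode))
  times
}

#' Shared-path (phylogenetic covariance) matrix
#'
#' `C[i, j]` is the root-to-MRCA path length shared by tips `i` and `j`;
#' diagonals are root-to-tip path lengths. This is the Brownian-motion
#' covariance structure implied by the tree, as used by the phylogenetic
#' t-test.
#'
#' @param tree A rooted `"phylo"` object with branch lengths.
#' @param order Optional character vector (subset/permutation of the tip
#'   labels) giving the row/column order.
#' @return A symmetric positive-semidefinite matrix with dimnames.
#' @export
shared_path_matrix <- function(tree, order = NULL) {
  validate_tree(tree)
  C <- ape::vcv.phylo(tree)
  if (!is.null(order)) {
    missing <- setdiff(order, rownames(C))
    if (length(missing))
      stop("unknown tip labels: ", paste(missing, collapse = ", "))
    C <- C[order, order, drop = FALSE]
  }
  C
}
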