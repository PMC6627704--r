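#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}), which is exact on additive
#' distance matrices. Negative branch-length estimates -- a known artifact of
#' NJ on noisy, non-additive distances -- are clamped to zero with the
#' deficit transferred to the adjacent edge through the same node, so path
#' lengths through the affected node are preserved; the raw edge lengths are
#' kept in the `raw_edge_length` attribute.
#'
#' @param d Symmetric distance matrix with row/column names (the leaf
#'   labels), at least 3 leaves.
#' @return An \pkg{ape} `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 leaves")
  if (!isSymmetric(unname(d), tol = 1e-12)) stop("distance matrix must be symmetric")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  tree <- ape::nj(d)
  raw <- tree$edge.length
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1L]
    sib <- which(tree$edge[, 1L] == parent & seq_along(tree$edge.length) != e)
    if (length(sib)) tree$edge.length[sib[1L]] <- tree$edge.length[sib[1L]] + deficit
  }
  attr(tree, "raw_edge_length") <- raw
  tree
}

#' Write a tree in Newick format
#'
#' Standard Newick with branch lengths; reading the file back yields the same
#' topology and lengths.
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(!nzchar(tree$tip.label)))
    stop("every leaf must carry a non-empty label")
  ape::write.tree(tree, file = path)
  invisible(NULL)
}
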