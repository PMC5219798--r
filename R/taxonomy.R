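#' Label every internal node with a synthetic taxonym
#'
#' Assigns each internal node (root included) a taxonym derived from its id
#' (\code{prefix + id}), giving a fully taxonomically informed tree whose
#' clades can host pinned tips. Intended for simulation studies and tests
#' where no real taxonomy is available; lineages for pinning candidates can
#' then be generated with \code{\link{getNdLng}}.
#'
#' @param tree a \code{NodeTree}
#' @param prefix taxonym prefix (default \code{"cl_"})
#' @return the tree with taxonyms set on all internal nodes.
#' @examples
#' tr <- taxonomiseTree(balancedTree(4))
#' getNdLng(tr, "t1")
#' @export
taxonomiseTree <- function(tree, prefix = "cl_") {
  internals <- setdiff(nodeIds(tree), tipIds(tree))
  setTxnyms(tree, structure(paste0(prefix, internals), names = internals))
}
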