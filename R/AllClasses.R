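#' NodeTree: a phylogenetic tree stored as a dictionary of node records
#'
#' A \code{NodeTree} holds a rooted phylogenetic tree as a named list of node
#' records (the node list) rather than as an edge matrix. Every record stores
#' its identity, the length of the edge immediately above it (its span), the
#' full ancestor path to the root, its immediate children, the set of tips
#' that descend from it, and - when the tree carries branch lengths -
#' precomputed branch-length summaries. Because each record carries its own
#' context, adding or removing a tip only rewrites the records on the
#' insertion path and in the subtree below the split edge; the rest of the
#' tree is untouched.
#'
#' @slot ndlst named list of node records. Each record is a list with
#'   elements \code{id}, \code{spn} (\code{NA} when absent), \code{prid}
#'   (ancestor ids, nearest parent first), \code{ptid} (immediate child ids,
#'   in stored order), \code{kids} (descendant tip ids), \code{txnym}
#'   (optional taxonomic name), \code{user} (free-form list), \code{pd}
#'   (total span of all descendant nodes) and \code{prdst} (root-to-node
#'   distance, own span included).
#' @slot root id of the root node (the unique node with an empty \code{prid}).
#' @slot ntips,nnds number of tips / number of nodes (tips, internals, root).
#' @slot wspn \code{TRUE} iff every non-root node has a span.
#' @slot pd total branch length: the sum of all non-root spans
#'   (\code{NA} when \code{wspn} is \code{FALSE}).
#' @slot age tree age: the maximum root-to-tip distance (\code{NA} when
#'   \code{wspn} is \code{FALSE}).
#' @slot tol extant tolerance: tips whose age is at most \code{tol} count as
#'   extant.
#'
#' Node ages are not stored in the records: the age of a node is always
#' \code{treeAge(tree) - prdst} and is computed on demand (see
#' \code{\link{getNdAge}}), so that operations that change the tree age do
#' not have to rewrite every record.
#'
#' @seealso \code{\link{buildTree}}, \code{\link{readNewick}},
#'   \code{\link{validateTree}}, \code{\link{refreshDerived}}
#' @export
setClass("NodeTree",
  representation(
    ndlst = "list",
    root = "character",
    ntips = "integer",
    nnds = "integer",
    wspn = "logical",
    pd = "numeric",
    age = "numeric",
    tol = "numeric"
  ),
  prototype(
    ndlst = list(), root = NA_character_, ntips = 0L, nnds = 0L,
    wspn = FALSE, pd = NA_real_, age = NA_real_, tol = 0
  )
)

setValidity("NodeTree", function(object) {
  # cheap structural checks only; validateTree() performs the full audit
  if (length(object@ndlst) == 0L) return("empty node list")
  if (is.null(names(object@ndlst)) || anyDuplicated(names(object@ndlst))) {
    return("node list must be uniquely named")
  }
  if (!object@root %in% names(object@ndlst)) {
    return("root id not present in node list")
  }
  if (object@ntips < 2L) return("a tree must have at least 2 tips")
  TRUE
})

#' @describeIn NodeTree one-line-per-field tree summary (see
#'   \code{\link{summariseTree}} for the text itself)
#' @param object a \code{NodeTree}
#' @export
setMethod("show", "NodeTree", function(object) {
  cat(summariseTree(object))
  invisible(NULL)
})

#' @describeIn NodeTree tree-level lookup by slot name, e.g.
#'   \code{tree["tips"]}; equivalent to \code{\link{treeSlot}}
#' @param x a \code{NodeTree}
#' @param i a slot name (see \code{\link{treeSlot}}) or, for \code{[[}, a
#'   node id
#' @export
setMethod("[", signature(x = "NodeTree", i = "character"), function(x, i) {
  treeSlot(x, i)
})

#' @describeIn NodeTree node-level lookup by id, e.g. \code{tree[["t1"]]};
#'   equivalent to \code{\link{nodeInfo}}
#' @export
setMethod("[[", signature(x = "NodeTree", i = "character"), function(x, i) {
  nodeInfo(x, i)
})
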