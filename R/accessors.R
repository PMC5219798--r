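#' Tree-level accessors
#'
#' Read-only access to the tree-level summary slots, which incremental
#' operations keep consistent with the node records at all times.
#'
#' @param tree a \code{NodeTree}
#' @return \code{rootId}: the root node id; \code{nTips}/\code{nNodes}:
#'   counts; \code{treePD}: total branch length (sum of non-root spans);
#'   \code{treeAge}: maximum root-to-tip distance; \code{hasSpans}: whether
#'   every non-root node carries a span; \code{tipIds}/\code{nodeIds}: id
#'   vectors; \code{extantTol}: the extant-tip age tolerance;
#'   \code{extantTips}: ids of tips with age at most \code{extantTol}.
#' @name tree-accessors
NULL

#' @rdname tree-accessors
#' @export
rootId <- function(tree) tree@root

#' @rdname tree-accessors
#' @export
nTips <- function(tree) tree@ntips

#' @rdname tree-accessors
#' @export
nNodes <- function(tree) tree@nnds

#' @rdname tree-accessors
#' @export
treePD <- function(tree) tree@pd

#' @rdname tree-accessors
#' @export
treeAge <- function(tree) tree@age

#' @rdname tree-accessors
#' @export
hasSpans <- function(tree) tree@wspn

#' @rdname tree-accessors
#' @export
extantTol <- function(tree) tree@tol

#' @rdname tree-accessors
#' @export
tipIds <- function(tree) {
  ids <- names(tree@ndlst)
  ids[vapply(tree@ndlst, .isTip, logical(1))]
}

#' @rdname tree-accessors
#' @export
nodeIds <- function(tree) names(tree@ndlst)

#' @rdname tree-accessors
#' @export
extantTips <- function(tree) {
  .checkSpans(tree, "extantTips")
  tips <- tipIds(tree)
  ages <- tree@age - vapply(tree@ndlst[tips], `[[`, numeric(1), "prdst")
  tips[ages <= tree@tol + .TOL]
}

#' Look up a tree-level summary by name
#'
#' The character-indexing counterpart of the accessors: \code{tree["tips"]}
#' returns the tip ids, \code{tree["pd"]} the total branch length, and so on.
#'
#' @param tree a \code{NodeTree}
#' @param name one of \code{"tips"}, \code{"nodes"} (internal node ids,
#'   root included), \code{"all"} (every id), \code{"ntips"},
#'   \code{"nnodes"}, \code{"pd"}, \code{"age"}, \code{"root"}.
#' @return the requested summary datum.
#' @examples
#' tr <- readNewick("((A:1,B:1)n1:1,C:2)root;")
#' tr["tips"]
#' tr["pd"]
#' @export
treeSlot <- function(tree, name) {
  stopifnot(is.character(name), length(name) == 1L)
  valid <- c("tips", "nodes", "all", "ntips", "nnodes", "pd", "age", "root")
  switch(name,
    tips = tipIds(tree),
    nodes = setdiff(nodeIds(tree), tipIds(tree)),
    all = nodeIds(tree),
    ntips = tree@ntips,
    nnodes = tree@nnds,
    pd = tree@pd,
    age = tree@age,
    root = tree@root,
    .stopf("unknown tree slot '%s'; valid names: %s", name,
           paste(valid, collapse = ", "))
  )
}

#' Read-only view of one node record
#'
#' Returns the record for one node, with its age (tree age minus
#' root-to-node distance) computed on the fly. Printing the returned object
#' gives a per-field node summary.
#'
#' @param tree a \code{NodeTree}
#' @param id a node id
#' @return a list of class \code{"ndNode"} with the record fields plus
#'   \code{age}.
#' @examples
#' tr <- readNewick("((A:1,B:1)n1:1,C:2)root;")
#' tr[["n1"]]
#' @export
nodeInfo <- function(tree, id) {
  .checkId(tree, id)
  nd <- tree@ndlst[[id]]
  nd$age <- if (tree@wspn) tree@age - nd$prdst else NA_real_
  class(nd) <- "ndNode"
  nd
}

#' @export
print.ndNode <- function(x, ...) {
  cat(summariseNodeRecord(x), sep = "")
  invisible(x)
}

summariseNodeRecord <- function(nd) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "<none>"
  num <- function(v) if (is.null(v) || is.na(v)) "<no spans>" else
    format(v, digits = 7)
  paste0(
    "node:     ", nd$id, if (.isTip(nd)) "  (tip)" else
      if (!length(nd$prid)) "  (root)" else "  (internal)", "\n",
    "span:     ", num(nd$spn), "\n",
    "parent:   ", fmt(nd$prid[seq_len(min(1L, length(nd$prid)))]), "\n",
    "children: ", fmt(nd$ptid), "\n",
    "kids:     ", length(nd$kids), "\n",
    "pd:       ", num(nd$pd), "\n",
    "prdst:    ", num(nd$prdst), "\n",
    "age:      ", num(nd$age), "\n",
    if (!is.na(nd$txnym)) paste0("taxonym:  ", nd$txnym, "\n") else ""
  )
}

#' Text summaries of a tree and of a single node
#'
#' \code{summariseTree} renders the tree-level summary printed by
#' \code{show}; \code{summariseNode} renders the per-node record view.
#'
#' @param tree a \code{NodeTree}
#' @param id a node id (for \code{summariseNode})
#' @return a character scalar (multi-line text).
#' @export
summariseTree <- function(tree) {
  paste0(
    "NodeTree (node-list phylogeny)\n",
    "tips:   ", tree@ntips, "\n",
    "nodes:  ", tree@nnds, "\n",
    "root:   ", tree@root, "\n",
    "spans:  ", if (tree@wspn) "all nodes" else "absent/partial", "\n",
    if (tree@wspn) paste0(
      "pd:     ", format(tree@pd, digits = 7), "\n",
      "age:    ", format(tree@age, digits = 7), "\n"
    ) else "",
    "extant tolerance: ", format(tree@tol), "\n"
  )
}

#' @rdname summariseTree
#' @export
summariseNode <- function(tree, id) {
  summariseNodeRecord(nodeInfo(tree, id))
}
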