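#' Per-node retrieval: ancestors, descendants, kids, ages, lineages
#'
#' The \emph{get} family reads precomputed node-record fields or derives
#' simple quantities from them. \code{getNdPrid} returns the stored ancestor
#' path (nearest parent first, ending at the root; empty for the root).
#' \code{getNdPtid} returns the full recursive descendant closure in
#' preorder (the record's \code{ptid} field stores immediate children only;
#' the closure is the useful query). \code{getNdKids} returns the stored
#' descendant-tip set. \code{getNdAge} returns tree age minus the node's
#' root-to-node distance, so extant tips of an ultrametric tree have age 0.
#'
#' @param tree a \code{NodeTree}
#' @param id a node id
#' @return \code{getNdPrid}, \code{getNdPtid}, \code{getNdKids}: character
#'   vectors of ids; \code{getNdAge}: a numeric scalar.
#' @examples
#' tr <- readNewick("((A:1,B:1)n1:1,C:2)root;")
#' getNdPrid(tr, "A")   # "n1" "root"
#' getNdKids(tr, "n1")  # "A" "B"
#' getNdAge(tr, "n1")   # 1
#' @name node-queries
NULL

#' @rdname node-queries
#' @export
getNdPrid <- function(tree, id) {
  .checkId(tree, id)
  tree@ndlst[[id]]$prid
}

#' @rdname node-queries
#' @export
getNdPtid <- function(tree, id) {
  .checkId(tree, id)
  .preorder(tree@ndlst, id)[-1L]
}

#' @rdname node-queries
#' @export
getNdKids <- function(tree, id) {
  .checkId(tree, id)
  tree@ndlst[[id]]$kids
}

#' @rdname node-queries
#' @export
getNdAge <- function(tree, id) {
  .checkId(tree, id)
  .checkSpans(tree, "getNdAge")
  tree@age - tree@ndlst[[id]]$prdst
}

#' Most recent common ancestor of a set of nodes
#'
#' A node counts as an ancestor of itself, so
#' \code{getPrnt(tree, c("A", "n1"))} is \code{"n1"} when \code{"A"}
#' descends from \code{"n1"}.
#'
#' @param tree a \code{NodeTree}
#' @param ids two or more node ids
#' @return the id of the deepest node whose descendant closure (self
#'   included) contains every queried id.
#' @export
getPrnt <- function(tree, ids) {
  if (length(ids) < 2L) .stopf("getPrnt needs at least 2 ids")
  .checkIds(tree, ids)
  common <- Reduce(intersect,
                   lapply(ids, function(i) c(i, tree@ndlst[[i]]$prid)))
  depth <- vapply(common, function(i) length(tree@ndlst[[i]]$prid), integer(1))
  common[[which.max(depth)]]
}

#' Path between two nodes via their most recent common ancestor
#'
#' @param tree a \code{NodeTree}
#' @param fromId,toId node ids
#' @return the ordered vector of node ids from \code{fromId} up to the MRCA
#'   and back down to \code{toId} (both endpoints included;
#'   \code{getPath(tree, x, x)} is \code{x}).
#' @export
getPath <- function(tree, fromId, toId) {
  .checkId(tree, fromId); .checkId(tree, toId)
  if (fromId == toId) return(fromId)
  m <- getPrnt(tree, c(fromId, toId))
  up <- c(fromId, tree@ndlst[[fromId]]$prid)
  up <- up[seq_len(match(m, up))]
  down <- c(toId, tree@ndlst[[toId]]$prid)
  down <- down[seq_len(match(m, down) - 1L)]
  c(up, rev(down))
}

#' Extract the clade below a node as a new tree
#'
#' @param tree a \code{NodeTree}
#' @param id an internal node id (the new root; its span, being the stem of
#'   the extracted clade, is dropped)
#' @return a valid \code{NodeTree} containing \code{id} and all its
#'   descendants.
#' @export
getSubtree <- function(tree, id) {
  .checkId(tree, id)
  if (.isTip(tree@ndlst[[id]])) .stopf("cannot take the subtree of tip '%s'", id)
  ids <- .preorder(tree@ndlst, id)
  specs <- data.frame(
    id = ids,
    parent = vapply(ids, function(i) {
      if (i == id) NA_character_ else tree@ndlst[[i]]$prid[[1L]]
    }, character(1)),
    spn = vapply(ids, function(i) {
      if (i == id) NA_real_ else tree@ndlst[[i]]$spn
    }, numeric(1)),
    txnym = vapply(ids, function(i) tree@ndlst[[i]]$txnym, character(1)),
    stringsAsFactors = FALSE
  )
  out <- buildTree(specs)
  out@tol <- tree@tol
  for (i in ids) out@ndlst[[i]]$user <- tree@ndlst[[i]]$user
  out
}

#' Taxonomic lineage of a node
#'
#' Collects the taxonyms found along the root-to-node path, root-most first.
#' Nodes without a taxonym are skipped (taxonyms are optional and
#' non-unique); it is an error only if no node on the path carries one.
#'
#' @param tree a \code{NodeTree}
#' @param id a node id
#' @return a character vector of taxonyms, root-most first.
#' @export
getNdLng <- function(tree, id) {
  .checkId(tree, id)
  path <- c(rev(tree@ndlst[[id]]$prid), id)
  tx <- vapply(path, function(i) tree@ndlst[[i]]$txnym, character(1))
  tx <- tx[!is.na(tx) & nzchar(tx)]
  if (!length(tx)) {
    .stopf("no node on the root path of '%s' carries a taxonym", id)
  }
  unname(tx)
}

#' Apply a per-node operation over many nodes
#'
#' The vectorisation contract of the node-list model: the result is
#' identical to applying \code{perNodeOp} independently to each id, the
#' order of evaluation is unobservable, and the output is a named list in
#' the order of \code{ids}.
#'
#' @param tree a \code{NodeTree}
#' @param ids node ids (all must exist; the first unknown id is reported)
#' @param perNodeOp a function \code{(tree, id, ...)}
#' @param ... passed through to \code{perNodeOp}
#' @return a named list, one element per id.
#' @examples
#' tr <- readNewick("((A:1,B:1)n1:1,C:2)root;")
#' unlist(mapOverNodes(tr, c("A", "B", "C"), getNdAge))
#' @export
mapOverNodes <- function(tree, ids, perNodeOp, ...) {
  .checkIds(tree, ids)
  out <- lapply(ids, function(i) perNodeOp(tree, i, ...))
  names(out) <- ids
  out
}
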