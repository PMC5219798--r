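#' Pairwise patristic distance matrix
#'
#' Path-length distances on the tree:
#' \code{d(a,b) = prdst(a) + prdst(b) - 2 prdst(mrca(a,b))}, the sum of
#' spans along the path joining the two nodes through their most recent
#' common ancestor.
#'
#' @param tree a \code{NodeTree} with spans
#' @param ids node ids (default: all tips)
#' @return a symmetric numeric matrix with zero diagonal, dimnames
#'   \code{ids}.
#' @examples
#' tr <- readNewick("((A:1,B:1)n1:1,C:2)root;")
#' calcDstMtrx(tr)["A", "C"] # 4
#' @export
calcDstMtrx <- function(tree, ids = tipIds(tree)) {
  .checkSpans(tree, "calcDstMtrx")
  .checkIds(tree, ids)
  k <- length(ids)
  prdst <- vapply(tree@ndlst[ids], `[[`, numeric(1), "prdst")
  out <- matrix(0, k, k, dimnames = list(ids, ids))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        m <- getPrnt(tree, c(ids[[i]], ids[[j]]))
        d <- prdst[[i]] + prdst[[j]] - 2 * tree@ndlst[[m]]$prdst
        out[i, j] <- out[j, i] <- d
      }
    }
  }
  out
}

#' Faith phylogenetic diversity of a tip set
#'
#' The sum of spans over the minimal subtree connecting the tips, excluding
#' the stem edge above the set's most recent common ancestor; with all tips
#' of the tree, this equals the tree's total branch length.
#'
#' @param tree a \code{NodeTree} with spans
#' @param tips at least two tip ids
#' @return a non-negative numeric scalar (branch-length units).
#' @export
calcPhyDv <- function(tree, tips) {
  .checkSpans(tree, "calcPhyDv")
  .checkTips(tree, tips)
  if (length(tips) < 2L) .stopf("calcPhyDv needs at least 2 tips")
  m <- getPrnt(tree, tips)
  nodes <- unique(unlist(lapply(tips, function(t) {
    p <- c(t, tree@ndlst[[t]]$prid)
    p[seq_len(match(m, p) - 1L)]
  })))
  sum(vapply(tree@ndlst[nodes], `[[`, numeric(1), "spn"))
}

#' Fair Proportion evolutionary distinctness
#'
#' Every edge's span is divided equally among the tips that descend from it;
#' a tip's Fair Proportion score is the sum of its shares along its path to
#' the root (its own edge included, the root excluded since the root has no
#' preceding edge). Composed from the node records exactly as the node-list
#' model intends: the ancestor path gives the edges, the stored
#' descendant-tip sets give each edge's divisor. Scores over all tips sum
#' to the tree's total branch length.
#'
#' @param tree a \code{NodeTree} with spans
#' @param tips tip ids (default: all tips)
#' @return a named numeric vector of scores, one per tip.
#' @examples
#' tr <- readNewick("((A:1,B:1)n1:1,C:2)root;")
#' calcFrPrp(tr)  # A 1.5, B 1.5, C 2
#' @export
calcFrPrp <- function(tree, tips = tipIds(tree)) {
  .checkSpans(tree, "calcFrPrp")
  .checkTips(tree, tips)
  share <- .edgeShares(tree)
  vapply(tips, function(t) {
    path <- c(t, tree@ndlst[[t]]$prid)
    sum(share[path[path != tree@root]])
  }, numeric(1))
}

# span / number-of-descendant-tips for every non-root node (tips divide by 1)
.edgeShares <- function(tree) {
  ids <- names(tree@ndlst)
  vapply(tree@ndlst, function(nd) {
    if (is.na(nd$spn)) return(0)
    nd$spn / max(1L, length(nd$kids))
  }, numeric(1))
}

#' Shared fraction of represented branch length between two communities
#'
#' A community (a set of tips) "represents" every non-root node on a path
#' from one of its tips to the root. The overlap is the summed span of the
#' nodes represented by both communities divided by the summed span of the
#' nodes represented by the first: an asymmetric, UniFrac-style fraction of
#' the first community's branch length that the second also covers. Set
#' \code{norm = "union"} for the symmetric variant (shared over union).
#'
#' @param tree a \code{NodeTree} with spans
#' @param c1,c2 non-empty tip-id vectors
#' @param norm \code{"community"} (denominator: c1's represented span,
#'   default) or \code{"union"}
#' @return a numeric scalar in [0, 1].
#' @examples
#' tr <- readNewick("((A:1,B:1)n1:1,C:2)root;")
#' calcOvrlp(tr, c("A", "B"), c("B", "C")) # 2/3
#' @export
calcOvrlp <- function(tree, c1, c2, norm = c("community", "union")) {
  norm <- match.arg(norm)
  .checkSpans(tree, "calcOvrlp")
  if (!length(c1) || !length(c2)) .stopf("communities must be non-empty")
  .checkTips(tree, c1); .checkTips(tree, c2)
  r1 <- .reprNodes(tree, c1)
  r2 <- .reprNodes(tree, c2)
  spn <- function(ids) sum(vapply(tree@ndlst[ids], `[[`, numeric(1), "spn"))
  denom <- if (norm == "community") spn(r1) else spn(union(r1, r2))
  spn(intersect(r1, r2)) / denom
}

# all non-root nodes on any tip-to-root path of the community
.reprNodes <- function(tree, tips) {
  setdiff(unique(unlist(lapply(tips, function(t) {
    c(t, tree@ndlst[[t]]$prid)
  }))), tree@root)
}

#' Robinson-Foulds distance between two trees on their shared tips
#'
#' Both trees are restricted to the tips they share, every internal node's
#' descendant-tip set is reduced to a bipartition of the shared tips, and
#' the distance is the number of non-trivial bipartitions present in
#' exactly one of the two trees.
#'
#' @param tree1,tree2 \code{NodeTree}s sharing at least 3 tip ids
#' @return a non-negative integer (0 for topologically identical trees).
#' @export
calcTrDst <- function(tree1, tree2) {
  shared <- intersect(tipIds(tree1), tipIds(tree2))
  if (length(shared) < 3L) {
    .stopf("trees share only %d tips; at least 3 required", length(shared))
  }
  s1 <- .bipartitions(tree1, shared)
  s2 <- .bipartitions(tree2, shared)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# canonical keys of non-trivial bipartitions of `shared` induced by the
# internal nodes; the side not containing the reference tip is the key
.bipartitions <- function(tree, shared) {
  ref <- sort(shared)[[1L]]
  keys <- character(0)
  for (id in setdiff(nodeIds(tree), tipIds(tree))) {
    clade <- intersect(tree@ndlst[[id]]$kids, shared)
    if (ref %in% clade) clade <- setdiff(shared, clade)
    if (length(clade) >= 2L && length(clade) <= length(shared) - 2L) {
      keys <- c(keys, paste(sort(clade), collapse = "\r"))
    }
  }
  unique(keys)
}

.checkTips <- function(tree, tips) {
  .checkIds(tree, tips, "tip")
  notTip <- tips[!vapply(tree@ndlst[tips], .isTip, logical(1))]
  if (length(notTip)) .stopf("'%s' is not a tip", notTip[[1L]])
  invisible(tips)
}
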