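#' Add a tip on an edge within an age range
#'
#' Inserts a new internal node on the edge above \code{edgeNodeId} at an
#' attachment age drawn uniformly from the overlap of the requested age
#' range \code{[endAge, strtAge]} with the edge's own age interval, and
#' hangs the new tip from it with span \code{attachmentAge - tipAge}. Ages
#' decrease toward the tips (so \code{strtAge > endAge}); a zero-width
#' overlap gives a deterministic attachment.
#'
#' Only the local records are rewritten: the two new nodes, the split edge's
#' node and its descendants (whose ancestor paths gain the new node), and
#' the ancestors of the insertion point (whose descendant-tip sets and
#' per-node diversity gain the new tip). The instrumentation counter
#' (\code{\link{touchCount}}) counts these writes.
#'
#' @param tree a \code{NodeTree} with spans
#' @param newId id for the new tip (must be unused)
#' @param edgeNodeId the node below the edge to split (not the root)
#' @param strtAge,endAge requested attachment age range (older, younger)
#' @param tipAge age of the new tip (default 0 = extant)
#' @param newNdId id for the new internal node (default: auto, prefix
#'   \code{"p"})
#' @param rngSeed optional seed for the uniform attachment draw
#' @return the augmented tree; all invariants hold
#'   (\code{\link{refreshDerived}} is the correctness oracle).
#' @examples
#' tr <- readNewick("((A:1,B:1)n1:1,C:2)root;")
#' tr2 <- addTip(tr, "D", "C", strtAge = 2, endAge = 0, rngSeed = 1)
#' nTips(tr2) # 4
#' @export
addTip <- function(tree, newId, edgeNodeId, strtAge, endAge, tipAge = 0,
                   newNdId = NULL, rngSeed = NULL) {
  .checkSpans(tree, "addTip")
  .checkId(tree, edgeNodeId, "edge node")
  if (edgeNodeId == tree@root) .stopf("cannot add a tip on the root's edge")
  if (newId %in% names(tree@ndlst)) .stopf("id '%s' already in tree", newId)
  if (!nzchar(newId) || grepl("[[:space:]]", newId)) {
    .stopf("new tip id must be non-empty without whitespace")
  }
  if (tipAge < 0) .stopf("tipAge must be non-negative")
  if (strtAge < endAge) .stopf("strtAge must be >= endAge (ages decrease toward tips)")
  if (!is.null(rngSeed)) set.seed(rngSeed)

  ndlst <- tree@ndlst
  e <- ndlst[[edgeNodeId]]
  pId <- e$prid[[1L]]
  ageE <- tree@age - e$prdst
  ageP <- tree@age - ndlst[[pId]]$prdst
  lo <- max(endAge, ageE, tipAge)
  hi <- min(strtAge, ageP)
  if (hi < lo - .TOL) {
    .stopf(paste0("age range [%g, %g] does not overlap edge '%s' ",
                  "(ages [%g, %g]) above tip age %g"),
           endAge, strtAge, edgeNodeId, ageE, ageP, tipAge)
  }
  attachAge <- if (hi - lo <= .TOL) lo else stats::runif(1L, lo, hi)

  qId <- if (is.null(newNdId)) .freshId(c(names(ndlst), newId), "p") else newNdId
  if (qId %in% names(ndlst) || qId == newId) {
    .stopf("id '%s' already in tree", qId)
  }

  qPrdst <- ndlst[[pId]]$prdst + max(0, ageP - attachAge)
  tipSpn <- max(0, attachAge - tipAge)
  eKids <- if (.isTip(e)) edgeNodeId else e$kids

  q <- .newNd(qId, spn = qPrdst - ndlst[[pId]]$prdst,
              prid = c(pId, ndlst[[pId]]$prid),
              ptid = c(edgeNodeId, newId),
              kids = c(eKids, newId),
              pd = e$pd + (e$prdst - qPrdst) + tipSpn,
              prdst = qPrdst)
  newTip <- .newNd(newId, spn = tipSpn,
                   prid = c(qId, q$prid),
                   pd = 0, prdst = qPrdst + tipSpn)

  # split edge: its node and every descendant gains q in its ancestor path
  e$spn <- e$prdst - qPrdst
  e$prid <- c(qId, e$prid)
  ndlst[[edgeNodeId]] <- e
  desc <- .preorder(ndlst, edgeNodeId)[-1L]
  for (d in desc) {
    nd <- ndlst[[d]]
    at <- match(pId, nd$prid)
    nd$prid <- append(nd$prid, qId, after = at - 1L)
    ndlst[[d]] <- nd
  }
  # insertion path: parent and its ancestors gain the new tip
  anc <- c(pId, ndlst[[pId]]$prid)
  for (a in anc) {
    nd <- ndlst[[a]]
    if (a == pId) nd$ptid[nd$ptid == edgeNodeId] <- qId
    nd$kids <- c(nd$kids, newId)
    nd$pd <- nd$pd + tipSpn
    ndlst[[a]] <- nd
  }
  ndlst[[qId]] <- q
  ndlst[[newId]] <- newTip
  .markTouched(2L + 1L + length(desc) + length(anc))

  tree@ndlst <- ndlst
  tree@ntips <- tree@ntips + 1L
  tree@nnds <- tree@nnds + 2L
  tree@pd <- tree@pd + tipSpn
  tree@age <- max(tree@age, newTip$prdst)
  tree
}

#' Remove a tip
#'
#' Deletes a tip; a parent left with a single child is spliced out, the two
#' spans summing so that all remaining pairwise distances are preserved. If
#' the root itself is left with a single child, the root absorbs that child
#' (the child's span, lying on no tip-to-tip path, is dropped).
#'
#' @param tree a \code{NodeTree}
#' @param id a tip id; the tree must keep at least 2 tips
#' @return the reduced tree.
#' @export
rmTip <- function(tree, id) {
  .checkId(tree, id, "tip")
  if (!.isTip(tree@ndlst[[id]])) .stopf("'%s' is not a tip", id)
  if (tree@ntips < 3L) .stopf("removing '%s' would leave fewer than 2 tips", id)

  ndlst <- tree@ndlst
  wspn <- tree@wspn
  pId <- ndlst[[id]]$prid[[1L]]
  spnT <- ndlst[[id]]$spn
  ndlst[[id]] <- NULL
  removed <- 1L

  anc <- c(pId, ndlst[[pId]]$prid)
  for (a in anc) {
    nd <- ndlst[[a]]
    nd$kids <- setdiff(nd$kids, id)
    if (a == pId) nd$ptid <- setdiff(nd$ptid, id)
    if (wspn) nd$pd <- nd$pd - spnT
    ndlst[[a]] <- nd
  }
  touched <- length(anc)
  spliceSpn <- 0

  if (length(ndlst[[pId]]$ptid) == 1L) {
    cId <- ndlst[[pId]]$ptid[[1L]]
    if (pId != tree@root) {
      # splice parent: child's span absorbs the parent's
      gp <- ndlst[[pId]]$prid[[1L]]
      nd <- ndlst[[cId]]
      nd$spn <- if (is.na(nd$spn) || is.na(ndlst[[pId]]$spn)) NA_real_ else
        nd$spn + ndlst[[pId]]$spn
      nd$prid <- nd$prid[nd$prid != pId]
      ndlst[[cId]] <- nd
      for (d in .preorder(ndlst, cId)[-1L]) {
        dd <- ndlst[[d]]
        dd$prid <- dd$prid[dd$prid != pId]
        ndlst[[d]] <- dd
      }
      gnd <- ndlst[[gp]]
      gnd$ptid[gnd$ptid == pId] <- cId
      ndlst[[gp]] <- gnd
      touched <- touched + 2L + length(.preorder(ndlst, cId)) - 1L
      ndlst[[pId]] <- NULL
      removed <- removed + 1L
    } else {
      # root absorbs its single remaining child; the child's span lies on
      # no tip-to-tip path and is dropped
      spliceSpn <- if (wspn) ndlst[[cId]]$spn else 0
      rt <- ndlst[[pId]]
      rt$ptid <- ndlst[[cId]]$ptid
      if (wspn) rt$pd <- rt$pd - spliceSpn
      ndlst[[pId]] <- rt
      for (d in .preorder(ndlst, cId)[-1L]) {
        dd <- ndlst[[d]]
        dd$prid <- dd$prid[dd$prid != cId]
        if (wspn) dd$prdst <- dd$prdst - spliceSpn
        ndlst[[d]] <- dd
      }
      touched <- touched + length(.preorder(ndlst, cId))
      ndlst[[cId]] <- NULL
      removed <- removed + 1L
    }
  }
  .markTouched(touched)

  tree@ndlst <- ndlst
  tree@ntips <- tree@ntips - 1L
  tree@nnds <- tree@nnds - removed
  if (wspn) {
    tree@pd <- tree@pd - spnT - spliceSpn
    tips <- tipIds(tree)
    tree@age <- max(vapply(tree@ndlst[tips], `[[`, numeric(1), "prdst"))
  }
  tree
}

#' Set one node's span
#'
#' Replaces the branch length above \code{id}. Root-to-node distances in the
#' node's subtree and per-node diversity along its root path are updated
#' incrementally.
#'
#' @param tree a \code{NodeTree}
#' @param id a non-root node id
#' @param spn new span (non-negative)
#' @return the updated tree.
#' @export
setNdSpn <- function(tree, id, spn) {
  .checkId(tree, id)
  if (id == tree@root) .stopf("the root has no preceding edge")
  if (is.na(spn) || spn < 0) .stopf("span must be non-negative")
  old <- tree@ndlst[[id]]$spn
  if (!tree@wspn || is.na(old)) {
    tree@ndlst[[id]]$spn <- spn
    return(refreshDerived(tree))
  }
  delta <- spn - old
  ndlst <- tree@ndlst
  ndlst[[id]]$spn <- spn
  sub <- .preorder(ndlst, id)
  for (d in sub) ndlst[[d]]$prdst <- ndlst[[d]]$prdst + delta
  anc <- ndlst[[id]]$prid
  for (a in anc) ndlst[[a]]$pd <- ndlst[[a]]$pd + delta
  .markTouched(length(sub) + length(anc))
  tree@ndlst <- ndlst
  tree@pd <- tree@pd + delta
  tips <- tipIds(tree)
  tree@age <- max(vapply(tree@ndlst[tips], `[[`, numeric(1), "prdst"))
  tree
}

#' Rescale a tree to a target age or total branch length
#'
#' Linear rescalings: every span is multiplied by
#' \code{targetAge / treeAge(tree)} (resp. \code{targetPD / treePD(tree)}),
#' so all patristic distances and Fair Proportion scores scale by the same
#' factor.
#'
#' @param tree a \code{NodeTree} with spans
#' @param targetAge,targetPD positive target value
#' @return the rescaled tree.
#' @name rescale
NULL

#' @rdname rescale
#' @export
setAge <- function(tree, targetAge) {
  .checkSpans(tree, "setAge")
  if (targetAge <= 0) .stopf("targetAge must be positive")
  .scaleSpans(tree, targetAge / tree@age)
}

#' @rdname rescale
#' @export
setPD <- function(tree, targetPD) {
  .checkSpans(tree, "setPD")
  if (targetPD <= 0) .stopf("targetPD must be positive")
  .scaleSpans(tree, targetPD / tree@pd)
}

.scaleSpans <- function(tree, f) {
  ndlst <- tree@ndlst
  for (id in names(ndlst)) {
    nd <- ndlst[[id]]
    if (!is.na(nd$spn)) nd$spn <- nd$spn * f
    nd$pd <- nd$pd * f
    nd$prdst <- nd$prdst * f
    ndlst[[id]] <- nd
  }
  tree@ndlst <- ndlst
  tree@pd <- tree@pd * f
  tree@age <- tree@age * f
  tree
}

#' Reroot the tree at an internal node
#'
#' Reverses the edges between the old and the new root; the new root loses
#' its span (a root has no preceding edge) and the old root, if left with a
#' single child, is spliced out with the two spans summed. Pairwise tip
#' distances are preserved: rerooting does not change the unrooted metric.
#'
#' @param tree a \code{NodeTree}
#' @param newRootId an internal node id
#' @return the rerooted tree.
#' @export
setRoot <- function(tree, newRootId) {
  .checkId(tree, newRootId)
  if (.isTip(tree@ndlst[[newRootId]])) .stopf("cannot root at tip '%s'", newRootId)
  if (newRootId == tree@root) return(tree)

  ndlst <- tree@ndlst
  path <- c(rev(ndlst[[newRootId]]$prid), newRootId)  # old root ... new root
  oldSpn <- lapply(ndlst[path], `[[`, "spn")
  for (i in length(path):2L) {
    child <- path[[i]]; parent <- path[[i - 1L]]
    ndlst[[child]]$ptid <- c(ndlst[[child]]$ptid, parent)
    ndlst[[parent]]$ptid <- setdiff(ndlst[[parent]]$ptid, child)
    ndlst[[parent]]$spn <- oldSpn[[i]]
  }
  ndlst[[newRootId]]$spn <- NA_real_

  oldRoot <- path[[1L]]
  if (length(ndlst[[oldRoot]]$ptid) == 1L) {
    cId <- ndlst[[oldRoot]]$ptid[[1L]]
    newParent <- path[[2L]]
    ndlst[[newParent]]$ptid[ndlst[[newParent]]$ptid == oldRoot] <- cId
    ndlst[[cId]]$spn <- if (is.na(ndlst[[cId]]$spn) ||
                            is.na(ndlst[[oldRoot]]$spn)) NA_real_ else
      ndlst[[cId]]$spn + ndlst[[oldRoot]]$spn
    ndlst[[oldRoot]] <- NULL
  }

  tree@ndlst <- ndlst
  tree@root <- newRootId
  tree@nnds <- length(ndlst)
  refreshDerived(tree)
}

#' Set the extant-tip age tolerance
#'
#' Tips whose age is at most \code{tol} count as extant (see
#' \code{\link{extantTips}}).
#'
#' @param tree a \code{NodeTree}
#' @param tol non-negative tolerance in branch-length units
#' @return the updated tree.
#' @export
setTol <- function(tree, tol) {
  if (is.na(tol) || tol < 0) .stopf("tol must be non-negative")
  tree@tol <- tol
  tree
}

#' Assign taxonyms to nodes
#'
#' @param tree a \code{NodeTree}
#' @param txnyms a named character vector: names are node ids, values the
#'   taxonyms (non-unique allowed)
#' @return the updated tree.
#' @export
setTxnyms <- function(tree, txnyms) {
  stopifnot(is.character(txnyms), !is.null(names(txnyms)))
  .checkIds(tree, names(txnyms))
  for (id in names(txnyms)) tree@ndlst[[id]]$txnym <- txnyms[[id]]
  tree
}

#' Pin new tips onto a tree under taxonomic constraints
#'
#' For each candidate, its lineage (root-most name first) is walked from the
#' most specific name toward the root; the first name carried by any node's
#' taxonym selects the host clade (among several nodes carrying the name,
#' the one with the most descendant tips, ties broken by id order). The new
#' tip is then attached by \code{\link{addTip}} on an edge drawn uniformly
#' from the host clade's edges - the clade's own stem edge included - whose
#' age interval can accommodate the tip's age. Candidates whose lineage
#' matches no taxonym in the tree are skipped and reported. Candidates are
#' processed in input order, and each pinned tip takes the most specific
#' name of its lineage as its own taxonym, so earlier pins can host later
#' ones.
#'
#' @param tree a \code{NodeTree} with spans and taxonyms (at least on the
#'   root)
#' @param lineages a named list of character vectors: names are the new tip
#'   ids, each vector a root-first lineage
#' @param tipAges ages of the new tips (recycled; default 0 = extant)
#' @param rngSeed optional seed governing edge choice and attachment draws
#' @return the augmented tree, with a \code{data.frame} attached as
#'   attribute \code{"pinReport"} (columns \code{tipId}, \code{matchedName},
#'   \code{hostId}, \code{edgeId}, \code{skipped}).
#' @export
pinTips <- function(tree, lineages, tipAges = 0, rngSeed = NULL) {
  .checkSpans(tree, "pinTips")
  stopifnot(is.list(lineages))
  if (!length(lineages)) {
    attr(tree, "pinReport") <- data.frame(
      tipId = character(0), matchedName = character(0),
      hostId = character(0), edgeId = character(0), skipped = logical(0))
    return(tree)
  }
  if (is.null(names(lineages)) || any(!nzchar(names(lineages)))) {
    .stopf("lineages must be named by the new tip ids")
  }
  if (!is.null(rngSeed)) set.seed(rngSeed)
  tipAges <- rep_len(tipAges, length(lineages))

  rep_rows <- vector("list", length(lineages))
  for (k in seq_along(lineages)) {
    newId <- names(lineages)[[k]]
    lng <- lineages[[k]]
    tipAge <- tipAges[[k]]
    placed <- FALSE
    matchedName <- NA_character_; hostId <- NA_character_
    edgeId <- NA_character_
    if (newId %in% names(tree@ndlst)) {
      .stopf("candidate tip id '%s' already in tree", newId)
    }
    txnyms <- vapply(tree@ndlst, `[[`, character(1), "txnym")
    for (name in rev(lng)) {
      matches <- names(txnyms)[!is.na(txnyms) & txnyms == name]
      if (!length(matches)) next
      nk <- vapply(matches, function(i) {
        max(1L, length(tree@ndlst[[i]]$kids))
      }, integer(1))
      matches <- sort(matches[nk == max(nk)])
      host <- matches[[1L]]
      clade <- c(host, getNdPtid(tree, host))
      cands <- setdiff(clade, tree@root)
      if (length(cands)) {
        agesP <- vapply(cands, function(i) {
          tree@age - tree@ndlst[[tree@ndlst[[i]]$prid[[1L]]]]$prdst
        }, numeric(1))
        cands <- cands[agesP >= tipAge - .TOL]
      }
      if (!length(cands)) next
      edgeId <- cands[[sample.int(length(cands), 1L)]]
      strt <- tree@age - tree@ndlst[[tree@ndlst[[edgeId]]$prid[[1L]]]]$prdst
      end <- tree@age - tree@ndlst[[edgeId]]$prdst
      tree <- addTip(tree, newId, edgeId, strtAge = strt, endAge = end,
                     tipAge = tipAge)
      tree@ndlst[[newId]]$txnym <- lng[[length(lng)]]
      matchedName <- name; hostId <- host
      placed <- TRUE
      break
    }
    rep_rows[[k]] <- data.frame(tipId = newId, matchedName = matchedName,
                                hostId = hostId, edgeId = edgeId,
                                skipped = !placed)
  }
  attr(tree, "pinReport") <- do.call(rbind, rep_rows)
  tree
}
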