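#' Build a NodeTree from parent-pointer node specifications
#'
#' Constructs a \code{\linkS4class{NodeTree}} from a table of nodes given as
#' (id, parent, span, taxonym) rows. Exactly one row must have no parent (the
#' root). All derived record fields (ancestor paths, descendant-tip sets,
#' per-node phylogenetic diversity, root-to-node distances) and tree-level
#' summaries are computed by \code{\link{refreshDerived}}.
#'
#' @param nodeSpecs a \code{data.frame} with columns \code{id} (character,
#'   unique, no whitespace), \code{parent} (character; \code{NA} for the
#'   root), and optionally \code{spn} (non-negative numeric, \code{NA} for
#'   "no branch length") and \code{txnym} (character, \code{NA} allowed).
#' @return a valid \code{NodeTree}.
#' @examples
#' specs <- data.frame(
#'   id     = c("root", "n1", "A", "B", "C"),
#'   parent = c(NA, "root", "n1", "n1", "root"),
#'   spn    = c(NA, 1, 1, 1, 2)
#' )
#' tr <- buildTree(specs)
#' treeSlot(tr, "pd") # 5
#' @export
buildTree <- function(nodeSpecs) {
  stopifnot(is.data.frame(nodeSpecs), all(c("id", "parent") %in% names(nodeSpecs)))
  ids <- as.character(nodeSpecs$id)
  parents <- as.character(nodeSpecs$parent)
  spns <- if ("spn" %in% names(nodeSpecs)) as.numeric(nodeSpecs$spn) else
    rep(NA_real_, length(ids))
  txs <- if ("txnym" %in% names(nodeSpecs)) as.character(nodeSpecs$txnym) else
    rep(NA_character_, length(ids))

  if (anyNA(ids) || any(!nzchar(ids)) || any(grepl("[[:space:]]", ids))) {
    .stopf("node ids must be non-empty and contain no whitespace")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) .stopf("duplicate node id: '%s'", dup[[1L]])
  isRoot <- is.na(parents) | !nzchar(parents)
  if (sum(isRoot) != 1L) {
    .stopf("expected exactly one root (row without a parent), found %d",
           sum(isRoot))
  }
  bad <- setdiff(parents[!isRoot], ids)
  if (length(bad)) .stopf("unknown parent id: '%s'", bad[[1L]])
  if (any(spns < 0, na.rm = TRUE)) .stopf("spans must be non-negative")

  ndlst <- vector("list", length(ids))
  names(ndlst) <- ids
  for (i in seq_along(ids)) {
    ndlst[[i]] <- .newNd(ids[[i]], spn = spns[[i]], txnym = txs[[i]])
  }
  for (i in which(!isRoot)) {
    p <- parents[[i]]
    ndlst[[p]]$ptid <- c(ndlst[[p]]$ptid, ids[[i]])
  }
  tree <- new("NodeTree", ndlst = ndlst, root = ids[[which(isRoot)]],
              ntips = 2L, nnds = length(ids))
  refreshDerived(tree)
}

#' Recompute all derived fields from topology and spans
#'
#' The full-recompute oracle for the incremental updaters: every derived
#' record field (\code{prid}, \code{kids}, \code{pd}, \code{prdst}) and every
#' tree-level summary is recomputed from immediate-child pointers
#' (\code{ptid}) and spans alone. Incremental operations such as
#' \code{\link{addTip}} are contracted to produce exactly what
#' \code{refreshDerived} would.
#'
#' @param tree a \code{NodeTree} whose \code{ptid} pointers and spans are
#'   consistent (derived fields may be stale).
#' @return the tree with all derived fields freshly computed.
#' @export
refreshDerived <- function(tree) {
  ndlst <- tree@ndlst
  ids <- names(ndlst)
  root <- tree@root
  if (!root %in% ids) .stopf("root id '%s' not in node list", root)

  # parent map from child pointers; every non-root node must be referenced
  # as a child exactly once
  parent <- structure(rep(NA_character_, length(ids)), names = ids)
  for (id in ids) {
    for (ch in ndlst[[id]]$ptid) {
      if (!ch %in% ids) .stopf("node '%s' points to unknown child '%s'", id, ch)
      if (!is.na(parent[[ch]])) .stopf("node '%s' has more than one parent", ch)
      parent[[ch]] <- id
    }
  }
  if (!is.na(parent[[root]])) .stopf("root '%s' has a parent", root)
  orphan <- ids[is.na(parent) & ids != root]
  if (length(orphan)) .stopf("node '%s' is not reachable from the root", orphan[[1L]])

  ord <- .preorder(ndlst, root)
  if (length(ord) != length(ids)) {
    .stopf("topology contains a cycle or unreachable nodes")
  }

  spn <- vapply(ndlst, function(nd) nd$spn %||% NA_real_, numeric(1))
  tipFlag <- vapply(ndlst, .isTip, logical(1))
  ntips <- sum(tipFlag)
  if (ntips < 2L) .stopf("a tree must have at least 2 tips (found %d)", ntips)
  wspn <- !any(is.na(spn[ids != root]))

  prid <- vector("list", length(ids)); names(prid) <- ids
  prdst <- structure(rep(NA_real_, length(ids)), names = ids)
  for (id in ord) {
    if (id == root) {
      prid[[id]] <- character(0)
      if (wspn) prdst[[id]] <- if (is.na(spn[[id]])) 0 else spn[[id]]
    } else {
      p <- parent[[id]]
      prid[[id]] <- c(p, prid[[p]])
      if (wspn) prdst[[id]] <- prdst[[p]] + spn[[id]]
    }
  }

  kids <- vector("list", length(ids)); names(kids) <- ids
  pd <- structure(rep(NA_real_, length(ids)), names = ids)
  for (id in rev(ord)) {
    ch <- ndlst[[id]]$ptid
    if (!length(ch)) {
      kids[[id]] <- character(0)
      if (wspn) pd[[id]] <- 0
    } else {
      kk <- character(0)
      for (c1 in ch) kk <- c(kk, if (.isTip(ndlst[[c1]])) c1 else kids[[c1]])
      kids[[id]] <- kk
      if (wspn) pd[[id]] <- sum(spn[ch] + pd[ch])
    }
  }

  for (id in ids) {
    nd <- ndlst[[id]]
    nd$prid <- prid[[id]]
    nd$kids <- kids[[id]]
    nd$pd <- pd[[id]]
    nd$prdst <- prdst[[id]]
    ndlst[[id]] <- nd
  }

  tree@ndlst <- ndlst
  tree@ntips <- as.integer(ntips)
  tree@nnds <- length(ids)
  tree@wspn <- wspn
  tree@pd <- if (wspn) pd[[root]] else NA_real_
  tree@age <- if (wspn) max(prdst[tipFlag]) else NA_real_
  methods::validObject(tree)
  tree
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Audit every node-record and tree-level invariant
#'
#' Checks referential integrity (every id referenced by an ancestor path,
#' child pointer or descendant-tip set exists), the tip/root/internal slot
#' rules, the ancestor-path and descendant-tip recursions, and - when the
#' tree has spans - the numeric derived fields against a fresh recompute
#' (absolute tolerance 1e-9). Reporting only: never raises.
#'
#' @param tree a \code{NodeTree} (possibly corrupted).
#' @return a \code{data.frame} with columns \code{nodeId} and
#'   \code{invariant}; zero rows means the tree is valid.
#' @export
validateTree <- function(tree) {
  bad <- function(nodeId, invariant) {
    viol[[length(viol) + 1L]] <<- data.frame(nodeId = nodeId,
                                             invariant = invariant)
  }
  viol <- list()
  ndlst <- tree@ndlst
  ids <- names(ndlst)
  root <- tree@root

  if (is.null(ids) || anyDuplicated(ids)) {
    bad(NA_character_, "node list uniquely named")
    return(do.call(rbind, viol))
  }
  for (id in ids) {
    nd <- ndlst[[id]]
    if (!identical(nd$id, id)) bad(id, "record id matches list name")
    for (fld in c("prid", "ptid", "kids")) {
      miss <- setdiff(nd[[fld]], ids)
      if (length(miss)) bad(id, paste0(fld, " references unknown id"))
    }
  }
  if (!root %in% ids) {
    bad(NA_character_, "root present")
    return(do.call(rbind, viol))
  }

  nRootLike <- sum(vapply(ndlst, function(nd) length(nd$prid) == 0L, logical(1)))
  if (nRootLike != 1L) bad(NA_character_, "exactly one node has empty prid")
  if (length(ndlst[[root]]$prid)) bad(root, "root has empty prid")
  if (!length(ndlst[[root]]$ptid)) bad(root, "root has children")

  for (id in ids) {
    nd <- ndlst[[id]]
    if (id != root) {
      if (!length(nd$prid)) {
        bad(id, "non-root has non-empty prid")
        next
      }
      p <- nd$prid[[1L]]
      if (!p %in% ids || !id %in% ndlst[[p]]$ptid) {
        bad(id, "prid[1] is the parent (appears in its ptid)")
      } else if (!identical(nd$prid, c(p, ndlst[[p]]$prid))) {
        bad(id, "prid equals parent's prid with parent prepended")
      }
      if (!is.na(nd$spn) && nd$spn < 0) bad(id, "span non-negative")
    }
    if (.isTip(nd)) {
      if (length(nd$kids)) bad(id, "tip has empty kids")
    } else {
      kk <- character(0)
      ok <- TRUE
      for (ch in nd$ptid) {
        if (!ch %in% ids) { ok <- FALSE; break }
        kk <- c(kk, if (.isTip(ndlst[[ch]])) ch else ndlst[[ch]]$kids)
      }
      if (ok && !setequal(nd$kids, kk)) {
        bad(id, "kids equals union of children's kids")
      }
    }
  }

  # spanning-tree / derived-field audit via full recompute
  ref <- tryCatch(refreshDerived(tree), error = function(e) e)
  if (inherits(ref, "error")) {
    bad(NA_character_, paste0("topology is a rooted spanning tree (",
                              conditionMessage(ref), ")"))
    return(.bindViol(viol))
  }
  numEq <- function(a, b) {
    (is.na(a) && is.na(b)) || (!is.na(a) && !is.na(b) && abs(a - b) <= .TOL)
  }
  for (id in ids) {
    nd <- ndlst[[id]]
    rf <- ref@ndlst[[id]]
    if (!numEq(nd$pd %||% NA_real_, rf$pd)) bad(id, "pd equals recompute")
    if (!numEq(nd$prdst %||% NA_real_, rf$prdst)) bad(id, "prdst equals recompute")
  }
  if (tree@ntips != ref@ntips) bad(NA_character_, "ntips equals recompute")
  if (tree@nnds != ref@nnds) bad(NA_character_, "nnds equals recompute")
  if (!identical(tree@wspn, ref@wspn)) bad(NA_character_, "wspn equals recompute")
  if (!numEq(tree@pd, ref@pd)) bad(NA_character_, "tree pd equals recompute")
  if (!numEq(tree@age, ref@age)) bad(NA_character_, "tree age equals recompute")
  if (tree@ntips < 2L) bad(NA_character_, "at least 2 tips")

  .bindViol(viol)
}

.bindViol <- function(viol) {
  if (length(viol)) do.call(rbind, viol) else
    data.frame(nodeId = character(0), invariant = character(0))
}
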