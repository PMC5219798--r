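# internal helpers shared across the package

.TOL <- 1e-9

.ndtreeEnv <- new.env(parent = emptyenv())
.ndtreeEnv$touched <- 0L

# count node records written by the incremental updaters (addTip/rmTip/
# setNdSpn); reads and tree-level slot updates are free
.markTouched <- function(n = 1L) {
  .ndtreeEnv$touched <- .ndtreeEnv$touched + as.integer(n)
  invisible(NULL)
}

#' Instrumentation: node records written by incremental updates
#'
#' The incremental manipulation operations (\code{\link{addTip}},
#' \code{\link{rmTip}}, \code{\link{setNdSpn}}) maintain a counter of how
#' many node records they wrote. The counter substantiates the locality
#' contract of the node-list model: the work done by a tip insertion scales
#' with the depth of the insertion point plus the subtree hanging below the
#' split edge, not with the size of the tree.
#'
#' @return \code{touchCount} returns the number of node records written since
#'   the last reset; \code{resetTouchCount} zeroes the counter and invisibly
#'   returns the previous value.
#' @examples
#' tr <- balancedTree(8, 1)
#' resetTouchCount()
#' tr <- addTip(tr, "x", "t1", strtAge = 1, endAge = 0, rngSeed = 1)
#' touchCount()
#' @export
touchCount <- function() .ndtreeEnv$touched

#' @rdname touchCount
#' @export
resetTouchCount <- function() {
  old <- .ndtreeEnv$touched
  .ndtreeEnv$touched <- 0L
  invisible(old)
}

.checkId <- function(tree, id, what = "node") {
  if (length(id) != 1L || !is.character(id)) {
    stop("expected a single ", what, " id", call. = FALSE)
  }
  if (!id %in% names(tree@ndlst)) {
    stop("unknown ", what, " id: '", id, "'", call. = FALSE)
  }
  invisible(id)
}

.checkIds <- function(tree, ids, what = "node") {
  bad <- setdiff(ids, names(tree@ndlst))
  if (length(bad)) {
    stop("unknown ", what, " id: '", bad[[1L]], "'", call. = FALSE)
  }
  invisible(ids)
}

.isTip <- function(nd) length(nd$ptid) == 0L

.checkSpans <- function(tree, op) {
  if (!tree@wspn) {
    stop(op, " requires branch lengths on every non-root node", call. = FALSE)
  }
  invisible(TRUE)
}

# fresh id with the given prefix, guaranteed absent from `taken`
.freshId <- function(taken, prefix, start = 1L) {
  k <- start
  repeat {
    cand <- paste0(prefix, k)
    if (!cand %in% taken) return(cand)
    k <- k + 1L
  }
}

.newNd <- function(id, spn = NA_real_, prid = character(0),
                   ptid = character(0), kids = character(0),
                   txnym = NA_character_, user = list(),
                   pd = NA_real_, prdst = NA_real_) {
  list(id = id, spn = spn, prid = prid, ptid = ptid, kids = kids,
       txnym = txnym, user = user, pd = pd, prdst = prdst)
}

# preorder walk over node ids starting at `id` (inclusive), children in
# stored ptid order; iterative so deep trees cannot overflow the call stack
.preorder <- function(ndlst, id) {
  out <- character(length(ndlst))
  n <- 0L
  stack <- id
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    n <- n + 1L
    out[[n]] <- cur
    kids <- ndlst[[cur]]$ptid
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  out[seq_len(n)]
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
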