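#' Read a Newick string into a NodeTree
#'
#' Parses a single rooted Newick tree. Tip labels become tip ids. Internal
#' labels become internal ids when \code{internalLabelsAsIds} is \code{TRUE}
#' (the default); otherwise they are kept in the node's user slot under
#' \code{"label"}. Unlabelled internal nodes receive deterministic automatic
#' ids \code{n1, n2, ...} assigned in preorder, skipping any id already in
#' use. Branch lengths become spans; a length on the root is stored but, as
#' the root has no preceding edge, it never contributes to the tree's total
#' branch length or to Fair Proportion scores.
#'
#' @param text a Newick string terminated by \code{";"}.
#' @param internalLabelsAsIds treat internal labels as node ids (default
#'   \code{TRUE}); when \code{FALSE} they are stored as user data and auto
#'   ids are assigned.
#' @param autoIdPrefix prefix for automatic internal ids (default
#'   \code{"n"}).
#' @return a valid \code{NodeTree}.
#' @examples
#' tr <- readNewick("((A:1.0,B:1.0)n1:1.0,C:2.0)root;")
#' nTips(tr)     # 3
#' treeAge(tr)   # 2
#' @export
readNewick <- function(text, internalLabelsAsIds = TRUE, autoIdPrefix = "n") {
  stopifnot(is.character(text), length(text) == 1L)
  ch <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  perr <- function(pos, msg) {
    .stopf("Newick parse error at character %d: %s", pos, msg)
  }

  lab <- character(0); len <- numeric(0); par <- integer(0)
  internal <- logical(0)
  newNode <- function(parent, isInternal) {
    lab <<- c(lab, NA_character_); len <<- c(len, NA_real_)
    par <<- c(par, parent); internal <<- c(internal, isInternal)
    length(lab)
  }

  pos <- 1L
  stack <- integer(0)
  cur <- NA_integer_   # node a label/length may attach to
  done <- FALSE

  readLabel <- function() {
    if (ch[[pos]] == "'") {
      out <- character(0)
      i <- pos + 1L
      repeat {
        if (i > n) perr(pos, "unterminated quoted label")
        if (ch[[i]] == "'") {
          if (i < n && ch[[i + 1L]] == "'") { out <- c(out, "'"); i <- i + 2L }
          else { i <- i + 1L; break }
        } else { out <- c(out, ch[[i]]); i <- i + 1L }
      }
      pos <<- i
      paste(out, collapse = "")
    } else {
      i <- pos
      while (i <= n && !ch[[i]] %in% c("(", ")", ",", ":", ";", "[", "]") &&
             !grepl("[[:space:]]", ch[[i]])) i <- i + 1L
      out <- paste(ch[pos:(i - 1L)], collapse = "")
      pos <<- i
      out
    }
  }
  readNumber <- function() {
    i <- pos
    while (i <= n && grepl("[0-9eE+.\\-]", ch[[i]])) i <- i + 1L
    if (i == pos) perr(pos, "expected a branch length after ':'")
    val <- suppressWarnings(as.numeric(paste(ch[pos:(i - 1L)], collapse = "")))
    if (is.na(val)) perr(pos, "malformed branch length")
    pos <<- i
    val
  }

  while (pos <= n) {
    c0 <- ch[[pos]]
    if (grepl("[[:space:]]", c0)) { pos <- pos + 1L; next }
    if (done) perr(pos, "text after terminating ';'")
    if (c0 == "(") {
      idx <- newNode(if (length(stack)) stack[[length(stack)]] else NA_integer_,
                     TRUE)
      stack <- c(stack, idx)
      cur <- NA_integer_
      pos <- pos + 1L
    } else if (c0 == ")") {
      if (!length(stack)) perr(pos, "unbalanced ')'")
      cur <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      pos <- pos + 1L
      if (pos <= n && !ch[[pos]] %in% c("(", ")", ",", ":", ";")) {
        lab[[cur]] <- readLabel()
      }
    } else if (c0 == ",") {
      if (!length(stack)) perr(pos, "',' outside parentheses")
      cur <- NA_integer_
      pos <- pos + 1L
    } else if (c0 == ":") {
      pos <- pos + 1L
      if (is.na(cur)) {   # anonymous leaf with only a length
        cur <- newNode(if (length(stack)) stack[[length(stack)]] else
                         NA_integer_, FALSE)
      }
      len[[cur]] <- readNumber()
    } else if (c0 == ";") {
      if (length(stack)) perr(pos, "unbalanced '(' before ';'")
      if (!length(lab)) perr(pos, "empty tree")
      done <- TRUE
      pos <- pos + 1L
    } else {
      if (!is.na(cur)) perr(pos, "unexpected label")
      cur <- newNode(if (length(stack)) stack[[length(stack)]] else
                       NA_integer_, FALSE)
      lab[[cur]] <- readLabel()
    }
  }
  if (!done) perr(n + 1L, "missing terminating ';'")
  if (sum(is.na(par)) != 1L) perr(1L, "expected exactly one root clause")
  if (any(!internal & is.na(lab))) perr(1L, "unlabelled tip")
  childless <- internal &
    !vapply(seq_along(lab), function(i) any(par == i, na.rm = TRUE), logical(1))
  if (any(childless)) perr(1L, "internal node with no children")

  user <- vector("list", length(lab))
  if (!internalLabelsAsIds) {
    for (i in which(internal & !is.na(lab))) {
      user[[i]] <- list(label = lab[[i]])
      lab[[i]] <- NA_character_
    }
  }
  dup <- lab[!is.na(lab)][duplicated(lab[!is.na(lab)])]
  if (length(dup)) .stopf("duplicate label in Newick: '%s'", dup[[1L]])
  # nodes were created in preorder; fill auto ids in that order
  taken <- lab[!is.na(lab)]
  k <- 1L
  for (i in which(is.na(lab))) {
    id <- .freshId(taken, autoIdPrefix, k)
    k <- as.integer(sub(autoIdPrefix, "", id, fixed = TRUE)) + 1L
    lab[[i]] <- id
    taken <- c(taken, id)
  }

  specs <- data.frame(
    id = lab,
    parent = ifelse(is.na(par), NA_character_, lab[par]),
    spn = len,
    stringsAsFactors = FALSE
  )
  tree <- buildTree(specs)
  for (i in seq_along(user)) {
    if (!is.null(user[[i]])) tree@ndlst[[lab[[i]]]]$user <- user[[i]]
  }
  tree
}

#' Write a NodeTree as a Newick string
#'
#' Children are written in stored order, so the writer is order-stable;
#' spans are printed with the shortest decimal representation that
#' round-trips the double exactly, so \code{readNewick(writeNewick(tree))}
#' reproduces topology, ids and spans without loss.
#'
#' @param tree a \code{NodeTree}.
#' @param writeSpans write \code{:length} fields (default: only when the
#'   tree has them).
#' @return a Newick string terminated by \code{";"}.
#' @export
writeNewick <- function(tree, writeSpans = hasSpans(tree)) {
  ndlst <- tree@ndlst
  wr <- function(id) {
    nd <- ndlst[[id]]
    inner <- if (length(nd$ptid)) {
      paste0("(", paste(vapply(nd$ptid, wr, character(1)), collapse = ","), ")")
    } else ""
    spnStr <- if (writeSpans && !is.na(nd$spn)) {
      paste0(":", .fmtSpan(nd$spn))
    } else ""
    paste0(inner, .quoteLabel(id), spnStr)
  }
  paste0(wr(tree@root), ";")
}

.fmtSpan <- function(x) {
  s <- trimws(formatC(x, digits = 15, format = "g"))
  if (!is.na(suppressWarnings(as.numeric(s))) && as.numeric(s) == x) return(s)
  sprintf("%.17g", x)
}

.quoteLabel <- function(id) {
  if (grepl("[][(),:;']", id)) {
    paste0("'", gsub("'", "''", id, fixed = TRUE), "'")
  } else id
}
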