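#' Fully balanced ultrametric tree
#'
#' @param nTips number of tips (a power of two, at least 2)
#' @param spn span of every edge (default 1)
#' @return an ultrametric \code{NodeTree} with tips \code{t1..tn} and
#'   internal ids \code{n1..}; tree age is \code{spn * log2(nTips)}.
#' @examples
#' treeSlot(balancedTree(4, 1), "pd") # 6
#' @export
balancedTree <- function(nTips, spn = 1) {
  if (nTips < 2 || bitwAnd(nTips, nTips - 1L) != 0L) {
    .stopf("nTips must be a power of two >= 2 (got %s)", nTips)
  }
  rows <- list(data.frame(id = "n1", parent = NA_character_, spn = NA_real_))
  nextInternal <- 2L
  nextTip <- 1L
  # (id, tips-to-generate) work queue
  queue <- list(list(id = "n1", n = as.integer(nTips)))
  while (length(queue)) {
    job <- queue[[1L]]; queue <- queue[-1L]
    for (half in c(job$n %/% 2L, job$n %/% 2L)) {
      if (half == 1L) {
        id <- paste0("t", nextTip); nextTip <- nextTip + 1L
      } else {
        id <- paste0("n", nextInternal); nextInternal <- nextInternal + 1L
        queue <- c(queue, list(list(id = id, n = half)))
      }
      rows[[length(rows) + 1L]] <- data.frame(id = id, parent = job$id,
                                              spn = spn)
    }
  }
  buildTree(do.call(rbind, rows))
}

#' Random pure-birth (Yule) tree
#'
#' Simulates a constant-rate pure-birth process: waiting times between
#' speciations are exponential with rate equal to the number of extant
#' lineages, and the splitting lineage is chosen uniformly. After the last
#' speciation the pendant edges are extended by one further exponential
#' waiting time, so the tree is ultrametric with positive terminal spans.
#'
#' @param nTips number of tips (at least 2)
#' @param rngSeed optional seed
#' @return an ultrametric \code{NodeTree} with tips \code{t1..tn}.
#' @export
randYuleTree <- function(nTips, rngSeed = NULL) {
  if (nTips < 2) .stopf("nTips must be at least 2")
  if (!is.null(rngSeed)) set.seed(rngSeed)
  nTips <- as.integer(nTips)

  # per-lineage records; pendant spans accumulate until the lineage splits
  id <- c("t1", "t2")
  parent <- c("n1", "n1")
  spn <- c(0, 0)
  closedId <- "n1"; closedParent <- NA_character_; closedSpn <- NA_real_
  pend <- c(1L, 2L)  # indices of open (pendant) lineages
  nextInternal <- 2L
  k <- 2L
  while (k < nTips) {
    w <- stats::rexp(1L, rate = k)
    spn[pend] <- spn[pend] + w
    split <- pend[[sample.int(k, 1L)]]
    newInt <- paste0("n", nextInternal); nextInternal <- nextInternal + 1L
    # the split lineage's pendant edge closes as the new internal node
    closedId <- c(closedId, newInt)
    closedParent <- c(closedParent, parent[[split]])
    closedSpn <- c(closedSpn, spn[[split]])
    k <- k + 1L
    id <- c(id, paste0("t", k))
    parent <- c(parent, newInt)
    spn <- c(spn, 0)
    parent[[split]] <- newInt
    spn[[split]] <- 0
    pend <- c(pend, length(id))
  }
  spn[pend] <- spn[pend] + stats::rexp(1L, rate = nTips)
  buildTree(data.frame(
    id = c(closedId, id),
    parent = c(closedParent, parent),
    spn = c(closedSpn, spn)
  ))
}

#' Colless imbalance index
#'
#' The sum over internal nodes of the absolute difference between the
#' numbers of tips descending from the node's two children. Defined for
#' strictly binary trees; polytomies are rejected.
#'
#' @param tree a binary \code{NodeTree}
#' @return a non-negative integer.
#' @examples
#' collessIndex(balancedTree(8)) # 0
#' @export
collessIndex <- function(tree) {
  total <- 0L
  for (id in setdiff(nodeIds(tree), tipIds(tree))) {
    ch <- tree@ndlst[[id]]$ptid
    if (length(ch) != 2L) {
      .stopf("collessIndex requires a binary tree; node '%s' has %d children",
             id, length(ch))
    }
    cnt <- vapply(ch, function(c1) {
      nd <- tree@ndlst[[c1]]
      if (.isTip(nd)) 1L else length(nd$kids)
    }, integer(1))
    total <- total + abs(cnt[[1L]] - cnt[[2L]])
  }
  total
}

#' Evolutionary-distinctness-biased Markov tree growth
#'
#' Grows a tree in discrete iterations. Each iteration, in order: (1) the
#' Fair Proportion evolutionary distinctness of every extant tip is
#' computed; (2) with probability \code{birthProb} one extant tip is chosen
#' with weight proportional to \code{FP^(-edPower)} and a new tip is
#' attached at its terminus (both daughter spans start at zero); (3) with
#' probability \code{deathProb} a tip is chosen analogously (from the same
#' weights) and removed; (4) every extant tip's span is extended by
#' \code{timeStep}. With \code{edPower = 0} the weights are uniform and the
#' process reduces to the equal-rates Markov model; with \code{edPower > 0},
#' evolutionarily distinct tips speciate and go extinct at lower rates.
#' Extinct lineages remain in the tree with their spans frozen unless
#' \code{pruneExtinct} is set.
#'
#' @param tree seed tree (default: a two-tip balanced tree, unit spans)
#' @param nIterations number of iterations
#' @param birthProb,deathProb per-iteration event probabilities in [0, 1]
#' @param edPower bias exponent (0 = equal rates)
#' @param timeStep span increment per iteration (default 1)
#' @param pruneExtinct drop non-extant tips from the returned tree
#' @param rngSeed optional seed
#' @return a list with elements \code{tree} (valid \code{NodeTree}),
#'   \code{log} (a \code{data.frame}: iteration, event, tipId, nTips),
#'   \code{completed} and \code{reason} (non-\code{NA} when the run halted
#'   early because the tree or its extant fringe was exhausted).
#' @examples
#' sim <- simulateEDBMM(nIterations = 10, birthProb = 1, deathProb = 0,
#'                      rngSeed = 1)
#' nTips(sim$tree) # 12
#' @export
simulateEDBMM <- function(tree = balancedTree(2, 1), nIterations,
                          birthProb, deathProb, edPower = 0, timeStep = 1,
                          pruneExtinct = FALSE, rngSeed = NULL) {
  .checkSpans(tree, "simulateEDBMM")
  stopifnot(nIterations >= 1, birthProb >= 0, birthProb <= 1,
            deathProb >= 0, deathProb <= 1, edPower >= 0, timeStep > 0)
  if (!is.null(rngSeed)) set.seed(rngSeed)

  logRows <- list()
  completed <- TRUE
  reason <- NA_character_
  tipCounter <- 0L

  for (it in seq_len(nIterations)) {
    extant <- extantTips(tree)
    if (!length(extant)) {
      completed <- FALSE; reason <- "no extant tips left"; break
    }
    fp <- calcFrPrp(tree, extant)
    w <- (fp + 1e-12)^(-edPower)
    w <- w / sum(w)

    if (stats::runif(1L) < birthProb) {
      mother <- extant[[sample.int(length(extant), 1L, prob = w)]]
      tipCounter <- tipCounter + 1L
      newId <- .freshId(names(tree@ndlst), "s", tipCounter)
      a <- getNdAge(tree, mother)
      tree <- addTip(tree, newId, mother, strtAge = a, endAge = a,
                     tipAge = a)
      logRows[[length(logRows) + 1L]] <- data.frame(
        iteration = it, event = "birth", tipId = newId, nTips = tree@ntips)
    }
    if (stats::runif(1L) < deathProb) {
      if (tree@ntips <= 3L) {
        completed <- FALSE; reason <- "tip count would fall below 3"; break
      }
      victim <- extant[[sample.int(length(extant), 1L, prob = w)]]
      tree <- rmTip(tree, victim)
      logRows[[length(logRows) + 1L]] <- data.frame(
        iteration = it, event = "death", tipId = victim, nTips = tree@ntips)
    }

    extant <- extantTips(tree)
    if (!length(extant)) {
      completed <- FALSE; reason <- "no extant tips left"; break
    }
    ndlst <- tree@ndlst
    for (t in extant) {
      ndlst[[t]]$spn <- ndlst[[t]]$spn + timeStep
      ndlst[[t]]$prdst <- ndlst[[t]]$prdst + timeStep
    }
    # pd of every ancestor of an extended tip grows by timeStep per
    # extended descendant tip
    perAnc <- table(unlist(lapply(extant, function(t) ndlst[[t]]$prid)))
    for (a in names(perAnc)) {
      ndlst[[a]]$pd <- ndlst[[a]]$pd + timeStep * perAnc[[a]]
    }
    tree@ndlst <- ndlst
    tree@pd <- tree@pd + timeStep * length(extant)
    tips <- tipIds(tree)
    tree@age <- max(vapply(tree@ndlst[tips], `[[`, numeric(1), "prdst"))
  }

  tree <- refreshDerived(tree)  # numerical hygiene after incremental growth
  if (pruneExtinct) {
    for (t in setdiff(tipIds(tree), extantTips(tree))) {
      if (tree@ntips > 2L) tree <- rmTip(tree, t)
    }
  }
  list(
    tree = tree,
    log = if (length(logRows)) do.call(rbind, logRows) else
      data.frame(iteration = integer(0), event = character(0),
                 tipId = character(0), nTips = integer(0)),
    completed = completed,
    reason = reason
  )
}
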