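#' Generate two disjoint communities with phylogenetic distance bias
#'
#' A seed tip is drawn uniformly (without replacement) for each community;
#' the remaining members are then drawn without replacement with weight
#' \code{(d(t, seed) + 1e-6)^(-psi)}, where \code{d} is the patristic
#' distance to the community's seed. With \code{psi = 0} both communities
#' are uniform random disjoint tip sets; larger \code{psi} concentrates
#' each community around its seed, reducing the phylogenetic overlap
#' between the two.
#'
#' @param tree a \code{NodeTree} with spans
#' @param size1,size2 community sizes (their sum at most \code{nTips})
#' @param psi non-negative bias strength (0 = uniform)
#' @param rngSeed optional seed
#' @return a list with character vectors \code{c1} and \code{c2} (disjoint
#'   tip sets) and the two \code{seeds}.
#' @export
genCommunities <- function(tree, size1, size2, psi = 0, rngSeed = NULL) {
  .checkSpans(tree, "genCommunities")
  if (psi < 0) .stopf("psi must be non-negative")
  tips <- tipIds(tree)
  if (size1 < 1 || size2 < 1) .stopf("community sizes must be positive")
  if (size1 + size2 > length(tips)) {
    .stopf("community sizes %d + %d exceed the %d tips",
           size1, size2, length(tips))
  }
  if (!is.null(rngSeed)) set.seed(rngSeed)

  seeds <- sample(tips, 2L)
  pool <- setdiff(tips, seeds)
  drawFor <- function(seed, n, pool) {
    if (!n) return(character(0))
    d <- vapply(pool, function(t) .tipDist(tree, t, seed), numeric(1))
    w <- (d + 1e-6)^(-psi)
    pool[sample.int(length(pool), n, prob = w)]
  }
  m1 <- drawFor(seeds[[1L]], size1 - 1L, pool)
  pool <- setdiff(pool, m1)
  m2 <- drawFor(seeds[[2L]], size2 - 1L, pool)
  list(c1 = c(seeds[[1L]], m1), c2 = c(seeds[[2L]], m2), seeds = seeds)
}

.tipDist <- function(tree, a, b) {
  m <- getPrnt(tree, c(a, b))
  tree@ndlst[[a]]$prdst + tree@ndlst[[b]]$prdst - 2 * tree@ndlst[[m]]$prdst
}

#' Permutation test for phylogenetic turnover between two communities
#'
#' The observed statistic is \code{\link{calcOvrlp}(tree, c1, c2)}: the
#' fraction of the first community's represented branch length that the
#' second community shares. Null communities replace \code{c2} with uniform
#' random tip sets of the same size, disjoint from \code{c1} (matching the
#' generation constraint); the one-tailed p-value asks whether the observed
#' overlap is lower than expected under random membership (low overlap =
#' phylogenetic turnover), with the +1 rank correction so p is never 0:
#' \code{p = (1 + #\{null <= observed\}) / (nPerm + 1)}.
#'
#' @param tree a \code{NodeTree} with spans
#' @param c1,c2 disjoint non-empty tip-id vectors
#' @param nPerm number of permutations (at least 19)
#' @param rngSeed optional seed
#' @return a list of class \code{"turnoverResult"}: \code{observedOverlap},
#'   \code{nullOverlaps}, \code{pValue}, \code{nPerm}, \code{rngSeed}.
#' @export
permTestOvrlp <- function(tree, c1, c2, nPerm = 99L, rngSeed = NULL) {
  .checkSpans(tree, "permTestOvrlp")
  if (nPerm < 19L) .stopf("nPerm must be at least 19")
  .checkTips(tree, c1); .checkTips(tree, c2)
  if (length(intersect(c1, c2))) {
    .stopf("communities overlap in membership ('%s')",
           intersect(c1, c2)[[1L]])
  }
  if (!is.null(rngSeed)) set.seed(rngSeed)

  obs <- calcOvrlp(tree, c1, c2)
  pool <- setdiff(tipIds(tree), c1)
  nulls <- vapply(seq_len(nPerm), function(i) {
    calcOvrlp(tree, c1, pool[sample.int(length(pool), length(c2))])
  }, numeric(1))
  structure(list(
    observedOverlap = obs,
    nullOverlaps = nulls,
    pValue = (1 + sum(nulls <= obs)) / (nPerm + 1),
    nPerm = as.integer(nPerm),
    rngSeed = rngSeed
  ), class = "turnoverResult")
}

#' @export
print.turnoverResult <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic turnover permutation test\nobserved overlap: %.6f\nnull overlaps:    mean %.6f (n = %d)\np-value:          %.6g (one-tailed, low overlap = turnover)\n",
    x$observedOverlap, mean(x$nullOverlaps), x$nPerm, x$pValue))
  invisible(x)
}
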