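# shared fixtures and oracles, all built in code

t1Tree <- function() readNewick("((A:1,B:1)n1:1,C:2)root;")

# non-ultrametric: tip ages 1 (A), 0 (B), 0 (C)
t3Tree <- function() readNewick("((A:1,B:2)n1:1,C:3)root;")

twoCherryTree <- function() readNewick("((A:1,B:1)n1:1,(C:1,D:1)n2:1)root;")

# slot-for-slot comparison of a maintained tree against the full-recompute
# oracle: exact for ids/topology/sets, 1e-9 for reals
expect_tree_equals_refresh <- function(tree) {
  ref <- refreshDerived(tree)
  for (id in nodeIds(tree)) {
    nd <- tree@ndlst[[id]]
    rf <- ref@ndlst[[id]]
    expect_identical(nd$prid, rf$prid, label = paste0("prid of ", id))
    expect_identical(nd$ptid, rf$ptid, label = paste0("ptid of ", id))
    expect_true(setequal(nd$kids, rf$kids), label = paste0("kids of ", id))
    if (hasSpans(tree)) {
      expect_lt(abs(nd$pd - rf$pd), 1e-9, label = paste0("pd of ", id))
      expect_lt(abs(nd$prdst - rf$prdst), 1e-9,
                label = paste0("prdst of ", id))
    }
  }
  expect_identical(nTips(tree), nTips(ref))
  expect_identical(nNodes(tree), nNodes(ref))
  expect_identical(hasSpans(tree), hasSpans(ref))
  if (hasSpans(tree)) {
    expect_lt(abs(treePD(tree) - treePD(ref)), 1e-9)
    expect_lt(abs(treeAge(tree) - treeAge(ref)), 1e-9)
  }
  invisible(TRUE)
}

# fast boolean version of the same comparison, for per-operation checking
# inside long loops
treeMatchesRefresh <- function(tree) {
  ref <- refreshDerived(tree)
  for (id in nodeIds(tree)) {
    nd <- tree@ndlst[[id]]
    rf <- ref@ndlst[[id]]
    if (!identical(nd$prid, rf$prid) || !identical(nd$ptid, rf$ptid) ||
        !setequal(nd$kids, rf$kids)) return(FALSE)
    if (hasSpans(tree) &&
        (abs(nd$pd - rf$pd) > 1e-9 || abs(nd$prdst - rf$prdst) > 1e-9)) {
      return(FALSE)
    }
  }
  isTRUE(nTips(tree) == nTips(ref) && nNodes(tree) == nNodes(ref) &&
         (!hasSpans(tree) || (abs(treePD(tree) - treePD(ref)) <= 1e-9 &&
                              abs(treeAge(tree) - treeAge(ref)) <= 1e-9)))
}

# exact expected Colless imbalance under the pure-birth (Yule) shape
# distribution, from the uniform root-split recursion:
# E[I_n] = mean_i ( |n - 2i| + E[I_i] + E[I_{n-i}] ), i uniform on 1..n-1
yuleCollessExpectation <- function(n) {
  E <- numeric(n)
  if (n >= 3) {
    for (m in 3:n) {
      i <- 1:(m - 1)
      E[m] <- mean(abs(m - 2 * i) + E[i] + E[m - i])
    }
  }
  E[n]
}

# independent Colless recount by naive recursive tip counting
bruteColless <- function(tree) {
  countTips <- function(id) {
    ch <- tree@ndlst[[id]]$ptid
    if (!length(ch)) return(1L)
    sum(vapply(ch, countTips, integer(1)))
  }
  tot <- 0L
  for (id in setdiff(nodeIds(tree), tipIds(tree))) {
    ch <- tree@ndlst[[id]]$ptid
    tot <- tot + abs(countTips(ch[[1]]) - countTips(ch[[2]]))
  }
  tot
}

# patristic distance by explicit path walking (independent of prdst algebra)
brutePathDist <- function(tree, a, b) {
  if (a == b) return(0)
  path <- getPath(tree, a, b)
  m <- getPrnt(tree, c(a, b))
  sum(vapply(setdiff(path, m), function(i) tree@ndlst[[i]]$spn, numeric(1)))
}

# grow a balanced tree by repeatedly doubling every tip at its terminus,
# recording the touched-record count of each insertion
growBalancedRecording <- function(targetTips) {
  tr <- balancedTree(2, 1)
  k <- 0L
  ns <- integer(0)
  touched <- integer(0)
  while (nTips(tr) < targetTips) {
    for (tp in tipIds(tr)) {
      k <- k + 1L
      a <- getNdAge(tr, tp)
      resetTouchCount()
      tr <- addTip(tr, paste0("x", k), tp, strtAge = a, endAge = a,
                   tipAge = a)
      ns <- c(ns, nTips(tr))
      touched <- c(touched, touchCount())
    }
  }
  list(tree = tr, ns = ns, touched = touched)
}
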