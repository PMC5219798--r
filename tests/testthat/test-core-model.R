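test_that("buildTree constructs a valid tree with all derived fields", {
  specs <- data.frame(
    id = c("root", "n1", "A", "B", "C"),
    parent = c(NA, "root", "n1", "n1", "root"),
    spn = c(NA, 1, 1, 1, 2)
  )
  tr <- buildTree(specs)
  expect_s4_class(tr, "NodeTree")
  expect_identical(nTips(tr), 3L)
  expect_identical(nNodes(tr), 5L)
  expect_equal(treePD(tr), 5)
  expect_equal(treeAge(tr), 2)
  expect_identical(nrow(validateTree(tr)), 0L)
})

test_that("buildTree rejects degenerate and inconsistent inputs", {
  expect_error(buildTree(data.frame(id = "only", parent = NA)), "one root|2 tips")
  expect_error(
    buildTree(data.frame(id = c("r", "A", "B"), parent = c(NA, "nX", "r"))),
    "unknown parent id: 'nX'")
  expect_error(
    buildTree(data.frame(id = c("r", "A", "A"), parent = c(NA, "r", "r"))),
    "duplicate node id: 'A'")
  expect_error(
    buildTree(data.frame(id = c("r", "A", "B"), parent = c(NA, NA, "r"))),
    "exactly one root")
  expect_error(
    buildTree(data.frame(id = c("r", "a b"), parent = c(NA, "r"))),
    "whitespace")
  expect_error(
    buildTree(data.frame(id = c("r", "A", "B"), parent = c(NA, "r", "r"),
                         spn = c(NA, -1, 1))),
    "non-negative")
})

test_that("validateTree reports injected invariant violations", {
  tr <- t1Tree()
  expect_identical(nrow(validateTree(tr)), 0L)

  broken <- tr
  broken@ndlst[["A"]]$prid <- "n1"  # truncate ancestor chain
  rep1 <- validateTree(broken)
  expect_true(any(grepl("prid", rep1$invariant)))
  expect_true("A" %in% rep1$nodeId)

  broken2 <- tr
  broken2@ndlst[["root"]]$kids <- c("A", "B")  # drop C from root's kids
  rep2 <- validateTree(broken2)
  expect_true(any(grepl("kids", rep2$invariant)))

  broken3 <- tr
  broken3@ndlst[["n1"]]$ptid <- c("A", "B", "zzz")  # dangling child pointer
  rep3 <- validateTree(broken3)
  expect_true(any(grepl("unknown id", rep3$invariant)))

  broken4 <- tr
  broken4@ndlst[["C"]]$pd <- 99  # stale derived value
  expect_true(any(grepl("pd equals recompute", validateTree(broken4)$invariant)))
})

test_that("refreshDerived is idempotent and recomputes from topology alone", {
  tr <- t1Tree()
  expect_tree_equals_refresh(tr)

  # scramble every derived field; refresh must restore them exactly
  scr <- tr
  for (id in nodeIds(scr)) {
    scr@ndlst[[id]]$prid <- character(0)
    scr@ndlst[[id]]$kids <- character(0)
    scr@ndlst[[id]]$pd <- -1
    scr@ndlst[[id]]$prdst <- -1
  }
  fixed <- refreshDerived(scr)
  expect_identical(fixed@ndlst[["A"]]$prid, c("n1", "root"))
  expect_true(setequal(fixed@ndlst[["root"]]$kids, c("A", "B", "C")))
  expect_equal(fixed@ndlst[["n1"]]$pd, 2)
  expect_equal(fixed@ndlst[["C"]]$prdst, 2)
  expect_identical(nrow(validateTree(fixed)), 0L)
})

test_that("span-free trees disable span-dependent fields and operations", {
  nf <- readNewick("((A,B)n1,C)root;")
  expect_false(hasSpans(nf))
  expect_true(is.na(treePD(nf)))
  expect_true(is.na(treeAge(nf)))
  expect_identical(nrow(validateTree(nf)), 0L)
  expect_error(getNdAge(nf, "A"), "branch lengths")
  expect_error(calcFrPrp(nf), "branch lengths")
  expect_error(calcDstMtrx(nf), "branch lengths")
  # partial spans count as span-free
  expect_false(hasSpans(readNewick("((A:1,B)n1:1,C:2)root;")))
})

test_that("treeSlot exposes tree-level summaries by name", {
  tr <- t1Tree()
  expect_setequal(treeSlot(tr, "tips"), c("A", "B", "C"))
  expect_setequal(treeSlot(tr, "nodes"), c("n1", "root"))
  expect_identical(treeSlot(tr, "ntips"), 3L)
  expect_identical(treeSlot(tr, "nnodes"), 5L)
  expect_equal(treeSlot(tr, "pd"), 5)
  expect_equal(treeSlot(tr, "age"), 2)
  expect_identical(treeSlot(tr, "root"), "root")
  expect_error(treeSlot(tr, "bogus"), "tips, nodes")
  expect_identical(tr["tips"], treeSlot(tr, "tips"))
})

test_that("nodeInfo gives a per-node view with on-demand age", {
  tr <- t1Tree()
  n1 <- nodeInfo(tr, "n1")
  expect_setequal(n1$ptid, c("A", "B"))
  expect_equal(n1$age, 1)
  expect_identical(nodeInfo(tr, "root")$prid, character(0))
  expect_error(nodeInfo(tr, "zzz"), "unknown node id: 'zzz'")
  expect_identical(tr[["n1"]]$ptid, n1$ptid)
  txt <- summariseNode(tr, "n1")
  expect_match(txt, "A, B")
  expect_match(summariseNode(tr, "root"), "parent:   <none>")
  expect_match(summariseNode(tr, "A"), "children: <none>")
})

test_that("random manipulation sequences keep maintained slots equal to the oracle", {
  set.seed(42)
  tr <- randYuleTree(50, rngSeed = 42)
  for (i in 1:120) {
    op <- sample(3, 1)
    nds <- setdiff(nodeIds(tr), rootId(tr))
    if (op == 1) {
      e <- sample(nds, 1)
      tr <- addTip(tr, paste0("q", i), e,
                   strtAge = getNdAge(tr, getNdPrid(tr, e)[1]),
                   endAge = getNdAge(tr, e))
    } else if (op == 2 && nTips(tr) > 3) {
      tr <- rmTip(tr, sample(tipIds(tr), 1))
    } else {
      tr <- setNdSpn(tr, sample(nds, 1), runif(1, 0, 2))
    }
  }
  expect_tree_equals_refresh(tr)
  expect_identical(nrow(validateTree(tr)), 0L)
})

test_that("conservation: treePD is the non-root span sum, ultrametric tip ages are 0", {
  for (seed in c(1, 2, 3)) {
    tr <- randYuleTree(40, rngSeed = seed)
    spans <- vapply(setdiff(nodeIds(tr), rootId(tr)),
                    function(i) tr@ndlst[[i]]$spn, numeric(1))
    expect_lt(abs(treePD(tr) - sum(spans)), 1e-9)
    ages <- vapply(tipIds(tr), function(t) getNdAge(tr, t), numeric(1))
    expect_lt(max(abs(ages)), 1e-9)  # pure-birth trees are ultrametric
  }
  t3 <- t3Tree()
  expect_equal(treeAge(t3), 3)
  expect_equal(getNdAge(t3, "A"), 1)
})
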