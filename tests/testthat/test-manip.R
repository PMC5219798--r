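test_that("addTip inserts within the age overlap and keeps invariants", {
  tr <- t1Tree()
  t2 <- addTip(tr, "D", "C", strtAge = 2, endAge = 0, tipAge = 0, rngSeed = 1)
  expect_identical(nTips(t2), 4L)
  expect_identical(nrow(validateTree(t2)), 0L)
  expect_tree_equals_refresh(t2)
  # both D and C are extant, so d(C,D) = 2 * attachment age
  set.seed(1)
  attach_age <- runif(1, 0, 2)
  expect_lt(abs(calcDstMtrx(t2, c("C", "D"))["C", "D"] - 2 * attach_age), 1e-9)
  expect_equal(treePD(t2), treePD(tr) + attach_age)

  # degenerate interval: deterministic attachment
  t3 <- addTip(tr, "D", "C", strtAge = 1, endAge = 1)
  expect_equal(calcDstMtrx(t3, c("C", "D"))["C", "D"], 2)

  expect_error(addTip(tr, "D", "C", strtAge = 5, endAge = 4), "does not overlap")
  expect_error(addTip(tr, "A", "C", strtAge = 1, endAge = 1), "already in tree")
  expect_error(addTip(tr, "D", "root", strtAge = 1, endAge = 1), "root")
  expect_error(addTip(tr, "D", "C", strtAge = 1, endAge = 1, tipAge = -1),
               "non-negative")
})

test_that("rmTip splices unary parents and preserves remaining distances", {
  tr <- t1Tree()
  out <- rmTip(tr, "A")
  expect_identical(sort(tipIds(out)), c("B", "C"))
  expect_equal(calcDstMtrx(out)["B", "C"], 4)  # B.spn + n1.spn + C.spn
  expect_identical(nrow(validateTree(out)), 0L)
  expect_tree_equals_refresh(out)

  # root left with one child: root absorbs it, metric preserved
  ra <- rmTip(tr, "C")
  expect_identical(sort(tipIds(ra)), c("A", "B"))
  expect_equal(calcDstMtrx(ra)["A", "B"], 2)
  expect_identical(nrow(validateTree(ra)), 0L)

  expect_error(rmTip(tr, "n1"), "not a tip")
  expect_error(rmTip(readNewick("(A:1,B:1);"), "A"), "fewer than 2")

  # add-then-remove restores the tip count and total branch length
  t2 <- addTip(tr, "D", "C", strtAge = 2, endAge = 0, rngSeed = 7)
  t3 <- rmTip(t2, "D")
  expect_identical(nTips(t3), nTips(tr))
  expect_lt(abs(treePD(t3) - treePD(tr)), 1e-9)
})

test_that("setNdSpn updates spans incrementally with correct propagation", {
  tr <- t1Tree()
  out <- setNdSpn(tr, "C", 3)
  expect_equal(treePD(out), 6)
  expect_equal(treeAge(out), 3)
  expect_tree_equals_refresh(out)
  ident <- setNdSpn(tr, "C", 2)
  expect_equal(treePD(ident), treePD(tr))
  expect_error(setNdSpn(tr, "C", -1), "non-negative")
  expect_error(setNdSpn(tr, "root", 1), "root")
  # shrinking an internal edge shifts descendants' root distances
  out2 <- setNdSpn(tr, "n1", 0.25)
  expect_equal(out2@ndlst[["A"]]$prdst, 1.25)
  expect_tree_equals_refresh(out2)
})

test_that("setAge and setPD are linear rescalings", {
  tr <- t1Tree()
  half <- setAge(tr, 1)
  expect_equal(treeAge(half), 1)
  expect_equal(treePD(half), 2.5)
  expect_equal(calcDstMtrx(half), calcDstMtrx(tr) / 2)
  expect_equal(calcFrPrp(half), calcFrPrp(tr) / 2)
  expect_tree_equals_refresh(half)
  expect_equal(treeAge(setAge(tr, treeAge(tr))), treeAge(tr))

  scaled <- setPD(tr, 10)
  expect_equal(treePD(scaled), 10)
  expect_equal(calcDstMtrx(scaled), calcDstMtrx(tr) * 2)
  expect_error(setAge(tr, 0), "positive")
  expect_error(setPD(readNewick("((A,B)n1,C)r;"), 1), "branch lengths")
})

test_that("setRoot reverses edges and preserves the unrooted metric", {
  tr <- t1Tree()
  rr <- setRoot(tr, "n1")
  expect_identical(rootId(rr), "n1")
  expect_identical(nrow(validateTree(rr)), 0L)
  expect_equal(calcDstMtrx(rr)["A", "C"], 4)
  expect_identical(setRoot(tr, "root"), tr)
  expect_error(setRoot(tr, "A"), "tip")

  for (seed in c(2, 6)) {
    y <- randYuleTree(15, rngSeed = seed)
    target <- sample(setdiff(nodeIds(y), c(tipIds(y), rootId(y))), 1)
    ry <- setRoot(y, target)
    expect_identical(nrow(validateTree(ry)), 0L)
    expect_equal(calcDstMtrx(ry)[tipIds(y), tipIds(y)],
                 calcDstMtrx(y)[tipIds(y), tipIds(y)], tolerance = 1e-9)
  }
})

test_that("setTol controls the extant tip set", {
  t3 <- t3Tree()  # tip ages: A 1, B 0, C 0
  expect_setequal(extantTips(t3), c("B", "C"))
  expect_setequal(extantTips(setTol(t3, 1)), c("A", "B", "C"))
  expect_error(setTol(t3, -0.1), "non-negative")
})

test_that("pinTips honours the lowest matching taxonomic rank", {
  base <- setTxnyms(t1Tree(), c(root = "Mammalia", n1 = "Felidae"))
  # candidate with a Felidae lineage must always join the n1 clade
  for (seed in 1:30) {
    out <- pinTips(base, list(newcat = c("Mammalia", "Felidae")),
                   rngSeed = seed)
    rep <- attr(out, "pinReport")
    expect_false(rep$skipped)
    expect_identical(rep$hostId, "n1")
    m <- getPrnt(out, c("newcat", "A", "B"))
    expect_true(all(getNdKids(out, m) %in% c("A", "B", "newcat")))
    expect_identical(nrow(validateTree(out)), 0L)
  }
  # root-level lineage may attach anywhere; still valid
  out <- pinTips(base, list(stray = "Mammalia"), rngSeed = 3)
  expect_false(attr(out, "pinReport")$skipped)
  expect_identical(nTips(out), 4L)
  # unmatched lineages are skipped and reported, tree unchanged
  out <- pinTips(base, list(alien = c("Plantae", "Rosaceae")), rngSeed = 1)
  expect_true(attr(out, "pinReport")$skipped)
  expect_identical(nTips(out), 3L)
  # empty candidate list: identity with empty report
  out <- pinTips(base, list())
  expect_identical(nrow(attr(out, "pinReport")), 0L)
  expect_identical(nTips(out), 3L)
  # sequential pinning: an earlier pin can host a later candidate via its
  # inherited taxonym
  two <- pinTips(base, list(cat1 = c("Mammalia", "Felidae"),
                            cat2 = c("Mammalia", "Felidae")), rngSeed = 11)
  expect_identical(nTips(two), 5L)
  expect_identical(nrow(validateTree(two)), 0L)
})

test_that("setTxnyms attaches taxonyms by id", {
  tr <- setTxnyms(t1Tree(), c(n1 = "Felidae"))
  expect_identical(tr@ndlst[["n1"]]$txnym, "Felidae")
  expect_error(setTxnyms(t1Tree(), c(zzz = "X")), "unknown")
})
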