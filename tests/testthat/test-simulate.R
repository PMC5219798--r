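test_that("balancedTree builds fully balanced ultrametric trees", {
  bt <- balancedTree(4, 1)
  expect_equal(treePD(bt), 6)
  expect_equal(treeAge(bt), 2)
  expect_identical(collessIndex(bt), 0L)
  expect_identical(nTips(balancedTree(2, 1)), 2L)
  expect_error(balancedTree(3), "power of two")
  ages <- vapply(tipIds(bt), function(t) getNdAge(bt, t), numeric(1))
  expect_lt(max(abs(ages)), 1e-9)
})

test_that("randYuleTree is deterministic under a seed and shape-consistent with theory", {
  y <- randYuleTree(30, rngSeed = 4)
  expect_identical(nTips(y), 30L)
  expect_identical(nrow(validateTree(y)), 0L)
  expect_identical(writeNewick(randYuleTree(30, rngSeed = 4)), writeNewick(y))
  expect_false(identical(writeNewick(randYuleTree(30, rngSeed = 5)),
                         writeNewick(y)))
  # mean Colless over replicates matches the exact pure-birth expectation
  n <- 16
  vals <- vapply(1:300, function(s) {
    as.numeric(collessIndex(randYuleTree(n, rngSeed = 10000 + s)))
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - yuleCollessExpectation(n)), 3 * se)
})

test_that("collessIndex matches hand enumeration and a brute-force recount", {
  expect_identical(collessIndex(balancedTree(8)), 0L)
  caterpillar <- readNewick("(((A:1,B:1)n1:1,C:2)n2:1,D:3)root;")
  expect_identical(collessIndex(caterpillar), 3L)  # |1-3| + |1-2| + |1-1|
})

test_that("collessIndex rejects polytomies", {
  poly <- buildTree(data.frame(id = c("r", "A", "B", "C"),
                               parent = c(NA, "r", "r", "r"),
                               spn = c(NA, 1, 1, 1)))
  expect_error(collessIndex(poly), "binary")
  for (seed in c(2, 9)) {
    y <- randYuleTree(20, rngSeed = seed)
    expect_identical(collessIndex(y), bruteColless(y))
  }
})

test_that("EDBMM event accounting and determinism hold", {
  # pure birth from a cherry: k accepted births give 2 + k tips
  sim <- simulateEDBMM(nIterations = 25, birthProb = 1, deathProb = 0,
                       rngSeed = 2)
  expect_identical(nTips(sim$tree), 27L)
  expect_identical(sum(sim$log$event == "birth"), 25L)
  expect_true(sim$completed)
  expect_identical(nrow(validateTree(sim$tree)), 0L)
  # byte-identical reruns under the same seed
  sim2 <- simulateEDBMM(nIterations = 25, birthProb = 1, deathProb = 0,
                        rngSeed = 2)
  expect_identical(writeNewick(sim2$tree), writeNewick(sim$tree))
  expect_identical(sim2$log, sim$log)
})

test_that("EDBMM tip-count drift matches birthProb - deathProb", {
  drift <- vapply(1:60, function(s) {
    sim <- simulateEDBMM(tree = balancedTree(16, 1), nIterations = 20,
                         birthProb = 0.6, deathProb = 0.3, rngSeed = 400 + s)
    (nTips(sim$tree) - 16) / 20
  }, numeric(1))
  se <- sd(drift) / sqrt(length(drift))
  expect_lt(abs(mean(drift) - 0.3), 3 * se)
})

test_that("EDBMM halts gracefully when tips run out and validates en route", {
  sim <- simulateEDBMM(tree = balancedTree(4, 1), nIterations = 50,
                       birthProb = 0, deathProb = 1, rngSeed = 6)
  expect_false(sim$completed)
  expect_match(sim$reason, "below 3")
  expect_identical(nrow(validateTree(sim$tree)), 0L)
  # long mixed run stays valid, extinct lineages frozen unless pruned
  sim2 <- simulateEDBMM(tree = balancedTree(8, 1), nIterations = 100,
                        birthProb = 0.5, deathProb = 0.2, rngSeed = 7)
  expect_identical(nrow(validateTree(sim2$tree)), 0L)
  pruned <- simulateEDBMM(tree = balancedTree(8, 1), nIterations = 100,
                          birthProb = 0.5, deathProb = 0.2,
                          pruneExtinct = TRUE, rngSeed = 7)
  expect_identical(nrow(validateTree(pruned$tree)), 0L)
  expect_lte(nTips(pruned$tree), nTips(sim2$tree))
})
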