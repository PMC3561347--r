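test_that("matrix distance is a metric with hand-checkable values", {
  A <- randomExchangeability(1)
  B <- randomExchangeability(2)
  C <- randomExchangeability(3)
  expect_equal(matrixDistance(A, A), 0)
  expect_equal(matrixDistance(A, B), matrixDistance(B, A))
  expect_gte(matrixDistance(A, B), 0)
  ## triangle inequality on sampled triples
  expect_lte(matrixDistance(A, C),
             matrixDistance(A, B) + matrixDistance(B, C) + 1e-12)
  ## single-pair difference of 0.3
  r2 <- rho(A)
  r2["A", "R"] <- r2["R", "A"] <- r2["A", "R"] + 0.3
  expect_equal(matrixDistance(A, exchangeabilityMatrix(r2)), 0.3)
})

test_that("pair difference table reconstructs the second matrix", {
  A <- randomExchangeability(4)
  B <- randomExchangeability(5)
  d <- matrixDifference(A, B)
  expect_identical(nrow(d), 190L)
  rebuilt <- rho(A)
  rebuilt[cbind(d$res_i, d$res_j)] <- d$a - d$diff
  rebuilt[cbind(d$res_j, d$res_i)] <- d$a - d$diff
  expect_equal(rebuilt, rho(B))
})

test_that("random partitions have exact sizes and are uniform", {
  lab <- randomPartition(3580, c(1750, 1025, 805), seed = 2)
  expect_identical(tabulate(lab), c(1750L, 1025L, 805L))
  expect_identical(randomPartition(5, 5L, seed = 1), rep(1L, 5))
  expect_error(randomPartition(10, c(4, 4), seed = 1), "sum to n")
  ## n = 4 into (2,2): 3 distinct unordered splits, uniform over seeds
  splits <- vapply(1:3000, function(s) {
    lab <- randomPartition(4, c(2, 2), seed = s)
    paste(sort(which(lab == lab[1])), collapse = "")
  }, "")
  tab <- table(splits)
  expect_identical(length(tab), 3L)
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("noise analysis enforces its contracts", {
  fx <- makeFixture(sharedSupportSpec(groupSizes = c(40L, 30L), nTaxa = 5L,
                                      seed = 3))
  R0 <- exchangeabilityMatrix(matrix(1, 20, 20))
  expect_error(noiseAnalysis(fx$msa, fx$tree, fx$map, R0, S = 1),
               "S must be >= 2")
  na <- noiseAnalysis(fx$msa, fx$tree, fx$map, R0, S = 2, seed = 4,
                      fitOptions = list(
                        method = "joint",
                        control = c(fastFit$control, list(maxit = 40L))))
  expect_s4_class(na, "NoiseAnalysis")
  expect_identical(na@S, 2L)
  expect_identical(dim(na@random), c(2L, 2L))
  expect_equal(na@pBonferroni, pmin(1, na@pValue * 2))
  tab <- noiseTable(na)
  expect_named(tab, c("class", "d_obs", "mean_d_rand", "sd_d_rand",
                      "t", "p", "p_bonf"))
})

test_that("branch ratios follow the (Bl_R / Bl_ref) - 1 definition", {
  tr <- randomTree(6, seed = 6)
  expect_equal(branchRatio(tr, tr), rep(0, nrow(tr$edge)))
  tr2 <- tr; tr2$edge.length <- 2 * tr$edge.length
  expect_equal(branchRatio(tr2, tr), rep(1, nrow(tr$edge)))
  ## hand-built three-branch example
  star <- ape::stree(3, "star")
  a <- star; a$edge.length <- c(0.1, 0.2, 0.3)
  b <- star; b$edge.length <- c(0.1, 0.1, 0.6)
  expect_equal(branchRatio(a, b), c(0, 1, -0.5))
  ## zero reference branch flagged undefined
  b0 <- star; b0$edge.length <- c(0.1, 0, 0.6)
  expect_warning(r <- branchRatio(a, b0), "zero length")
  expect_true(is.na(r[2]))
  ## topology mismatch
  other <- randomTree(6, seed = 60)
  expect_error(branchRatio(tr, other), "topology mismatch")
})

test_that("branch ratios align edges across differently ordered trees", {
  tr <- randomTree(8, seed = 14)
  shuffled <- ape::read.tree(text = ape::write.tree(ape::rotateConstr(
    tr, rev(tr$tip.label))))
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 3
  r <- branchRatio(tr2, shuffled)
  expect_equal(r, rep(2, nrow(tr$edge)))
})

test_that("branch-length mixing is a weighted mean per branch", {
  tr <- randomTree(5, seed = 7)
  t2 <- tr; t2$edge.length <- tr$edge.length + 0.2
  expect_equal(mixBranchLengths(list(tr, t2), c(1, 0))$edge.length,
               stats::reorder(tr, "postorder")$edge.length)
  mixed <- mixBranchLengths(list(tr, t2), c(0.5, 0.5))
  expect_equal(mixed$edge.length,
               stats::reorder(tr, "postorder")$edge.length + 0.1)
  expect_error(mixBranchLengths(list(tr, t2), c(0.7, 0.7)), "sum to 1")
})
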