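test_that("branch-length optimization improves and stabilizes at the optimum", {
  tr <- randomTree(6, seed = 41, range = c(0.1, 0.4))
  Q <- buildRateMatrix(randomExchangeability(41), randomFrequencies(41))
  msa <- simulateAlignment(tr, Q, 800, seed = 6)
  start <- tr
  start$edge.length <- rep(0.15, nrow(tr$edge))
  fit <- optimizeBranchLengths(msa, start, Q)
  expect_gte(attr(fit, "logLik"), logLikelihood(msa, start, Q))
  expect_gte(attr(fit, "logLik"), logLikelihood(msa, tr, Q))  # beats truth
  ## restarting at the optimum changes nothing measurable
  fit2 <- optimizeBranchLengths(msa, fit, Q)
  expect_lt(abs(attr(fit2, "logLik") - attr(fit, "logLik")), 1e-4)
  ## identical sequences drive all branch lengths to the lower bound
  flat <- setNames(rep(paste(rep("A", 30), collapse = ""), 6), tr$tip.label)
  fit0 <- optimizeBranchLengths(flat, tr, Q)
  expect_lt(max(fit0$edge.length), 1e-6)
})

test_that("simulated branch lengths are recovered within tolerance", {
  tr <- randomTree(6, seed = 2, range = c(0.05, 0.5))
  Q <- buildRateMatrix(randomExchangeability(7),
                       randomFrequencies(2, floor = 0.5))
  msa <- simulateAlignment(tr, Q, 5000, seed = 9)
  start <- tr
  start$edge.length <- rep(0.1, nrow(tr$edge))
  fit <- optimizeBranchLengths(msa, start, Q)
  truth <- stats::reorder(tr, "postorder")$edge.length
  rel <- abs(fit$edge.length - truth) / truth
  expect_lt(max(rel[truth >= 0.05]), 0.15)
})

test_that("branch scale factor is recovered and self-consistent", {
  tr <- randomTree(6, seed = 5, range = c(0.1, 0.4))
  Q <- buildRateMatrix(randomExchangeability(5), randomFrequencies(5))
  msa <- simulateAlignment(tr, Q, 1200, seed = 11)
  base <- optimizeBranchLengths(msa, tr, Q)
  ## full data against its own ML tree: s = 1
  sc <- fitBranchScale(msa, base, Q)
  expect_equal(sc$s, 1, tolerance = 1e-3)
  ## data simulated on 2x the tree: s ~ 2
  tr2 <- tr; tr2$edge.length <- 2 * tr$edge.length
  msa2 <- simulateAlignment(tr2, Q, 1200, seed = 12)
  sc2 <- fitBranchScale(msa2, tr, Q)
  expect_equal(sc2$s, 2, tolerance = 0.2)
  expect_false(sc2$boundary)
  ## disjoint taxon sets are an error
  other <- setNames(as.character(msa), paste0("z", 1:6))
  expect_error(fitBranchScale(other, tr, Q), "empty intersection")
})

test_that("exchangeability fit recovers a planted sparse process", {
  aa <- aminoAcids()
  rhoM <- matrix(0.05, 20, 20, dimnames = list(aa, aa))
  for (p in list(c("L", "I"), c("A", "T"), c("G", "S"),
                 c("V", "I"), c("F", "Y"), c("R", "K")))
    rhoM[p[1], p[2]] <- rhoM[p[2], p[1]] <- 8
  diag(rhoM) <- 0
  Rtrue <- exchangeabilityMatrix(rhoM)
  tr <- randomTree(10, seed = 4, range = c(0.05, 0.3))
  pi <- randomFrequencies(4, floor = 0.5)
  msa <- simulateAlignment(tr, buildRateMatrix(Rtrue, pi), 1000, seed = 8)
  fit <- fitExchangeabilities(msa, tr, method = "joint")
  piHat <- frequencies(fit)
  truthNorm <- rhoM / buildRateMatrix(Rtrue, piHat)@scale
  r <- cor(rho(fit)[lower.tri(rhoM)], truthNorm[lower.tri(rhoM)])
  expect_gt(r, 0.9)
  ## trace bookkeeping
  expect_identical(nrow(fitTrace(fit)), 1L)
  expect_true(is.finite(logLik(fit)))
  ## starting at the truth: the fit cannot do worse than the truth's logL
  Qtrue <- buildRateMatrix(Rtrue, piHat)
  llTruth <- attr(optimizeBranchLengths(msa, tr, Qtrue), "logLik")
  expect_gte(logLik(fit) + 0.5, llTruth)
})

test_that("joint and cyclic strategies agree on a small dataset", {
  fx <- makeFixture(sharedSupportSpec(groupSizes = 150L, nTaxa = 6L,
                                      seed = 13))
  fj <- fitExchangeabilities(fx$msa, fx$tree, method = "joint",
                             control = fastFit$control)
  fc <- fitExchangeabilities(fx$msa, fx$tree, method = "cyclic",
                             control = c(fastFit$control,
                                         list(cycleTol = 0.005)))
  expect_lt(abs(logLik(fj) - logLik(fc)), 0.1)
  expect_true(fj@converged)
})

test_that("published seed matrices load in canonical order", {
  skip_if_not_installed("phangorn")
  sm <- seedMatrices(c("uniform", "mtmam", "WAG"))
  expect_named(sm, c("uniform", "mtmam", "WAG"))
  for (m in sm) expect_true(validObject(m))
  ## mtmam should be far from uniform
  expect_gt(matrixDistance(sm$mtmam, sm$uniform), 1)
})
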