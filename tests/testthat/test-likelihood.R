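test_that("pruning equals the two-taxon closed form", {
  tr <- structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
                       edge.length = c(0.2, 0.35),
                       tip.label = c("a", "b"), Nnode = 1L),
                  class = "phylo")
  Q <- buildRateMatrix(randomExchangeability(1), randomFrequencies(1))
  pi <- frequencies(Q)
  msa <- c(a = "A", b = "R")
  P <- transitionMatrix(Q, 0.55)
  expect_equal(logLikelihood(msa, tr, Q), log(pi[1] * P["A", "R"]),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("pruning matches brute-force enumeration on small trees", {
  for (s in 1:6) {
    nt <- sample(3:5, 1)
    tr <- randomTree(nt, seed = s)
    Q <- buildRateMatrix(randomExchangeability(s), randomFrequencies(s))
    msa <- simulateAlignment(tr, Q, 8, seed = s + 50)
    expect_equal(logLikelihood(msa, tr, Q), bruteForceLogLik(msa, tr, Q),
                 tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to rooting and exchangeability scale", {
  tr <- randomTree(7, seed = 3)
  R <- randomExchangeability(3)
  pi <- randomFrequencies(3)
  Q <- buildRateMatrix(R, pi)
  msa <- simulateAlignment(tr, Q, 100, seed = 7)
  base <- logLikelihood(msa, tr, Q)
  for (og in c(1, 3, 5)) {
    rer <- ape::root(tr, outgroup = tr$tip.label[og], resolve.root = TRUE)
    expect_equal(logLikelihood(msa, rer, Q), base, tolerance = 1e-8)
  }
  Qs <- buildRateMatrix(exchangeabilityMatrix(13 * rho(R)), pi)
  expect_equal(logLikelihood(msa, tr, Qs), base, tolerance = 1e-9)
})

test_that("likelihood agrees with an independent phylogenetics package", {
  skip_if_not_installed("phangorn")
  tr <- randomTree(6, seed = 8)
  R <- randomExchangeability(8)
  pi <- randomFrequencies(8)
  Q <- buildRateMatrix(R, pi)
  msa <- simulateAlignment(tr, Q, 150, seed = 2)
  pd <- phangorn::phyDat(do.call(rbind, strsplit(as.character(msa), "")),
                         type = "AA")
  fit <- phangorn::pml(tr, pd, bf = pi, Q = rho(R)[lower.tri(rho(R))])
  expect_equal(logLikelihood(msa, tr, Q), fit$logLik, tolerance = 1e-6)
})

test_that("gaps and pattern compression do not corrupt the likelihood", {
  tr <- randomTree(4, seed = 12)
  Q <- buildRateMatrix(randomExchangeability(12), randomFrequencies(12))
  msa <- as.character(simulateAlignment(tr, Q, 12, seed = 1))
  ## duplicate columns: likelihood is additive over sites
  doubled <- setNames(paste0(msa, msa), names(msa))
  expect_equal(logLikelihood(doubled, tr, Q),
               2 * logLikelihood(msa, tr, Q), tolerance = 1e-9)
  ## a gapped site contributes the marginal over the missing tip
  gapped <- msa
  substr(gapped[1], 1, 1) <- "-"
  expect_equal(logLikelihood(gapped, tr, Q),
               bruteForceLogLik(gapped, tr, Q), tolerance = 1e-8)
  expect_error(logLikelihood(setNames(msa, c("a", "b", "x", "y")), tr, Q),
               "unmatched")
})

test_that("analytic gradients match central finite differences", {
  tr <- randomTree(5, seed = 21)
  rhoM <- rho(randomExchangeability(21))
  pi <- randomFrequencies(21)
  msa <- simulateAlignment(tr, buildRateMatrix(exchangeabilityMatrix(rhoM),
                                               pi), 60, seed = 4)
  prep <- aaSiteClass:::.prepTreeData(msa, tr)
  pairs <- aaSiteClass:::.freePairs(c("W", "V"))
  g <- aaSiteClass:::.gradEval(prep, rhoM, pi, pairs, TRUE)
  ll <- function(rm, tv) {
    p <- prep; p$t <- tv
    aaSiteClass:::.gradEval(p, rm, pi, pairs, FALSE)$loglik
  }
  eps <- 1e-4
  set.seed(5)
  for (m in sample(nrow(pairs), 5)) {
    i <- pairs[m, 1]; j <- pairs[m, 2]
    up <- rhoM; up[i, j] <- up[j, i] <- up[i, j] * exp(eps)
    dn <- rhoM; dn[i, j] <- dn[j, i] <- dn[i, j] * exp(-eps)
    num <- (ll(up, prep$t) - ll(dn, prep$t)) / (2 * eps)
    expect_equal(g$grad_theta[m], num, tolerance = 1e-4)
  }
  for (e in sample(length(prep$t), 3)) {
    up <- prep$t; up[e] <- up[e] + eps
    dn <- prep$t; dn[e] <- dn[e] - eps
    num <- (ll(rhoM, up) - ll(rhoM, dn)) / (2 * eps)
    expect_equal(g$grad_t[e], num, tolerance = 1e-4)
  }
})

test_that("simulation is deterministic, stationary and seed-sensitive", {
  tr <- randomTree(6, seed = 31)
  Q <- buildRateMatrix(randomExchangeability(31), randomFrequencies(31))
  a <- simulateAlignment(tr, Q, 40, seed = 9)
  b <- simulateAlignment(tr, Q, 40, seed = 9)
  expect_identical(as.character(a), as.character(b))
  expect_false(identical(as.character(simulateAlignment(tr, Q, 40, seed = 10)),
                         as.character(a)))
  ## zero-length star tree: all sequences identical to the root draw
  star <- ape::stree(5, "star")
  star$edge.length <- rep(0, 5)
  s0 <- simulateAlignment(star, Q, 30, seed = 2)
  expect_identical(length(unique(as.character(s0))), 1L)
  ## long branches: observed frequencies approach pi within 3 SE
  star$edge.length <- rep(50, 5)
  big <- simulateAlignment(star, Q, 4000, seed = 3)
  obs <- empiricalFrequencies(big, pseudocount = 0)
  n <- 5 * 4000
  se <- sqrt(frequencies(Q) * (1 - frequencies(Q)) / n)
  expect_true(all(abs(obs - frequencies(Q)) < 3 * se + 1e-3))
})
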