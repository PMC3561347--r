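test_that("empirical frequencies count canonical residues with a pseudocount", {
  ## equal counts of all residues -> uniform
  msa <- c(a = paste(aminoAcids(), collapse = ""),
           b = paste(rev(aminoAcids()), collapse = ""))
  expect_equal(unname(empiricalFrequencies(msa)), rep(0.05, 20),
               tolerance = 1e-6)
  ## single-residue alignment: pi_A ~ 1, others positive
  pa <- empiricalFrequencies(c(a = "AAAA", b = "AAAA"))
  expect_gt(pa[["A"]], 0.999)
  expect_true(all(pa > 0))
  ## hand normalization without pseudocount
  p <- empiricalFrequencies(c(a = "AAAAAGGGGG", b = "AAAAAGGGGG"),
                            pseudocount = 0)
  expect_equal(p[["A"]], 0.5)
  expect_equal(p[["G"]], 0.5)
  ## gaps excluded
  expect_equal(empiricalFrequencies(c(a = "A---"), pseudocount = 0)[["A"]], 1)
  expect_error(empiricalFrequencies(c(a = "----")), "empty subset")
})

test_that("rate matrix construction normalizes, balances and ignores scale", {
  piU <- rep(0.05, 20)
  Q <- buildRateMatrix(exchangeabilityMatrix(matrix(1, 20, 20)), piU)
  q <- rateMatrix(Q)
  ## all-ones R with uniform pi: every off-diagonal rate 1/19
  off <- q; diag(off) <- NA
  expect_equal(unname(off[!is.na(off)]), rep(1 / 19, 380))
  expect_lt(max(abs(rowSums(q))), 1e-10)
  expect_equal(-sum(piU * diag(q)), 1, tolerance = 1e-10)
  ## detailed balance and scale invariance on a random model
  R <- randomExchangeability(2)
  pi <- randomFrequencies(2)
  Q2 <- buildRateMatrix(R, pi)
  bal <- pi * rateMatrix(Q2) - t(pi * rateMatrix(Q2))
  expect_lt(max(abs(bal)), 1e-10)
  Q7 <- buildRateMatrix(exchangeabilityMatrix(7 * rho(R)), pi)
  expect_equal(rateMatrix(Q7), rateMatrix(Q2), tolerance = 1e-12)
  expect_error(buildRateMatrix(R, c(rep(0.1, 10), rep(0, 10))),
               "pseudocount")
})

test_that("transition matrices match the 20-state equal-rates closed form", {
  Q <- buildRateMatrix(exchangeabilityMatrix(matrix(1, 20, 20)), rep(0.05, 20))
  expect_equal(transitionMatrix(Q, 0), diag(20), tolerance = 1e-12,
               ignore_attr = TRUE)
  for (t in c(0.01, 0.1, 0.5, 1, 2, 5, 20)) {
    P <- transitionMatrix(Q, t)
    expect_equal(unname(diag(P)),
                 rep(1 / 20 + (19 / 20) * exp(-(20 / 19) * t), 20),
                 tolerance = 1e-10)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0))
  }
  ## semigroup property on a random model
  Q2 <- buildRateMatrix(randomExchangeability(4), randomFrequencies(4))
  P1 <- transitionMatrix(Q2, 0.3)
  P2 <- transitionMatrix(Q2, 0.7)
  expect_equal(P1 %*% P2, transitionMatrix(Q2, 1.0), tolerance = 1e-8)
  expect_error(transitionMatrix(Q2, -0.1), ">= 0")
})

test_that("exchangeability matrices validate and round-trip the pair layout", {
  expect_error(new("ExchangeabilityMatrix",
                   rho = matrix(-1, 20, 20,
                                dimnames = list(aminoAcids(), aminoAcids()))),
               "non-negative")
  R <- randomExchangeability(9)
  v <- aaSiteClass:::.columnLowerToPaml(rho(R)[lower.tri(rho(R))])
  back <- exchangeabilityMatrix(v)
  expect_equal(rho(back), rho(R))
})
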