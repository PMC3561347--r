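## Shared helpers: tiny trees, random reversible models, and the
## brute-force likelihood oracle (explicit sum over all internal-state
## combinations) used to validate the pruning engine.

randomExchangeability <- function(seed = 1L) {
  set.seed(seed)
  rho <- matrix(rexp(400) + 0.05, 20, 20)
  rho <- rho + t(rho)
  diag(rho) <- 0
  exchangeabilityMatrix(rho)
}

randomFrequencies <- function(seed = 1L, floor = 0.2) {
  set.seed(seed)
  pi <- rexp(20) + floor
  pi / sum(pi)
}

randomTree <- function(nTips, seed = 1L, range = c(0.05, 0.5)) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(nTips))
  tr$edge.length <- runif(nrow(tr$edge), range[1], range[2])
  tr
}

## Likelihood by explicit enumeration of internal-node states; exponential
## in the number of internal nodes, so only usable for <= 5 tips.
bruteForceLogLik <- function(msa, tree, Q) {
  m <- do.call(rbind, strsplit(as.character(msa), ""))
  rownames(m) <- names(msa)
  tree <- stats::reorder(tree, "postorder")
  m <- m[tree$tip.label, , drop = FALSE]
  states <- matrix(match(m, aminoAcids()), nrow(m))
  ntip <- nrow(m)
  nnode <- tree$Nnode
  pi <- frequencies(Q)
  Plist <- lapply(seq_len(nrow(tree$edge)),
                  function(e) transitionMatrix(Q, tree$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(1:20), nnode)))
  total <- 0
  for (site in seq_len(ncol(states))) {
    s <- 0
    for (g in seq_len(nrow(grid))) {
      full <- c(states[, site], grid[g, ])
      pr <- pi[full[ntip + 1L]]
      for (e in seq_len(nrow(tree$edge))) {
        child <- full[tree$edge[e, 2L]]
        if (is.na(child)) next  # gapped tip: sum_s' P[s, s'] = 1
        pr <- pr * Plist[[e]][full[tree$edge[e, 1L]], child]
        if (pr == 0) break
      }
      s <- s + pr
    }
    total <- total + log(s)
  }
  total
}

## fast fit options shared by the heavier integration tests
fastFit <- list(method = "joint",
                control = list(thetaMin = log(1e-2), thetaMax = log(1e2)))
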