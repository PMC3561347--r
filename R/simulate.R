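#' Simulate an amino-acid alignment along a tree
#'
#' Root states are drawn from the stationary frequencies and evolved along
#' every branch with the transition matrices of the supplied rate matrix.
#' Deterministic given `seed`.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param Q a [RateMatrix-class].
#' @param nSites number of sites (>= 1).
#' @param seed integer seed.
#' @return An `AAStringSet` named by the tree's tip labels.
#' @export
simulateAlignment <- function(tree, Q, nSites, seed = 1L) {
  if (nSites < 1L) stop("nSites must be >= 1")
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nNodes <- ntip + tree$Nnode
  eg <- .eigenQ(Q)
  E <- nrow(tree$edge)
  states <- matrix(0L, nNodes, nSites)
  withSeed(seed, {
    states[ntip + 1L, ] <- sample.int(20L, nSites, replace = TRUE,
                                      prob = eg$pi)
    for (e in rev(seq_len(E))) {  # preorder: parents before children
      u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
      P <- eg$V %*% (exp(eg$lambda * tree$edge.length[e]) * eg$Vinv)
      P[P < 0] <- 0
      for (s in 1:20) {
        idx <- which(states[u, ] == s)
        if (length(idx))
          states[v, idx] <- sample.int(20L, length(idx), replace = TRUE,
                                       prob = P[s, ])
      }
    }
  })
  aa <- aminoAcids()
  seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1L,
                function(s) paste(aa[s], collapse = ""))
  Biostrings::AAStringSet(setNames(seqs, tree$tip.label))
}
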