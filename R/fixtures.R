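#' Specification for a synthetic group-structured alignment
#'
#' Describes a fixture in which disjoint blocks of sites evolve under
#' group-specific frequency profiles and exchangeability matrices on one
#' shared tree.  The defaults emulate the class structure reported for
#' mitochondrial proteins: three groups with concentrated, largely disjoint
#' dominant-residue profiles - a large hydrophobic group dominated by
#' leucine and isoleucine, a hydrophilic helix-amenable group dominated by
#' alanine and threonine, and a small group dominated by glycine, proline,
#' serine and asparagine - each exchanging fast among its own dominant residues and
#' slowly elsewhere.
#'
#' @param nTaxa number of tips of the shared random tree (default 75,
#'   the order of a genome-wide vertebrate sampling).
#' @param groupSizes per-group site counts (default 100, 60, 40).
#' @param frequencies list of 20-vectors (one per group); defaults as
#'   above.
#' @param matrices list of exchangeability matrices (one per group);
#'   defaults: distinct sparse-dominant matrices among each group's
#'   dominant residues.
#' @param branchRange uniform range for the tree's branch lengths
#'   (default 0.5 - 1.2 expected substitutions per site: mitochondrial
#'   protein alignments spanning a class such as mammals are deeply
#'   diverged, and sites need enough substitutions to express their
#'   group's exchange process rather than their root state).
#' @param profileConcentration Dirichlet precision for per-site equilibrium
#'   profiles: each site draws its own frequency vector from
#'   Dirichlet(concentration x group profile), emulating the residual
#'   site-to-site heterogeneity within a class that real alignments show.
#'   `Inf` gives every site exactly the group profile.  Default 50.
#' @param seed integer seed for tree generation and simulation.
#' @return A list of class `FixtureSpec`.
#' @export
fixtureSpec <- function(nTaxa = 75L, groupSizes = c(100L, 60L, 40L),
                        frequencies = NULL, matrices = NULL,
                        branchRange = c(0.5, 1.2),
                        profileConcentration = 50, seed = 1L) {
  k <- length(groupSizes)
  if (any(groupSizes < 1L)) stop("group site counts must be >= 1")
  if (is.null(frequencies)) frequencies <- .defaultGroupFrequencies(k)
  if (is.null(matrices)) matrices <- .defaultGroupMatrices(k)
  if (length(frequencies) != k || length(matrices) != k)
    stop("need one frequency profile and one matrix per group")
  frequencies <- lapply(frequencies, .checkFrequencies)
  structure(list(nTaxa = as.integer(nTaxa),
                 groupSizes = as.integer(groupSizes),
                 frequencies = frequencies, matrices = matrices,
                 branchRange = branchRange,
                 profileConcentration = profileConcentration,
                 seed = as.integer(seed)),
            class = "FixtureSpec")
}

## concentrated profiles on largely disjoint dominant residue sets
.defaultGroupFrequencies <- function(k) {
  aa <- aminoAcids()
  mk <- function(weights) {
    v <- setNames(rep(0.001, 20), aa)
    v[names(weights)] <- weights
    v / sum(v)
  }
  all <- list(
    mk(c(L = 0.20, I = 0.19, V = 0.18, F = 0.17, M = 0.16)),
    mk(c(A = 0.20, T = 0.19, K = 0.18, E = 0.17, Q = 0.16)),
    mk(c(G = 0.23, P = 0.23, S = 0.22, N = 0.21)))
  if (k > 3L) stop("default profiles cover at most 3 groups")
  all[seq_len(k)]
}

## distinct exchangeability structures per group: conservative exchange is
## fast among each group's dominant (physiochemically similar) residues
.defaultGroupMatrices <- function(k) {
  boost <- function(domset, hi = 12, lo = 4) {
    aa <- aminoAcids()
    r <- matrix(lo, 20, 20, dimnames = list(aa, aa))
    r[domset, domset] <- hi
    diag(r) <- 0
    exchangeabilityMatrix(r)
  }
  all <- list(
    boost(c("L", "I", "V", "F", "M")),
    boost(c("A", "T", "K", "E", "Q")),
    boost(c("G", "P", "S", "N")))
  if (k > 3L) stop("default matrices cover at most 3 groups")
  all[seq_len(k)]
}

#' Generate a group-structured synthetic alignment
#'
#' Simulates one alignment block per group under the group's rate matrix on
#' a shared random tree, concatenates the blocks, and shuffles the site
#' order; the returned partition map records the true group of every site.
#' Deterministic given the spec's seed.
#'
#' @param spec a [fixtureSpec()].
#' @return List: `msa` (`AAStringSet`), `tree`, `map` (integer true-group
#'   labels per site), `frequencies`, `matrices`, `spec`.
#' @export
makeFixture <- function(spec = fixtureSpec()) {
  stopifnot(inherits(spec, "FixtureSpec"))
  k <- length(spec$groupSizes)
  tree <- withSeed(deriveSeed(spec$seed, "tree"), {
    ## unrooted: under a reversible model only the sum of the two branches
    ## incident to a root of degree two is identifiable
    tr <- ape::unroot(ape::rtree(spec$nTaxa))
    tr$edge.length <- runif(nrow(tr$edge), spec$branchRange[1],
                            spec$branchRange[2])
    tr
  })
  blocks <- lapply(seq_len(k), function(g) {
    if (is.infinite(spec$profileConcentration)) {
      Q <- buildRateMatrix(spec$matrices[[g]], spec$frequencies[[g]])
      return(.asResidueMatrix(simulateAlignment(
        tree, Q, spec$groupSizes[g],
        seed = deriveSeed(spec$seed, "sim", g))))
    }
    ## per-site equilibrium profiles: Dirichlet variation over the group's
    ## dominant residues (weight >= 0.05); rare residues keep their fixed
    ## small weights, so no site is dominated by an atypical residue
    w <- spec$frequencies[[g]]
    dom <- w >= 0.05
    alpha <- spec$profileConcentration * w[dom]
    cols <- lapply(seq_len(spec$groupSizes[g]), function(s) {
      piS <- withSeed(deriveSeed(spec$seed, "pi", g, s), {
        z <- rgamma(length(alpha), shape = alpha)
        z <- z + 1e-8
        out <- w
        out[dom] <- sum(w[dom]) * z / sum(z)
        out / sum(out)
      })
      Q <- buildRateMatrix(spec$matrices[[g]], piS)
      .asResidueMatrix(simulateAlignment(tree, Q, 1L,
                                         seed = deriveSeed(spec$seed,
                                                           "sim", g, s)))
    })
    do.call(cbind, cols)
  })
  m <- do.call(cbind, blocks)
  labels <- rep(seq_len(k), spec$groupSizes)
  perm <- withSeed(deriveSeed(spec$seed, "shuffle"), sample.int(ncol(m)))
  m <- m[, perm, drop = FALSE]
  labels <- labels[perm]
  msa <- Biostrings::AAStringSet(apply(m, 1L, paste, collapse = ""))
  names(msa) <- tree$tip.label
  list(msa = msa, tree = tree, map = labels,
       frequencies = spec$frequencies, matrices = spec$matrices, spec = spec)
}

#' Rand index between two partitions
#'
#' Probability that a random pair of sites is treated concordantly (placed
#' together in both partitions or apart in both) - invariant to label
#' permutation, so suitable for scoring recovered against planted classes.
#'
#' @param a,b integer label vectors of equal length.
#' @return Scalar in \[0, 1\].
#' @export
randIndex <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  n <- length(a)
  if (n < 2L) return(1)
  tab <- table(a, b)
  sumsq <- function(x) sum(x * (x - 1) / 2)
  together <- sumsq(tab)
  pairsA <- sumsq(rowSums(tab))
  pairsB <- sumsq(colSums(tab))
  total <- n * (n - 1) / 2
  (total + 2 * together - pairsA - pairsB) / total
}

#' Shared-support fixture: classes differing only in their exchange process
#'
#' A complementary fixture flavor for validating matrix-level machinery
#' (noise analysis, likelihood cross-validation).  All classes share one
#' equal-frequency profile over eight residues (A L I V S T G P), but each
#' class exchanges fast along its own disjoint perfect matching of those
#' residues and slowly elsewhere.  Because the classes share residue
#' support, a matrix fitted to one class is genuinely wrong for another -
#' unlike profiles with disjoint dominant sets, where each class informs
#' only its own block of the matrix.
#'
#' @param groupSizes per-class site counts (up to 3 classes; default
#'   250, 150).
#' @param nTaxa tree tips (default 8).
#' @param fast exchangeability on the class's matched pairs (default 12).
#' @param slow exchangeability among the other shared-residue pairs
#'   (default 0.5).
#' @param seed integer seed.
#' @return A [fixtureSpec()] object; pass to [makeFixture()].
#' @export
sharedSupportSpec <- function(groupSizes = c(250L, 150L), nTaxa = 8L,
                              fast = 12, slow = 0.5, seed = 1L) {
  k <- length(groupSizes)
  if (k > 3L) stop("at most 3 classes have disjoint matchings defined")
  aa <- aminoAcids()
  res8 <- c("A", "L", "I", "V", "S", "T", "G", "P")
  prof <- setNames(rep(1e-8, 20), aa)
  prof[res8] <- 0.125
  prof <- prof / sum(prof)
  matchings <- list(
    list(c("A", "L"), c("I", "V"), c("S", "T"), c("G", "P")),
    list(c("A", "G"), c("L", "S"), c("I", "T"), c("V", "P")),
    list(c("A", "V"), c("L", "I"), c("S", "P"), c("T", "G")))
  mats <- lapply(matchings[seq_len(k)], function(mm) {
    r <- matrix(1e-4, 20, 20, dimnames = list(aa, aa))
    r[res8, res8] <- slow
    for (p in mm) { r[p[1], p[2]] <- fast; r[p[2], p[1]] <- fast }
    diag(r) <- 0
    exchangeabilityMatrix(r)
  })
  fixtureSpec(nTaxa = nTaxa, groupSizes = groupSizes,
              frequencies = rep(list(prof), k), matrices = mats,
              profileConcentration = Inf, seed = seed)
}
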