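#' Euclidean distance between two exchangeability matrices
#'
#' The square root of the summed squared differences over the 190
#' off-diagonal pairs.  Exchangeabilities are only defined up to scale, so
#' both matrices must be on the mean-rate-one scale before comparison;
#' matrices emitted by [fitExchangeabilities()] already are, and frequency
#' vectors can be supplied to renormalize arbitrary inputs.
#'
#' @param A,B [ExchangeabilityMatrix-class] objects (or 20 x 20 symmetric
#'   matrices).
#' @param piA,piB optional frequency vectors; when given, the corresponding
#'   matrix is rescaled so its rate matrix has mean rate one.
#' @return Non-negative scalar; zero iff the matrices are equal.
#' @export
matrixDistance <- function(A, B, piA = NULL, piB = NULL) {
  a <- .pairValues(A, piA)
  b <- .pairValues(B, piB)
  sqrt(sum((a - b)^2))
}

.pairValues <- function(R, pi = NULL) {
  r <- if (is(R, "ExchangeabilityMatrix")) R@rho else
    exchangeabilityMatrix(R)@rho
  if (!is.null(pi)) r <- r / buildRateMatrix(exchangeabilityMatrix(r), pi)@scale
  r[lower.tri(r)]
}

#' Per-pair difference table between two exchangeability matrices
#'
#' The 190-row table of elementwise differences behind matrix heat maps;
#' `A` minus `B` per unordered residue pair.  `B` is exactly recoverable
#' from `A` and the table.
#'
#' @inheritParams matrixDistance
#' @return data.frame with columns `res_i`, `res_j`, `a`, `b`, `diff`.
#' @export
matrixDifference <- function(A, B) {
  p <- .allPairs()
  aa <- aminoAcids()
  a <- .pairValues(A); b <- .pairValues(B)
  ## lower.tri is column-wise; .allPairs() rows are in the same order
  data.frame(res_i = aa[p[, 1L]], res_j = aa[p[, 2L]],
             a = a, b = b, diff = a - b)
}

#' Random partition of sites into groups of fixed sizes
#'
#' Uniformly random assignment of `n` sites to `length(sizes)` groups with
#' exactly the requested sizes; the null model of the noise analysis.
#'
#' @param n number of sites.
#' @param sizes positive integers summing to `n`.
#' @param seed integer seed.
#' @return Integer vector of group labels in 1..k.
#' @export
randomPartition <- function(n, sizes, seed = 1L) {
  sizes <- as.integer(sizes)
  if (any(sizes <= 0L)) stop("sizes must be positive")
  if (sum(sizes) != n) stop("sizes must sum to n (", sum(sizes), " != ", n, ")")
  labels <- integer(n)
  withSeed(seed, {
    labels[sample.int(n)] <- rep(seq_along(sizes), sizes)
  })
  labels
}

#' Noise analysis: do class-specific matrices exceed random structure?
#'
#' Fits an exchangeability matrix to every class of the observed partition
#' and to every class of `S` random partitions with the same class sizes,
#' measures each matrix's distance to a reference matrix (fitted to the
#' complete data), and tests per class - one-sample t-test, one-sided,
#' df = S-1 - whether the mean random distance is less than the observed
#' distance.  Bonferroni correction is applied over the k classes.  A failed
#' replicate fit is dropped with a warning (S is reduced in the result).
#'
#' @param msa alignment with named sequences.
#' @param tree fixed topology with branch lengths.
#' @param assignment observed site classes: a [SiteClassPartition-class] or
#'   an integer label vector.
#' @param referenceR reference matrix (mean-rate-one scale), usually the
#'   fit to the complete data.
#' @param S random partitions (default 50; at least 2).
#' @param seed integer master seed.
#' @param fitOptions list passed on to [fitExchangeabilities()]: `method`,
#'   `initials` (default: start from `referenceR`), `control`.
#' @param classFits optional list of pre-computed observed class fits
#'   ([ExchangeabilityFit-class]), to avoid refitting.
#' @return A [NoiseAnalysis-class].
#' @export
noiseAnalysis <- function(msa, tree, assignment, referenceR, S = 50L,
                          seed = 1L, fitOptions = list(), classFits = NULL) {
  if (S < 2L) stop("S must be >= 2 (the t-test needs df >= 1)")
  labels <- if (is(assignment, "SiteClassPartition")) siteLabels(assignment)
            else as.integer(assignment)
  k <- max(labels)
  sizes <- tabulate(labels, nbins = k)
  if (any(sizes == 0L)) stop("every class must contain at least one site")
  m <- .asResidueMatrix(msa)
  refRho <- if (is(referenceR, "ExchangeabilityMatrix")) referenceR else
    exchangeabilityMatrix(referenceR)

  fitClass <- function(cols) {
    sub <- m[, cols, drop = FALSE]
    fitExchangeabilities(
      sub, tree,
      method = fitOptions$method %||% "cyclic",
      initials = fitOptions$initials %||% list(reference = refRho),
      control = fitOptions$control %||% list())
  }

  observed <- numeric(k)
  for (i in seq_len(k)) {
    fi <- if (!is.null(classFits)) classFits[[i]] else
      fitClass(which(labels == i))
    observed[i] <- matrixDistance(exchangeabilities(fi), refRho)
  }

  random <- matrix(NA_real_, 0L, k)
  for (j in seq_len(S)) {
    lab_j <- randomPartition(length(labels), sizes,
                             seed = deriveSeed(seed, "noise", j))
    row <- try(vapply(seq_len(k), function(i)
      matrixDistance(exchangeabilities(fitClass(which(lab_j == i))), refRho),
      0), silent = TRUE)
    if (inherits(row, "try-error")) {
      warning("replicate ", j, " failed and was dropped")
      next
    }
    random <- rbind(random, row)
  }
  Sused <- nrow(random)
  if (Sused < 2L) stop("fewer than 2 successful replicates; cannot test")
  tt <- lapply(seq_len(k), function(i)
    t.test(random[, i], mu = observed[i], alternative = "less"))
  pv <- vapply(tt, `[[`, 0, "p.value")
  new("NoiseAnalysis", observed = observed, random = unname(random),
      tStat = vapply(tt, function(x) unname(x$statistic), 0),
      pValue = pv, pBonferroni = pmin(1, pv * k), S = Sused)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabulate a noise analysis
#'
#' One row per class: observed distance, mean and SD of the random
#' distances, t statistic, p-value and Bonferroni-adjusted p-value.
#'
#' @param x a [NoiseAnalysis-class].
#' @return data.frame in the standard reporting schema.
#' @export
noiseTable <- function(x) {
  stopifnot(is(x, "NoiseAnalysis"))
  data.frame(class = seq_along(x@observed),
             d_obs = x@observed,
             mean_d_rand = colMeans(x@random),
             sd_d_rand = apply(x@random, 2L, sd),
             t = x@tStat, p = x@pValue, p_bonf = x@pBonferroni)
}

#' Per-branch relative difference between two trees
#'
#' (Bl_R / Bl_ref) - 1 per branch: 0 means no difference, positive values
#' mark branches longer under the class-specific matrix.
#'
#' @param treeR,treeRef trees with identical topologies.
#' @return Numeric vector, one entry per edge of the (postorder) reference
#'   tree; NA where the reference branch has zero length (flagged with a
#'   warning).
#' @export
branchRatio <- function(treeR, treeRef) {
  pair <- .matchTopology(treeR, treeRef)
  ratio <- pair$a$edge.length / pair$b$edge.length - 1
  zero <- pair$b$edge.length == 0
  if (any(zero)) {
    warning(sum(zero), " reference branch(es) of zero length; ratio undefined")
    ratio[zero] <- NA_real_
  }
  ratio
}

## reorder both trees postorder and verify they share one topology
.matchTopology <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label))
    stop("topology mismatch: different tip label sets")
  a <- stats::reorder(a, "postorder")
  b <- stats::reorder(b, "postorder")
  relab <- match(a$tip.label, b$tip.label)
  edgeKey <- function(tr, map = NULL) {
    ## identify each edge by the sorted set of tips below it
    ntip <- length(tr$tip.label)
    below <- vector("list", ntip + tr$Nnode)
    lab <- if (is.null(map)) seq_len(ntip) else map
    for (i in seq_len(ntip)) below[[i]] <- lab[i]
    for (e in seq_len(nrow(tr$edge))) {
      u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
      below[[u]] <- c(below[[u]], below[[v]])
    }
    vapply(tr$edge[, 2L], function(v)
      paste(sort(below[[v]]), collapse = ","), "")
  }
  ka <- edgeKey(a, relab)
  kb <- edgeKey(b)
  ord <- match(ka, kb)  # a's edge e corresponds to b's edge ord[e]
  if (any(is.na(ord)))
    stop("topology mismatch: trees differ in structure")
  bAligned <- a
  bAligned$edge.length <- b$edge.length[ord]
  list(a = a, b = bAligned)
}

#' Mix branch lengths across trees by class frequencies
#'
#' Per-branch weighted arithmetic mean of the branch lengths of several
#' trees with a shared topology - the whole-data branch-length summary of a
#' partitioned fit, weighting each class's tree by its share of sites.
#'
#' @param trees list of trees with identical topologies.
#' @param weights non-negative weights summing to 1 (class site
#'   frequencies).
#' @return A tree with the mixed branch lengths.
#' @export
mixBranchLengths <- function(trees, weights) {
  if (length(trees) < 1L) stop("need at least one tree")
  if (length(weights) != length(trees)) stop("one weight per tree")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  base <- stats::reorder(trees[[1L]], "postorder")
  mixed <- base$edge.length * weights[1L]
  for (i in seq_along(trees)[-1L]) {
    pair <- .matchTopology(base, trees[[i]])
    mixed <- mixed + pair$b$edge.length * weights[i]
  }
  base$edge.length <- mixed
  base
}
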