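## Internal: validate msa/tree, encode tip states, compress site patterns.
## Site-pattern compression is mandatory for tractability: identical
## alignment columns share one likelihood evaluation (weights carry the
## multiplicity).
.prepTreeData <- function(msa, tree, columns = NULL) {
  m <- .asResidueMatrix(msa)
  if (is.null(rownames(m))) stop("alignment sequences must be named")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  missing <- setdiff(tree$tip.label, rownames(m))
  extra <- setdiff(rownames(m), tree$tip.label)
  if (length(missing) || length(extra))
    stop("leaf labels do not match alignment names; unmatched: ",
         paste(c(missing, extra), collapse = " "))
  if (!is.null(columns)) m <- m[, columns, drop = FALSE]
  m <- m[tree$tip.label, , drop = FALSE]
  tree <- stats::reorder(tree, "postorder")
  states <- matrix(match(m, aminoAcids(), nomatch = 0L), nrow(m), ncol(m))
  keys <- apply(states, 2L, paste, collapse = ",")
  first <- which(!duplicated(keys))
  weights <- as.numeric(table(factor(keys, levels = keys[first])))
  list(states = states[, first, drop = FALSE], weights = weights,
       edge = tree$edge, t = tree$edge.length,
       nNodes = length(tree$tip.label) + tree$Nnode,
       root = length(tree$tip.label) + 1L, tree = tree,
       nSites = ncol(m))
}

## P(t) cube for all edges from one eigensystem
.pcube <- function(eg, t) {
  E <- length(t)
  P <- array(0, c(20L, 20L, E))
  for (e in seq_len(E)) {
    Pe <- eg$V %*% (exp(eg$lambda * t[e]) * eg$Vinv)
    Pe[Pe < 0] <- 0
    P[, , e] <- Pe
  }
  P
}

#' Phylogenetic log-likelihood of an alignment under a reversible model
#'
#' Felsenstein pruning over compressed site patterns, with stationary
#' frequencies at the (arbitrary) root; by reversibility the value is
#' invariant to root placement.
#'
#' @param msa alignment with named sequences matching the tree's tips.
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param Q a [RateMatrix-class].
#' @param perSite if TRUE, also return per-site log-likelihoods.
#' @return The log-likelihood (scalar), or a list with `logLik` and
#'   `siteLogLik` when `perSite = TRUE`.
#' @export
logLikelihood <- function(msa, tree, Q, perSite = FALSE) {
  prep <- .prepTreeData(msa, tree)
  eg <- .eigenQ(Q)
  res <- cpp_loglik(prep$states, prep$weights, prep$edge,
                    .pcube(eg, prep$t), eg$pi, prep$nNodes, prep$root)
  if (!perSite) return(res$loglik)
  keys <- apply(matrix(match(.asResidueMatrix(msa)[tree$tip.label, ],
                             aminoAcids(), nomatch = 0L),
                       length(tree$tip.label)), 2L, paste, collapse = ",")
  first <- which(!duplicated(keys))
  idx <- match(keys, keys[first])
  list(logLik = res$loglik, siteLogLik = res$sitelik[idx])
}

## Internal: log-likelihood and analytic gradient at (theta, t).
## theta are log exchangeabilities of the free pairs; pairs/refPair fixed.
.gradEval <- function(prep, rhoMat, pi, pairs, gradTheta = TRUE) {
  rm <- buildRateMatrix(exchangeabilityMatrix(rhoMat), pi)
  eg <- .eigenQ(rm)
  rhoFree <- rhoMat[cbind(pairs[, 1L], pairs[, 2L])]
  res <- cpp_loglik_grad(prep$states, prep$weights, prep$edge, prep$t,
                         eg$V, eg$Vinv, eg$lambda, eg$pi,
                         prep$nNodes, prep$root,
                         as.integer(pairs[, 1L]), as.integer(pairs[, 2L]),
                         rhoFree, rm@scale, gradTheta)
  res
}
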