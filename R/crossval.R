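#' Randomly split a class's sites into training and validation halves
#'
#' Uniformly random 50/50 split; with an odd number of sites the extra one
#' goes to training.
#'
#' @param sites integer vector of site indices (>= 2 sites).
#' @param seed integer seed.
#' @return List with sorted integer vectors `T` and `V`.
#' @export
splitHalf <- function(sites, seed = 1L) {
  n <- length(sites)
  if (n < 2L) stop("need at least 2 sites to split")
  perm <- withSeed(seed, sample(sites))
  nT <- ceiling(n / 2)
  list(T = sort(perm[seq_len(nT)]), V = sort(perm[-seq_len(nT)]))
}

#' One replicate of the 50% likelihood cross-validation
#'
#' Each class is split in half; an exchangeability matrix is fitted to every
#' training half, and every validation half is scored under every training
#' matrix and under the complete-data (joint) matrix.  By default each
#' (validation set, matrix) evaluation re-optimizes branch lengths and uses
#' the validation set's empirical frequencies, since the exchangeabilities -
#' not the branch lengths - are the object under validation;
#' `reoptimizeBranches = FALSE` reuses the supplied tree's lengths instead.
#'
#' @param msa alignment with named sequences.
#' @param assignment site classes ([SiteClassPartition-class] or integer
#'   labels).
#' @param tree fixed topology with branch lengths.
#' @param jointR the complete-data matrix (mean-rate-one scale), supplied
#'   rather than refitted per replicate.
#' @param seed integer seed for the splits.
#' @param fitOptions list forwarded to [fitExchangeabilities()] for the
#'   training fits: `method`, `initials` (default: start from `jointR`),
#'   `control`.
#' @param reoptimizeBranches re-optimize branch lengths per evaluation
#'   (default TRUE).
#' @return List: `logL` ((k+1) x k matrix, rows R0 and the training
#'   matrices, columns the validation sets), `splits`, `trainingFits`.
#' @export
cvReplicate <- function(msa, assignment, tree, jointR, seed = 1L,
                        fitOptions = list(), reoptimizeBranches = TRUE) {
  labels <- if (is(assignment, "SiteClassPartition")) siteLabels(assignment)
            else as.integer(assignment)
  k <- max(labels)
  m <- .asResidueMatrix(msa)
  jointR <- if (is(jointR, "ExchangeabilityMatrix")) jointR else
    exchangeabilityMatrix(jointR)

  splits <- lapply(seq_len(k), function(i)
    splitHalf(which(labels == i), seed = deriveSeed(seed, "cvsplit", i)))
  trainingFits <- lapply(seq_len(k), function(i) {
    fitExchangeabilities(
      m[, splits[[i]]$T, drop = FALSE], tree,
      method = fitOptions$method %||% "cyclic",
      initials = fitOptions$initials %||% list(joint = jointR),
      control = fitOptions$control %||% list())
  })

  mats <- c(list(R0 = jointR),
            setNames(lapply(trainingFits, exchangeabilities),
                     paste0("R_T", seq_len(k))))
  logL <- matrix(NA_real_, k + 1L, k,
                 dimnames = list(names(mats), paste0("V", seq_len(k))))
  for (i in seq_len(k)) {
    sub <- m[, splits[[i]]$V, drop = FALSE]
    piV <- empiricalFrequencies(sub)
    for (nm in names(mats)) {
      Q <- buildRateMatrix(mats[[nm]], piV)
      logL[nm, i] <- tryCatch({
        if (reoptimizeBranches) {
          tr <- optimizeBranchLengths(sub, tree, Q,
                                      control = fitOptions$control %||% list())
          attr(tr, "logLik")
        } else logLikelihood(sub, tree, Q)
      }, error = function(e) NA_real_)
    }
  }
  list(logL = logL, splits = splits, trainingFits = trainingFits)
}

#' Summarize cross-validation replicates
#'
#' For every validation set V_i, the mean and standard deviation (over
#' replicates) of the log-likelihood advantage of the matching training
#' matrix R_Ti over each alternative matrix (the joint matrix and the other
#' training matrices).  Positive means favor the class-specific matrix.
#'
#' @param replicates list of [cvReplicate()] results (>= 2).
#' @return data.frame with columns `validation`, `alternative`,
#'   `meanDelta`, `sdDelta`.
#' @export
cvSummary <- function(replicates) {
  if (length(replicates) < 2L) stop("need at least 2 replicates")
  k <- ncol(replicates[[1L]]$logL)
  alts <- rownames(replicates[[1L]]$logL)
  out <- NULL
  for (i in seq_len(k)) {
    winner <- paste0("R_T", i)
    for (a in setdiff(alts, winner)) {
      deltas <- vapply(replicates, function(r)
        r$logL[winner, i] - r$logL[a, i], 0)
      out <- rbind(out, data.frame(
        validation = paste0("V", i), alternative = a,
        meanDelta = mean(deltas), sdDelta = sd(deltas)))
    }
  }
  out
}
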