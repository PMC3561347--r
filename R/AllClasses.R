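#' @import methods
#' @importFrom stats kmeans optim optimize sd t.test var setNames runif rexp
#' @importFrom utils read.table write.table head
#' @useDynLib aaSiteClass, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

setOldClass("phylo")

#' Canonical amino-acid order
#'
#' The one-letter codes of the 20 canonical amino acids in the order used by
#' every matrix and frequency vector in this package: A R N D C Q E G H I L K
#' M F P S T W Y V.  This is the classical PAML/property-table order; all
#' exchangeability matrices, rate matrices and frequency vectors are indexed
#' in it, and PAML-style `.dat` files are read and written in it.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aminoAcids()
aminoAcids <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

## symbols excluded from profile means and frequency counts
.GAP_SYMBOLS <- c("-", ".", "?")
.AMBIG_SYMBOLS <- c("X", "B", "Z", "J", "U", "O")

#' SiteProfiles: per-site mean physiochemical property vectors
#'
#' An n x 9 matrix of per-site means of the nine property scales, together
#' with the 1-based alignment column index of every retained site and the
#' number of sequences (canonical residues) that contributed to each mean.
#'
#' @slot profiles numeric matrix, one row per site, columns P1..P9.
#' @slot siteIds integer, 1-based MSA column indices.
#' @slot nSeqUsed integer, residues contributing to each site mean.
#' @export
setClass("SiteProfiles",
  representation(profiles = "matrix", siteIds = "integer", nSeqUsed = "integer"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@profiles) != 9L)
      msg <- c(msg, "profiles must have 9 columns (P1..P9)")
    if (nrow(object@profiles) != length(object@siteIds))
      msg <- c(msg, "siteIds length must equal number of profile rows")
    if (nrow(object@profiles) != length(object@nSeqUsed))
      msg <- c(msg, "nSeqUsed length must equal number of profile rows")
    if (length(object@profiles) && !all(is.finite(object@profiles)))
      msg <- c(msg, "all profile entries must be finite")
    if (length(msg)) msg else TRUE
  })

#' SiteClassPartition: a hard assignment of sites to classes
#'
#' @slot labels integer, per-site class in 1..k; class 1 is the largest.
#' @slot centroids k x 9 matrix of class centroids in property space.
#' @slot withinSS numeric(1), pooled within-class sum of squares (W_k).
#' @slot gapCurve the [GapCurve-class] used to select k, or NULL.
#' @slot ruleSatisfied logical(1), FALSE when no k satisfied the
#'   1-standard-error rule and the largest evaluated k was returned.
#' @export
setClass("SiteClassPartition",
  representation(labels = "integer", centroids = "matrix",
                 withinSS = "numeric", gapCurve = "ANY",
                 ruleSatisfied = "logical"),
  prototype(gapCurve = NULL, ruleSatisfied = TRUE),
  validity = function(object) {
    msg <- character()
    k <- nrow(object@centroids)
    if (length(object@labels) &&
        (min(object@labels) < 1L || max(object@labels) > k))
      msg <- c(msg, "labels must lie in 1..k")
    if (!all(seq_len(k) %in% object@labels))
      msg <- c(msg, "every class must contain at least one site")
    if (length(object@withinSS) != 1L || object@withinSS < 0)
      msg <- c(msg, "withinSS must be a single non-negative number")
    if (length(msg)) msg else TRUE
  })

#' GapCurve: gap statistics over a range of class counts
#'
#' @slot k integer vector of evaluated class counts (always starting at 1).
#' @slot gap numeric, Gap(k) per k.
#' @slot sk numeric, standard-error term per k (includes the sqrt(1+1/B)
#'   inflation).
#' @slot logW numeric, log pooled within-class dispersion of the data.
#' @slot logWref numeric, mean log dispersion over the reference draws.
#' @slot B integer(1), number of reference draws.
#' @export
setClass("GapCurve",
  representation(k = "integer", gap = "numeric", sk = "numeric",
                 logW = "numeric", logWref = "numeric", B = "integer"),
  validity = function(object) {
    msg <- character()
    n <- length(object@k)
    if (any(lengths(list(object@gap, object@sk, object@logW,
                         object@logWref)) != n))
      msg <- c(msg, "gap, sk, logW, logWref must match length of k")
    if (any(object@sk < 0)) msg <- c(msg, "sk must be non-negative")
    if (any(diff(object@k) != 1L)) msg <- c(msg, "k must be consecutive")
    if (length(msg)) msg else TRUE
  })

#' ExchangeabilityMatrix: symmetric amino-acid exchangeabilities
#'
#' The symmetric, frequency-independent component R of a reversible
#' 20-state substitution model, Q = R diag(pi).  The diagonal is zero and
#' the 190 off-diagonal pairs are non-negative; during optimization one
#' reference pair is held fixed, leaving 189 free parameters.
#'
#' @slot rho 20 x 20 symmetric non-negative matrix, zero diagonal, rows and
#'   columns in [aminoAcids()] order.
#' @slot refPair character(2), the amino-acid pair whose entry is fixed
#'   (not free) during optimization.
#' @export
setClass("ExchangeabilityMatrix",
  representation(rho = "matrix", refPair = "character"),
  prototype(refPair = c("W", "V")),
  validity = function(object) {
    msg <- character()
    r <- object@rho
    if (!all(dim(r) == c(20L, 20L)))
      msg <- c(msg, "rho must be 20 x 20")
    else {
      if (!isTRUE(all.equal(r, t(r), tolerance = 1e-8, check.attributes = FALSE)))
        msg <- c(msg, "rho must be symmetric")
      if (any(diag(r) != 0)) msg <- c(msg, "rho diagonal must be zero")
      if (any(r < 0)) msg <- c(msg, "rho entries must be non-negative")
      if (!identical(rownames(r), aminoAcids()) ||
          !identical(colnames(r), aminoAcids()))
        msg <- c(msg, "rho dimnames must be the canonical amino-acid order")
    }
    if (length(object@refPair) != 2L ||
        !all(object@refPair %in% aminoAcids()))
      msg <- c(msg, "refPair must name two canonical amino acids")
    if (length(msg)) msg else TRUE
  })

#' RateMatrix: normalized instantaneous rate matrix Q
#'
#' Built as q_ij = rho_ij * pi_j for i != j, diagonal set so rows sum to
#' zero, and the whole matrix rescaled so the mean substitution rate
#' -sum_i pi_i q_ii equals one (branch lengths are then expected
#' substitutions per site).
#'
#' @slot q 20 x 20 rate matrix after normalization.
#' @slot scale numeric(1), the normalization constant divided out.
#' @slot pi the stationary frequencies the matrix was built with.
#' @export
setClass("RateMatrix",
  representation(q = "matrix", scale = "numeric", pi = "numeric"),
  validity = function(object) {
    msg <- character()
    q <- object@q
    if (!all(dim(q) == c(20L, 20L))) msg <- c(msg, "q must be 20 x 20")
    else {
      if (max(abs(rowSums(q))) > 1e-8) msg <- c(msg, "rows of q must sum to 0")
      off <- q; diag(off) <- 0
      if (any(off < 0)) msg <- c(msg, "off-diagonal rates must be >= 0")
    }
    if (length(object@pi) != 20L || abs(sum(object@pi) - 1) > 1e-9)
      msg <- c(msg, "pi must be 20 frequencies summing to 1")
    if (length(msg)) msg else TRUE
  })

#' ExchangeabilityFit: result of maximum-likelihood estimation
#'
#' @slot rho the fitted [ExchangeabilityMatrix-class], rescaled so that the
#'   rate matrix built with `pi` has mean rate one.
#' @slot pi empirical frequencies used during the fit.
#' @slot tree the fitted tree (branch lengths at the optimum).
#' @slot logLik maximized log-likelihood.
#' @slot trace one row per (method, initial) run: method, initial, logLik,
#'   iterations, converged.
#' @slot converged logical(1) for the winning run.
#' @slot nonIdentifiable character, residues absent from the data whose
#'   exchangeabilities are reported but not informed by it.
#' @export
setClass("ExchangeabilityFit",
  representation(rho = "ExchangeabilityMatrix", pi = "numeric",
                 tree = "phylo", logLik = "numeric", trace = "data.frame",
                 converged = "logical", nonIdentifiable = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@logLik) != 1L || !is.finite(object@logLik))
      msg <- c(msg, "logLik must be a single finite number")
    if (length(object@pi) != 20L) msg <- c(msg, "pi must have length 20")
    if (length(msg)) msg else TRUE
  })

#' NoiseAnalysis: random-partition test of class structure
#'
#' @slot observed per-class distance d(R_i, R_0) between the class-specific
#'   and the reference matrix.
#' @slot random S x k matrix of distances d(R*_ij, R_0) for matrices fitted
#'   to random partitions of the same sizes.
#' @slot tStat,pValue,pBonferroni per-class one-sample t-test of whether the
#'   mean random distance is less than the observed distance (one-sided,
#'   df = S-1), with Bonferroni correction over the k classes.
#' @slot S integer(1), replicates actually used (failed fits are dropped).
#' @export
setClass("NoiseAnalysis",
  representation(observed = "numeric", random = "matrix", tStat = "numeric",
                 pValue = "numeric", pBonferroni = "numeric", S = "integer"),
  validity = function(object) {
    msg <- character()
    k <- length(object@observed)
    if (ncol(object@random) != k)
      msg <- c(msg, "random must have one column per class")
    if (any(object@observed < 0) || any(object@random < 0))
      msg <- c(msg, "distances must be non-negative")
    bad <- abs(object@pBonferroni -
               pmin(1, object@pValue * k)) > 1e-12
    if (any(bad)) msg <- c(msg, "pBonferroni must equal min(1, p * k)")
    if (length(msg)) msg else TRUE
  })
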