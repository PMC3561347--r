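#' Empirical amino-acid frequencies of an alignment (or subset)
#'
#' Counts canonical residues (gaps and ambiguity codes are excluded) and
#' normalizes with a small pseudocount added to every residue class, so
#' frequencies are strictly positive even for residues absent from the
#' subset - a necessary guard because some site classes are dominated by a
#' handful of amino acids.
#'
#' @param msa alignment in any representation accepted by [profileMatrix()].
#' @param pseudocount added to each of the 20 counts (default 1e-6).
#' @return Named numeric vector of 20 frequencies summing to 1.
#' @export
empiricalFrequencies <- function(msa, pseudocount = 1e-6) {
  m <- .asResidueMatrix(msa)
  counts <- table(factor(as.vector(m), levels = aminoAcids()))
  n <- sum(counts)
  if (n == 0L) stop("empty subset: no canonical residues to count")
  pi <- (as.numeric(counts) + pseudocount) / (n + 20 * pseudocount)
  setNames(pi, aminoAcids())
}

#' Construct an exchangeability matrix from pair values
#'
#' @param rho either a 20 x 20 symmetric matrix, or a vector of 190 values
#'   filling the lower triangle row-wise in [aminoAcids()] order (the
#'   PAML `.dat` layout: row r holds the pairs of residue r+1 with residues
#'   1..r).
#' @param refPair the pair fixed during optimization (default W, V).
#' @return An [ExchangeabilityMatrix-class].
#' @export
exchangeabilityMatrix <- function(rho, refPair = c("W", "V")) {
  aa <- aminoAcids()
  if (is.matrix(rho)) {
    r <- rho
    dimnames(r) <- list(aa, aa)
    diag(r) <- 0
    r <- (r + t(r)) / 2  # tolerate asymmetric rounding in inputs
  } else {
    if (length(rho) != 190L)
      stop("rho vector must have 190 entries (lower triangle)")
    r <- matrix(0, 20, 20, dimnames = list(aa, aa))
    r[lower.tri(r)] <- .pamlToColumnLower(rho)
    r <- r + t(r)
  }
  new("ExchangeabilityMatrix", rho = r, refPair = refPair)
}

## PAML .dat rows are the row-wise lower triangle (row r: pairs (r+1, 1..r));
## R's lower.tri fills column-wise.  Convert between the two orderings.
.pamlRowOrder <- function() {
  idx <- which(lower.tri(matrix(0, 20, 20)), arr.ind = TRUE)
  order(idx[, "row"], idx[, "col"])
}
.pamlToColumnLower <- function(v) { out <- v; out[.pamlRowOrder()] <- v; out }
.columnLowerToPaml <- function(v) v[.pamlRowOrder()]

#' Build the normalized instantaneous rate matrix Q = R diag(pi)
#'
#' Off-diagonal rates are q_ij = rho_ij pi_j; the diagonal makes rows sum
#' to zero and the matrix is rescaled so the mean rate -sum_i pi_i q_ii is
#' one.  Because of the rescaling, Q is invariant to the overall scale of
#' the exchangeabilities.
#'
#' @param R an [ExchangeabilityMatrix-class] (or 20 x 20 symmetric matrix).
#' @param pi strictly positive frequency vector summing to 1.
#' @return A [RateMatrix-class].
#' @export
buildRateMatrix <- function(R, pi) {
  r <- if (is(R, "ExchangeabilityMatrix")) R@rho else {
    exchangeabilityMatrix(R)@rho
  }
  pi <- .checkFrequencies(pi)
  zero <- pi <= 0
  if (any(zero & colSums(r) > 0))
    stop("zero frequency for residue(s) ",
         paste(aminoAcids()[zero], collapse = " "),
         " with nonzero exchangeability; use empiricalFrequencies() with a ",
         "pseudocount")
  q <- r * rep(pi, each = 20)          # q_ij = rho_ij * pi_j
  diag(q) <- -rowSums(q)
  scale <- -sum(pi * diag(q))
  if (scale <= 0) stop("degenerate rate matrix: zero mean rate")
  new("RateMatrix", q = q / scale, scale = scale, pi = unname(pi))
}

.checkFrequencies <- function(pi) {
  if (length(pi) != 20L) stop("pi must have 20 entries")
  if (any(pi < 0)) stop("pi must be non-negative")
  if (abs(sum(pi) - 1) > 1e-9) stop("pi must sum to 1")
  pi
}

## Symmetric eigendecomposition of a reversible Q: with B = diag(sqrt(pi))
## Q diag(1/sqrt(pi)) symmetric, Q = V diag(lambda) Vinv with real V.
.eigenQ <- function(Q) {
  q <- if (is(Q, "RateMatrix")) Q@q else Q
  pi <- if (is(Q, "RateMatrix")) Q@pi else stop("need a RateMatrix")
  sq <- sqrt(pi)
  B <- q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  es <- eigen(B, symmetric = TRUE)
  list(V = es$vectors / sq, Vinv = t(es$vectors) * rep(sq, each = 20),
       lambda = es$values, pi = pi)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed by symmetric eigendecomposition (reversibility makes
#' diag(sqrt(pi)) Q diag(1/sqrt(pi)) symmetric); tiny negative entries from
#' round-off are clamped to zero.
#'
#' @param Q a [RateMatrix-class].
#' @param t branch length (expected substitutions per site), t >= 0.
#' @return 20 x 20 stochastic matrix.
#' @export
transitionMatrix <- function(Q, t) {
  if (t < 0) stop("t must be >= 0")
  eg <- .eigenQ(Q)
  P <- eg$V %*% (exp(eg$lambda * t) * eg$Vinv)
  P[P < 0] <- 0
  dimnames(P) <- list(aminoAcids(), aminoAcids())
  P
}
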