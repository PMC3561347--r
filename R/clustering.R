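#' Pooled within-class sum of squares
#'
#' W_k: the sum over sites of squared Euclidean distance to the centroid of
#' the class the site is assigned to.
#'
#' @param X numeric matrix, one row per site.
#' @param labels integer class labels in 1..k; every class must be occupied.
#' @return Non-negative scalar.
#' @export
#' @examples
#' withinDispersion(matrix(c(0, 2)), c(1L, 1L))  # (0-1)^2 + (2-1)^2 = 2
withinDispersion <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  if (length(labels) != nrow(X)) stop("labels must match rows of X")
  k <- max(labels)
  if (min(labels) < 1L || !all(seq_len(k) %in% labels))
    stop("empty cluster: labels must cover 1..k")
  w <- 0
  for (g in seq_len(k)) {
    xg <- X[labels == g, , drop = FALSE]
    ctr <- colMeans(xg)
    w <- w + sum(sweep(xg, 2L, ctr)^2)
  }
  w
}

#' Best-of-restarts K-means partition of sites
#'
#' Runs Hartigan-Wong K-means from `nRestarts` random initializations and
#' keeps the restart with the smallest pooled within-class dispersion
#' (ties break toward the earlier restart).  Classes are relabelled by
#' decreasing size, so class 1 is always the largest.
#'
#' @param X numeric matrix of site property profiles (or a
#'   [SiteProfiles-class]).
#' @param k number of classes, 1 <= k <= number of distinct rows.
#' @param nRestarts random initializations (default 1000).
#' @param seed integer master seed; the run is deterministic given it.
#' @param iterMax K-means iteration cap per restart.
#' @return A [SiteClassPartition-class].
#' @export
kmeansPartition <- function(X, k, nRestarts = 1000L, seed = 1L,
                            iterMax = 100L) {
  if (is(X, "SiteProfiles")) X <- profiles(X)
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= ", n)
  if (nRestarts < 1L) stop("nRestarts must be >= 1")
  ux <- unique(X)
  if (k > nrow(ux))
    stop("k exceeds the number of distinct profiles (", nrow(ux), ")")
  if (k == 1L) {
    ctr <- matrix(colMeans(X), 1L, ncol(X),
                  dimnames = list(NULL, colnames(X)))
    return(new("SiteClassPartition", labels = rep(1L, n), centroids = ctr,
               withinSS = withinDispersion(X, rep(1L, n))))
  }
  best <- NULL
  withSeed(seed, {
    for (r in seq_len(nRestarts)) {
      ctrs <- ux[sample.int(nrow(ux), k), , drop = FALSE]
      km <- suppressWarnings(
        stats::kmeans(X, centers = ctrs, iter.max = iterMax,
                      algorithm = "Hartigan-Wong"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  ## relabel by decreasing class size (ties: original label order)
  sz <- tabulate(best$cluster, nbins = k)
  ord <- order(sz, decreasing = TRUE)
  relab <- integer(k); relab[ord] <- seq_len(k)
  labels <- relab[best$cluster]
  ctr <- best$centers[ord, , drop = FALSE]
  rownames(ctr) <- NULL
  new("SiteClassPartition", labels = as.integer(labels), centroids = ctr,
      withinSS = withinDispersion(X, labels))
}

#' Draw a shape-aware uniform reference dataset
#'
#' Implements the reference null of the gap statistic: the data are centered
#' and rotated into their right-singular-vector basis, a dataset of the same
#' shape is drawn uniformly inside the axis-aligned bounding box in that
#' basis, and the draw is rotated back.  This respects the overall shape
#' (orientation and extent) of the observed cloud.
#'
#' @param X numeric matrix with at least 2 rows.
#' @param seed integer seed (optional; caller may manage the RNG stream).
#' @return Matrix of the same dimensions as `X`.
#' @export
referenceDraw <- function(X, seed = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("X must have at least 2 rows")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc)
  if (max(sv$d) <= 0) stop("degenerate X: rank 0 (all rows identical)")
  Xp <- Xc %*% sv$v
  lo <- apply(Xp, 2L, min)
  hi <- apply(Xp, 2L, max)
  draw <- function() {
    Zp <- matrix(runif(length(Xp)), nrow(Xp), ncol(Xp))
    Zp <- sweep(sweep(Zp, 2L, hi - lo, "*"), 2L, lo, "+")
    sweep(Zp %*% t(sv$v), 2L, mu, "+")
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

#' Gap statistic curve over k = 1..kMax
#'
#' For each k, the pooled within-class dispersion W_k of the data (best of
#' `nRestarts` K-means restarts) is compared with its expectation under `B`
#' reference draws ([referenceDraw()]): Gap(k) = mean_b log W*_kb - log W_k.
#' The standard-error term is s_k = sd_b(log W*_kb) * sqrt(1 + 1/B).
#' Reference fits use fewer restarts (`refRestarts`) than the observed data,
#' a documented cost-saving default.
#'
#' @param X site profile matrix (or [SiteProfiles-class]).
#' @param kMax largest number of classes evaluated (>= 2); k = 1 is always
#'   included so the "no structure" outcome is expressible.
#' @param B number of reference draws (default 100).
#' @param nRestarts K-means restarts for the observed data (default 1000).
#' @param refRestarts K-means restarts per reference fit (default 25).
#' @param seed integer master seed; per-draw streams are derived from it.
#' @return A [GapCurve-class].
#' @export
gapCurve <- function(X, kMax, B = 100L, nRestarts = 1000L,
                     refRestarts = 25L, seed = 1L) {
  if (is(X, "SiteProfiles")) X <- profiles(X)
  X <- as.matrix(X)
  if (kMax < 2L) stop("kMax must be >= 2")
  if (B < 1L) stop("B must be >= 1")
  ks <- seq_len(kMax)
  logW <- vapply(ks, function(k)
    log(kmeansPartition(X, k, nRestarts = nRestarts,
                        seed = deriveSeed(seed, "obs", k))@withinSS), 0)
  logWref <- matrix(NA_real_, B, kMax)
  for (b in seq_len(B)) {
    Z <- referenceDraw(X, seed = deriveSeed(seed, "ref", b))
    logWref[b, ] <- vapply(ks, function(k)
      log(kmeansPartition(Z, k, nRestarts = refRestarts,
                          seed = deriveSeed(seed, "reffit", b, k))@withinSS), 0)
  }
  gap <- colMeans(logWref) - logW
  sdk <- apply(logWref, 2L, function(v) sqrt(mean((v - mean(v))^2)))
  sk <- sdk * sqrt(1 + 1 / B)
  new("GapCurve", k = as.integer(ks), gap = gap, sk = sk,
      logW = logW, logWref = colMeans(logWref), B = as.integer(B))
}

#' Select the number of classes by the 1-standard-error rule
#'
#' Returns the smallest k with Gap(k) >= Gap(k+1) - s_(k+1).  When no
#' evaluated k satisfies the rule, the largest evaluated k is returned with
#' `ruleSatisfied = FALSE` (interpret as "no clear structure at this range").
#'
#' @param stats a [GapCurve-class], or a list/data.frame with elements `k`,
#'   `gap`, `sk` covering consecutive k.
#' @return List with elements `k` (integer) and `ruleSatisfied` (logical).
#' @export
#' @examples
#' ## printed gap/s values for k = 2..4 of a mitochondrial dataset select k = 3
#' selectK(list(k = 2:4, gap = c(0.5980, 0.6371, 0.6209),
#'              sk = c(0.0087, 0.0073, 0.0066)))$k
selectK <- function(stats) {
  if (is(stats, "GapCurve")) {
    ks <- stats@k; gap <- stats@gap; sk <- stats@sk
  } else {
    ks <- stats$k; gap <- stats$gap; sk <- stats$sk
  }
  if (any(diff(ks) != 1L)) stop("stats must cover consecutive k")
  for (i in seq_along(ks)[-length(ks)]) {
    if (gap[i] >= gap[i + 1] - sk[i + 1])
      return(list(k = as.integer(ks[i]), ruleSatisfied = TRUE))
  }
  list(k = as.integer(ks[length(ks)]), ruleSatisfied = FALSE)
}

#' Cluster alignment sites into physiochemical classes
#'
#' End-to-end composition: property profiles ([profileMatrix()]), gap curve
#' ([gapCurve()]), 1-SE selection of k ([selectK()]), and the final
#' best-of-restarts partition at the selected k.
#'
#' @param msa an amino-acid alignment (see [profileMatrix()]).
#' @param kMax largest k evaluated (default 6).
#' @param B reference draws for the gap curve (default 100).
#' @param nRestarts K-means restarts for observed-data fits (default 1000).
#' @param refRestarts restarts per reference fit (default 25).
#' @param seed integer master seed.
#' @param table property table, default [kideraTable()].
#' @return A [SiteClassPartition-class] carrying the [GapCurve-class] in its
#'   `gapCurve` slot; `ruleSatisfied` is FALSE when no k met the rule.
#' @export
clusterSites <- function(msa, kMax = 6L, B = 100L, nRestarts = 1000L,
                         refRestarts = 25L, seed = 1L,
                         table = kideraTable()) {
  prof <- profileMatrix(msa, table = table)
  gc <- gapCurve(profiles(prof), kMax = kMax, B = B, nRestarts = nRestarts,
                 refRestarts = refRestarts, seed = seed)
  sel <- selectK(gc)
  if (!sel$ruleSatisfied)
    warning("no k in 1..", kMax, " satisfied the 1-SE rule; using k = ",
            sel$k)
  part <- kmeansPartition(profiles(prof), sel$k, nRestarts = nRestarts,
                          seed = deriveSeed(seed, "final", sel$k))
  part@gapCurve <- gc
  part@ruleSatisfied <- sel$ruleSatisfied
  part
}
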