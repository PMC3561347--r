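## Free-pair bookkeeping: the 190 unordered pairs in canonical order, minus
## the reference pair, which is held at 1 on the optimization scale (the
## likelihood only identifies exchangeabilities up to a common factor).
.allPairs <- function() {
  idx <- which(lower.tri(matrix(0, 20, 20)), arr.ind = TRUE)
  cbind(i = idx[, "col"], j = idx[, "row"])  # i < j in canonical order
}

.freePairs <- function(refPair = c("W", "V")) {
  aa <- aminoAcids()
  ij <- sort(match(refPair, aa))
  p <- .allPairs()
  p[!(p[, 1L] == ij[1L] & p[, 2L] == ij[2L]), , drop = FALSE]
}

## rho matrix -> free-parameter vector (log scale, reference pair at 1)
.packTheta <- function(rhoMat, pairs, refPair) {
  aa <- aminoAcids()
  ref <- rhoMat[refPair[1L], refPair[2L]]
  if (!is.finite(ref) || ref <= 0) ref <- mean(rhoMat[lower.tri(rhoMat)])
  v <- rhoMat[cbind(pairs[, 1L], pairs[, 2L])] / ref
  log(pmin(pmax(v, 1e-6), 1e3))
}

.unpackTheta <- function(theta, pairs, refPair) {
  aa <- aminoAcids()
  r <- matrix(0, 20, 20, dimnames = list(aa, aa))
  r[cbind(pairs[, 1L], pairs[, 2L])] <- exp(theta)
  r[refPair[1L], refPair[2L]] <- 1
  r <- r + t(r)
  r
}

## L-BFGS-B needs finite objective/gradient values even where a site
## likelihood underflows to zero; a large penalty makes the line search
## backtrack out of such regions.
.finiteNegLL <- function(v) if (is.finite(v)) v else 1e15
.finiteGrad <- function(g) { g[!is.finite(g)] <- 0; g }

.fitControl <- function(control = list()) {
  def <- list(maxit = 500L, factr = 1e8, branchMaxit = 200L,
              cycleTol = 0.01, maxCycles = 20L, branchTol = 1e-6,
              tMin = 1e-8, tMax = 1e2, thetaMin = log(1e-6),
              thetaMax = log(1e3))
  def[names(control)] <- control
  def
}

#' Optimize branch lengths under a fixed rate matrix
#'
#' Maximum-likelihood branch lengths by bounded quasi-Newton (L-BFGS-B) over
#' log branch lengths with the analytic likelihood gradient, iterated until
#' the improvement per pass falls below `tol`.  The log-likelihood never
#' decreases relative to the input tree (the input is returned if no
#' improvement is found).  Branch lengths are bounded below by 1e-8 to keep
#' the transition matrices well conditioned.
#'
#' @param msa alignment with named sequences.
#' @param tree starting tree with branch lengths.
#' @param Q a [RateMatrix-class].
#' @param tol convergence tolerance on the log-likelihood (default 1e-6).
#' @param control optimizer settings, see [fitExchangeabilities()].
#' @return The tree with optimized branch lengths; attributes `logLik` and
#'   `converged` carry the optimum and a convergence flag.
#' @export
optimizeBranchLengths <- function(msa, tree, Q, tol = 1e-6,
                                  control = list()) {
  ctl <- .fitControl(control)
  prep <- .prepTreeData(msa, tree)
  eg <- .eigenQ(Q)
  res <- .optimBranches(prep, eg, ctl, tol)
  out <- prep$tree
  out$edge.length <- res$t
  if (!res$converged)
    warning("branch-length optimization did not converge; best tree returned")
  attr(out, "logLik") <- res$loglik
  attr(out, "converged") <- res$converged
  out
}

## L-BFGS-B over log branch lengths, analytic gradient; repeated until the
## pass-to-pass improvement drops below tol.
.optimBranches <- function(prep, eg, ctl, tol = NULL) {
  if (is.null(tol)) tol <- ctl$branchTol
  t0 <- pmax(prep$t, ctl$tMin)
  ll <- function(tv) {
    cpp_loglik(prep$states, prep$weights, prep$edge, .pcube(eg, tv),
               eg$pi, prep$nNodes, prep$root)$loglik
  }
  start <- ll(t0)
  cache <- new.env()
  eval_at <- function(lt) {
    key <- paste(signif(lt, 12), collapse = ",")
    if (!is.null(cache$key) && identical(cache$key, key)) return(cache$val)
    r <- cpp_loglik_grad(prep$states, prep$weights, prep$edge, exp(lt),
                         eg$V, eg$Vinv, eg$lambda, eg$pi, prep$nNodes,
                         prep$root, integer(0), integer(0), numeric(0),
                         1, FALSE)
    cache$key <- key
    cache$val <- r
    r
  }
  cur <- log(t0); curLL <- start; converged <- FALSE
  for (pass in 1:10) {
    opt <- try(optim(cur, fn = function(p) .finiteNegLL(-eval_at(p)$loglik),
                     gr = function(p) .finiteGrad(-eval_at(p)$grad_t * exp(p)),
                     method = "L-BFGS-B",
                     lower = log(ctl$tMin), upper = log(ctl$tMax),
                     control = list(maxit = ctl$branchMaxit)), silent = TRUE)
    if (inherits(opt, "try-error")) break
    if (-opt$value > curLL) { cur <- opt$par; delta <- -opt$value - curLL
                              curLL <- -opt$value }
    else delta <- 0
    if (delta < tol) { converged <- TRUE; break }
  }
  if (curLL < start) { cur <- log(t0); curLL <- start }
  list(t = exp(cur), loglik = curLL, converged = converged)
}

## L-BFGS-B over the 189 log exchangeabilities at fixed branch lengths.
## ctl$thetaLower/ctl$thetaUpper may be vectors; pairs uninformed by the
## data (a residue with zero counts) are pinned by equal bounds.
.optimTheta <- function(prep, theta, pairs, refPair, pi, ctl) {
  cache <- new.env()
  eval_at <- function(th) {
    key <- paste(signif(th, 12), collapse = ",")
    if (!is.null(cache$key) && identical(cache$key, key)) return(cache$val)
    rhoMat <- .unpackTheta(th, pairs, refPair)
    r <- .gradEval(prep, rhoMat, pi, pairs, gradTheta = TRUE)
    cache$key <- key
    cache$val <- r
    r
  }
  opt <- optim(theta,
               fn = function(th) .finiteNegLL(-eval_at(th)$loglik),
               gr = function(th) .finiteGrad(-eval_at(th)$grad_theta),
               method = "L-BFGS-B",
               lower = ctl$thetaLower %||% ctl$thetaMin,
               upper = ctl$thetaUpper %||% ctl$thetaMax,
               control = list(maxit = ctl$maxit, factr = ctl$factr))
  list(theta = opt$par, loglik = -opt$value,
       iterations = opt$counts[["function"]],
       converged = opt$convergence == 0L)
}

#' Maximum-likelihood estimation of amino-acid exchangeabilities
#'
#' Estimates the 189 free exchangeabilities (and branch lengths) of a
#' reversible 20-state model on a fixed tree topology.  Two strategies are
#' available, mirroring the two-phase protocol used for empirical
#' mitochondrial matrices:
#'
#' * `"joint"`: all 189 log-scaled exchangeabilities and all log branch
#'   lengths are optimized together by bounded quasi-Newton (L-BFGS-B) with
#'   the analytic gradient.
#' * `"cyclic"`: alternate phases - branch lengths under fixed
#'   exchangeabilities, then exchangeabilities under fixed branch lengths -
#'   repeated until the cycle-to-cycle log-likelihood gain is below
#'   `control$cycleTol` (default 0.01).
#'
#' Every (method, initial matrix) combination is run and the highest
#' log-likelihood result returned, with the full per-run trace.  Frequencies
#' are empirical (never optimized).  The emitted matrix is rescaled so the
#' rate matrix built with `pi` has mean rate one.
#'
#' @param msa alignment with named sequences matching the tree.
#' @param tree fixed topology with starting branch lengths.
#' @param method `"cyclic"`, `"joint"`, or both.
#' @param initials named list of starting exchangeability matrices
#'   ([ExchangeabilityMatrix-class] or plain symmetric 20 x 20); default the
#'   uniform (all-ones) matrix.  See [seedMatrices()] for published starts.
#' @param pi frequencies; default [empiricalFrequencies()] of `msa`.
#' @param control list overriding optimizer defaults: `maxit` (500 per
#'   phase), `factr` (L-BFGS-B tolerance, 1e8), `cycleTol` (0.01),
#'   `maxCycles` (20), `branchMaxit` (200), bounds `thetaMin`/`thetaMax`
#'   (log 1e-6 / log 1e3) and `tMin`/`tMax` (1e-8 / 100).
#' @param refPair exchangeability pair fixed during optimization; default
#'   the two most abundant residues in `msa` (a rare anchor pair would put
#'   the whole matrix on an uninformed scale).
#' @return An [ExchangeabilityFit-class].
#' @export
fitExchangeabilities <- function(msa, tree, method = c("cyclic", "joint"),
                                 initials = NULL, pi = NULL,
                                 control = list(), refPair = NULL) {
  method <- match.arg(method, several.ok = TRUE)
  ctl <- .fitControl(control)
  if (is.null(pi)) pi <- empiricalFrequencies(msa)
  if (is.null(initials))
    initials <- list(uniform = exchangeabilityMatrix(matrix(1, 20, 20)))
  if (is.null(names(initials)))
    names(initials) <- paste0("init", seq_along(initials))
  prep <- .prepTreeData(msa, tree)

  ## residues absent from the data: their exchangeabilities are reported but
  ## not informed by it
  counts <- table(factor(aminoAcids()[prep$states[prep$states > 0]],
                         levels = aminoAcids()))
  nonIdent <- names(counts)[counts == 0L]
  ## anchor the fixed reference pair on the two most abundant residues:
  ## anchoring on a rare pair leaves the whole matrix scaled by an
  ## uninformed value, and the box bounds then cut off the optimum
  if (is.null(refPair))
    refPair <- names(sort(counts, decreasing = TRUE))[1:2]
  pairs <- .freePairs(refPair)
  ## pairs involving a zero-count residue are not informed by the data:
  ## pin them at their starting values (flat likelihood directions would
  ## otherwise drift arbitrarily under quasi-Newton line searches)
  informed <- counts[pairs[, 1L]] > 0 & counts[pairs[, 2L]] > 0

  runs <- list()
  for (mth in method) for (nm in names(initials)) {
    R0 <- initials[[nm]]
    rhoMat <- if (is(R0, "ExchangeabilityMatrix")) R0@rho else
      exchangeabilityMatrix(R0)@rho
    theta0 <- .packTheta(rhoMat, pairs, refPair)
    ctl$thetaLower <- ifelse(informed, ctl$thetaMin, theta0)
    ctl$thetaUpper <- ifelse(informed, ctl$thetaMax, theta0)
    run <- try(
      if (mth == "joint") .runJoint(prep, theta0, pairs, refPair, pi, ctl)
      else .runCyclic(prep, theta0, pairs, refPair, pi, ctl),
      silent = TRUE)
    if (inherits(run, "try-error")) {
      runs[[paste(mth, nm, sep = ".")]] <-
        list(method = mth, initial = nm, loglik = -Inf, iterations = 0L,
             converged = FALSE, failed = TRUE)
      next
    }
    run$method <- mth; run$initial <- nm; run$failed <- FALSE
    runs[[paste(mth, nm, sep = ".")]] <- run
  }
  lls <- vapply(runs, `[[`, 0, "loglik")
  if (all(!is.finite(lls))) stop("all optimization runs failed")
  best <- runs[[which.max(lls)]]

  rhoMat <- .unpackTheta(best$theta, pairs, refPair)
  scale <- buildRateMatrix(exchangeabilityMatrix(rhoMat), pi)@scale
  emittedMat <- rhoMat / scale
  if (any(!informed)) {
    ## pairs not informed by this subset report the starting matrix's
    ## (normalized) values rather than an arbitrary optimizer position
    startRho <- initials[[best$initial]]
    startRho <- if (is(startRho, "ExchangeabilityMatrix")) startRho@rho else
      exchangeabilityMatrix(startRho)@rho
    startNorm <- startRho /
      buildRateMatrix(exchangeabilityMatrix(startRho), pi)@scale
    up <- pairs[!informed, , drop = FALSE]
    emittedMat[up] <- startNorm[up]
    emittedMat[up[, 2:1, drop = FALSE]] <- startNorm[up]
  }
  emitted <- exchangeabilityMatrix(emittedMat, refPair = refPair)
  tree2 <- prep$tree
  tree2$edge.length <- best$t
  trace <- data.frame(
    method = vapply(runs, `[[`, "", "method"),
    initial = vapply(runs, `[[`, "", "initial"),
    logLik = lls,
    iterations = vapply(runs, function(r) as.integer(r$iterations), 0L),
    converged = vapply(runs, `[[`, TRUE, "converged"),
    row.names = NULL)
  new("ExchangeabilityFit", rho = emitted, pi = unname(pi), tree = tree2,
      logLik = best$loglik, trace = trace, converged = best$converged,
      nonIdentifiable = nonIdent)
}

.runJoint <- function(prep, theta0, pairs, refPair, pi, ctl) {
  nT <- length(theta0); E <- length(prep$t)
  cache <- new.env()
  eval_at <- function(par) {
    key <- paste(signif(par, 12), collapse = ",")
    if (!is.null(cache$key) && identical(cache$key, key)) return(cache$val)
    th <- par[seq_len(nT)]; tv <- exp(par[nT + seq_len(E)])
    p2 <- prep; p2$t <- tv
    r <- .gradEval(p2, .unpackTheta(th, pairs, refPair), pi, pairs, TRUE)
    r$grad_t <- r$grad_t * tv  # chain rule for log branch lengths
    cache$key <- key; cache$val <- r
    r
  }
  par0 <- c(theta0, log(pmax(prep$t, ctl$tMin)))
  opt <- optim(par0,
               fn = function(p) .finiteNegLL(-eval_at(p)$loglik),
               gr = function(p)
                 .finiteGrad(-c(eval_at(p)$grad_theta, eval_at(p)$grad_t)),
               method = "L-BFGS-B",
               lower = c(ctl$thetaLower %||% rep(ctl$thetaMin, nT),
                         rep(log(ctl$tMin), E)),
               upper = c(ctl$thetaUpper %||% rep(ctl$thetaMax, nT),
                         rep(log(ctl$tMax), E)),
               control = list(maxit = ctl$maxit, factr = ctl$factr))
  list(theta = opt$par[seq_len(nT)], t = exp(opt$par[nT + seq_len(E)]),
       loglik = -opt$value, iterations = opt$counts[["function"]],
       converged = opt$convergence == 0L)
}

.runCyclic <- function(prep, theta0, pairs, refPair, pi, ctl) {
  theta <- theta0
  iters <- 0L
  ll <- -Inf
  converged <- FALSE
  for (cycle in seq_len(ctl$maxCycles)) {
    eg <- .eigenQ(buildRateMatrix(
      exchangeabilityMatrix(.unpackTheta(theta, pairs, refPair)), pi))
    br <- .optimBranches(prep, eg, ctl)
    prep$t <- br$t
    th <- .optimTheta(prep, theta, pairs, refPair, pi, ctl)
    theta <- th$theta
    iters <- iters + th$iterations
    if (is.finite(ll) && th$loglik - ll < ctl$cycleTol) {
      ll <- max(ll, th$loglik); converged <- TRUE; break
    }
    ll <- th$loglik
  }
  list(theta = theta, t = prep$t, loglik = ll, iterations = iters,
       converged = converged)
}

#' Published exchangeability matrices as optimizer starting points
#'
#' Retrieves published empirical amino-acid exchangeability matrices (for
#' example mtmam, mtREV24, JTT, WAG) from the phangorn package's model
#' collection, as starting values for [fitExchangeabilities()].  `"uniform"`
#' is always available and needs no extra package.  Any 20 x 20 symmetric
#' non-negative matrix can serve as a start; a physicochemical distance
#' matrix supplied here is used as-is, with no conversion.
#'
#' @param names character vector of model names; `"uniform"` plus any model
#'   known to phangorn (case-insensitive: `"mtmam"`, `"mtREV24"`, `"JTT"`,
#'   `"WAG"`, ...).
#' @return Named list of [ExchangeabilityMatrix-class] objects.
#' @export
seedMatrices <- function(names = c("uniform", "mtmam", "WAG")) {
  out <- list()
  for (nm in names) {
    if (tolower(nm) == "uniform") {
      out[[nm]] <- exchangeabilityMatrix(matrix(1, 20, 20))
      next
    }
    if (!requireNamespace("phangorn", quietly = TRUE))
      stop("seed matrix '", nm, "' needs the phangorn package")
    avail <- getFromNamespace(".aamodels", "phangorn")
    hit <- avail[match(tolower(nm), tolower(avail))]
    if (is.na(hit)) stop("unknown seed matrix: ", nm)
    getQ <- getFromNamespace("getModelAA", "phangorn")
    grab <- function() { getQ(hit, bf = FALSE, Q = TRUE); Q }
    Q <- NULL
    qvec <- grab()
    out[[nm]] <- exchangeabilityMatrix(.lowerColumnFromPhangorn(qvec))
  }
  out
}

## phangorn stores Q as the column-wise lower triangle in the same
## canonical residue order; rebuild the full matrix.
.lowerColumnFromPhangorn <- function(qvec) {
  aa <- aminoAcids()
  r <- matrix(0, 20, 20, dimnames = list(aa, aa))
  r[lower.tri(r)] <- qvec
  r + t(r)
}

#' Fit a branch-length scale factor for a data partition
#'
#' One-dimensional ML estimate of a single multiplier `s` applied to every
#' branch of a reference tree, for one subset of sites - the constrained
#' alternative to free per-partition branch lengths.
#'
#' @param msa alignment (the partition's sites) with named sequences.
#' @param tree reference tree whose branch lengths are held fixed.
#' @param Q a [RateMatrix-class].
#' @param interval search interval for `s` (default 1e-3 .. 100).
#' @return List with `s`, `logLik`, and `boundary` (TRUE when the optimum
#'   sits on the interval edge, with a warning).
#' @export
fitBranchScale <- function(msa, tree, Q, interval = c(1e-3, 100)) {
  m <- .asResidueMatrix(msa)
  common <- intersect(tree$tip.label, rownames(m))
  if (length(common) == 0L)
    stop("empty intersection of taxa between alignment and tree")
  if (length(common) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, common)
  prep <- .prepTreeData(m[common, , drop = FALSE], tree)
  eg <- .eigenQ(Q)
  f <- function(logs) {
    cpp_loglik(prep$states, prep$weights, prep$edge,
               .pcube(eg, prep$t * exp(logs)), eg$pi,
               prep$nNodes, prep$root)$loglik
  }
  opt <- optimize(f, log(interval), maximum = TRUE, tol = 1e-9)
  s <- exp(opt$maximum)
  boundary <- min(abs(log(s) - log(interval))) < 1e-4
  if (boundary)
    warning("branch scale optimum at the search boundary (s = ",
            signif(s, 4), ")")
  list(s = s, logLik = opt$objective, boundary = boundary)
}
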