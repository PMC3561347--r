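#' @rdname SiteProfiles-class
#' @param x a SiteProfiles object
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))

#' @rdname SiteProfiles-class
#' @export
setMethod("profiles", "SiteProfiles", function(x) x@profiles)

#' @rdname SiteProfiles-class
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))

#' @rdname SiteProfiles-class
#' @export
setMethod("siteIds", "SiteProfiles", function(x) x@siteIds)

#' @rdname SiteClassPartition-class
#' @param x a SiteClassPartition object
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))

#' @rdname SiteClassPartition-class
#' @export
setMethod("siteLabels", "SiteClassPartition", function(x) x@labels)

#' @rdname SiteClassPartition-class
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname SiteClassPartition-class
#' @export
setMethod("centroids", "SiteClassPartition", function(x) x@centroids)

#' @rdname SiteClassPartition-class
#' @export
setGeneric("withinSS", function(x) standardGeneric("withinSS"))

#' @rdname SiteClassPartition-class
#' @export
setMethod("withinSS", "SiteClassPartition", function(x) x@withinSS)

#' @rdname SiteClassPartition-class
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' @rdname SiteClassPartition-class
#' @export
setMethod("nClasses", "SiteClassPartition", function(x) nrow(x@centroids))

#' @rdname SiteClassPartition-class
#' @export
setGeneric("classSizes", function(x) standardGeneric("classSizes"))

#' @rdname SiteClassPartition-class
#' @export
setMethod("classSizes", "SiteClassPartition", function(x)
  tabulate(x@labels, nbins = nClasses(x)))

#' @rdname GapCurve-class
#' @param x a GapCurve object
#' @export
setGeneric("gapValues", function(x) standardGeneric("gapValues"))

#' @rdname GapCurve-class
#' @export
setMethod("gapValues", "GapCurve", function(x) setNames(x@gap, paste0("k=", x@k)))

#' @rdname GapCurve-class
#' @export
setGeneric("seValues", function(x) standardGeneric("seValues"))

#' @rdname GapCurve-class
#' @export
setMethod("seValues", "GapCurve", function(x) setNames(x@sk, paste0("k=", x@k)))

#' @rdname ExchangeabilityMatrix-class
#' @param x an ExchangeabilityMatrix (or ExchangeabilityFit)
#' @export
setGeneric("rho", function(x) standardGeneric("rho"))

#' @rdname ExchangeabilityMatrix-class
#' @export
setMethod("rho", "ExchangeabilityMatrix", function(x) x@rho)

#' @rdname ExchangeabilityFit-class
#' @export
setMethod("rho", "ExchangeabilityFit", function(x) x@rho@rho)

#' @rdname ExchangeabilityFit-class
#' @param x an ExchangeabilityFit object
#' @export
setGeneric("exchangeabilities", function(x) standardGeneric("exchangeabilities"))

#' @rdname ExchangeabilityFit-class
#' @export
setMethod("exchangeabilities", "ExchangeabilityFit", function(x) x@rho)

#' @rdname ExchangeabilityFit-class
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @rdname ExchangeabilityFit-class
#' @export
setMethod("frequencies", "ExchangeabilityFit", function(x) x@pi)

#' @rdname RateMatrix-class
#' @param x a RateMatrix object
#' @export
setMethod("frequencies", "RateMatrix", function(x) x@pi)

#' @rdname ExchangeabilityFit-class
#' @export
setGeneric("fittedTree", function(x) standardGeneric("fittedTree"))

#' @rdname ExchangeabilityFit-class
#' @export
setMethod("fittedTree", "ExchangeabilityFit", function(x) x@tree)

#' @rdname ExchangeabilityFit-class
#' @export
setGeneric("fitTrace", function(x) standardGeneric("fitTrace"))

#' @rdname ExchangeabilityFit-class
#' @export
setMethod("fitTrace", "ExchangeabilityFit", function(x) x@trace)

#' @rdname ExchangeabilityFit-class
#' @param object an ExchangeabilityFit
#' @param ... unused
#' @export
setMethod("logLik", "ExchangeabilityFit", function(object, ...)
  structure(object@logLik, class = "logLik", df = 189L))

#' @rdname RateMatrix-class
#' @export
setGeneric("rateMatrix", function(x) standardGeneric("rateMatrix"))

#' @rdname RateMatrix-class
#' @export
setMethod("rateMatrix", "RateMatrix", function(x) x@q)

setMethod("show", "SiteProfiles", function(object) {
  cat("SiteProfiles:", nrow(object@profiles), "sites x",
      ncol(object@profiles), "properties\n")
  if (nrow(object@profiles)) {
    cat("  site ids:", .rangeLabel(object@siteIds), "\n")
    cat("  residues per site:", min(object@nSeqUsed), "-",
        max(object@nSeqUsed), "\n")
  }
})

setMethod("show", "SiteClassPartition", function(object) {
  sz <- classSizes(object)
  cat("SiteClassPartition:", length(object@labels), "sites in",
      length(sz), "classes\n")
  cat("  class sizes:", paste(sz, collapse = " / "), "\n")
  cat("  pooled within-class SS:", format(object@withinSS, digits = 6), "\n")
  if (!object@ruleSatisfied)
    cat("  note: no k satisfied the 1-SE rule; largest evaluated k used\n")
})

setMethod("show", "GapCurve", function(object) {
  cat("GapCurve over k =", min(object@k), "..", max(object@k),
      " (B =", object@B, "reference draws)\n")
  df <- data.frame(k = object@k, gap = round(object@gap, 4),
                   s_k = round(object@sk, 4))
  print(df, row.names = FALSE)
})

setMethod("show", "ExchangeabilityMatrix", function(object) {
  v <- object@rho[lower.tri(object@rho)]
  cat("ExchangeabilityMatrix: 20 x 20 symmetric, 190 pairs\n")
  cat("  pair range:", format(min(v), digits = 4), "-",
      format(max(v), digits = 4),
      " (reference pair ", paste(object@refPair, collapse = "-"), ")\n",
      sep = "")
})

setMethod("show", "RateMatrix", function(object) {
  cat("RateMatrix: 20 x 20, mean rate",
      format(-sum(object@pi * diag(object@q)), digits = 6),
      "(scale", format(object@scale, digits = 4), ")\n")
})

setMethod("show", "ExchangeabilityFit", function(object) {
  cat("ExchangeabilityFit: logLik =", format(object@logLik, digits = 10), "\n")
  cat("  runs:", nrow(object@trace), " converged:", object@converged, "\n")
  if (length(object@nonIdentifiable))
    cat("  residues absent from data:",
        paste(object@nonIdentifiable, collapse = " "), "\n")
})

setMethod("show", "NoiseAnalysis", function(object) {
  cat("NoiseAnalysis:", object@S, "random partitions,",
      length(object@observed), "classes\n")
  print(noiseTable(object), row.names = FALSE)
})

.rangeLabel <- function(x) {
  if (length(x) <= 6) paste(x, collapse = " ")
  else paste0(x[1], "..", x[length(x)])
}
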