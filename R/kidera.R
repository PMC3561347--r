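#' The nine physiochemical property scales for the 20 amino acids
#'
#' Returns the 20 x 9 table of property-scale values used to transform an
#' alignment into per-site property profiles.  The nine scales are the
#' near-orthogonal factors distilled by Kidera and colleagues from 188
#' amino-acid property measures: P1 bulk, P2-P3 hydrophobicity of the free
#' amino acid, P4 hydrophobicity in proteins, P5-P6 beta-structure
#' preference, P7 alpha-helix preference, P8-P9 bend preference.  Each scale
#' is centered across the 20 residues, so column sums are near zero.
#'
#' @return A 20 x 9 numeric matrix; rows named by one-letter residue code in
#'   [aminoAcids()] order, columns P1..P9.
#' @export
#' @examples
#' kideraTable()["A", "P1"]   # -1.44
kideraTable <- function() {
  vals <- c(
    ## P1     P2     P3     P4     P5     P6     P7     P8     P9
    -1.44, -0.47,  0.11,  0.32, -0.51, -0.86,  1.35, -1.29, -0.60,  # A
     1.16, -0.57, -1.52, -1.07, -0.28, -0.13, -0.16,  0.28, -0.03,  # R
    -0.34, -1.25, -0.60, -0.96, -1.00, -1.19, -0.97,  1.19,  1.27,  # N
    -0.54, -0.75, -1.74, -1.07, -1.17, -1.72, -0.06,  0.74,  1.39,  # D
    -0.75,  0.06,  0.63,  1.50,  0.60,  1.14, -0.53,  1.18, -0.19,  # C
     0.22, -1.24, -0.46, -1.05,  0.19, -0.42,  0.57, -0.14, -0.12,  # Q
     0.17, -0.62, -1.65, -1.03, -1.74, -1.78,  1.96, -1.21, -0.27,  # E
    -2.16, -1.02, -0.19, -0.03, -0.84, -0.99, -1.72,  1.43,  1.73,  # G
     0.52, -0.46, -0.18, -0.13, -0.56, -0.10,  0.59, -0.27, -0.27,  # H
     0.21,  1.37,  0.97,  1.52,  1.91,  1.27,  0.06, -1.30, -1.49,  # I
     0.25,  1.06,  1.01,  1.14,  0.69,  0.02,  0.93, -1.36, -1.14,  # L
     0.68, -0.16, -1.62, -1.76, -0.86, -1.19,  0.71,  0.40,  0.15,  # K
     0.44,  0.20,  0.72,  1.00,  0.45,  0.24,  1.39, -1.24, -1.29,  # M
     1.09,  1.46,  1.24,  1.16,  0.88,  0.48,  0.37, -0.46, -0.75,  # F
    -0.71,  0.90,  0.21, -0.72, -1.26,  0.86, -1.72,  1.03,  1.98,  # P
    -1.21, -1.19, -0.33, -0.46, -0.54,  0.22, -0.99,  0.74,  1.02,  # S
    -0.67, -0.97,  0.01, -0.36,  0.57,  0.86, -0.68,  0.11,  0.14,  # T
     2.08,  2.06,  1.55,  0.67,  0.61,  0.42,  0.23,  0.83, -0.52,  # W
     1.34,  1.16,  1.04, -0.07,  1.02,  1.21, -1.25,  0.94,  0.30,  # Y
    -0.34,  0.42,  0.77,  1.38,  1.84,  1.66, -0.09, -1.63, -1.32)  # V
  matrix(vals, nrow = 20, ncol = 9, byrow = TRUE,
         dimnames = list(aminoAcids(), paste0("P", 1:9)))
}

#' Mean property vector of one alignment column
#'
#' Averages the property-table rows of the canonical residues observed in an
#' alignment column.  Gap symbols (`-`, `.`, `?`) and ambiguity/unknown codes
#' (X, B, Z, J, U, O) are excluded from both numerator and denominator; a
#' stop symbol (`*`) is invalid input.
#'
#' @param column character vector of residue symbols (one per sequence).
#' @param table property table, default [kideraTable()].
#' @return Named numeric vector of 9 property means.
#' @export
#' @examples
#' siteProfile(c("A", "V"))[["P1"]]   # mean of -1.44 and -0.34
siteProfile <- function(column, table = kideraTable()) {
  if (!length(column)) stop("column must be non-empty")
  column <- toupper(as.character(column))
  .checkSymbols(column)
  keep <- column %in% rownames(table)
  if (!any(keep))
    stop("all-gap site: column contains no canonical residue")
  colMeans(table[column[keep], , drop = FALSE])
}

.checkSymbols <- function(symbols) {
  legal <- c(aminoAcids(), .GAP_SYMBOLS, .AMBIG_SYMBOLS)
  bad <- setdiff(unique(symbols), legal)
  if ("*" %in% bad)
    stop("stop symbol '*' is not allowed in a curated protein alignment")
  if (length(bad))
    stop("illegal residue symbol(s): ", paste(bad, collapse = " "))
  invisible(TRUE)
}

#' Transform an alignment into a site-by-property profile matrix
#'
#' Replaces every amino acid by its nine property-scale values and averages
#' within each alignment column, yielding an n x 9 matrix of mean property
#' vectors (n = alignment columns).  This is the numerical representation on
#' which sites are clustered into classes.
#'
#' @param msa an alignment: `AAStringSet`, character matrix (sequences x
#'   sites), or character vector of equal-length sequences.
#' @param table property table, default [kideraTable()].
#' @return A [SiteProfiles-class] object.
#' @export
#' @examples
#' msa <- c(s1 = "ARN", s2 = "AVN", s3 = "A-N")
#' profiles(profileMatrix(msa))
profileMatrix <- function(msa, table = kideraTable()) {
  m <- .asResidueMatrix(msa)
  .checkSymbols(as.vector(m))
  n <- ncol(m)
  canon <- matrix(m %in% rownames(table), nrow(m), n)
  used <- colSums(canon)
  if (any(used == 0L))
    stop("all-gap column(s): ", paste(which(used == 0L), collapse = " "))
  ## indicator (20 x nseq-per-col) averaging via counts: for each column,
  ## profile = t(table) %*% counts / used
  idx <- matrix(match(m, rownames(table)), nrow(m), n)
  counts <- matrix(0, 20L, n)
  for (s in seq_len(nrow(m))) {
    ok <- !is.na(idx[s, ])
    j <- which(ok)
    counts[cbind(idx[s, j], j)] <- counts[cbind(idx[s, j], j)] + 1
  }
  prof <- t(crossprod(table, counts) / rep(used, each = 9L))
  colnames(prof) <- colnames(table)
  new("SiteProfiles", profiles = prof, siteIds = seq_len(n),
      nSeqUsed = as.integer(used))
}

## Coerce supported alignment representations to a character matrix
## (rows = sequences, columns = sites); errors on ragged input.
.asResidueMatrix <- function(msa) {
  if (inherits(msa, "AAStringSet") || inherits(msa, "XStringSet")) {
    w <- Biostrings::width(msa)
    if (length(unique(w)) > 1L)
      stop("ragged alignment: sequence lengths ", paste(unique(w), collapse = ", "))
    m <- do.call(rbind, strsplit(as.character(msa), ""))
    rownames(m) <- names(msa)
    return(toupper(m))
  }
  if (is.matrix(msa)) {
    return(toupper(msa))
  }
  if (is.character(msa)) {
    w <- nchar(msa)
    if (length(unique(w)) > 1L)
      stop("ragged alignment: sequence lengths ", paste(unique(w), collapse = ", "))
    m <- do.call(rbind, strsplit(msa, ""))
    rownames(m) <- names(msa)
    return(toupper(m))
  }
  stop("unsupported alignment representation: ", class(msa)[1])
}

#' Write / read a site profile matrix as TSV
#'
#' The export has a leading 1-based `site` column and columns P1..P9;
#' values round-trip to at least six decimals.
#'
#' @param x a [SiteProfiles-class] object.
#' @param path file path.
#' @return `writeProfiles` returns `path` invisibly; `readProfiles` returns
#'   a [SiteProfiles-class] (with `nSeqUsed` restored when present).
#' @export
writeProfiles <- function(x, path) {
  stopifnot(is(x, "SiteProfiles"))
  df <- data.frame(site = x@siteIds, n_used = x@nSeqUsed,
                   signif(as.data.frame(x@profiles), 10))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfiles
#' @export
readProfiles <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  pcols <- grep("^P[1-9]$", names(df), value = TRUE)
  prof <- as.matrix(df[, pcols])
  colnames(prof) <- pcols
  rownames(prof) <- NULL
  nused <- if ("n_used" %in% names(df)) as.integer(df$n_used)
           else rep(NA_integer_, nrow(df))
  new("SiteProfiles", profiles = prof, siteIds = as.integer(df$site),
      nSeqUsed = nused)
}
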