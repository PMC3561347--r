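#' Read an amino-acid alignment
#'
#' FASTA is parsed with Biostrings (wrapped lines are concatenated);
#' PHYLIP is parsed by a relaxed-dialect reader that accepts sequential and
#' interleaved layouts, names up to 50 characters (no whitespace in names)
#' and wrapped sequence blocks.  Duplicate names, ragged sequences and
#' illegal symbols are format errors.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"`; default guesses from the file
#'   extension (`.phy`/`.phylip` vs anything else).
#' @return An `AAStringSet`.
#' @export
readAlignment <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(phy|phylip)$", path, ignore.case = TRUE))
      "phylip" else "fasta"
  }
  format <- match.arg(format, c("fasta", "phylip"))
  msa <- if (format == "fasta") Biostrings::readAAStringSet(path)
         else .readPhylip(path)
  nm <- names(msa)
  if (anyDuplicated(nm))
    stop("duplicated taxon name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = " "))
  w <- Biostrings::width(msa)
  if (length(unique(w)) > 1L)
    stop("ragged alignment: sequence lengths ",
         paste(unique(w), collapse = ", "))
  .checkSymbols(unique(strsplit(paste(as.character(msa), collapse = ""),
                                "")[[1]]))
  msa
}

#' Write an amino-acid alignment
#'
#' @param msa an `AAStringSet` (or named character vector).
#' @param path file path.
#' @param format `"fasta"` or `"phylip"` (relaxed sequential, names up to
#'   50 characters).
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(msa, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (!inherits(msa, "XStringSet"))
    msa <- Biostrings::AAStringSet(msa)
  if (format == "fasta") {
    Biostrings::writeXStringSet(msa, path, width = 60L)
  } else {
    nm <- names(msa)
    if (any(nchar(nm) > 50L))
      stop("PHYLIP names are limited to 50 characters")
    if (any(grepl("[[:space:]]", nm)))
      stop("PHYLIP names must not contain whitespace")
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf(" %d %d", length(msa), Biostrings::width(msa)[1]), con)
    writeLines(sprintf("%-12s %s", nm, as.character(msa)), con)
  }
  invisible(path)
}

## Relaxed PHYLIP reader: sequential first (token stream: a name, then
## residue chunks until nchar is reached), interleaved as fallback.
.readPhylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PHYLIP file")
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]),
                                              "[[:space:]]+")[[1]]))
  if (length(hdr) < 2L || any(is.na(hdr[1:2])))
    stop("line 1: malformed PHYLIP header (expect 'ntaxa nchar')")
  ntax <- hdr[1]; nchr <- hdr[2]
  body <- lines[-1]

  seqTry <- .phylipSequential(body, ntax, nchr)
  if (!is.null(seqTry)) return(Biostrings::AAStringSet(seqTry))
  intTry <- .phylipInterleaved(body, ntax, nchr)
  if (!is.null(intTry)) return(Biostrings::AAStringSet(intTry))
  stop("could not parse PHYLIP body as sequential or interleaved (",
       ntax, " x ", nchr, ")")
}

.phylipSequential <- function(body, ntax, nchr) {
  toks <- unlist(strsplit(trimws(body), "[[:space:]]+"))
  toks <- toks[nzchar(toks)]
  out <- character(0)
  i <- 1L
  for (s in seq_len(ntax)) {
    if (i > length(toks)) return(NULL)
    nm <- toks[i]; i <- i + 1L
    seq <- ""
    while (nchar(seq) < nchr) {
      if (i > length(toks)) return(NULL)
      seq <- paste0(seq, toks[i]); i <- i + 1L
    }
    if (nchar(seq) != nchr) return(NULL)
    out[nm] <- seq
  }
  if (i <= length(toks)) return(NULL)  # leftovers: not sequential
  out
}

.phylipInterleaved <- function(body, ntax, nchr) {
  if (length(body) %% ntax != 0L) return(NULL)
  nm <- character(ntax); seqs <- rep("", ntax)
  for (ln in seq_along(body)) {
    tax <- ((ln - 1L) %% ntax) + 1L
    toks <- strsplit(trimws(body[ln]), "[[:space:]]+")[[1]]
    if (ln <= ntax) {
      if (length(toks) < 2L) return(NULL)
      nm[tax] <- toks[1]
      seqs[tax] <- paste(toks[-1], collapse = "")
    } else {
      seqs[tax] <- paste0(seqs[tax], paste(toks, collapse = ""))
    }
  }
  if (any(nchar(seqs) != nchr)) return(NULL)
  setNames(seqs, nm)
}

#' Read / write a PAML-style exchangeability matrix file
#'
#' The `.dat` layout: 19 lower-triangular rows (row r holds the
#' exchangeabilities of residue r+1 with residues 1..r, in the canonical
#' [aminoAcids()] order), followed by an optional line of 20 equilibrium
#' frequencies.  Values round-trip to at least 6 significant digits.
#'
#' @param path file path.
#' @return `readPamlMatrix`: list with `R` ([ExchangeabilityMatrix-class])
#'   and `pi` (frequencies, or NULL when the file has none).
#' @export
readPamlMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 19L)
    stop("truncated file: expected 19 triangle rows, found ", length(lines))
  vals <- vector("list", 19L)
  for (r in seq_len(19L)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[r]),
                                              "[[:space:]]+")[[1]]))
    if (length(v) != r || any(is.na(v)))
      stop("row ", r, ": expected ", r, " numeric entries, found ",
           length(v))
    vals[[r]] <- v
  }
  pi <- NULL
  if (length(lines) > 19L) {
    rest <- suppressWarnings(as.numeric(unlist(
      strsplit(trimws(lines[-seq_len(19L)]), "[[:space:]]+"))))
    rest <- rest[!is.na(rest)]
    if (length(rest) >= 20L) pi <- setNames(rest[1:20], aminoAcids())
  }
  R <- exchangeabilityMatrix(unlist(vals))
  list(R = R, pi = pi)
}

#' @rdname readPamlMatrix
#' @param R an [ExchangeabilityMatrix-class] (or 20 x 20 symmetric matrix).
#' @param pi optional frequency vector appended after the triangle.
#' @param digits significant digits written (default 6).
#' @export
writePamlMatrix <- function(R, path, pi = NULL, digits = 6L) {
  r <- if (is(R, "ExchangeabilityMatrix")) R@rho else
    exchangeabilityMatrix(R)@rho
  con <- file(path, "w"); on.exit(close(con))
  for (row in 2:20)
    writeLines(paste(signif(r[row, seq_len(row - 1L)], digits),
                     collapse = " "), con)
  if (!is.null(pi)) {
    writeLines("", con)
    writeLines(paste(signif(pi, digits), collapse = " "), con)
  }
  invisible(path)
}

#' Read / write a site-class partition map as TSV
#'
#' Two columns: `site` (1-based, contiguous 1..n) and `group` (1..k, group
#' 1 the largest).  The file round-trips losslessly.
#'
#' @param path file path.
#' @return `readPartitionMap`: integer vector of group labels (length n).
#' @export
readPartitionMap <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (!all(c("site", "group") %in% names(df)))
    stop("partition map needs 'site' and 'group' columns")
  df <- df[order(df$site), ]
  if (!identical(as.integer(df$site), seq_len(nrow(df))))
    stop("sites must cover 1..n contiguously")
  g <- as.integer(df$group)
  if (min(g) < 1L || !all(seq_len(max(g)) %in% g))
    stop("group labels must cover 1..k")
  g
}

#' @rdname readPartitionMap
#' @param labels integer group labels (or a [SiteClassPartition-class]).
#' @export
writePartitionMap <- function(labels, path) {
  if (is(labels, "SiteClassPartition")) labels <- siteLabels(labels)
  write.table(data.frame(site = seq_along(labels),
                         group = as.integer(labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
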