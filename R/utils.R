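# Internal helpers shared across modules.

# Gene/drug identity: trim whitespace, collapse internal runs, uppercase.
# No alias resolution (documented limitation).
.normSymbol <- function(x) toupper(gsub("[[:space:]]+", " ", trimws(x)))

.pairKey <- function(drug, gene) paste(drug, gene, sep = "\r")

# Nearest-rank percentile of a sorted-ascending sample: value at rank
# ceiling(p/100 * n). p = 0 maps below the sample (returns 0 for
# nonnegative data so that every observation passes a >= comparison).
.nearestRank <- function(x, p) {
  stopifnot(p >= 0, p <= 100, length(x) > 0)
  x <- sort(x)
  r <- ceiling(p / 100 * length(x))
  if (r < 1) return(0)
  x[[r]]
}

# Value of the k-th largest element where k = ceiling(q * n); genes with
# value >= this cut form the "top q fraction" (ties included).
.topFractionCut <- function(x, q) {
  stopifnot(q > 0, q <= 1, length(x) > 0)
  sort(x, decreasing = TRUE)[[ceiling(q * length(x))]]
}

.msg <- function(...) message("[crgnet] ", sprintf(...))

# Read a TSV whose first row holds cell ids and first column row ids;
# returns a validated numeric matrix, naming the offending row/column on
# parse failure. Shared by the expression and activity loaders.
.readIdMatrix <- function(path, missingTokens = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = NULL,
                    quote = "", comment.char = "")
  if (ncol(raw) < 2) stop("matrix file needs an id column and data columns: ",
                          path)
  ids <- trimws(raw[[1]])
  cells <- trimws(colnames(raw)[-1])
  dup <- .checkUniqueIds(cells, "cell-line")
  if (!is.null(dup)) stop(dup)
  vals <- as.matrix(raw[, -1, drop = FALSE])
  out <- matrix(NA_real_, nrow(vals), ncol(vals),
                dimnames = list(ids, cells))
  for (j in seq_len(ncol(vals))) {
    v <- trimws(vals[, j])
    isMissing <- v %in% missingTokens
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!isMissing & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   v[bad[1]], ids[bad[1]], cells[j]))
    num[isMissing] <- NA_real_
    out[, j] <- num
  }
  out
}
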