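#' Discard drugs with too many missing activity values
#'
#' A drug is removed when its fraction of missing cell-line activities is
#' strictly greater than `maxMissingFraction` ("more than" the threshold;
#' a drug exactly at it is retained). Removals are messaged.
#'
#' @param acts an [ActivityMatrix-class].
#' @param maxMissingFraction fraction in (0, 1); default 0.8.
#' @return the filtered [ActivityMatrix-class].
#' @export
filterDrugsByMissingness <- function(acts, maxMissingFraction = 0.8) {
  stopifnot(maxMissingFraction > 0, maxMissingFraction < 1)
  frac <- rowMeans(is.na(acts@.Data))
  drop <- frac > maxMissingFraction
  if (all(drop))
    stop("all drugs exceed the missingness threshold ", maxMissingFraction)
  if (any(drop))
    .msg("discarded %d of %d drug(s) missing in > %.0f%% of cell lines",
         sum(drop), length(drop), 100 * maxMissingFraction)
  new("ActivityMatrix", acts@.Data[!drop, , drop = FALSE])
}

#' Pearson correlation over jointly observed positions
#'
#' Computes the Pearson correlation of two equal-length series using only
#' positions where both are observed. The correlation is undefined
#' (`NA`) when fewer than `minComplete` joint observations remain or when
#' either restricted series has zero variance.
#'
#' @param x,y numeric vectors of equal length; `NA` marks gaps.
#' @param minComplete minimum joint observations (>= 3; default 10).
#' @return list with `pcc` (numeric or `NA`) and `n_complete`.
#' @export
pairwisePCC <- function(x, y, minComplete = 10) {
  if (length(x) != length(y)) stop("series lengths differ")
  stopifnot(minComplete >= 3)
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < minComplete || sd(x[ok]) == 0 || sd(y[ok]) == 0)
    return(list(pcc = NA_real_, n_complete = n))
  list(pcc = cor(x[ok], y[ok]), n_complete = n)
}

#' Build the initial drug-candidate gene edge table
#'
#' One row per (drug, gene) pair with a defined Pearson correlation between
#' the drug's activity profile and the gene's expression profile over their
#' shared cell lines (intersection, ordered as in the expression matrix).
#' Pairs whose correlation is undefined (too few joint observations or a
#' constant sub-series) are recorded in the `"undefined"` attribute with a
#' reason.
#'
#' @param acts an [ActivityMatrix-class].
#' @param expr an [ExpressionMatrix-class].
#' @param minComplete minimum joint observations per pair (default 10).
#' @return data.frame with columns `drug`, `gene`, `pcc`, `n_complete`,
#'   plus attribute `undefined` (data.frame drug/gene/reason).
#' @export
buildEdgeTable <- function(acts, expr, minComplete = 10) {
  cells <- intersect(cellIds(expr), cellIds(acts))
  if (length(cells) < minComplete)
    stop("only ", length(cells), " shared cell line(s); need >= ", minComplete)
  if (length(cells) < ncol(expr) || length(cells) < ncol(acts))
    .msg("aligning on %d shared cell line(s)", length(cells))
  A <- acts@.Data[, cells, drop = FALSE]
  E <- expr@.Data[, cells, drop = FALSE]
  # pairwise-complete correlations, vectorized over the full cross product
  suppressWarnings(
    R <- cor(t(A), t(E), use = "pairwise.complete.obs"))
  N <- (!is.na(A)) %*% t(!is.na(E))
  # zero-variance sub-series give NA/NaN from cor(); small n handled here
  R[N < minComplete] <- NA_real_
  df <- data.frame(
    drug = rep(rownames(A), times = nrow(E)),
    gene = rep(rownames(E), each = nrow(A)),
    pcc = as.vector(R),
    n_complete = as.integer(as.vector(N)),
    stringsAsFactors = FALSE)
  bad <- is.na(df$pcc)
  undef <- df[bad, c("drug", "gene", "n_complete")]
  undef$reason <- ifelse(undef$n_complete < minComplete,
                         "too few joint observations", "zero variance")
  df <- df[!bad, , drop = FALSE]
  if (nrow(df) == 0) stop("no (drug, gene) pair has a defined correlation")
  df <- df[order(df$drug, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "undefined") <- undef
  df
}

# rows of `edges` matching compendium pairs (inner join on normalized ids)
.seedEdges <- function(edges, compendium) {
  key <- .pairKey(edges$drug, edges$gene)
  p <- compendiumPairs(compendium)
  edges[key %in% .pairKey(p$drug, p$gene), , drop = FALSE]
}

#' Seed-based absolute-correlation threshold (Filter C cut)
#'
#' Ranks the absolute correlations of the seed (compendium) pairs that have
#' a defined PCC in ascending order and returns the nearest-rank
#' `percentile` value (rank `ceiling(p/100 * N)`), so that at least
#' `100 - percentile` percent of seed pairs satisfy `|pcc| >= tau`.
#'
#' @param edges edge table from [buildEdgeTable()].
#' @param compendium a [Compendium-class] of seed pairs.
#' @param percentile percentile in \[0, 100\]; default 5. `0` yields a
#'   threshold of 0 (every defined pair passes).
#' @return `tau`, the absolute-PCC threshold.
#' @export
ccrgAbsPccThreshold <- function(edges, compendium, percentile = 5) {
  se <- .seedEdges(edges, compendium)
  if (nrow(se) == 0)
    stop("no seed pair has a defined correlation; cannot set the threshold")
  .nearestRank(abs(se$pcc), percentile)
}

#' Classify a pair's correlation against the drug's correlation null
#'
#' For one (drug, gene) pair, compares its correlation `pcc` with the
#' distribution of that drug's correlations across all genes using
#' `z = |pcc - mu| / delta`. Pairs with `z` below `zThreshold` are
#' "random"; otherwise "larger" or "smaller" by the sign of `pcc - mu`.
#'
#' @param pcc the pair's correlation.
#' @param allPccs numeric vector, the drug's defined correlations across
#'   genes (at least 30).
#' @param zThreshold classification threshold; default 0.8.
#' @param sdType `"population"` (divide by n; default) or `"sample"`.
#' @return list with `z`, `class` (one of `"larger"`, `"smaller"`,
#'   `"random"`), `mu`, `delta`.
#' @export
drugNullZ <- function(pcc, allPccs, zThreshold = 0.8,
                      sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  allPccs <- allPccs[!is.na(allPccs)]
  if (length(allPccs) < 30)
    stop("need >= 30 defined correlations for the drug null")
  mu <- mean(allPccs)
  delta <- sd(allPccs)
  if (sdType == "population")
    delta <- delta * sqrt((length(allPccs) - 1) / length(allPccs))
  if (!is.finite(delta) || delta == 0)
    stop("zero spread in the drug's correlations; z undefined")
  z <- abs(pcc - mu) / delta
  cls <- if (z < zThreshold) "random"
         else if (pcc > mu) "larger" else "smaller"
  list(z = z, class = cls, mu = mu, delta = delta)
}

#' Summarize the seed-pair correlation distribution
#'
#' Reports the fraction of defined seed-pair correlations inside the bands
#' \[-0.3, 0.3\] and \[-0.5, 0.5\] plus histogram counts on bins of width
#' 0.1 over \[-1, 1\].
#'
#' @param edges edge table from [buildEdgeTable()].
#' @param compendium a [Compendium-class]; when `NULL`, all edges are
#'   summarized.
#' @return list with `n`, `frac_within_0.3`, `frac_within_0.5`, `breaks`,
#'   `counts`; all-`NA` fractions with a warning when no pair survives.
#' @export
pccDistributionSummary <- function(edges, compendium = NULL) {
  se <- if (is.null(compendium)) edges else .seedEdges(edges, compendium)
  pcc <- se$pcc[!is.na(se$pcc)]
  if (length(pcc) == 0) {
    warning("no defined correlations to summarize")
    return(list(n = 0L, frac_within_0.3 = NA_real_,
                frac_within_0.5 = NA_real_,
                breaks = seq(-1, 1, 0.1), counts = integer(20)))
  }
  breaks <- seq(-1, 1, 0.1)
  counts <- as.integer(table(cut(pcc, breaks, include.lowest = TRUE)))
  list(n = length(pcc),
       frac_within_0.3 = mean(abs(pcc) <= 0.3),
       frac_within_0.5 = mean(abs(pcc) <= 0.5),
       breaks = breaks, counts = counts)
}
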