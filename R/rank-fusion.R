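#' Rank ratios of a score vector
#'
#' Converts scores to rank ratios in (0, 1\]: rank 1 is the best score and
#' the ratio is rank / n. Ties receive the mean of the tied rank positions
#' by default (`"average"`), or the minimum with `"min"` (competition
#' ranking).
#'
#' @param scores named numeric vector.
#' @param higherIsBetter logical; default `TRUE`.
#' @param ties tie method, `"average"` (default) or `"min"`.
#' @return named numeric vector of rank ratios.
#' @export
rankRatios <- function(scores, higherIsBetter = TRUE,
                       ties = c("average", "min")) {
  ties <- match.arg(ties)
  if (length(scores) == 0) stop("no scores to rank")
  s <- if (higherIsBetter) -scores else scores
  rank(s, ties.method = ties) / length(scores)
}

#' Q order-statistic for rank aggregation
#'
#' Integrates rank ratios \eqn{r_1, \ldots, r_N} from N data sources into
#' a single score: the probability that the order statistics of N i.i.d.
#' uniform(0,1) variables fall below the sorted ratios,
#' \eqn{P(U_{(j)} \le r_{(j)} \; \forall j)}. Computed as \eqn{N! V_N}
#' with the recursion
#' \deqn{V_0 = 1, \quad V_k = \sum_{i=1}^{k} (-1)^{i-1}
#'   \frac{V_{k-i}}{i!} \, r_{(N-k+1)}^{\,i},}
#' over the ascending-sorted ratios (sorting is internal, so the result is
#' permutation invariant). Small values mean jointly strong ranks;
#' `q = 1` when every ratio is 1, and `q = r^N` when all ratios equal `r`.
#'
#' @param ratios numeric vector of rank ratios, each in (0, 1\].
#' @return the Q score in (0, 1\].
#' @export
qStatistic <- function(ratios) {
  if (length(ratios) == 0) stop("no ratios")
  if (any(is.na(ratios)) || any(ratios <= 0) || any(ratios > 1))
    stop("rank ratios must lie in (0, 1]")
  r <- sort(ratios)
  N <- length(r)
  V <- numeric(N + 1)
  V[1] <- 1
  for (k in seq_len(N)) {
    i <- seq_len(k)
    V[k + 1] <- sum((-1)^(i - 1) * V[k - i + 1] *
                      r[N - k + 1]^i / factorial(i))
  }
  factorial(N) * V[N + 1]
}

#' Fuse degree and betweenness ranks into Q scores
#'
#' Ranks the supplied genes by degree and by betweenness (both
#' higher-is-better), converts each to rank ratios, and combines the two
#' with [qStatistic()]. Genes missing either centrality are excluded with
#' a warning. Output is sorted by ascending `q_score` (strongest joint
#' evidence first), ties broken by gene id.
#'
#' @param degrees,betweenness named numeric vectors.
#' @param genes genes to rank (default: those with both centralities).
#' @param ties passed to [rankRatios()].
#' @return data.frame with columns `gene`, `rank_ratio_degree`,
#'   `rank_ratio_betweenness`, `q_score`.
#' @export
fuseGeneRanks <- function(degrees, betweenness,
                          genes = intersect(names(degrees),
                                            names(betweenness)),
                          ties = "average") {
  genes <- unique(.normSymbol(genes))
  have <- genes %in% names(degrees) & genes %in% names(betweenness)
  if (any(!have)) {
    warning(sum(!have), " gene(s) missing a centrality excluded")
    genes <- genes[have]
  }
  if (length(genes) == 0) stop("no genes with both centralities")
  rd <- rankRatios(degrees[genes], ties = ties)
  rb <- rankRatios(betweenness[genes], ties = ties)
  q <- vapply(seq_along(genes), function(i) qStatistic(c(rd[i], rb[i])), 0)
  out <- data.frame(gene = genes, rank_ratio_degree = unname(rd),
                    rank_ratio_betweenness = unname(rb),
                    q_score = q, stringsAsFactors = FALSE)
  out <- out[order(out$q_score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
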