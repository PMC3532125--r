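#' Hypergeometric over-representation p-value
#'
#' Probability, under random selection of `nPred` predictions from `M`
#' candidate pairs containing `m` seed pairs, of hitting at least `nHit`
#' seeds: the upper hypergeometric tail
#' \eqn{\sum_{x \ge n} C(N, x) C(M-N, m-x) / C(M, m)}.
#'
#' @param M total candidate pairs.
#' @param nPred number of predicted pairs.
#' @param m seed pairs among the candidates.
#' @param nHit seed pairs among the predictions.
#' @return p-value in (0, 1\].
#' @export
hypergeomOverrepP <- function(M, nPred, m, nHit) {
  if (any(c(M, nPred, m, nHit) < 0) || nHit > m || nHit > nPred ||
      m > M || nPred > M || nHit < nPred - (M - m))
    stop("inconsistent hypergeometric counts")
  phyper(nHit - 1, nPred, M - nPred, m, lower.tail = FALSE)
}

#' ROC curve and AUC via the rank (Mann-Whitney) statistic
#'
#' Higher scores must indicate the positive class. The AUC equals
#' U / (n_pos * n_neg) with tied scores contributing half credit, and the
#' curve is the (sensitivity, specificity) path of a threshold sweep over
#' the distinct scores.
#'
#' @param scores named numeric vector.
#' @param labels logical (or coercible) vector aligned with `scores`,
#'   `TRUE` for positives.
#' @return list with `auc`, `n_pos`, `n_neg`, and `curve` (data.frame
#'   `threshold`, `sensitivity`, `specificity`).
#' @export
rocAUC <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0 || nNeg == 0)
    stop("need at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  U <- sum(r[labels]) - nPos * (nPos + 1) / 2
  auc <- U / (nPos * nNeg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last <- which(!duplicated(s, fromLast = TRUE))  # end of each tied block
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  list(auc = auc, n_pos = nPos, n_neg = nNeg,
       curve = data.frame(threshold = s[last], sensitivity = tp / nPos,
                          specificity = 1 - fp / nNeg))
}

# top-K pairs by |pcc|, deterministic tie-break (|pcc| desc, drug, gene)
.topKByAbsPcc <- function(edges, K) {
  if (K > nrow(edges))
    stop("matched count K = ", K, " exceeds ", nrow(edges), " edges")
  if (K == 0) return(edges[0, , drop = FALSE])
  o <- order(-abs(edges$pcc), edges$drug, edges$gene)
  out <- edges[o[seq_len(K)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare the combined filter with the matched-count correlation baseline
#'
#' For each threshold in `thresholds` (used for both the degree and the
#' betweenness top fraction), forms the combined method's predicted pairs
#' (genes passing Filters A and B, pairs passing the |PCC| cut `tau`) and
#' a correlation-only baseline constrained to the same number of pairs
#' (top |PCC|), then counts the seed pairs each identifies and computes
#' the hypergeometric over-representation p-value of each against the pool
#' of candidate pairs. Also reports ROC curves over the drug-gene pairs
#' whose gene sits in the network: the combined method scores every pair
#' by `-q_score` of its gene from degree/betweenness rank fusion (each
#' gene appears in the same number of pairs, so this equals the
#' gene-level ROC), the baseline scores each pair by its absolute
#' correlation; a pair is positive when its gene is a compendium gene.
#'
#' @param edges edge table from [buildEdgeTable()].
#' @param compendium a [Compendium-class] of seed pairs.
#' @param candidateGenes genes passing Filter A (from
#'   [candidateGenesFromTerms()]).
#' @param degrees,betweenness centrality vectors over network genes.
#' @param tau absolute-PCC threshold (from [ccrgAbsPccThreshold()]).
#' @param thresholds numeric vector of joint top fractions; default
#'   `seq(0.01, 0.20, by = 0.01)`.
#' @return list with `table` (data.frame threshold, method,
#'   n_predicted, n_identified_seeds, enrichment_p), `roc_combined`,
#'   `roc_baseline` (from [rocAUC()]).
#' @export
compareWithBaseline <- function(edges, compendium, candidateGenes,
                                degrees, betweenness, tau,
                                thresholds = seq(0.01, 0.20, by = 0.01)) {
  seedKey <- with(compendiumPairs(compendium), .pairKey(drug, gene))
  key <- .pairKey(edges$drug, edges$gene)
  M <- nrow(edges)
  m <- sum(key %in% seedKey)
  rows <- lapply(thresholds, function(q) {
    gset <- topFractionFilter(degrees, betweenness,
                              genes = candidateGenes,
                              qDegree = q, qBetweenness = q)
    pred <- edges$gene %in% gset & abs(edges$pcc) >= tau
    K <- sum(pred)
    base <- .topKByAbsPcc(edges, K)
    nHitC <- sum(key[pred] %in% seedKey)
    nHitB <- sum(.pairKey(base$drug, base$gene) %in% seedKey)
    data.frame(threshold = q,
               method = c("combined", "correlation-only"),
               n_predicted = K,
               n_identified_seeds = c(nHitC, nHitB),
               enrichment_p = c(
                 if (K) hypergeomOverrepP(M, K, m, nHitC) else 1,
                 if (K) hypergeomOverrepP(M, K, m, nHitB) else 1),
               stringsAsFactors = FALSE)
  })
  univ <- intersect(unique(edges$gene),
                    intersect(names(degrees), names(betweenness)))
  fused <- fuseGeneRanks(degrees, betweenness, genes = univ)
  combScore <- setNames(-fused$q_score, fused$gene)
  ev <- edges[edges$gene %in% univ, , drop = FALSE]
  labels <- ev$gene %in% geneIds(compendium)
  list(table = do.call(rbind, rows),
       roc_combined = rocAUC(unname(combScore[ev$gene]), labels),
       roc_baseline = rocAUC(abs(ev$pcc), labels))
}
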