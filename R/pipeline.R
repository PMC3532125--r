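#' Pipeline configuration
#'
#' Collects every tunable of the three-filter prioritization with its
#' default: Filter A (enrichment cutoff `alpha`, ontology `depthLimit` and
#' `depthRule`), Filter B (top fractions `qDegree`, `qBetweenness`),
#' Filter C (`pccPercentile` of the seed pairs' absolute correlations),
#' plus the drug missingness cutoff, the minimum joint observations per
#' correlation, the z classification threshold, the number of null
#' permutations and the RNG seed. The realized configuration is embedded
#' in every [PredictionTable-class] for provenance.
#'
#' @param alpha Filter A raw p-value cutoff (default 0.01).
#' @param depthLimit ontology depth for enrichment (default 5).
#' @param depthRule `"equal"` or `"atMost"` (default `"equal"`).
#' @param qDegree,qBetweenness Filter B top fractions in (0, 1\]
#'   (default 0.01 each).
#' @param pccPercentile Filter C percentile of seed |PCC|s (default 5).
#' @param minComplete minimum joint observations per correlation
#'   (default 10).
#' @param maxMissingFraction drug missingness cutoff (default 0.8).
#' @param zThreshold correlation-null classification threshold
#'   (default 0.8).
#' @param nPerm permutations for the centrality null reports
#'   (default 999).
#' @param seed RNG seed for every stochastic step (default 1).
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(alpha = 0.01, depthLimit = 5,
                           depthRule = "equal", qDegree = 0.01,
                           qBetweenness = 0.01, pccPercentile = 5,
                           minComplete = 10, maxMissingFraction = 0.8,
                           zThreshold = 0.8, nPerm = 999, seed = 1) {
  stopifnot(alpha >= 0, alpha <= 1, qDegree > 0, qDegree <= 1,
            qBetweenness > 0, qBetweenness <= 1,
            pccPercentile >= 0, pccPercentile <= 100,
            maxMissingFraction > 0, maxMissingFraction < 1,
            minComplete >= 3, zThreshold >= 0, nPerm >= 1)
  list(alpha = alpha, depthLimit = depthLimit, depthRule = depthRule,
       qDegree = qDegree, qBetweenness = qBetweenness,
       pccPercentile = pccPercentile, minComplete = minComplete,
       maxMissingFraction = maxMissingFraction, zThreshold = zThreshold,
       nPerm = nPerm, seed = seed,
       version = as.character(packageVersion("crgnet")))
}

.stageCheck <- function(n, stage, detail) {
  if (n == 0)
    stop("stage '", stage, "' emptied the candidate set (", detail, ")")
  invisible(n)
}

#' Run the combined three-filter prioritization
#'
#' Executes, in order: the drug missingness filter; the drug-gene edge
#' table (pairwise-complete Pearson correlations); Filter A (genes
#' annotated to seed-enriched, depth-limited ontology terms); Filter B
#' (top-fraction degree AND betweenness among network genes); Filter C
#' (absolute correlation at least the seed-percentile threshold `tau`);
#' and degree/betweenness rank fusion over the surviving genes. Every
#' stage logs its in/out cardinalities; a stage that empties the candidate
#' set raises an error naming the stage and its threshold. Alongside the
#' prediction table the characterization reports are returned: the
#' enrichment table, the centrality null comparisons, and the seed-pair
#' correlation distribution summary.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param acts an [ActivityMatrix-class].
#' @param network an undirected `igraph` (see [loadNetwork()]).
#' @param annotation a [GeneAnnotation-class].
#' @param dag an [OntologyDAG-class].
#' @param compendium a [Compendium-class] of seed pairs.
#' @param config a [pipelineConfig()].
#' @param characterize logical; compute the permutation null-comparison
#'   reports (default `TRUE`; they are diagnostic only).
#' @return a [PredictionTable-class].
#' @export
runPipeline <- function(expr, acts, network, annotation, dag, compendium,
                        config = pipelineConfig(), characterize = TRUE) {
  seeds <- geneIds(compendium)

  acts <- filterDrugsByMissingness(acts, config$maxMissingFraction)
  .msg("missingness filter: %d drug(s) retained", nrow(acts))

  edges <- buildEdgeTable(acts, expr, minComplete = config$minComplete)
  .msg("edge table: %d (drug, gene) pair(s) with defined PCC", nrow(edges))

  # Filter A: genes in seed-enriched depth-limited terms
  background <- intersect(unique(unlist(geneSets(annotation))),
                          geneIds(expr))
  enr <- enrichedTerms(seeds, annotation, dag, background = background,
                       alpha = config$alpha,
                       depthLimit = config$depthLimit,
                       depthRule = config$depthRule)
  .stageCheck(nrow(enr), "Filter A (GO enrichment)",
              sprintf("alpha = %g, depth %s %d", config$alpha,
                      if (config$depthRule == "equal") "==" else "<=",
                      config$depthLimit))
  goGenes <- suppressWarnings(
    candidateGenesFromTerms(enr, annotation, measured = geneIds(expr)))
  .stageCheck(length(goGenes), "Filter A (GO enrichment)",
              sprintf("alpha = %g", config$alpha))
  .msg("Filter A: %d enriched term(s) -> %d candidate gene(s)",
       nrow(enr), length(goGenes))

  # Filter B: joint top-fraction centrality
  deg <- degreeMap(network)
  btw <- betweennessMap(network)
  netGenes <- topFractionFilter(deg, btw, genes = goGenes,
                                qDegree = config$qDegree,
                                qBetweenness = config$qBetweenness)
  .stageCheck(length(netGenes), "Filter B (network centrality)",
              sprintf("qDegree = %g, qBetweenness = %g",
                      config$qDegree, config$qBetweenness))
  .msg("Filter B: %d candidate gene(s) in the top fractions",
       length(netGenes))

  # Filter C: seed-percentile |PCC| threshold
  tau <- ccrgAbsPccThreshold(edges, compendium,
                             percentile = config$pccPercentile)
  keep <- edges$gene %in% netGenes & abs(edges$pcc) >= tau
  .stageCheck(sum(keep), "Filter C (|PCC| threshold)",
              sprintf("tau = %g (percentile %g)", tau,
                      config$pccPercentile))
  .msg("Filter C: tau = %.4g; %d pair(s) survive all filters",
       tau, sum(keep))

  surv <- edges[keep, , drop = FALSE]
  fused <- fuseGeneRanks(deg, btw, genes = unique(surv$gene))
  tab <- merge(surv, fused, by = "gene", sort = FALSE)
  tab$degree <- as.numeric(deg[tab$gene])
  tab$betweenness <- as.numeric(btw[tab$gene])
  tab$pass_go <- TRUE; tab$pass_network <- TRUE; tab$pass_pcc <- TRUE
  tab <- tab[, c("drug", "gene", "pcc", "n_complete", "degree",
                 "betweenness", "rank_ratio_degree",
                 "rank_ratio_betweenness", "q_score",
                 "pass_go", "pass_network", "pass_pcc")]
  tab <- tab[order(tab$drug, tab$q_score, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL

  reports <- list(enrichment = enr,
                  pcc_summary = suppressWarnings(
                    pccDistributionSummary(edges, compendium)),
                  tau = tau, candidate_genes_go = goGenes,
                  candidate_genes_network = netGenes)
  if (characterize) {
    reports$null_degree <- randomSetNullComparison(
      deg, seeds, nPerm = config$nPerm, seed = config$seed,
      metric = "degree")
    reports$null_betweenness <- randomSetNullComparison(
      btw, seeds, nPerm = config$nPerm, seed = config$seed + 1L,
      metric = "betweenness")
  }
  cfg <- config
  cfg$tau <- tau
  new("PredictionTable", table = tab, config = cfg, reports = reports)
}

#' Matched-count correlation-only baseline
#'
#' The comparison method: rank all (drug, gene) edges by absolute Pearson
#' correlation and keep the top `K`, where `K` defaults to the number of
#' pairs the combined method predicted (the matched-count rule). Tie-break
#' at the K-th |PCC| is deterministic (|PCC| descending, then drug, then
#' gene).
#'
#' @param edges edge table from [buildEdgeTable()].
#' @param combined a [PredictionTable-class] from [runPipeline()] (used
#'   for `K` and the provenance config), or `NULL` if `K` is given.
#' @param K number of pairs to keep; default `nrow(predictions(combined))`.
#' @return a [PredictionTable-class] with centrality/fusion columns `NA`
#'   and filter flags `FALSE` except `pass_pcc`.
#' @export
runBaseline <- function(edges, combined = NULL, K = NULL) {
  if (is.null(K)) {
    if (is.null(combined)) stop("either 'combined' or 'K' is required")
    K <- nrow(predictions(combined))
  }
  top <- .topKByAbsPcc(edges, K)
  n <- nrow(top)
  tab <- data.frame(drug = top$drug, gene = top$gene, pcc = top$pcc,
                    n_complete = top$n_complete,
                    degree = rep(NA_real_, n),
                    betweenness = rep(NA_real_, n),
                    rank_ratio_degree = rep(NA_real_, n),
                    rank_ratio_betweenness = rep(NA_real_, n),
                    q_score = rank(-abs(top$pcc),
                                   ties.method = "average") /
                      max(1, n),
                    pass_go = rep(FALSE, n), pass_network = rep(FALSE, n),
                    pass_pcc = rep(TRUE, n), stringsAsFactors = FALSE)
  cfg <- if (is.null(combined)) list(method = "correlation-only", K = K)
         else c(pipelineConfigOf(combined), method = "correlation-only")
  new("PredictionTable", table = tab, config = cfg, reports = list())
}
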