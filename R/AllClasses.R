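#' @import methods
#' @importFrom stats cor sd quantile rnorm runif setNames complete.cases
#'   dhyper phyper p.adjust
#' @importFrom utils read.delim write.table head combn packageVersion
NULL

.checkUniqueIds <- function(ids, what) {
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    return(sprintf("%s identifiers must be non-empty", what))
  if (anyDuplicated(ids))
    return(sprintf("duplicate %s identifiers: %s", what,
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  NULL
}

#' Gene-expression matrix (genes x cell lines)
#'
#' A numeric matrix of log-scale expression intensities with unique gene
#' symbols as row names and unique cell-line labels as column names. All
#' values must be finite and at least three cell lines are required, since
#' downstream correlations are meaningless below that.
#'
#' @slot .Data numeric matrix, genes x cells.
#' @export
setClass("ExpressionMatrix", contains = "matrix", validity = function(object) {
  msgs <- c(.checkUniqueIds(rownames(object), "gene"),
            .checkUniqueIds(colnames(object), "cell-line"))
  if (!is.numeric(object@.Data))
    msgs <- c(msgs, "expression values must be numeric")
  else if (any(!is.finite(object@.Data)))
    msgs <- c(msgs, "expression values must all be finite")
  if (ncol(object) < 3)
    msgs <- c(msgs, "at least 3 cell lines are required")
  if (length(msgs)) msgs else TRUE
})

#' Drug-activity matrix (drugs x cell lines)
#'
#' A numeric matrix of lgGI50 values (log10 of the concentration inhibiting
#' growth by 50%) with unique drug labels as row names. Missing activity
#' values are explicit `NA`s, never silent zeros.
#'
#' @slot .Data numeric matrix, drugs x cells, `NA` permitted.
#' @export
setClass("ActivityMatrix", contains = "matrix", validity = function(object) {
  msgs <- c(.checkUniqueIds(rownames(object), "drug"),
            .checkUniqueIds(colnames(object), "cell-line"))
  if (!is.numeric(object@.Data))
    msgs <- c(msgs, "activity values must be numeric")
  else if (any(is.infinite(object@.Data)))
    msgs <- c(msgs, "activity values must be finite or NA")
  if (ncol(object) < 3)
    msgs <- c(msgs, "at least 3 cell lines are required")
  if (length(msgs)) msgs else TRUE
})

#' Curated drug-gene compendium
#'
#' Literature-curated pairs of a drug and a chemosensitivity-related gene
#' (CCRGs), the seed/positive-label source for the whole pipeline. The
#' identity key is the (drug, gene) pair after whitespace trimming and case
#' normalization; optional columns record the cell line, PubMed id and a
#' free-text description.
#'
#' @slot pairs data.frame with columns `drug`, `gene` and optionally
#'   `cell_line`, `pmid`, `description`; one row per distinct pair.
#' @export
setClass("Compendium", representation(pairs = "data.frame"),
  validity = function(object) {
    p <- object@pairs
    msgs <- character()
    if (!all(c("drug", "gene") %in% names(p)))
      msgs <- c(msgs, "pairs must have 'drug' and 'gene' columns")
    else {
      if (any(!nzchar(p$drug)) || any(!nzchar(p$gene)))
        msgs <- c(msgs, "drug and gene names must be non-empty")
      if (anyDuplicated(paste(p$drug, p$gene, sep = "\r")))
        msgs <- c(msgs, "duplicate (drug, gene) pairs")
    }
    if (length(msgs)) msgs else TRUE
  })

#' Gene-set annotation (term -> genes)
#'
#' Maps annotation-term identifiers (e.g. GO ids) to sets of gene symbols,
#' with optional human-readable names and a namespace (BP/MF/CC) per term.
#'
#' @slot sets named list of character vectors (unique, uppercased symbols).
#' @slot termNames named character, term descriptions ("" when absent).
#' @slot namespaces named character, term namespaces ("" when unknown).
#' @export
setClass("GeneAnnotation",
  representation(sets = "list", termNames = "character",
                 namespaces = "character"),
  validity = function(object) {
    msgs <- character()
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      msgs <- c(msgs, "term ids must be unique and named")
    if (any(lengths(object@sets) == 0))
      msgs <- c(msgs, "every term must annotate at least one gene")
    if (length(msgs)) msgs else TRUE
  })

#' Ontology DAG with precomputed term depths
#'
#' Child-to-parent links of an ontology, validated acyclic, with the roots
#' (parentless terms) auto-detected and the depth of every term (length of
#' the shortest path from a root) precomputed at construction.
#'
#' @slot parents named list: term id -> character vector of parent ids.
#' @slot roots character, parentless term ids.
#' @slot depths named integer, shortest-path depth from the nearest root.
#' @export
setClass("OntologyDAG",
  representation(parents = "list", roots = "character", depths = "integer"),
  validity = function(object) {
    msgs <- character()
    if (length(object@roots) == 0)
      msgs <- c(msgs, "DAG must have at least one root")
    if (any(is.na(object@depths)))
      msgs <- c(msgs, "some terms cannot reach a root")
    if (length(msgs)) msgs else TRUE
  })

#' Table of prioritized drug-gene predictions
#'
#' Per-drug surviving (drug, gene) pairs after the three filters, with the
#' evidence behind each: Pearson correlation, centralities, rank ratios,
#' the fused Q score and per-filter pass flags. The configuration that
#' produced the table is carried along for provenance.
#'
#' @slot table data.frame with columns drug, gene, pcc, n_complete, degree,
#'   betweenness, rank_ratio_degree, rank_ratio_betweenness, q_score,
#'   pass_go, pass_network, pass_pcc.
#' @slot config list, the [pipelineConfig()] used (plus derived values such
#'   as the realized PCC threshold `tau`).
#' @slot reports list of characterization reports (enrichment table,
#'   centrality null comparisons, PCC distribution summary).
#' @export
setClass("PredictionTable",
  representation(table = "data.frame", config = "list", reports = "list"),
  validity = function(object) {
    need <- c("drug", "gene", "pcc", "n_complete", "degree", "betweenness",
              "rank_ratio_degree", "rank_ratio_betweenness", "q_score",
              "pass_go", "pass_network", "pass_pcc")
    msgs <- character()
    if (!all(need %in% names(object@table)))
      msgs <- c(msgs, paste("missing columns:",
                            paste(setdiff(need, names(object@table)),
                                  collapse = ", ")))
    else if (nrow(object@table) &&
             anyDuplicated(paste(object@table$drug, object@table$gene,
                                 sep = "\r")))
      msgs <- c(msgs, "(drug, gene) pairs must be unique")
    if (length(msgs)) msgs else TRUE
  })
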