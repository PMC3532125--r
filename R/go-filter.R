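#' Depth of an ontology term
#'
#' Depth is the length of the shortest child-to-parent path from the term
#' to a root of its namespace (roots have depth 0); precomputed at DAG
#' construction.
#'
#' @param dag an [OntologyDAG-class].
#' @param termId term identifier(s).
#' @return integer depth(s).
#' @export
termDepth <- function(dag, termId) {
  miss <- setdiff(termId, names(dag@depths))
  if (length(miss))
    stop("unknown term(s): ", paste(miss, collapse = ", "))
  dag@depths[termId]
}

.checkTable <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("negative contingency cell")
  if (any(cells != floor(cells))) stop("contingency cells must be integers")
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    stop("degenerate contingency table: a zero margin")
  invisible(cells)
}

#' Exact point probability of a 2x2 table
#'
#' Hypergeometric point mass of the observed table at fixed margins,
#' `(a+b)! (c+d)! (a+c)! (b+d)! / (n! a! b! c! d!)`, evaluated in log space.
#' Cells follow the standard disjoint layout: `a` = study genes in the
#' term, `b` = non-study background genes in the term, `c` = study genes
#' outside it, `d` = the remaining background.
#'
#' @param a,b,c,d nonnegative integer cell counts with positive margins.
#' @return the point probability in (0, 1\].
#' @export
fisherPointProbability <- function(a, b, c, d) {
  .checkTable(a, b, c, d)
  # drawing the a+c study genes from n, of which a+b lie in the term
  dhyper(a, a + b, c + d, a + c)
}

#' One-sided enrichment p-value of a 2x2 table
#'
#' Upper hypergeometric tail: the total point probability of all tables
#' with the same margins and at least `a` study genes in the term.
#'
#' @inheritParams fisherPointProbability
#' @return the tail probability in (0, 1\].
#' @export
fisherEnrichmentP <- function(a, b, c, d) {
  .checkTable(a, b, c, d)
  phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Depth-limited Fisher-exact term enrichment of a gene list
#'
#' Tests every annotation term for over-representation of `studyGenes`
#' against `background` with the one-sided Fisher exact (hypergeometric)
#' test, keeping terms whose raw tail p-value is at most `alpha` and whose
#' ontology depth satisfies the depth rule. All namespaces are considered.
#' No multiple-testing correction is applied by default (set
#' `pAdjust = "BH"` to add an adjusted column and filter on it).
#'
#' @param studyGenes character vector of study gene symbols.
#' @param annotation a [GeneAnnotation-class].
#' @param dag an [OntologyDAG-class]; terms absent from it are skipped.
#' @param background character vector of background gene symbols; default
#'   is every annotated gene. Study genes outside the background are
#'   dropped with a message.
#' @param alpha raw p-value cutoff; default 0.01.
#' @param depthLimit target depth; default 5.
#' @param depthRule `"equal"` (depth == limit; default) or `"atMost"`.
#' @param pAdjust `"none"` (default) or a [stats::p.adjust()] method.
#' @return data.frame with columns `term`, `name`, `namespace`, `depth`,
#'   `a`, `b`, `c`, `d`, `p_point`, `p_tail` (and `p_adjust` unless
#'   "none"), ordered by `p_tail`.
#' @export
enrichedTerms <- function(studyGenes, annotation, dag,
                          background = NULL, alpha = 0.01,
                          depthLimit = 5, depthRule = c("equal", "atMost"),
                          pAdjust = "none") {
  depthRule <- match.arg(depthRule)
  stopifnot(alpha >= 0, alpha <= 1)
  sets <- geneSets(annotation)
  if (is.null(background))
    background <- unique(unlist(sets, use.names = FALSE))
  background <- unique(.normSymbol(background))
  study <- intersect(unique(.normSymbol(studyGenes)), background)
  if (length(study) < length(unique(.normSymbol(studyGenes))))
    .msg("%d study gene(s) outside the background dropped",
         length(unique(.normSymbol(studyGenes))) - length(study))
  annotated <- unique(unlist(sets, use.names = FALSE))
  if (length(intersect(study, annotated)) == 0)
    stop("no study gene carries any annotation")
  known <- intersect(names(sets), names(dag@depths))
  rows <- lapply(known, function(id) {
    term <- intersect(sets[[id]], background)
    a <- length(intersect(study, term))
    b <- length(term) - a
    c <- length(study) - a
    d <- length(background) - length(study) - b
    if (a + b == 0 || c + d == 0) return(NULL)
    data.frame(term = id,
               name = unname(annotation@termNames[id]),
               namespace = unname(annotation@namespaces[id]),
               depth = unname(termDepth(dag, id)),
               a = a, b = b, c = c, d = d,
               p_point = fisherPointProbability(a, b, c, d),
               p_tail = fisherEnrichmentP(a, b, c, d),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(term = character(), name = character(),
                      namespace = character(), depth = integer(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), p_point = numeric(),
                      p_tail = numeric(), stringsAsFactors = FALSE)
  okDepth <- if (depthRule == "equal") res$depth == depthLimit
             else res$depth <= depthLimit
  pUse <- res$p_tail
  if (pAdjust != "none") {
    res$p_adjust <- p.adjust(res$p_tail, method = pAdjust)
    pUse <- res$p_adjust
  }
  res <- res[okDepth & pUse <= alpha, , drop = FALSE]
  res <- res[order(res$p_tail, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Candidate genes from enriched terms
#'
#' The union of all genes annotated to the enriched terms, optionally
#' restricted to the measured genes. An empty result is allowed (with a
#' warning): it signals Filter A leaves nothing.
#'
#' @param results data.frame from [enrichedTerms()].
#' @param annotation a [GeneAnnotation-class].
#' @param measured optional character vector restricting the union.
#' @return character vector of candidate gene symbols, sorted.
#' @export
candidateGenesFromTerms <- function(results, annotation, measured = NULL) {
  sets <- geneSets(annotation)
  genes <- unique(unlist(sets[intersect(results$term, names(sets))],
                         use.names = FALSE))
  if (!is.null(measured)) genes <- intersect(genes, .normSymbol(measured))
  if (length(genes) == 0) warning("no candidate genes from enriched terms")
  sort(genes)
}

.jaccard <- function(x, y) {
  u <- length(union(x, y))
  if (u == 0) return(0)
  length(intersect(x, y)) / u
}

.meanPairwiseSimilarity <- function(terms, sets) {
  if (length(terms) < 2) return(NA_real_)
  cmb <- combn(terms, 2)
  mean(vapply(seq_len(ncol(cmb)), function(k)
    .jaccard(sets[[cmb[1, k]]], sets[[cmb[2, k]]]), 0))
}

#' Functional coherence of a gene list's enriched terms
#'
#' Measures how similar the enriched terms of the study genes are to one
#' another (mean pairwise Jaccard similarity of the terms' annotated gene
#' sets) and compares it to the same statistic for random gene draws of
#' equal size, giving an empirical p-value with the +1 correction.
#'
#' @inheritParams enrichedTerms
#' @param nDraws number of random gene sets (>= 100; default 100).
#' @param seed RNG seed for the draws.
#' @param ... passed on to [enrichedTerms()].
#' @return list with `observed` (mean pairwise similarity; `NA` with fewer
#'   than 2 enriched terms), `null` (vector of null means), `p_empirical`.
#' @export
termSetSimilarity <- function(studyGenes, annotation, dag,
                              background = NULL, nDraws = 100, seed = 1,
                              ...) {
  stopifnot(nDraws >= 100)
  sets <- geneSets(annotation)
  if (is.null(background))
    background <- unique(unlist(sets, use.names = FALSE))
  study <- intersect(unique(.normSymbol(studyGenes)),
                     unique(.normSymbol(background)))
  res <- enrichedTerms(study, annotation, dag, background = background, ...)
  observed <- .meanPairwiseSimilarity(res$term, sets)
  if (is.na(observed))
    return(list(observed = NA_real_, null = numeric(0),
                p_empirical = NA_real_))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null <- vapply(seq_len(nDraws), function(i) {
    rnd <- sample(background, length(study))
    r <- tryCatch(
      enrichedTerms(rnd, annotation, dag, background = background, ...),
      error = function(e) NULL)
    s <- .meanPairwiseSimilarity(r$term, sets)
    if (is.na(s)) 0 else s
  }, 0)
  list(observed = observed, null = null,
       p_empirical = (sum(null >= observed) + 1) / (nDraws + 1))
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
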