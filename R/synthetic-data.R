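#' Specification of a synthetic screen fixture
#'
#' Defaults emulate an NCI-60-style study: a ~60-cell-line panel screened
#' for expression and drug activity with missing activity values, a
#' scale-free-like interaction network in which the seed genes are biased
#' toward hub/bottleneck positions, an ontology in which the seed genes
#' concentrate in a few depth-5 terms, and planted drug-gene correlations
#' spanning weak (|r| ~ 0.1) to strong (|r| ~ 0.6) effects so that most
#' planted pairs fall in the weakly correlated regime.
#'
#' @param nGenes number of genes (>= 50; default 2000).
#' @param nDrugs number of drugs (default 50).
#' @param nCells number of cell lines (default 60).
#' @param nSeedGenes number of planted seed genes (default 40).
#' @param nSeedPairs number of planted drug-gene pairs (default 40, one
#'   drug per pair).
#' @param plantedPccRange range of planted |correlations| (default
#'   c(0.1, 0.6)); signs alternate.
#' @param hubBias attachment bonus (>= 0) for seed genes during network
#'   growth; 0 makes seeds indistinguishable from background (default 25).
#' @param edgesPerNode preferential-attachment edges per added node
#'   (default 3).
#' @param nTerms number of depth-5 annotation terms (default 100).
#' @param seedTermCount number of terms the seed genes concentrate in
#'   (default 5).
#' @param termSize genes drawn per background term (default 20).
#' @param missingRate fraction of activity entries masked at random
#'   (default 0.1).
#' @param seed RNG seed for the whole bundle.
#' @return a `FixtureSpec` list.
#' @export
fixtureSpec <- function(nGenes = 2000, nDrugs = 50, nCells = 60,
                        nSeedGenes = 40, nSeedPairs = 40,
                        plantedPccRange = c(0.1, 0.6), hubBias = 25,
                        edgesPerNode = 3, nTerms = 100, seedTermCount = 5,
                        termSize = 20, missingRate = 0.1, seed = 1) {
  spec <- list(nGenes = nGenes, nDrugs = nDrugs, nCells = nCells,
               nSeedGenes = nSeedGenes, nSeedPairs = nSeedPairs,
               plantedPccRange = plantedPccRange, hubBias = hubBias,
               edgesPerNode = edgesPerNode, nTerms = nTerms,
               seedTermCount = seedTermCount, termSize = termSize,
               missingRate = missingRate, seed = seed)
  with(spec, {
    stopifnot(nGenes >= 50, nSeedGenes <= nGenes, nSeedPairs <= nDrugs,
              hubBias >= 0, missingRate >= 0, missingRate < 1,
              seedTermCount <= nTerms, nCells >= 10,
              all(plantedPccRange >= 0), all(plantedPccRange < 1))
  })
  spec
}

.geneNames <- function(n) sprintf("G%04d", seq_len(n))
.drugNames <- function(n) sprintf("DRUG%03d", seq_len(n))
.seedGenesOf <- function(spec) .geneNames(spec$nGenes)[seq_len(spec$nSeedGenes)]

#' Generate a scale-free-like interaction network with hub-biased seeds
#'
#' Grows a preferential-attachment graph: nodes are added in random order
#' and each new node attaches `edgesPerNode` edges to existing nodes with
#' probability proportional to `degree + 1 + hubBias * isSeed`. A positive
#' `hubBias` drives the planted seed genes toward hub/bottleneck
#' positions; `hubBias = 0` leaves them exchangeable with the background.
#'
#' @param spec a [fixtureSpec()].
#' @return an undirected simple `igraph` over the gene symbols.
#' @export
generateNetwork <- function(spec) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  genes <- .geneNames(spec$nGenes)
  isSeed <- setNames(genes %in% .seedGenesOf(spec), genes)
  ord <- sample(genes)
  m <- spec$edgesPerNode
  deg <- setNames(integer(spec$nGenes), genes)
  from <- character(0); to <- character(0)
  for (i in seq_along(ord)) {
    if (i == 1) next
    prev <- ord[seq_len(i - 1)]
    w <- deg[prev] + 1 + spec$hubBias * isSeed[prev]
    k <- min(m, length(prev))
    tgt <- if (length(prev) == 1) prev
           else sample(prev, k, prob = w)
    from <- c(from, rep(ord[i], k)); to <- c(to, tgt)
    deg[tgt] <- deg[tgt] + 1L
    deg[ord[i]] <- deg[ord[i]] + k
  }
  g <- igraph::graph_from_data_frame(data.frame(from, to), directed = FALSE,
                                     vertices = genes)
  igraph::simplify(g)
}

#' Generate an ontology DAG and annotation with concentrated seed terms
#'
#' Builds a rooted tree of depth 6 whose level-5 layer carries the
#' annotation terms (`nTerms`, plus a handful of shallower decoy terms at
#' depth 2 to exercise the depth filter). The planted seed genes are
#' concentrated into `seedTermCount` depth-5 terms; every term is padded
#' with uniformly drawn background genes.
#'
#' @param spec a [fixtureSpec()].
#' @return list with `annotation` ([GeneAnnotation-class]) and `dag`
#'   ([OntologyDAG-class]).
#' @export
generateAnnotation <- function(spec) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 1L)
  genes <- .geneNames(spec$nGenes)
  seeds <- .seedGenesOf(spec)
  # skeleton: root -> L1 ... -> L6; terms at depth 5 are the annotated ones
  nBranch <- max(2L, ceiling(spec$nTerms / 16))
  layers <- list("SYN:ROOT")
  child <- character(); parent <- character()
  for (d in 1:6) {
    nAt <- if (d == 5) spec$nTerms else nBranch * d
    ids <- sprintf("SYN:L%d_%03d", d, seq_len(nAt))
    parent <- c(parent, sample(layers[[d]], nAt, replace = TRUE))
    child <- c(child, ids)
    layers[[d + 1]] <- ids
  }
  dag <- .makeDAG(child, parent)
  depth5 <- layers[[6]]
  decoys <- sample(layers[[3]], min(4, length(layers[[3]])))
  seedTerms <- depth5[seq_len(spec$seedTermCount)]
  sets <- list()
  seedSplit <- split(seeds, rep(seq_len(spec$seedTermCount),
                                length.out = length(seeds)))
  for (k in seq_along(seedTerms))
    sets[[seedTerms[k]]] <- unique(c(
      seedSplit[[k]], sample(genes, ceiling(spec$termSize / 2))))
  for (t in setdiff(depth5, seedTerms))
    sets[[t]] <- sample(genes, spec$termSize)
  for (t in decoys) sets[[t]] <- sample(genes, spec$termSize)
  ids <- names(sets)
  ann <- new("GeneAnnotation", sets = sets,
             termNames = setNames(paste("synthetic term", ids), ids),
             namespaces = setNames(rep("BP", length(ids)), ids))
  list(annotation = ann, dag = dag)
}

#' Generate expression/activity matrices with planted correlations
#'
#' Expression values are i.i.d. standard normal per gene. Each planted
#' (drug, gene) pair receives activity
#' `rho * scale(expression) + sqrt(1 - rho^2) * noise` (a Gaussian copula:
#' the population correlation is exactly the target), with targets evenly
#' spanning `plantedPccRange` and alternating sign. Remaining drugs are
#' pure noise. Activity entries are then masked completely at random at
#' `missingRate`. The compendium lists the planted pairs.
#'
#' @param spec a [fixtureSpec()].
#' @return list with `expression`, `activity`, `compendium`, and
#'   `groundTruth` (data.frame drug, gene, target_pcc).
#' @export
generateScreen <- function(spec) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 2L)
  genes <- .geneNames(spec$nGenes)
  drugs <- .drugNames(spec$nDrugs)
  cells <- sprintf("CELL%02d", seq_len(spec$nCells))
  E <- matrix(rnorm(spec$nGenes * spec$nCells), spec$nGenes,
              dimnames = list(genes, cells))
  A <- matrix(rnorm(spec$nDrugs * spec$nCells), spec$nDrugs,
              dimnames = list(drugs, cells))
  seeds <- .seedGenesOf(spec)
  plantGene <- rep(seeds, length.out = spec$nSeedPairs)
  plantDrug <- drugs[seq_len(spec$nSeedPairs)]
  rho <- seq(spec$plantedPccRange[1], spec$plantedPccRange[2],
             length.out = spec$nSeedPairs)
  rho <- rho * rep_len(c(1, -1), spec$nSeedPairs)
  for (k in seq_len(spec$nSeedPairs)) {
    z <- as.numeric(scale(E[plantGene[k], ]))
    A[plantDrug[k], ] <- rho[k] * z +
      sqrt(1 - rho[k]^2) * rnorm(spec$nCells)
  }
  if (spec$missingRate > 0) {
    mask <- matrix(runif(length(A)) < spec$missingRate, nrow(A))
    A[mask] <- NA_real_
  }
  comp <- new("Compendium", pairs = data.frame(
    drug = plantDrug, gene = plantGene,
    cell_line = NA_character_, pmid = NA_character_,
    description = "planted synthetic pair", stringsAsFactors = FALSE))
  list(expression = new("ExpressionMatrix", E),
       activity = new("ActivityMatrix", A),
       compendium = comp,
       groundTruth = data.frame(drug = plantDrug, gene = plantGene,
                                target_pcc = rho, stringsAsFactors = FALSE))
}

#' Generate (and optionally write) a complete fixture bundle
#'
#' Produces every input the pipeline needs — expression and activity
#' matrices, interaction network, annotation + ontology, compendium — plus
#' the planted ground truth, all from one seed. When `dir` is given, the
#' bundle is written in the plain-text formats the loaders read (TSV
#' matrices, edge list, GMT, child-parent ontology TSV, compendium TSV)
#' together with a `manifest.txt` recording the spec.
#'
#' @param spec a [fixtureSpec()].
#' @param dir optional output directory (created if needed).
#' @return list with `expression`, `activity`, `network`, `annotation`,
#'   `dag`, `compendium`, `groundTruth`, `seedGenes`, `spec`, and `files`
#'   (named paths when written).
#' @export
generateFixtureBundle <- function(spec = fixtureSpec(), dir = NULL) {
  net <- generateNetwork(spec)
  ann <- generateAnnotation(spec)
  scr <- generateScreen(spec)
  bundle <- list(expression = scr$expression, activity = scr$activity,
                 network = net, annotation = ann$annotation,
                 dag = ann$dag, compendium = scr$compendium,
                 groundTruth = scr$groundTruth,
                 seedGenes = .seedGenesOf(spec), spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(expression = file.path(dir, "expression.tsv"),
               activity = file.path(dir, "activity.tsv"),
               network = file.path(dir, "network.tsv"),
               annotation = file.path(dir, "annotation.gmt"),
               ontology = file.path(dir, "ontology.tsv"),
               compendium = file.path(dir, "compendium.tsv"),
               groundTruth = file.path(dir, "ground_truth.tsv"),
               manifest = file.path(dir, "manifest.txt"))
    .writeIdMatrix(bundle$expression@.Data, files["expression"], "gene")
    .writeIdMatrix(bundle$activity@.Data, files["activity"], "drug")
    .writeEdgeList(bundle$network, files["network"])
    .writeGMT(bundle$annotation, files["annotation"])
    .writeOntologyTSV(bundle$dag, files["ontology"])
    write.table(compendiumPairs(bundle$compendium), files["compendium"],
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(bundle$groundTruth, files["groundTruth"],
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c("crgnet synthetic fixture bundle",
                 paste0(names(spec), " = ",
                        vapply(spec, function(x)
                          paste(x, collapse = ","), ""))),
               files["manifest"])
    bundle$files <- files
  }
  bundle
}
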