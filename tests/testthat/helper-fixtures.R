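# Small seeded fixture bundles, cached per test run so several test files
# can share one generation.

.fixtureCache <- new.env(parent = emptyenv())

smallSpec <- function(seed = 11) {
  fixtureSpec(nGenes = 300, nDrugs = 15, nCells = 60, nSeedGenes = 15,
              nSeedPairs = 15, nTerms = 40, seedTermCount = 4,
              termSize = 12, missingRate = 0.1, seed = seed)
}

smallBundle <- function(seed = 11) {
  key <- paste0("b", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateFixtureBundle(smallSpec(seed))
  .fixtureCache[[key]]
}

# edge table + centralities for the small bundle, cached too
smallDerived <- function(seed = 11) {
  key <- paste0("d", seed)
  if (is.null(.fixtureCache[[key]])) {
    b <- smallBundle(seed)
    suppressMessages({
      acts <- filterDrugsByMissingness(b$activity)
      edges <- buildEdgeTable(acts, b$expression)
    })
    .fixtureCache[[key]] <- list(
      edges = edges,
      degrees = degreeMap(b$network),
      betweenness = betweennessMap(b$network))
  }
  .fixtureCache[[key]]
}

quietPipeline <- function(b, config = pipelineConfig(), ...) {
  suppressMessages(suppressWarnings(
    runPipeline(b$expression, b$activity, b$network, b$annotation,
                b$dag, b$compendium, config = config, ...)))
}
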