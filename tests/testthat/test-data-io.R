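test_that("expression loader parses, collapses duplicate genes, rejects junk", {
  tf <- writeTempTSV(c("gene\tc1\tc2\tc3\tc4",
                       "g1\t1\t2\t3\t4",
                       "g2\t5\t6\t7\t8",
                       "g3\t9\t10\t11\t12"))
  m <- loadExpressionMatrix(tf)
  expect_s4_class(m, "ExpressionMatrix")
  expect_equal(dim(m), c(3L, 4L))
  expect_equal(unname(m@.Data["G2", ]), c(5, 6, 7, 8))

  dup <- writeTempTSV(c("gene\tc1\tc2\tc3\tc4",
                        "g1\t1\t2\t3\t4",
                        "g1\t3\t4\t5\t6"))
  expect_message(md <- loadExpressionMatrix(dup), "duplicate gene")
  expect_equal(nrow(md), 1L)
  expect_equal(unname(md@.Data["G1", ]), c(2, 3, 4, 5))

  bad <- writeTempTSV(c("gene\tc1\tc2\tc3", "g1\t1\tabc\t3"))
  expect_error(loadExpressionMatrix(bad), "abc")
  dupcell <- writeTempTSV(c("gene\tc1\tc1\tc3", "g1\t1\t2\t3"))
  expect_error(loadExpressionMatrix(dupcell), "cell-line")
})

test_that("activity loader flags missing tokens and aligns cells", {
  tf <- writeTempTSV(c("drug\tc1\tc2\tc3",
                       "d1\t1.2\tNaN\t3.0",
                       "d2\tNaN\tNaN\tNaN",
                       "d3\t1\t2\tNA"))
  a <- loadActivityMatrix(tf)
  expect_s4_class(a, "ActivityMatrix")
  expect_identical(is.na(a@.Data["D1", ]), c(c1 = FALSE, c2 = TRUE, c3 = FALSE))
  # all-missing drug retained at load; filtering is a separate op
  expect_true(all(is.na(a@.Data["D2", ])))
  expect_true(is.na(a@.Data["D3", "c3"]))

  nanOnly <- writeTempTSV(c("drug\tc1\tc2\tc3", "d1\t1.2\tNaN\t3.0"))
  onlyNaN <- loadActivityMatrix(nanOnly, missingTokens = "NaN")
  expect_true(is.na(onlyNaN@.Data["D1", "c2"]))
  # a token not declared missing is a parse error naming the cell
  expect_error(loadActivityMatrix(tf, missingTokens = "NaN"), "NA")
  expect_error(loadActivityMatrix(nanOnly, missingTokens = "none"), "NaN")
  expect_error(loadActivityMatrix(writeTempTSV(
    c("drug\tc1\tc2\tc3", "d1\tNaN\tNaN\tNaN")), missingTokens = "NaN"),
    "usable")
})

test_that("network loader deduplicates, drops self-loops, errors when empty", {
  tf <- writeTempTSV(c("a\tb", "b\ta", "b\tb", "a\tc"))
  expect_message(g <- loadNetwork(tf), "dropped 1 self-loop")
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::vcount(g), 3)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))

  single <- loadNetwork(writeTempTSV("x\ty"))
  expect_equal(igraph::ecount(single), 1)
  expect_equal(igraph::vcount(single), 2)

  expect_error(suppressMessages(
    loadNetwork(writeTempTSV(c("a\ta", "b\tb")))),
    "empty network after cleaning")
  expect_error(loadNetwork(writeTempTSV(character(0))), "edge list|empty")
})

test_that("GMT loader uppercases, unions duplicate terms, skips short lines", {
  tf <- writeTempTSV(c("GO:1\tdesc\tA\tB\tA",
                       "GO:2\tdesc2\tc\td",
                       "broken line",
                       "GO:2\tdesc2\te"))
  expect_warning(expect_warning(ann <- loadGeneSets(tf), "fewer than 3"),
                 "duplicate term")
  expect_setequal(geneSets(ann)[["GO:1"]], c("A", "B"))
  expect_setequal(geneSets(ann)[["GO:2"]], c("C", "D", "E"))
  expect_error(suppressWarnings(loadGeneSets(writeTempTSV("short\tline"))),
               "no usable")
})

test_that("ontology loader computes depths, detects cycles, reads OBO", {
  tsv <- writeTempTSV(c("t1\tr", "t2\tt1"))
  dag <- loadOntologyGraph(tsv)
  expect_equal(unname(termDepth(dag, c("r", "t1", "t2"))), c(0L, 1L, 2L))

  # diamond with a long branch: shortest path wins
  dia <- loadOntologyGraph(writeTempTSV(
    c("x\tr", "y\tr", "z\tx", "w\ty", "z\tw")))
  expect_equal(unname(termDepth(dia, "z")), 2L)

  expect_error(loadOntologyGraph(writeTempTSV(c("a\tb", "b\ta"))), "cycle")
  expect_error(termDepth(dag, "nope"), "unknown term")

  obo <- writeTempTSV(c("format-version: 1.2", "",
                        "[Term]", "id: GO:0", "name: root", "",
                        "[Term]", "id: GO:1", "is_a: GO:0 ! root", "",
                        "[Term]", "id: GO:2",
                        "relationship: part_of GO:1 ! mid", "",
                        "[Term]", "id: GO:9", "is_a: GO:1",
                        "is_obsolete: true"))
  d2 <- loadOntologyGraph(obo)
  expect_equal(unname(termDepth(d2, c("GO:0", "GO:1", "GO:2"))),
               c(0L, 1L, 2L))
  expect_false("GO:9" %in% names(d2@depths) &&
                 !is.na(d2@depths["GO:9"]) && d2@depths["GO:9"] > 0)
})

test_that("compendium loader normalizes, dedups, and summarizes", {
  tf <- writeTempTSV(c("drug\tgene", "d1\tg1", "D1 \t g1", "d2\tg1"))
  cp <- suppressMessages(loadCompendium(tf))
  expect_equal(unname(compendiumSummary(cp)), c(2L, 2L, 1L))

  tf2 <- writeTempTSV(c("drug\tgene", "d1\tg1", "d1\tg2", "d2\tg1"))
  s <- compendiumSummary(loadCompendium(tf2))
  expect_equal(unname(s), c(3L, 2L, 2L))

  expect_warning(cp3 <- loadCompendium(writeTempTSV(
    c("drug\tgene", "d1\t", "d2\tg2"))), "rejected")
  expect_equal(unname(compendiumSummary(cp3)["n_pairs"]), 1L)
  expect_error(loadCompendium(writeTempTSV(c("a\tb", "x\ty"))),
               "missing drug column")
})

test_that("prediction writer is deterministic and round-trips structure", {
  b <- smallBundle()
  cfg <- pipelineConfig(qDegree = 0.2, qBetweenness = 0.2)
  res <- quietPipeline(b, cfg)
  f1 <- tempfile(); f2 <- tempfile()
  writePredictions(res, f1)
  writePredictions(res, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  reread <- read.delim(f1)
  expect_equal(nrow(reread), nrow(predictions(res)))
  expect_equal(sort(reread$q_score), sort(predictions(res)$q_score),
               tolerance = 1e-9)

  empty <- new("PredictionTable", table = predictions(res)[0, ],
               config = list(), reports = list())
  fe <- tempfile()
  writePredictions(empty, fe)
  expect_equal(length(readLines(fe)), 1L)  # header only
})

test_that("matrix and network writers round-trip exactly", {
  b <- smallBundle()
  d <- tempfile()
  bundle <- generateFixtureBundle(smallSpec(), dir = d)
  e2 <- suppressMessages(loadExpressionMatrix(bundle$files["expression"]))
  expect_equal(e2@.Data, b$expression@.Data, tolerance = 1e-9)
  a2 <- suppressMessages(loadActivityMatrix(bundle$files["activity"]))
  expect_equal(a2@.Data, b$activity@.Data, tolerance = 1e-9)
  g2 <- suppressMessages(loadNetwork(bundle$files["network"]))
  expect_equal(igraph::ecount(g2), igraph::ecount(b$network))
  # loader is idempotent on its own written edge list
  t2 <- tempfile()
  crgnet:::.writeEdgeList(g2, t2)
  g3 <- suppressMessages(loadNetwork(t2))
  expect_identical(igraph::as_edgelist(g3), igraph::as_edgelist(g2))
})
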