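test_that("pairwisePCC matches closed forms, handles gaps and degeneracy", {
  expect_equal(pairwisePCC(c(1, 2, 3), c(2, 4, 6), minComplete = 3)$pcc, 1.0)
  expect_equal(pairwisePCC(c(1, 2, 3), c(6, 4, 2), minComplete = 3)$pcc, -1.0)

  r <- pairwisePCC(c(1, 2, NA, 4), c(2, 1, 5, 3), minComplete = 3)
  expect_equal(r$n_complete, 3L)
  expect_equal(r$pcc, cor(c(1, 2, 4), c(2, 1, 3)))

  # textbook closed form on gap-free series, to 1e-12
  set.seed(4)
  x <- rnorm(25); y <- rnorm(25)
  closed <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pairwisePCC(x, y, minComplete = 3)$pcc, closed,
               tolerance = 1e-12)

  # symmetry, positive-affine invariance, sign flip under negation
  expect_equal(pairwisePCC(x, y, 3)$pcc, pairwisePCC(y, x, 3)$pcc)
  expect_equal(pairwisePCC(2 * x + 7, y, 3)$pcc, pairwisePCC(x, y, 3)$pcc,
               tolerance = 1e-12)
  expect_equal(pairwisePCC(x, -y, 3)$pcc, -pairwisePCC(x, y, 3)$pcc,
               tolerance = 1e-12)

  expect_true(is.na(pairwisePCC(c(1, 2, NA, 4), c(2, 1, 5, 3),
                                minComplete = 4)$pcc))
  expect_true(is.na(pairwisePCC(rep(1, 5), rnorm(5), minComplete = 3)$pcc))
  expect_error(pairwisePCC(1:3, 1:4), "length")
})

test_that("missingness filter uses a strict inequality", {
  m <- matrix(rnorm(3 * 60), 3, 60,
              dimnames = list(c("D1", "D2", "D3"), sprintf("c%02d", 1:60)))
  m["D1", 1:49] <- NA  # 49/60 = 0.817 > 0.8 -> removed
  m["D2", 1:48] <- NA  # 48/60 = 0.8 exactly -> retained
  a <- new("ActivityMatrix", m)
  f <- suppressMessages(filterDrugsByMissingness(a, 0.8))
  expect_setequal(rownames(f), c("D2", "D3"))
  allgone <- new("ActivityMatrix",
                 matrix(NA_real_, 1, 60,
                        dimnames = list("D1", sprintf("c%02d", 1:60))))
  expect_error(filterDrugsByMissingness(allgone, 0.8), "all drugs")
})

test_that("edge table covers the cross product and flags undefined pairs", {
  cells <- sprintf("c%02d", 1:12)
  E <- matrix(rnorm(36), 3, 12, dimnames = list(c("GA", "GB", "GC"), cells))
  A <- matrix(rnorm(24), 2, 12, dimnames = list(c("D1", "D2"), cells))
  ed <- buildEdgeTable(new("ActivityMatrix", A), new("ExpressionMatrix", E),
                       minComplete = 10)
  expect_equal(nrow(ed), 6L)
  expect_equal(ed$pcc[ed$drug == "D1" & ed$gene == "GA"],
               cor(A["D1", ], E["GA", ]))

  # constant activity -> zero variance -> undefined with reason
  A2 <- A; A2["D2", ] <- 5
  ed2 <- buildEdgeTable(new("ActivityMatrix", A2),
                        new("ExpressionMatrix", E), minComplete = 10)
  expect_equal(nrow(ed2), 3L)
  undef <- attr(ed2, "undefined")
  expect_true(all(undef$drug == "D2"))
  expect_true(all(undef$reason == "zero variance"))

  expect_error(buildEdgeTable(
    new("ActivityMatrix",
        matrix(rnorm(9), 3, 3,
               dimnames = list(paste0("D", 1:3), paste0("x", 1:3)))),
    new("ExpressionMatrix", E), minComplete = 10), "shared cell")
})

test_that("planted correlations are recovered within sampling error", {
  b <- smallBundle()
  d <- smallDerived()
  gt <- b$groundTruth
  key <- paste(d$edges$drug, d$edges$gene)
  hit <- match(paste(gt$drug, gt$gene), key)
  expect_true(all(!is.na(hit)))
  n <- d$edges$n_complete[hit]
  # Fisher-z scaled deviations are ~N(0,1); with 15 independent pairs the
  # expected number outside 3 SE is ~0.04, so allow at most one, none extreme
  zdev <- abs(atanh(d$edges$pcc[hit]) - atanh(gt$target_pcc)) * sqrt(n - 3)
  expect_lte(sum(zdev > 3), 1)
  expect_true(all(zdev < 4.5))
  expect_lt(median(abs(d$edges$pcc[hit] - gt$target_pcc)),
            median(3 / sqrt(n - 3)))
})

test_that("seed |PCC| threshold is nearest-rank and monotone in percentile", {
  pcc <- seq(0.05, 1, by = 0.05)  # 20 seed pairs
  edges <- data.frame(drug = sprintf("d%02d", 1:20),
                      gene = sprintf("g%02d", 1:20),
                      pcc = pcc * rep_len(c(1, -1), 20), n_complete = 60)
  comp <- new("Compendium",
              pairs = data.frame(drug = toupper(edges$drug),
                                 gene = toupper(edges$gene)))
  edges$drug <- toupper(edges$drug); edges$gene <- toupper(edges$gene)
  expect_equal(ccrgAbsPccThreshold(edges, comp, percentile = 5), 0.05)
  expect_equal(ccrgAbsPccThreshold(edges, comp, percentile = 50), 0.50)
  expect_equal(ccrgAbsPccThreshold(edges, comp, percentile = 100), 1.0)
  expect_equal(ccrgAbsPccThreshold(edges, comp, percentile = 0), 0)

  # at least (100 - p)% of seed pairs meet the threshold
  for (p in c(5, 25, 60)) {
    tau <- ccrgAbsPccThreshold(edges, comp, percentile = p)
    expect_gte(sum(abs(edges$pcc) >= tau), ceiling((100 - p) / 100 * 20))
  }
  # monotone non-decreasing in percentile
  taus <- vapply(seq(0, 100, 10), function(p)
    ccrgAbsPccThreshold(edges, comp, p), 0)
  expect_true(all(diff(taus) >= 0))

  allc <- edges; allc$pcc <- 0.4
  expect_equal(ccrgAbsPccThreshold(allc, comp, 5), 0.4)
  expect_error(ccrgAbsPccThreshold(edges[0, ], comp, 5), "no seed pair")
})

test_that("drug-null z classification partitions pairs", {
  pccs <- rep(c(-0.2, 0, 0.2), 10)
  r <- drugNullZ(0.2, pccs, zThreshold = 0.8)
  popsd <- sqrt(mean((pccs - mean(pccs))^2))
  expect_equal(r$z, 0.2 / popsd)
  expect_equal(r$class, "larger")
  expect_equal(drugNullZ(mean(pccs), pccs)$z, 0)
  expect_equal(drugNullZ(mean(pccs), pccs)$class, "random")
  expect_equal(drugNullZ(-0.2, pccs)$class, "smaller")

  rs <- drugNullZ(0.2, pccs, sdType = "sample")
  expect_equal(rs$z, 0.2 / sd(pccs))

  expect_error(drugNullZ(0.1, rep(0.3, 40)), "zero spread")
  expect_error(drugNullZ(0.1, rnorm(10)), ">= 30")

  # classes partition all pairs of a drug on a fixture
  d <- smallDerived()
  one <- d$edges[d$edges$drug == d$edges$drug[1], ]
  cls <- vapply(one$pcc, function(p)
    drugNullZ(p, one$pcc)$class, "")
  expect_equal(sum(cls == "larger") + sum(cls == "smaller") +
                 sum(cls == "random"), nrow(one))

  # a planted strongly positive pair classifies as larger
  b <- smallBundle()
  gt <- b$groundTruth
  strong <- gt[which.max(gt$target_pcc), ]
  dd <- d$edges[d$edges$drug == strong$drug, ]
  expect_equal(drugNullZ(dd$pcc[dd$gene == strong$gene], dd$pcc)$class,
               "larger")
})

test_that("PCC distribution summary counts bands correctly", {
  edges <- data.frame(drug = c("D1", "D1", "D1"), gene = c("A", "B", "C"),
                      pcc = c(-0.1, 0.2, 0.6), n_complete = 60)
  s <- pccDistributionSummary(edges)
  expect_equal(s$frac_within_0.3, 2 / 3)
  expect_equal(s$frac_within_0.5, 2 / 3)
  expect_equal(sum(s$counts), 3L)

  z <- pccDistributionSummary(data.frame(drug = "D1", gene = "A", pcc = 0,
                                         n_complete = 60))
  expect_equal(z$frac_within_0.3, 1.0)
  expect_equal(z$frac_within_0.5, 1.0)

  expect_warning(e <- pccDistributionSummary(edges[0, ]), "no defined")
  expect_equal(e$n, 0L)
})
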