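# Hand-built QC toy: six cells, four single-rule violations, two clean.
qcToy <- function() {
  genes <- c(sprintf("g%03d", 1:400), "ERCC-1")
  m <- matrix(0L, 401, 6,
              dimnames = list(genes, c("clean1", "clean2", "lowGenes",
                                       "lowLib", "lowComplexity",
                                       "highSpike")))
  m[1:300, "clean1"] <- 1L
  m[1:300, "clean2"] <- 1L
  m[1:240, "lowGenes"] <- 2L       # 240 genes < 250, everything else fine
  m[1:260, "lowLib"] <- 1L         # library 260 < 300
  m[1:300, "lowComplexity"] <- 1L  # one dominant gene: top-200 share 0.956
  m["g001", "lowComplexity"] <- 2000L
  m[1:300, "highSpike"] <- 1L      # spike-ins are 25% of counts
  m["ERCC-1", "highSpike"] <- 100L
  toyCounts(m, isSpike = genes == "ERCC-1")
}

qcToyThresholds <- qcThresholds(minGenesPerCell = 250, minLibrarySize = 300,
                                maxTop200Fraction = 0.95,
                                maxSpikeFraction = 0.2, minGeneMeanCount = 1)
qcToyPanel <- capturePanel(c("g001", "g002"), "ERCC-1")

test_that("each cell rule fails exactly the intended cell", {
  res <- filterCells(qcToy(), qcToyPanel, qcToyThresholds)
  expect_setequal(res$cells, c("clean1", "clean2"))
  qc <- res$qc
  rownames(qc) <- qc$cell
  expect_equal(qc[, c("passGenes", "passLibrary", "passComplexity",
                      "passSpike")],
               data.frame(
                 passGenes = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
                 passLibrary = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
                 passComplexity = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
                 passSpike = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
                 row.names = c("clean1", "clean2", "lowGenes", "lowLib",
                               "lowComplexity", "highSpike")))
})

test_that("cell filtering is idempotent and the all-pass case is identity", {
  res <- filterCells(qcToy(), qcToyPanel, qcToyThresholds)
  res2 <- filterCells(res$counts, qcToyPanel, qcToyThresholds)
  expect_identical(colnames(res2$counts), colnames(res$counts))
  expect_true(all(res2$qc$pass))
  expect_error(
    filterCells(qcToy(), qcToyPanel,
                qcThresholds(minGenesPerCell = 400, minLibrarySize = 300,
                             maxTop200Fraction = 0.95,
                             maxSpikeFraction = 0.2)),
    "no cells passed")
})

test_that("gene filter is strict on the mean-count threshold", {
  m <- matrix(c(rep(1L, 10),        # mean 1.0 -> removed (strict >)
                rep(2L, 10),        # mean 2.0 -> kept
                rep(0L, 10),        # all-zero -> removed
                c(rep(3L, 4), rep(0L, 6))),  # mean 1.2 -> kept
              nrow = 4, byrow = TRUE,
              dimnames = list(c("border", "high", "zero", "sparse"),
                              sprintf("c%02d", 1:10)))
  out <- filterGenes(toyCounts(m), qcToyThresholds)
  expect_identical(rownames(out), c("high", "sparse"))
  allZero <- filterGenes(toyCounts(m[c("zero", "border"), , drop = FALSE]),
                         qcToyThresholds)
  expect_equal(nrow(allZero), 0L)
})

test_that("on-target fraction is panel counts over library size", {
  m <- matrix(c(3, 7), nrow = 2, dimnames = list(c("panelA", "otherB"), "c1"))
  fr <- onTargetFraction(toyCounts(m), capturePanel("panelA"))
  expect_equal(unname(fr$perCell), 0.3)
  frAll <- onTargetFraction(toyCounts(m), capturePanel(c("panelA", "otherB")))
  expect_equal(unname(frAll$perCell), 1)
  m0 <- cbind(m, c2 = c(0, 0))
  fr0 <- onTargetFraction(toyCounts(m0), capturePanel("panelA"))
  expect_true(is.na(fr0$perCell["c2"]))
})

test_that("genewise enrichment follows the CPM pseudocount arithmetic", {
  pre <- toyCounts(matrix(c(3, 999997), 2,
                          dimnames = list(c("a", "b"), "c1")))
  post <- toyCounts(matrix(c(127, 999873), 2,
                           dimnames = list(c("a", "b"), "c1")))
  expect_equal(unname(genewiseEnrichment(pre, post)["a"]), 5)  # log2(128/4)
  expect_equal(unname(genewiseEnrichment(pre, pre)), c(0, 0))
  # invariant to uniform per-cell depth scaling
  sim <- simulatePrePost(tinyConfig(seed = 41))
  doubled <- toyCounts(
    as.matrix(SummarizedExperiment::assay(sim$pre, "counts")) * 2L)
  expect_equal(unname(genewiseEnrichment(sim$pre, sim$pre)),
               unname(genewiseEnrichment(sim$pre, doubled)),
               tolerance = 1e-12)
  expect_error(genewiseEnrichment(sim$pre, sim$pre[, 1:3]), "same cells")
})

test_that("capture summary on identical libraries is the identity", {
  sim <- simulatePrePost(tinyConfig(seed = 42))
  cap <- captureSummary(sim$pre, sim$pre, sim$panel)
  expect_equal(cap@summary$detectedFoldChange, 1)
  expect_equal(cap@summary$meanExpressionCorrelation, 1)
  expect_equal(cap@summary$nExpressedPanelPre,
               cap@summary$nExpressedPanelPost)
})

test_that("capture summary matches hand computation on a toy", {
  pre <- toyCounts(matrix(c(1, 0, 4, 0, 2, 4), 3,
                          dimnames = list(c("tf1", "tf2", "bg"),
                                          c("c1", "c2"))))
  post <- toyCounts(matrix(c(8, 2, 2, 4, 6, 2), 3,
                           dimnames = list(c("tf1", "tf2", "bg"),
                                           c("c1", "c2"))))
  cap <- captureSummary(pre, post, capturePanel(c("tf1", "tf2")))
  expect_equal(cap@perCell$detectedPanelPre, c(1L, 1L))
  expect_equal(cap@perCell$detectedPanelPost, c(2L, 2L))
  expect_equal(cap@perCell$onTargetPre, c(1 / 5, 2 / 6))
  expect_equal(cap@perCell$onTargetPost, c(10 / 12, 10 / 12))
  expect_equal(cap@summary$nExpressedPanelPre, 2L)  # both have non-zero mean
  expect_equal(cap@summary$nExpressedPanelPost, 2L)
})
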