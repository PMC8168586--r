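test_that("log normalisation follows the size-factor arithmetic", {
  m <- matrix(c(0, 3, 6, 1), 2, dimnames = list(c("a", "b"),
                                                c("c1", "c2")))
  x <- normalizeLog(toyCounts(m))
  logc <- SummarizedExperiment::assay(x, "logcounts")
  expect_equal(unname(logc["a", "c1"]), 0)             # zero stays zero
  # library sf for c1 is 3/1e4, so the value is log2(3/sf + 1)
  expect_equal(unname(logc["b", "c1"]), log2(1e4 + 1))
  # unit size factors reproduce the bare pseudocount transform
  xu <- normalizeLog(toyCounts(m), sizeFactors = c(1, 1))
  expect_equal(
    unname(SummarizedExperiment::assay(xu, "logcounts")["b", "c1"]),
    log2(3 + 1))
  # doubling every cell's depth leaves library-normalised values unchanged
  x2 <- normalizeLog(toyCounts(m * 2))
  expect_equal(as.matrix(SummarizedExperiment::assay(x2, "logcounts")),
               as.matrix(logc))
  expect_error(normalizeLog(toyCounts(cbind(m, c3 = c(0, 0)))),
               "empty libraries")
})

makeBlobs <- function(seed, n = 60, g = 40, delta = 5) {
  set.seed(seed)
  grp <- rep(1:2, each = n / 2)
  m <- matrix(rnorm(g * n), g, n,
              dimnames = list(sprintf("g%02d", 1:g), sprintf("c%02d", 1:n)))
  m[1:10, grp == 2] <- m[1:10, grp == 2] + delta
  list(m = m, grp = grp)
}

test_that("well-separated blobs are recovered exactly", {
  b <- makeBlobs(7)
  cl <- clusterCells(b$m, k = 2, nHvg = NULL)
  expect_equal(adjustedRandIndex(clusterLabels(cl), b$grp), 1)
  cl1 <- clusterCells(b$m, k = 1)
  expect_equal(nlevels(clusterLabels(cl1)), 1L)
  expect_error(clusterCells(b$m, k = 100), "exceed")
  # silhouette selection finds the two blobs unaided
  clAuto <- clusterCells(b$m, kMax = 6)
  expect_equal(nlevels(clusterLabels(clAuto)), 2L)
  # graph clustering agrees on this easy geometry
  clG <- clusterCells(b$m, method = "knn_graph_louvain", seed = 5)
  expect_equal(adjustedRandIndex(clusterLabels(clG), b$grp), 1)
})

test_that("duplicating every cell preserves the partition structure", {
  b <- makeBlobs(8, n = 40)
  dup <- cbind(b$m, b$m)
  colnames(dup) <- sprintf("c%02d", seq_len(ncol(dup)))
  cl <- clusterCells(dup, k = 2, nHvg = NULL)
  lab <- clusterLabels(cl)
  expect_equal(adjustedRandIndex(lab, rep(b$grp, 2)), 1)
  expect_equal(unname(lab[1:40]), unname(lab[41:80]))
})

test_that("differential expression matches the exact rank-sum routine", {
  set.seed(9)
  m <- matrix(rpois(8 * 20, 5), 20, 8,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("c%d", 1:8)))
  x <- normalizeLog(toyCounts(m))
  labels <- factor(rep(c("A", "B"), each = 4))
  de <- differentialExpression(x, labels, "pair", groups = c("A", "B"))
  tab <- degTables(de)[["A_vs_B"]]
  logc <- SummarizedExperiment::assay(x, "logcounts")
  for (i in c(1, 7, 13)) {
    expect_equal(tab$p[i],
                 exactRankSumP(logc[i, 1:4], logc[i, 5:8])$p)
  }
  expect_equal(tab$fdr, p.adjust(tab$p, "BH"))
})

test_that("identical groups give p = 1 and zero fold change", {
  m <- matrix(rep(c(2, 5, 0), each = 6), 3, 6, byrow = TRUE,
              dimnames = list(c("a", "b", "z"), sprintf("c%d", 1:6)))
  x <- normalizeLog(toyCounts(m))
  de <- differentialExpression(x, factor(rep(1:2, each = 3)))
  tab <- degTables(de)[["1_vs_rest"]]
  expect_true(all(tab$p == 1))
  expect_true(all(abs(tab$lnFC) < 1e-12))
})

test_that("swapping group labels negates lnFC and preserves p", {
  sim <- simulatePrePost(tinyConfig(seed = 51))
  x <- normalizeLog(sim$pre)
  labels <- factor(clusterOfCell(sim$truth) == 1, labels = c("rest", "one"))
  de <- differentialExpression(x, labels, "pair", groups = c("one", "rest"))
  deSwap <- differentialExpression(x, labels, "pair",
                                   groups = c("rest", "one"))
  a <- degTables(de)[[1]]; b <- degTables(deSwap)[[1]]
  expect_equal(a$p, b$p)
  expect_equal(a$lnFC, -b$lnFC)
  expect_equal(a$pctIn, b$pctOut)
})

test_that("BH adjustment matches a hand-coded oracle", {
  bhOracle <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    out <- numeric(n); out[o] <- pmin(1, q)
    out
  }
  set.seed(10)
  for (rep in 1:5) {
    p <- runif(50)^2
    expect_equal(p.adjust(p, "BH"), bhOracle(p), tolerance = 1e-12)
  }
})

test_that("program genes separate in a two-cluster simulation", {
  cfg <- tinyConfig(seed = 52, nClusters = 2, branchParent = c(0, 1),
                    nTFsPerProgram = 2, nTargetsPerProgram = 8)
  sim <- simulatePrePost(cfg)
  x <- normalizeLog(sim$pre)
  de <- differentialExpression(x, factor(clusterOfCell(sim$truth)))
  sig <- unique(unlist(lapply(degTables(de),
                              function(t) t$gene[t$fdr <= 0.05])))
  pg <- programGenes(sim$truth)
  expect_gte(sum(pg %in% sig), ceiling(0.9 * length(pg)))
})
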