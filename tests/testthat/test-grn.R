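test_that("imputation rescales post counts by the per-cell library ratio", {
  pre <- toyCounts(matrix(c(2, 98), 2, dimnames = list(c("tf1", "bg"), "c1")),
                   isPanel = c(TRUE, FALSE))
  post <- toyCounts(matrix(c(8, 392), 2,
                           dimnames = list(c("tf1", "bg"), "c1")),
                    isPanel = c(TRUE, FALSE))
  imp <- imputeCapture(pre, post, capturePanel("tf1"))
  cm <- as.matrix(SummarizedExperiment::assay(imp, "counts"))
  expect_equal(cm["tf1", "c1"], 8 * 100 / 400)  # post count x preLib/postLib
  expect_equal(cm["bg", "c1"], 98)              # non-panel rows untouched
})

test_that("imputation with identical libraries is the identity", {
  sim <- simulatePrePost(tinyConfig(seed = 61))
  imp <- imputeCapture(sim$pre, sim$pre, sim$panel)
  expect_equal(as.matrix(SummarizedExperiment::assay(imp, "counts")),
               as.matrix(SummarizedExperiment::assay(sim$pre, "counts")))
})

test_that("panel genes absent pre-capture appear as new rows", {
  pre <- toyCounts(matrix(c(5, 5), 2, dimnames = list(c("g1", "g2"), "c1")))
  post <- toyCounts(matrix(c(4, 4, 12), 3,
                           dimnames = list(c("g1", "g2", "tfNew"), "c1")))
  imp <- imputeCapture(pre, post, capturePanel("tfNew"))
  expect_equal(nrow(imp), 3L)
  expect_equal(
    as.matrix(SummarizedExperiment::assay(imp, "counts"))["tfNew", "c1"],
    12 * 10 / 20)
  expect_error(imputeCapture(pre, post[, integer(0)], capturePanel("tfNew")),
               "same cells")
})

test_that("network edges follow the correlation and significance rules", {
  set.seed(62)
  n <- 60
  v <- rnorm(n)
  m <- rbind(g1 = v, g2 = v + rnorm(n, sd = 0.1), g3 = v + rnorm(n, sd = 2),
             g4 = -v + rnorm(n, sd = 0.1), g5 = rnorm(n))
  colnames(m) <- sprintf("c%02d", 1:n)
  net <- buildNetwork(m)
  # oracle: direct correlation matrix with the same thresholds
  r <- cor(t(m))
  p <- 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  padj <- matrix(p.adjust(p[upper.tri(p)], "BH"), )
  expected <- which(abs(r) > 0.8 & upper.tri(r), arr.ind = TRUE)
  e <- networkEdges(net)
  expect_setequal(paste(e$from, e$to),
                  paste(rownames(m)[expected[, 1]],
                        rownames(m)[expected[, 2]]))
  expect_equal(e$weight[e$from == "g1" & e$to == "g2"], r["g1", "g2"])
  expect_lt(e$weight[e$from == "g1" & e$to == "g4"], -0.8)
})

test_that("a duplicated gene row yields a unit-weight edge", {
  set.seed(63)
  v <- rnorm(30)
  m <- rbind(a = v, b = v, c = rnorm(30))
  colnames(m) <- sprintf("c%02d", 1:30)
  e <- networkEdges(buildNetwork(m))
  expect_equal(nrow(e), 1L)
  expect_equal(e$weight, 1)
})

test_that("independent noise genes produce no edges", {
  set.seed(64)
  m <- matrix(rnorm(50 * 100), 50, 100,
              dimnames = list(sprintf("g%02d", 1:50),
                              sprintf("c%03d", 1:100)))
  expect_equal(numEdges(buildNetwork(m)), 0L)
})

test_that("zero-variance genes are excluded and recorded", {
  m <- rbind(flat = rep(2, 20), live = rnorm(20))
  colnames(m) <- sprintf("c%02d", 1:20)
  net <- buildNetwork(m)
  expect_equal(attr(net, "excluded"), "flat")
  expect_false("flat" %in% networkNodes(net)$gene)
  expect_warning(buildNetwork(m["flat", , drop = FALSE]), "empty network")
})

test_that("networks are invariant to per-cell depth scaling", {
  sim <- simulatePrePost(tinyConfig(seed = 65, dispersion = 20))
  counts <- as.matrix(SummarizedExperiment::assay(sim$pre, "counts"))
  scaled <- toyCounts(t(t(counts) * rep(c(1L, 3L), length.out = ncol(counts))))
  n1 <- buildNetwork(normalizeLog(sim$pre))
  n2 <- buildNetwork(normalizeLog(scaled))
  e1 <- networkEdges(n1); e2 <- networkEdges(n2)
  expect_setequal(paste(e1$from, e1$to), paste(e2$from, e2$to))
})

subnetToy <- function() {
  nodes <- data.frame(
    gene = c("t1", "t2", "n1", "n2", "n3", "n4",
             sprintf("m%d", 1:6), "d1", "d2", "x", "y", "z", "w"),
    isTF = c(TRUE, TRUE, rep(FALSE, 16)))
  edges <- rbind(
    data.frame(from = "t1", to = c("n1", "n2", "n3", "n4")),
    data.frame(from = "t2", to = sprintf("m%d", 1:6)),
    data.frame(from = c("n1", "d1", "x", "x"), to = c("d1", "d2", "d1", "d2")),
    data.frame(from = c("y", "y", "z"), to = c("z", "w", "w")))
  geneNetwork(nodes, edges)
}

subnetTables <- function() {
  sig <- function(genes, lnFC, pctIn = 0.7, pctOut = 0.1) data.frame(
    gene = genes, lnFC = lnFC, p = 1e-4, fdr = 1e-3,
    pctIn = pctIn, pctOut = pctOut, significant = TRUE)
  list(
    A_vs_rest = sig(c("n1", "d1", "d2", "m1", "x"), c(1, 1, 1, 1, 1.2)),
    B_vs_rest = sig("x", 0.7),
    # down-regulated in B = up-regulated in C, expressed in 70% of C cells
    B_vs_C = sig(c("y", "z", "w"), -0.9, pctIn = 0.1, pctOut = 0.7))
}

test_that("cluster subnetwork rules match the hand-built toy", {
  sub <- clusterSubnetworks(subnetToy(), subnetTables())
  nodes <- networkNodes(sub)
  rownames(nodes) <- nodes$gene
  # t1 has 1/4 = 25% >= 20% neighbours in A's DEG set -> attached to A
  expect_equal(nodes["t1", "cluster"], "A")
  # t2 has 1/6 < 20% -> not attached; m1's component is below 3 nodes
  expect_false(any(c("t2", "m1") %in% nodes$gene))
  # multi-cluster DEG goes to the cluster with the highest lnFC
  expect_equal(nodes["x", "cluster"], "A")
  # pairwise table claims the down-regulated side for the second cluster
  expect_equal(unname(nodes[c("y", "z", "w"), "cluster"]), rep("C", 3))
  expect_setequal(nodes$gene, c("t1", "n1", "d1", "d2", "x", "y", "z", "w"))
})

test_that("subnetwork extraction is order-independent", {
  net <- subnetToy()
  perm <- sample(nrow(net@nodes))
  netP <- geneNetwork(net@nodes[perm, ], net@edges)
  a <- networkNodes(clusterSubnetworks(net, subnetTables()))
  b <- networkNodes(clusterSubnetworks(netP, subnetTables()))
  expect_equal(a[order(a$gene), c("gene", "cluster")],
               b[order(b$gene), c("gene", "cluster")],
               ignore_attr = TRUE)
})

test_that("small components are dropped at the stated size", {
  net <- geneNetwork(c("a", "b", "c", "d", "e"),
                     data.frame(from = c("a", "c", "d"),
                                to = c("b", "d", "e")))
  tabs <- list(A_vs_rest = data.frame(
    gene = c("a", "b", "c", "d", "e"), lnFC = 1, p = 1e-4, fdr = 1e-3,
    pctIn = 0.8, pctOut = 0, significant = TRUE))
  sub <- clusterSubnetworks(net, tabs)
  expect_setequal(networkNodes(sub)$gene, c("c", "d", "e"))  # 2-node pair out
})

test_that("degree bookkeeping matches an adjacency-count oracle", {
  star <- geneNetwork(c("hub", "a", "b", "c", "d"),
                      data.frame(from = "hub", to = c("a", "b", "c", "d")))
  dd <- degreeDistribution(star)
  expect_equal(sort(dd$perNode$degree), c(1, 1, 1, 1, 4))
  expect_equal(unname(degreeDistribution(geneNetwork(character(0)))$perNode$degree),
               integer(0))
  set.seed(66)
  nodes <- sprintf("n%02d", 1:12)
  pairs <- t(combn(nodes, 2))
  sel <- sample(nrow(pairs), 20)
  net <- geneNetwork(nodes, data.frame(from = pairs[sel, 1],
                                       to = pairs[sel, 2]))
  adj <- table(factor(c(pairs[sel, 1], pairs[sel, 2]), levels = nodes))
  expect_equal(degreesOf(net), unclass(adj)[order(names(adj))],
               ignore_attr = TRUE)
})
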