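neaToy <- function() {
  geneNetwork(letters[1:6],
              data.frame(from = c("a", "a", "b", "c", "d", "e"),
                         to   = c("b", "c", "c", "d", "e", "f")))
}

test_that("permutations preserve the degree sequence exactly", {
  net <- neaToy()
  want <- degreesOf(net)
  for (s in 1:200) {
    perm <- permuteNetwork(net, seed = s)
    expect_identical(degreesOf(perm), want)
    expect_equal(numEdges(perm), numEdges(net))
  }
})

test_that("NEA empirical p agrees with exhaustive enumeration on a toy", {
  net <- neaToy()
  geneSet <- c("e", "f")
  nullStats <- bruteNeaNull(net, geneSet)
  expect_gt(length(nullStats), 1)
  obs <- sum(networkEdges(net)$from %in% geneSet |
               networkEdges(net)$to %in% geneSet)
  pExact <- mean(nullStats >= obs)
  nPerm <- 2000
  res <- neaTest(net, geneSet, nPerm = nPerm, seed = 7)
  expect_equal(res@observed, obs)
  mcSE <- sqrt(pExact * (1 - pExact) / nPerm)
  expect_lt(abs(res@p - pExact), 3 * mcSE + 2 / (nPerm + 1))
})

test_that("NEA is deterministic and handles degenerate sets", {
  net <- neaToy()
  a <- neaTest(net, c("a", "b"), nPerm = 300, seed = 3)
  b <- neaTest(net, c("a", "b"), nPerm = 300, seed = 3)
  expect_identical(a@p, b@p)
  expect_identical(a@z, b@z)
  # the saturated set covers every edge in every permutation
  sat <- neaTest(net, letters[1:6], nPerm = 150, seed = 1)
  expect_equal(sat@p, 1)
  expect_false(sat@zDefined)
  expect_error(neaTest(net, c("zz"), nPerm = 150), "does not intersect")
})

test_that("NEA z is centred for random gene sets", {
  set.seed(8)
  nodes <- sprintf("n%02d", 1:20)
  pairs <- t(combn(nodes, 2))
  sel <- sample(nrow(pairs), 40)
  net <- geneNetwork(nodes, data.frame(from = pairs[sel, 1],
                                       to = pairs[sel, 2]))
  zs <- vapply(1:50, function(s) {
    gs <- sample(nodes, 5)
    neaTest(net, gs, nPerm = 200, seed = s)@z
  }, numeric(1))
  expect_lt(abs(mean(zs, na.rm = TRUE)), 0.3)
})

test_that("Fisher target enrichment matches exact enumeration", {
  # balanced table: no association
  res <- fisherTargetEnrichment(nodesA = sprintf("a%d", 1:20),
                                nodesB = sprintf("b%d", 1:20),
                                targets = c(sprintf("a%d", 1:10),
                                            sprintf("b%d", 1:10)),
                                universe = c(sprintf("a%d", 1:20),
                                             sprintf("b%d", 1:20)))
  expect_equal(res$oddsRatio, 1)
  expect_equal(res$p, 1)
  # 8/2 vs 2/8 split
  res2 <- fisherTargetEnrichment(nodesA = sprintf("a%d", 1:10),
                                 nodesB = sprintf("b%d", 1:10),
                                 targets = c(sprintf("a%d", 1:8),
                                             sprintf("b%d", 1:2)),
                                 universe = c(sprintf("a%d", 1:10),
                                              sprintf("b%d", 1:10)))
  expect_equal(res2$p, bruteFisherP(8, 2, 2, 8), tolerance = 1e-9)
  expect_equal(res2$p, fisher.test(matrix(c(8, 2, 2, 8), 2))$p.value)
  # zero margin: empty target set
  res3 <- fisherTargetEnrichment(nodesA = "a1", targets = character(),
                                 universe = c("a1", "b1"))
  expect_equal(res3$p, 1)
  expect_false(res3$orDefined)
})

test_that("one-network mode tables membership against the universe", {
  res <- fisherTargetEnrichment(nodesA = c("a", "b"),
                                targets = c("a", "c"),
                                universe = c("a", "b", "c", "d"))
  expect_equal(unname(res$table),
               matrix(c(1, 1, 1, 1), 2, byrow = TRUE))
})

test_that("TF-PPI enrichment agrees with the cluster-typing oracle", {
  universe <- sprintf("g%02d", 1:30)
  sub <- list(c1 = universe[1:8])
  gmt <- list(term1 = universe[5:14], term2 = universe[25:30],
              term3 = c("absent1", "absent2"))
  res <- tfppiEnrichment(sub, gmt, universe)
  oracle <- scoreClusterTypes(sub, gmt[1:2], universe)
  expect_equal(res$p, oracle$p)
  expect_equal(attr(res, "skipped"), "term3")
  # disjoint term -> p = 1; everything-everywhere -> p = 1
  expect_equal(res$p[res$term == "term2"], 1)
  resAll <- tfppiEnrichment(list(c1 = universe), list(t = universe),
                            universe)
  expect_equal(resAll$p, 1)
})

test_that("paired term comparison is an exact signed-rank test", {
  expect_equal(pairedTermComparison(c(1, 2, 3), c(1, 2, 3))$p, 1)
  res <- pairedTermComparison(rep(0, 5), 1:5)  # all post > pre, n = 5
  expect_equal(res$p, 0.0625)
  a <- pairedTermComparison(c(3, 1, 4, 2), c(5, 2, 2, 9))
  b <- pairedTermComparison(c(5, 2, 2, 9), c(3, 1, 4, 2))
  expect_equal(a$p, b$p)  # antisymmetric in the pair order
})

test_that("TF-target filtering applies both thresholds and deduplicates", {
  wt <- data.frame(tf = c("t1", "t1", "t2"), target = c("a", "b", "c"),
                   weight = c(0.1, 0.05, 0.4))
  pt <- data.frame(tf = c("t1", "t3"), target = c("a", "d"),
                   p = c(1e-8, 1e-7))
  res <- filterTfTargets(wt, pt)
  expect_equal(nrow(res), 2L)             # t1-a (both), t2-c (weight)
  expect_equal(res$source[res$tf == "t1"], "both")
  expect_false("t3" %in% res$tf)          # p = 1e-7 exactly is excluded
  expect_true(all(res$target != "b"))     # weight 0.05 < 0.1 excluded
  expect_equal(res$target[res$tf == "t2"], "c")  # weight 0.1 exactly kept
  expect_error(filterTfTargets(data.frame(tf = "t", weight = 1)),
               "malformed")
})
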