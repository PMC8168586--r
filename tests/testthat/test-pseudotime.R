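lineMatrix <- function(seed, n = 80, g = 30, noise = 0.3) {
  set.seed(seed)
  pos <- sort(runif(n))
  m <- outer(rnorm(g, sd = 1), pos) + matrix(rnorm(g * n, sd = noise), g, n)
  dimnames(m) <- list(sprintf("g%02d", 1:g), sprintf("c%02d", 1:n))
  list(m = m, pos = pos)
}

test_that("DC1 recovers a one-dimensional latent order", {
  l <- lineMatrix(71)
  co <- diffusionMap(l$m, nComponents = 3, nNeighbors = 10)
  expect_gte(abs(cor(co[, 1], l$pos, method = "spearman")), 0.9)
})

test_that("diffusion coordinates are equivariant to cell permutation", {
  l <- lineMatrix(72, n = 50)
  co <- diffusionMap(l$m, nComponents = 3, nNeighbors = 10)
  perm <- sample(ncol(l$m))
  co2 <- diffusionMap(l$m[, perm], nComponents = 3, nNeighbors = 10)
  for (j in 1:3) {
    agree <- cor(co[perm, j], co2[, j])
    expect_gt(abs(agree), 1 - 1e-8)  # identical up to component sign
  }
  # identical cells map to identical coordinates
  dup <- cbind(l$m, dupA = l$m[, 1], dupB = l$m[, 1])
  co3 <- diffusionMap(dup, nComponents = 2, nNeighbors = 10)
  expect_equal(co3["dupA", ], co3["dupB", ], tolerance = 1e-8)
})

test_that("coordinates are stable under uniform input scaling (up to sign)", {
  l <- lineMatrix(73, n = 40)
  co <- diffusionMap(l$m, nComponents = 2, nNeighbors = 10)
  co2 <- diffusionMap(l$m * 1.7, nComponents = 2, nNeighbors = 10)
  # scaling changes the kernel, not the geometry: orders must agree
  expect_gte(abs(cor(co[, 1], co2[, 1], method = "spearman")), 0.99)
})

test_that("degenerate inputs are rejected", {
  flat <- matrix(1, 10, 20,
                 dimnames = list(sprintf("g%d", 1:10), sprintf("c%d", 1:20)))
  expect_error(diffusionMap(flat, nComponents = 2, nNeighbors = 10),
               "degenerate")
  expect_error(diffusionMap(lineMatrix(1, n = 5)$m, nComponents = 8),
               "nComponents")
})

test_that("collinear clusters give one lineage with increasing pseudotime", {
  set.seed(74)
  centers <- c(0, 2, 4)
  lab <- rep(c("A", "B", "C"), each = 30)
  co <- cbind(DC1 = centers[as.integer(factor(lab))] + rnorm(90, sd = 0.2),
              DC2 = rnorm(90, sd = 0.2))
  rownames(co) <- sprintf("c%02d", 1:90)
  traj <- fitLineages(co, lab, "A")
  expect_equal(length(lineages(traj)), 1L)
  expect_equal(lineages(traj)[[1]], c("A", "B", "C"))
  mean_pt <- tapply(pseudotime(traj), lab, mean)
  expect_true(all(diff(mean_pt[c("A", "B", "C")]) > 0))
})

test_that("a V-shaped layout with the root at the vertex gives two lineages", {
  set.seed(75)
  lab <- rep(c("root", "left", "right"), each = 25)
  mu <- rbind(root = c(0, 0), left = c(2, 2), right = c(2, -2))
  co <- mu[lab, ] + matrix(rnorm(150, sd = 0.15), 75, 2)
  rownames(co) <- sprintf("c%02d", 1:75)
  colnames(co) <- c("DC1", "DC2")
  traj <- fitLineages(co, lab, "root")
  expect_equal(length(lineages(traj)), 2L)
  expect_setequal(vapply(lineages(traj), function(p) p[2], character(1)),
                  c("left", "right"))
  # root-cluster cells sit earliest on every lineage
  expect_equal(names(which.min(tapply(pseudotime(traj), lab, mean))), "root")
  expect_error(fitLineages(co, lab, "missing"), "not among")
})

test_that("a single cluster degrades to ordering along DC1", {
  co <- cbind(DC1 = seq(0, 1, length.out = 20), DC2 = 0)
  rownames(co) <- sprintf("c%02d", 1:20)
  traj <- fitLineages(co, rep("only", 20), "only")
  expect_equal(length(lineages(traj)), 1L)
  expect_equal(unname(pseudotime(traj)), seq(0, 1, length.out = 20))
})

test_that("pseudotime profiles smooth as specified", {
  n <- 50
  pt <- seq_len(n) / n
  m <- rbind(flat = rep(3, n),
             step = rep(c(0, 4), each = n / 2))
  colnames(m) <- sprintf("c%02d", 1:n)
  prof <- expressionAlongPseudotime(m, pt, c("flat", "step"), window = 5,
                                    center = FALSE)
  expect_true(all(prof["flat", ] == 3))
  expect_true(all(diff(prof["step", ]) >= 0))  # monotone across the step
  centered <- expressionAlongPseudotime(m, pt, "flat", window = 5)
  expect_true(all(centered == 0))
  raw <- expressionAlongPseudotime(m, pt, "step", window = 1,
                                   center = FALSE)
  expect_equal(unname(raw["step", ]), unname(m["step", ]))
  expect_error(expressionAlongPseudotime(m, pt, "step", window = 100),
               "window")
  expect_error(expressionAlongPseudotime(m, pt, "absent"), "not present")
})
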