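# Shared fixtures and independent oracles.

# small count container from a plain matrix
toyCounts <- function(m, genes = NULL, cells = NULL, isSpike = NULL,
                      isPanel = NULL) {
  if (is.null(rownames(m)))
    rownames(m) <- genes %||% sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- cells %||% sprintf("c%02d", seq_len(ncol(m)))
  gm <- data.frame(
    is_panel = isPanel %||% rep(FALSE, nrow(m)),
    is_spike = isSpike %||% rep(FALSE, nrow(m)))
  makeCountMatrix(m, geneMeta = gm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a desk-size simulator configuration for unit tests (defaults overridable)
tinyConfig <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(nCells = 80, nGenes = 300, nPanel = 40, nTFsPerProgram = 2,
         nTargetsPerProgram = 6, nMaturationGenes = 10, nSpikes = 10,
         nSpikesOnPanel = 6, seed = seed),
    list(...))
  do.call(simulationConfig, args)
}

adjustedRandIndex <- function(a, b) mclust::adjustedRandIndex(a, b)

# --- enumeration oracles (independent of the package implementations) ----

# two-sided rank-sum p by enumeration of all group assignments
bruteRankSumP <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  sets <- utils::combn(N, n1)
  ws <- apply(sets, 2L, function(idx) sum(r[idx]))
  lower <- mean(ws <= w + 1e-9)
  upper <- mean(ws >= w - 1e-9)
  min(1, 2 * min(lower, upper))
}

# two-sided signed-rank p by enumeration of all sign vectors
bruteSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  lower <- mean(ws <= w + 1e-9)
  upper <- mean(ws >= w - 1e-9)
  min(1, 2 * min(lower, upper))
}

# upper-tail hypergeometric by direct combinatorial summation
bruteHyperP <- function(k, K, n, N) {
  kk <- max(k, max(0, n - (N - K))):min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# two-sided Fisher p: sum of table probabilities not exceeding the
# observed one, margins fixed
bruteFisherP <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(xs, c1, N - c1, r1)
  obs <- stats::dhyper(a, c1, N - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# degree sequence of a GeneNetwork, sorted by gene
degreesOf <- function(net) {
  n <- networkNodes(net)
  stats::setNames(n$degree, n$gene)[order(n$gene)]
}

# exhaustive null of the NEA statistic over all simple graphs with the
# degree sequence of `net` (feasible for ~6 nodes)
bruteNeaNull <- function(net, geneSet) {
  nodes <- networkNodes(net)$gene
  pairs <- t(utils::combn(nodes, 2L))
  m <- numEdges(net)
  want <- degreesOf(net)
  stat <- integer(0)
  sets <- utils::combn(nrow(pairs), m)
  for (j in seq_len(ncol(sets))) {
    sel <- pairs[sets[, j], , drop = FALSE]
    deg <- table(factor(c(sel[, 1L], sel[, 2L]), levels = sort(nodes)))
    if (all(as.integer(deg) == as.integer(want)))
      stat <- c(stat, sum(sel[, 1L] %in% geneSet | sel[, 2L] %in% geneSet))
  }
  stat
}
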