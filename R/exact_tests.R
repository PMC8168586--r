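# Exact tie-aware Wilcoxon routines.
#
# Ties are handled with average ranks. Average ranks are multiples of 1/2,
# so doubling them gives integers and the exact null distribution of the
# (doubled) statistic can be built by dynamic programming over the rank
# multiset. Counts stay below 2^53 for the group sizes where the exact path
# is used, so double-precision DP is exact.

rankSumNullCounts <- function(r2, n1) {
  # number of size-n1 subsets of the doubled ranks r2 with each possible sum
  total <- sum(r2)
  dp <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
  dp[1L, 1L] <- 1
  for (r in r2) {
    kmax <- n1
    for (k in kmax:1) {
      shifted <- c(rep(0, r), dp[k, seq_len(total + 1L - r)])
      dp[k + 1L, ] <- dp[k + 1L, ] + shifted
    }
  }
  dp[n1 + 1L, ]  # index s+1 holds #subsets with doubled-rank sum s
}

#' Exact two-sided Wilcoxon rank-sum p-value
#'
#' Exact null distribution of the rank-sum of the first sample, with average
#' ranks for ties (the null is built over the observed tied rank multiset,
#' so ties are handled exactly, unlike \code{stats::wilcox.test}). Two-sided
#' p is twice the smaller tail, capped at 1.
#'
#' @param x,y numeric samples.
#' @return list with \code{statistic} (rank sum of \code{x}) and \code{p}.
#' @export
exactRankSumP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(x, y))
  r2 <- as.integer(round(2 * r))
  w2 <- sum(r2[seq_len(n1)])
  counts <- rankSumNullCounts(r2, n1)
  total <- sum(counts)
  s <- seq_along(counts) - 1L
  lower <- sum(counts[s <= w2]) / total
  upper <- sum(counts[s >= w2]) / total
  list(statistic = w2 / 2, p = min(1, 2 * min(lower, upper)))
}

#' Normal-approximation two-sided rank-sum p-value with tie correction
#'
#' @param x,y numeric samples.
#' @param correct apply a continuity correction of 0.5.
#' @return list with \code{statistic} and \code{p}.
#' @export
approxRankSumP <- function(x, y, correct = TRUE) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(r)
  tieTerm <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tieTerm)
  if (sigma2 <= 0) return(list(statistic = W, p = 1))
  dev <- W - mu
  cc <- if (correct) sign(dev) * 0.5 else 0
  z <- (dev - cc) / sqrt(sigma2)
  list(statistic = W, p = min(1, 2 * pnorm(-abs(z))))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact (tie-aware) null when both groups have at most \code{exactLimit}
#' observations, normal approximation with tie correction otherwise.
#' Constant data across both groups gives p = 1 by convention.
#'
#' @param x,y numeric samples.
#' @param exactLimit largest group size for the exact path (default 25).
#' @return list with \code{statistic}, \code{p} and \code{method}.
#' @export
rankSumTest <- function(x, y, exactLimit = 25) {
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = sum(rank(c(x, y))[seq_along(x)]), p = 1,
                method = "degenerate"))
  if (length(x) <= exactLimit && length(y) <= exactLimit) {
    out <- exactRankSumP(x, y)
    out$method <- "exact"
  } else {
    out <- approxRankSumP(x, y)
    out$method <- "normal"
  }
  out
}

signedRankNullCounts <- function(r2) {
  # distribution of the doubled positive-rank sum over the 2^n sign vectors
  total <- sum(r2)
  dp <- numeric(total + 1L)
  dp[1L] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), dp[seq_len(total + 1L - r)])
    dp <- dp + shifted
  }
  dp
}

#' Exact two-sided Wilcoxon signed-rank test
#'
#' Paired differences equal to zero are dropped; the absolute differences
#' are ranked with average ranks for ties, and the exact null distribution
#' of the positive-rank sum is built over all sign assignments. Above
#' \code{exactLimit} non-zero pairs a normal approximation with tie
#' correction is used. All differences zero gives p = 1.
#'
#' @param x,y paired numeric vectors, or a single vector of differences in
#'   \code{x} with \code{y} missing.
#' @param exactLimit largest number of non-zero pairs for the exact path.
#' @return list with \code{statistic} (positive-rank sum \eqn{W^+}),
#'   \code{p}, \code{nUsed} and \code{method}.
#' @export
signedRankTest <- function(x, y = NULL, exactLimit = 25) {
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p = 1, nUsed = 0L, method = "degenerate"))
  r <- rank(abs(d))
  r2 <- as.integer(round(2 * r))
  w2 <- sum(r2[d > 0])
  if (n <= exactLimit) {
    counts <- signedRankNullCounts(r2)
    total <- sum(counts)
    s <- seq_along(counts) - 1L
    lower <- sum(counts[s <= w2]) / total
    upper <- sum(counts[s >= w2]) / total
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    ties <- table(r)
    sigma2 <- sum(r^2) / 4  # equals n(n+1)(2n+1)/24 adjusted for ties
    dev <- w2 / 2 - mu
    z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = w2 / 2, p = p, nUsed = n, method = method)
}

#' Upper-tail hypergeometric overlap p-value
#'
#' \eqn{P(X \ge k)} for drawing \code{n} genes from a universe of \code{N}
#' containing \code{K} special genes and observing \code{k} of them.
#'
#' @param k observed overlap.
#' @param K special genes in the universe.
#' @param n drawn genes.
#' @param N universe size.
#' @return The upper-tail probability.
#' @export
hyperTestP <- function(k, K, n, N) {
  stopifnot(N > 0, K >= 0, K <= N, n >= 0, n <= N, k >= 0)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
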