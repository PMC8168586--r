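# Normalisation, dimensionality reduction, clustering, and rank-based
# differential expression.

#' Size-factor log normalisation
#'
#' Computes \code{log2(count / sizeFactor + 1)} per cell and stores it as
#' the \code{"logcounts"} assay. The default \code{"library"} factor is the
#' cell's library size divided by a fixed reference depth (\code{scale},
#' default 10,000 counts), so normalised values are exactly invariant to
#' any per-cell depth scaling, including a uniform change of sequencing
#' depth. \code{"medianRatio"} uses DESeq-style median-of-ratios factors;
#' a numeric vector supplies explicit per-cell factors.
#'
#' @param x count \code{SingleCellExperiment}.
#' @param sizeFactors \code{"library"}, \code{"medianRatio"}, or a numeric
#'   vector of per-cell size factors.
#' @param scale reference depth for \code{"library"} factors.
#' @return \code{x} with assay \code{"logcounts"} and
#'   \code{colData(x)$sizeFactor} added.
#' @export
normalizeLog <- function(x, sizeFactors = c("library", "medianRatio"),
                         scale = 1e4) {
  counts <- as.matrix(SummarizedExperiment::assay(x, "counts"))
  lib <- colSums(counts)
  if (any(lib == 0)) stop("cells with empty libraries cannot be normalised")
  sf <- if (is.numeric(sizeFactors)) {
    stopifnot(length(sizeFactors) == ncol(counts), all(sizeFactors > 0))
    sizeFactors
  } else switch(match.arg(sizeFactors),
    library = lib / scale,
    medianRatio = {
      if (!requireNamespace("DESeq2", quietly = TRUE))
        stop("median-ratio size factors require the DESeq2 package")
      DESeq2::estimateSizeFactorsForMatrix(counts)
    })
  logc <- log2(sweep(counts, 2L, sf, "/") + 1)
  SummarizedExperiment::assay(x, "logcounts") <- logc
  SummarizedExperiment::colData(x)$sizeFactor <- sf
  x
}

logcountsOf <- function(x) {
  if (is.matrix(x)) return(x)
  if (!"logcounts" %in% SummarizedExperiment::assayNames(x))
    stop("no 'logcounts' assay; run normalizeLog() first")
  as.matrix(SummarizedExperiment::assay(x, "logcounts"))
}

scaledPCA <- function(logc, nPcs, nHvg) {
  sds <- apply(logc, 1L, sd)
  keep <- sds > 0
  if (!is.null(nHvg) && sum(keep) > nHvg)
    keep <- keep & rank(-sds, ties.method = "first") <= nHvg
  z <- (logc[keep, , drop = FALSE] - rowMeans(logc[keep, , drop = FALSE])) /
    sds[keep]
  nPcs <- min(nPcs, nrow(z) - 1L, ncol(z) - 1L)
  prcomp(t(z), rank. = nPcs)$x
}

#' Cluster cells
#'
#' Cells are embedded by PCA of the scaled log-normalised values of the most
#' variable genes, then partitioned either by Ward hierarchical clustering
#' (default; when \code{k} is missing it is chosen to maximise the mean
#' silhouette width over \code{2..kMax}, ties broken toward smaller k) or by
#' Louvain community detection on a shared-neighbour kNN graph.
#'
#' @param x a normalised \code{SingleCellExperiment} or a genes x cells
#'   log-expression matrix.
#' @param method \code{"hierarchical_ward"} or \code{"knn_graph_louvain"}.
#' @param k number of clusters (hierarchical); \code{NULL} for silhouette
#'   selection. \code{k = 1} labels every cell identically.
#' @param kMax largest k tried during silhouette selection.
#' @param nPcs number of principal components (default 20).
#' @param nHvg number of highly variable genes kept (default 500).
#' @param nNeighbors kNN graph degree (Louvain).
#' @param resolution Louvain resolution parameter.
#' @param seed RNG seed (Louvain refinement).
#' @return A \linkS4class{ClusterResult} (empty DE tables).
#' @export
clusterCells <- function(x, method = c("hierarchical_ward",
                                       "knn_graph_louvain"),
                         k = NULL, kMax = 8, nPcs = 20, nHvg = 500,
                         nNeighbors = 15, resolution = 1, seed = 1) {
  method <- match.arg(method)
  logc <- logcountsOf(x)
  nCells <- ncol(logc)
  if (nCells < 2L) stop("clustering needs at least two cells")
  if (!is.null(k) && k > nCells) stop("k cannot exceed the number of cells")
  pc <- scaledPCA(logc, nPcs, nHvg)
  if (method == "hierarchical_ward") {
    if (!is.null(k) && k == 1L) {
      lab <- rep(1L, nCells)
    } else {
      d <- dist(pc)
      hc <- hclust(d, method = "ward.D2")
      if (is.null(k)) {
        ks <- 2:min(kMax, nCells - 1L)
        sil <- vapply(ks, function(kk) {
          mean(cluster::silhouette(cutree(hc, kk), d)[, "sil_width"])
        }, numeric(1))
        k <- ks[which.max(sil)]  # which.max takes the first = smallest k
      }
      lab <- cutree(hc, k)
    }
  } else {
    set.seed(seed)
    nn <- min(nNeighbors, nCells - 1L)
    d <- as.matrix(dist(pc))
    edges <- do.call(rbind, lapply(seq_len(nCells), function(i) {
      js <- order(d[i, ])[2:(nn + 1L)]
      cbind(i, js)
    }))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::simplify(g)
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    lab <- igraph::membership(comm)
  }
  labels <- factor(lab)
  names(labels) <- colnames(logc)
  new("ClusterResult", labels = labels, degTables = list())
}

normalizedCountsOf <- function(x) {
  # counts on the size-factor scale (not logged), for fold changes
  if (is.matrix(x)) return(2^x - 1)
  counts <- as.matrix(SummarizedExperiment::assay(x, "counts"))
  sf <- SummarizedExperiment::colData(x)$sizeFactor
  if (is.null(sf)) stop("no size factors; run normalizeLog() first")
  sweep(counts, 2L, sf, "/")
}

deTable <- function(norm, raw, inGroup, params, exactLimit = 25) {
  nIn <- sum(inGroup); nOut <- sum(!inGroup)
  if (nIn == 0L || nOut == 0L) stop("both groups must be non-empty")
  genes <- rownames(norm)
  if (nIn <= exactLimit && nOut <= exactLimit) {
    p <- vapply(seq_len(nrow(norm)), function(i)
      rankSumTest(norm[i, inGroup], norm[i, !inGroup])$p, numeric(1))
  } else {
    ranks <- t(apply(norm, 1L, rank))
    W <- rowSums(ranks[, inGroup, drop = FALSE])
    N <- nIn + nOut
    mu <- nIn * (N + 1) / 2
    tieTerm <- apply(norm, 1L, function(v) {
      tt <- tabulate(factor(v))
      sum(tt^3 - tt)
    }) / (N * (N - 1))
    sigma2 <- nIn * nOut / 12 * ((N + 1) - tieTerm)
    dev <- W - mu
    z <- ifelse(sigma2 > 0, (dev - sign(dev) * 0.5) / sqrt(sigma2), 0)
    p <- ifelse(sigma2 > 0, pmin(1, 2 * pnorm(-abs(z))), 1)
  }
  meanIn <- rowMeans(raw[, inGroup, drop = FALSE])
  meanOut <- rowMeans(raw[, !inGroup, drop = FALSE])
  lnFC <- log((meanIn + 1) / (meanOut + 1))
  pctIn <- rowMeans(raw[, inGroup, drop = FALSE] > 0)
  pctOut <- rowMeans(raw[, !inGroup, drop = FALSE] > 0)
  fdr <- p.adjust(p, method = "BH")
  data.frame(gene = genes, lnFC = lnFC, p = p, fdr = fdr,
             pctIn = pctIn, pctOut = pctOut,
             significant = fdr <= params@fdrCut &
               abs(lnFC) >= params@lnfcCut & pctIn >= params@minPct,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank-based differential expression
#'
#' Per gene: a two-sided Wilcoxon rank-sum test on log-normalised values
#' (exact tie-aware null when both groups have at most 25 cells, normal
#' approximation with tie correction otherwise), Benjamini-Hochberg FDR
#' over tested genes, the natural-log fold change of mean size-factor
#' normalised expression (pseudocount 1), and the fractions of cells with a
#' non-zero count in and out of the group. The significant set applies
#' \code{fdr <= fdrCut}, \code{|lnFC| >= lnfcCut} and
#' \code{pctIn >= minPct}.
#'
#' @param x normalised \code{SingleCellExperiment} (assay
#'   \code{"logcounts"} plus size factors).
#' @param labels factor of cluster labels (or a
#'   \linkS4class{ClusterResult}).
#' @param contrast \code{"one_vs_rest"} (one table per cluster) or
#'   \code{"pair"} (one table, \code{groups} names the two clusters).
#' @param groups for \code{contrast = "pair"}: the two cluster labels, first
#'   versus second.
#' @param params a \linkS4class{DEParams}.
#' @return A \linkS4class{ClusterResult} carrying the labels and DE tables
#'   (named \code{"<cluster>_vs_rest"} or \code{"<a>_vs_<b>"}).
#' @export
differentialExpression <- function(x, labels,
                                   contrast = c("one_vs_rest", "pair"),
                                   groups = NULL, params = deParams()) {
  contrast <- match.arg(contrast)
  if (is(labels, "ClusterResult")) labels <- clusterLabels(labels)
  labels <- as.factor(labels)
  norm <- logcountsOf(x)
  stopifnot(length(labels) == ncol(norm))
  raw <- normalizedCountsOf(x)
  tables <- list()
  if (contrast == "one_vs_rest") {
    for (cl in levels(labels)) {
      tables[[paste0(cl, "_vs_rest")]] <-
        deTable(norm, raw, labels == cl, params)
    }
  } else {
    if (is.null(groups) || length(groups) != 2L)
      stop("'groups' must name the two clusters to compare")
    keep <- labels %in% groups
    tables[[paste0(groups[1L], "_vs_", groups[2L])]] <-
      deTable(norm[, keep, drop = FALSE], raw[, keep, drop = FALSE],
              labels[keep] == groups[1L], params)
  }
  if (is.null(names(labels))) names(labels) <- colnames(norm)
  new("ClusterResult", labels = labels, degTables = tables)
}
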