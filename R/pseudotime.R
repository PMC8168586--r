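# Diffusion-map embedding, MST lineages, and gene-versus-pseudotime
# summaries.

#' Diffusion-map embedding of cells
#'
#' Builds a Gaussian kernel with a per-cell local bandwidth (the distance
#' to the \eqn{\lceil nNeighbors/2 \rceil}-th nearest neighbour),
#' symmetrised as \eqn{K_{ij} = \exp(-d_{ij}^2 / (2 \sigma_i \sigma_j))},
#' applies density normalisation (dividing by the product of row sums) to
#' remove sampling-density effects, row-normalises to a Markov transition
#' matrix and takes its leading non-trivial right eigenvectors scaled by
#' their eigenvalues as coordinates. Eigenvector signs are fixed by the
#' first-nonzero-positive convention, so results are fully deterministic.
#'
#' @param x normalised \code{SingleCellExperiment} (assay
#'   \code{"logcounts"}) or a genes x cells log-expression matrix.
#' @param nComponents number of diffusion components returned.
#' @param nNeighbors neighbourhood size controlling the local bandwidth.
#' @return cells x components matrix of diffusion coordinates.
#' @export
diffusionMap <- function(x, nComponents = 10, nNeighbors = 30) {
  logc <- logcountsOf(x)
  n <- ncol(logc)
  if (n < nComponents + 2L)
    stop("need at least nComponents + 2 cells")
  d <- as.matrix(dist(t(logc)))
  kLocal <- max(1L, ceiling(nNeighbors / 2))
  sigma <- apply(d, 1L, function(row) sort(row)[kLocal + 1L])
  if (any(sigma == 0))
    stop("degenerate spectrum: duplicate cells collapse the local bandwidth")
  K <- exp(-d^2 / (2 * outer(sigma, sigma)))
  diag(K) <- 0
  q <- rowSums(K)
  W <- K / outer(q, q)          # density normalisation
  dW <- rowSums(W)
  S <- W / outer(sqrt(dW), sqrt(dW))   # symmetric conjugate of the Markov matrix
  eig <- eigen(S, symmetric = TRUE)
  # right eigenvectors of the Markov matrix; drop the trivial constant one
  phi <- eig$vectors / sqrt(dW)
  comps <- seq(2L, nComponents + 1L)
  coords <- sweep(phi[, comps, drop = FALSE], 2L, eig$values[comps], "*")
  for (j in seq_len(ncol(coords))) {
    nz <- which(coords[, j] != 0)[1L]
    if (!is.na(nz) && coords[nz, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(colnames(logc),
                           paste0("DC", seq_len(ncol(coords))))
  coords
}

projectOntoPath <- function(points, path) {
  # orthogonal projection of points onto a piecewise-linear path;
  # returns arc-length position and distance to the path
  nSeg <- nrow(path) - 1L
  arcStart <- c(0, cumsum(sqrt(rowSums((path[-1L, , drop = FALSE] -
    path[-nrow(path), , drop = FALSE])^2))))
  best <- matrix(Inf, nrow(points), 2L)  # columns: distance, arc position
  for (s in seq_len(nSeg)) {
    a <- path[s, ]; b <- path[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    tt <- if (len2 == 0) rep(0, nrow(points)) else
      pmin(1, pmax(0, as.vector(sweep(points, 2L, a) %*% ab) / len2))
    proj <- sweep(outer(tt, ab), 2L, a, "+")
    dd <- sqrt(rowSums((points - proj)^2))
    better <- dd < best[, 1L]
    best[better, 1L] <- dd[better]
    best[better, 2L] <- arcStart[s] + tt[better] * sqrt(len2)
  }
  list(arc = best[, 2L], dist = best[, 1L],
       totalLength = arcStart[nrow(path)])
}

#' Fit lineages and pseudotime from a start cluster
#'
#' Builds the minimum spanning tree over cluster centroids in diffusion
#' space; lineages are the root-to-leaf paths. Each cell's pseudotime along
#' a lineage is the normalised arc length of its orthogonal projection onto
#' the lineage's piecewise-linear centroid path, and the cell is assigned
#' to the lineage whose path is nearest. With a single cluster, the trivial
#' lineage orders cells by the first diffusion component.
#'
#' @param coords cells x components diffusion coordinates.
#' @param labels factor of cluster labels per cell.
#' @param rootCluster label of the designated start cluster.
#' @return A \linkS4class{TrajectoryResult}.
#' @export
fitLineages <- function(coords, labels, rootCluster) {
  labels <- as.factor(labels)
  rootCluster <- as.character(rootCluster)
  if (!rootCluster %in% levels(labels))
    stop("root cluster '", rootCluster, "' not among the labels")
  stopifnot(nrow(coords) == length(labels))
  cls <- levels(labels)
  centers <- do.call(rbind, lapply(cls, function(cl)
    colMeans(coords[labels == cl, , drop = FALSE])))
  rownames(centers) <- cls
  if (length(cls) == 1L) {
    pt <- coords[, 1L]
    pt <- (pt - min(pt)) / max(max(pt) - min(pt), .Machine$double.eps)
    ptm <- matrix(pt, ncol = 1L,
                  dimnames = list(rownames(coords), "lineage1"))
    return(new("TrajectoryResult", coordinates = coords,
               clusterCenters = centers,
               mstEdges = data.frame(from = character(), to = character()),
               lineages = list(lineage1 = cls),
               pseudotimeMatrix = ptm,
               weights = matrix(1, nrow(coords), 1L,
                                dimnames = dimnames(ptm)),
               pseudotime = setNames(pt, rownames(coords)),
               rootCluster = rootCluster))
  }
  dC <- as.matrix(dist(centers))
  g <- igraph::graph_from_adjacency_matrix(dC, mode = "undirected",
                                           weighted = TRUE)
  tree <- igraph::mst(g)
  deg <- igraph::degree(tree)
  leaves <- setdiff(names(deg)[deg == 1L], rootCluster)
  if (!length(leaves)) leaves <- setdiff(cls, rootCluster)
  paths <- lapply(leaves, function(lf) {
    p <- igraph::shortest_paths(tree, from = rootCluster, to = lf)$vpath[[1L]]
    names(p)
  })
  names(paths) <- paste0("lineage", seq_along(paths))
  mstE <- igraph::as_data_frame(tree, what = "edges")
  ptm <- matrix(NA_real_, nrow(coords), length(paths),
                dimnames = list(rownames(coords), names(paths)))
  dmat <- ptm
  for (j in seq_along(paths)) {
    pr <- projectOntoPath(coords, centers[paths[[j]], , drop = FALSE])
    ptm[, j] <- pr$arc / max(pr$totalLength, .Machine$double.eps)
    dmat[, j] <- pr$dist
  }
  assign <- max.col(-dmat, ties.method = "first")
  weights <- matrix(0, nrow(coords), length(paths), dimnames = dimnames(ptm))
  weights[cbind(seq_len(nrow(coords)), assign)] <- 1
  consensus <- ptm[cbind(seq_len(nrow(coords)), assign)]
  new("TrajectoryResult", coordinates = coords, clusterCenters = centers,
      mstEdges = mstE, lineages = paths, pseudotimeMatrix = ptm,
      weights = weights,
      pseudotime = setNames(consensus, rownames(coords)),
      rootCluster = rootCluster)
}

#' Gene expression along pseudotime
#'
#' Orders cells by pseudotime and smooths each gene's log-normalised
#' expression with a centred rolling mean of the stated window (partial
#' windows at the ends). With \code{center = TRUE} each profile is centred
#' on its mean, the form used for heat-map export.
#'
#' @param x normalised \code{SingleCellExperiment} or genes x cells
#'   log-expression matrix.
#' @param pt pseudotime per cell (named or in column order).
#' @param genes genes to profile.
#' @param window rolling window size in cells (1 = no smoothing).
#' @param center subtract each gene's mean smoothed value.
#' @return genes x cells matrix of smoothed profiles over cells ordered by
#'   pseudotime (order in attribute \code{"cellOrder"}).
#' @export
expressionAlongPseudotime <- function(x, pt, genes, window = 20,
                                      center = TRUE) {
  logc <- logcountsOf(x)
  missing <- setdiff(genes, rownames(logc))
  if (length(missing))
    stop("genes not present: ", paste(missing, collapse = ", "))
  if (window > ncol(logc)) stop("window larger than the number of cells")
  if (!is.null(names(pt))) pt <- pt[colnames(logc)]
  ord <- order(pt)
  m <- logc[genes, ord, drop = FALSE]
  sm <- t(apply(m, 1L, function(v)
    zoo::rollapply(v, width = window, FUN = mean, partial = TRUE,
                   align = "center")))
  if (window == 1L) sm <- m  # identity smoothing
  if (center) sm <- sm - rowMeans(sm)
  dimnames(sm) <- list(genes, colnames(logc)[ord])
  attr(sm, "cellOrder") <- colnames(logc)[ord]
  sm
}
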