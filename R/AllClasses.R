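#' @import methods
#' @importFrom stats median cor dist hclust cutree prcomp p.adjust phyper
#'   pnorm pt plogis rnbinom rbinom rmultinom runif rnorm fisher.test
#'   quantile sd setNames aggregate complete.cases
#' @importFrom utils head read.delim write.table packageVersion
NULL

#' Capture panel description
#'
#' Holds the identifiers of the genes targeted by hybridisation-capture
#' probes, the spike-in identifiers present in the libraries, and the subset
#' of spike-ins that is itself covered by probes (in the transcription-factor
#' panel used as the reference design, 56 of the 92 ERCC spike-ins carry
#' probes).
#'
#' @slot targetGenes character vector of targeted gene identifiers.
#' @slot spikeIds character vector of spike-in identifiers.
#' @slot spikesOnPanel subset of \code{spikeIds} covered by capture probes.
#' @export
setClass("CapturePanel",
  slots = c(targetGenes = "character",
            spikeIds = "character",
            spikesOnPanel = "character"))

setValidity("CapturePanel", function(object) {
  msg <- character()
  if (length(object@targetGenes) == 0L)
    msg <- c(msg, "'targetGenes' must be non-empty")
  if (anyDuplicated(object@targetGenes))
    msg <- c(msg, "'targetGenes' contains duplicates")
  if (!all(object@spikesOnPanel %in% object@spikeIds))
    msg <- c(msg, "'spikesOnPanel' must be a subset of 'spikeIds'")
  if (length(intersect(object@targetGenes, object@spikeIds)))
    msg <- c(msg, "'targetGenes' and 'spikeIds' must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Construct a CapturePanel
#'
#' @param targetGenes character vector of targeted gene identifiers.
#' @param spikeIds character vector of spike-in identifiers (may be empty).
#' @param spikesOnPanel subset of \code{spikeIds} covered by probes.
#' @return A \linkS4class{CapturePanel}.
#' @examples
#' capturePanel(c("SOX2", "PAX6"), paste0("ERCC-", 1:4), "ERCC-1")
#' @export
capturePanel <- function(targetGenes, spikeIds = character(),
                         spikesOnPanel = character()) {
  new("CapturePanel", targetGenes = as.character(targetGenes),
      spikeIds = as.character(spikeIds),
      spikesOnPanel = as.character(spikesOnPanel))
}

#' Cell and gene quality-control thresholds
#'
#' Defaults follow the filtering rules used for deep full-length single-cell
#' libraries: cells must express at least 2000 genes, have a library of at
#' least 0.5 million counts, must not have their 200 most expressed genes
#' account for more than 50% of counts (library complexity), and must not
#' have spike-ins account for more than 14% of counts (endogenous RNA
#' content). Genes are retained when their mean count across cells exceeds 1.
#'
#' @slot minGenesPerCell minimum number of detected genes per cell.
#' @slot minLibrarySize minimum total counts per cell.
#' @slot maxTop200Fraction maximum fraction of counts in the cell's 200 most
#'   expressed genes.
#' @slot maxSpikeFraction maximum fraction of counts assigned to spike-ins.
#' @slot minGeneMeanCount genes are kept when mean count is strictly greater.
#' @export
setClass("QCThresholds",
  slots = c(minGenesPerCell = "numeric", minLibrarySize = "numeric",
            maxTop200Fraction = "numeric", maxSpikeFraction = "numeric",
            minGeneMeanCount = "numeric"))

setValidity("QCThresholds", function(object) {
  msg <- character()
  fr <- c(object@maxTop200Fraction, object@maxSpikeFraction)
  if (any(fr < 0 | fr > 1))
    msg <- c(msg, "fraction thresholds must lie in [0, 1]")
  if (object@minGenesPerCell <= 0 || object@minLibrarySize <= 0)
    msg <- c(msg, "count thresholds must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct QC thresholds
#'
#' @param minGenesPerCell,minLibrarySize,maxTop200Fraction,maxSpikeFraction,minGeneMeanCount
#'   see \linkS4class{QCThresholds}.
#' @return A \linkS4class{QCThresholds}.
#' @export
qcThresholds <- function(minGenesPerCell = 2000, minLibrarySize = 5e5,
                         maxTop200Fraction = 0.50, maxSpikeFraction = 0.14,
                         minGeneMeanCount = 1) {
  new("QCThresholds", minGenesPerCell = minGenesPerCell,
      minLibrarySize = minLibrarySize, maxTop200Fraction = maxTop200Fraction,
      maxSpikeFraction = maxSpikeFraction, minGeneMeanCount = minGeneMeanCount)
}

#' Undirected gene coexpression network
#'
#' Nodes are genes with attributes (transcription-factor flag, optional
#' cluster assignment, degree); edges are unordered gene pairs with a signed
#' correlation weight. Edges are stored in canonical order (first endpoint
#' lexicographically smaller), with no self-loops and no duplicates; the
#' stored degree always equals the incident-edge count.
#'
#' @slot nodes data.frame with columns \code{gene}, \code{isTF},
#'   \code{cluster} (NA when unassigned), \code{degree}.
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{weight}.
#' @export
setClass("GeneNetwork",
  slots = c(nodes = "data.frame", edges = "data.frame"))

setValidity("GeneNetwork", function(object) {
  n <- object@nodes; e <- object@edges
  msg <- character()
  if (!all(c("gene", "isTF", "cluster", "degree") %in% names(n)))
    msg <- c(msg, "'nodes' must have columns gene, isTF, cluster, degree")
  if (!all(c("from", "to", "weight") %in% names(e)))
    msg <- c(msg, "'edges' must have columns from, to, weight")
  if (length(msg)) return(msg)
  if (anyDuplicated(n$gene)) msg <- c(msg, "duplicate node identifiers")
  if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
    if (!all(c(e$from, e$to) %in% n$gene))
      msg <- c(msg, "edge endpoints must be nodes")
    if (any(e$from > e$to))
      msg <- c(msg, "edges must be in canonical order (from < to)")
    if (anyDuplicated(paste(e$from, e$to, sep = "\r")))
      msg <- c(msg, "duplicate edges")
  }
  deg <- tabulate(factor(c(e$from, e$to), levels = n$gene),
                  nbins = nrow(n))
  if (!identical(as.integer(n$degree), as.integer(deg)))
    msg <- c(msg, "stored degree does not equal incident-edge count")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneNetwork
#'
#' Edges are canonicalised (unordered pairs), self-loops rejected and degrees
#' recomputed; node attributes default to non-TF, unassigned cluster.
#'
#' @param nodes character vector of gene identifiers, or a data.frame with a
#'   \code{gene} column and optional \code{isTF}, \code{cluster} columns.
#' @param edges data.frame with columns \code{from}, \code{to} and optional
#'   \code{weight} (defaults to 1).
#' @return A \linkS4class{GeneNetwork}.
#' @examples
#' geneNetwork(c("a", "b", "c"), data.frame(from = "b", to = "a"))
#' @export
geneNetwork <- function(nodes, edges = NULL) {
  if (is.character(nodes))
    nodes <- data.frame(gene = nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$isTF)) nodes$isTF <- rep(FALSE, nrow(nodes))
  if (is.null(nodes$cluster)) nodes$cluster <- rep(NA_character_, nrow(nodes))
  nodes$cluster <- as.character(nodes$cluster)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    if (is.null(edges$weight)) edges$weight <- 1
    a <- pmin(as.character(edges$from), as.character(edges$to))
    b <- pmax(as.character(edges$from), as.character(edges$to))
    if (any(a == b)) stop("self-loops are not allowed")
    edges <- data.frame(from = a, to = b, weight = edges$weight,
                        stringsAsFactors = FALSE)
    edges <- edges[!duplicated(paste(a, b, sep = "\r")), , drop = FALSE]
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes$degree <- as.integer(
    tabulate(factor(c(edges$from, edges$to), levels = nodes$gene),
             nbins = nrow(nodes)))
  rownames(nodes) <- NULL
  new("GeneNetwork", nodes = nodes[, c("gene", "isTF", "cluster", "degree")],
      edges = edges)
}

#' Per-cell cluster labels with differential-expression tables
#'
#' @slot labels factor of cluster labels, named by cell identifier.
#' @slot degTables named list of per-comparison data.frames with columns
#'   \code{gene}, \code{lnFC}, \code{p}, \code{fdr}, \code{pctIn},
#'   \code{pctOut}, \code{significant}.
#' @export
setClass("ClusterResult",
  slots = c(labels = "factor", degTables = "list"))

setValidity("ClusterResult", function(object) {
  msg <- character()
  if (is.null(names(object@labels)) || anyDuplicated(names(object@labels)))
    msg <- c(msg, "'labels' must be uniquely named by cell")
  if (anyNA(object@labels)) msg <- c(msg, "every cell must have a label")
  for (nm in names(object@degTables)) {
    tab <- object@degTables[[nm]]
    if (!all(c("gene", "lnFC", "p", "fdr") %in% names(tab))) {
      msg <- c(msg, sprintf("table '%s' lacks required columns", nm)); next
    }
    if (any(tab$fdr < 0 | tab$fdr > 1, na.rm = TRUE))
      msg <- c(msg, sprintf("table '%s': fdr outside [0, 1]", nm))
    o <- order(tab$p)
    if (is.unsorted(tab$fdr[o]))
      msg <- c(msg, sprintf("table '%s': fdr not monotone in p", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Differential-expression thresholds
#'
#' @slot fdrCut Benjamini-Hochberg FDR cutoff (default 0.05).
#' @slot lnfcCut natural-log fold-change cutoff (default 0.5).
#' @slot minPct minimum fraction of in-group cells expressing the gene.
#' @export
setClass("DEParams",
  slots = c(fdrCut = "numeric", lnfcCut = "numeric", minPct = "numeric"))

#' Construct DE thresholds
#' @param fdrCut,lnfcCut,minPct see \linkS4class{DEParams}.
#' @return A \linkS4class{DEParams}.
#' @export
deParams <- function(fdrCut = 0.05, lnfcCut = 0.5, minPct = 0) {
  stopifnot(fdrCut >= 0, fdrCut <= 1, lnfcCut >= 0, minPct >= 0, minPct <= 1)
  new("DEParams", fdrCut = fdrCut, lnfcCut = lnfcCut, minPct = minPct)
}

#' Coexpression-network construction parameters
#'
#' @slot corrThreshold absolute Pearson correlation an edge must exceed
#'   (default 0.8).
#' @slot sigAlpha BH-adjusted correlation-test significance level.
#' @slot minComponent smallest connected component retained in
#'   cluster-specific subnetworks (default 3 nodes).
#' @slot degPct fraction of cluster cells that must express a DEG for it to
#'   enter a cluster subnetwork (default 0.5).
#' @slot tfNeighborFrac fraction of a TF's neighbours that must be cluster
#'   DEGs for the TF to be attached to the cluster (default 0.2).
#' @export
setClass("GRNParams",
  slots = c(corrThreshold = "numeric", sigAlpha = "numeric",
            minComponent = "numeric", degPct = "numeric",
            tfNeighborFrac = "numeric"))

#' Construct network parameters
#' @param corrThreshold,sigAlpha,minComponent,degPct,tfNeighborFrac see
#'   \linkS4class{GRNParams}.
#' @return A \linkS4class{GRNParams}.
#' @export
grnParams <- function(corrThreshold = 0.8, sigAlpha = 0.05, minComponent = 3,
                      degPct = 0.5, tfNeighborFrac = 0.2) {
  stopifnot(corrThreshold >= 0, corrThreshold <= 1, sigAlpha > 0,
            sigAlpha <= 1, minComponent >= 1, degPct >= 0, degPct <= 1,
            tfNeighborFrac >= 0, tfNeighborFrac <= 1)
  new("GRNParams", corrThreshold = corrThreshold, sigAlpha = sigAlpha,
      minComponent = minComponent, degPct = degPct,
      tfNeighborFrac = tfNeighborFrac)
}

#' Result of a permutation-based network enrichment test
#'
#' @slot observed observed connectivity statistic.
#' @slot nullMean,nullSD moments of the permutation null.
#' @slot z standardised statistic (NA when the null is degenerate).
#' @slot p add-one empirical p-value, \eqn{(1 + \#\{null \ge obs\})/(1 + B)}.
#' @slot nPerm number of permutations.
#' @slot seed RNG seed used.
#' @slot zDefined FALSE when the permutation null had zero spread.
#' @export
setClass("EnrichmentResult",
  slots = c(observed = "numeric", nullMean = "numeric", nullSD = "numeric",
            z = "numeric", p = "numeric", nPerm = "numeric", seed = "numeric",
            zDefined = "logical"))

setValidity("EnrichmentResult", function(object) {
  if (object@p <= 0 || object@p > 1) "empirical p must lie in (0, 1]" else TRUE
})

#' Cell-type marker sets
#'
#' Marker sets are pairwise disjoint: a gene claimed by more than one type is
#' dropped from all of them.
#'
#' @slot sets named list (one character vector of marker genes per cell type).
#' @slot provenance data.frame with columns \code{type}, \code{gene},
#'   \code{source}.
#' @export
setClass("MarkerTable",
  slots = c(sets = "list", provenance = "data.frame"))

setValidity("MarkerTable", function(object) {
  all.genes <- unlist(object@sets, use.names = FALSE)
  if (anyDuplicated(all.genes))
    "marker sets must be pairwise disjoint" else TRUE
})

#' Configuration of the paired pre/post-capture simulator
#'
#' See \code{\link{simulationConfig}} for the meaning and defaults of each
#' parameter.
#'
#' @export
setClass("SimulationConfig",
  slots = c(nCells = "numeric", nGenes = "numeric", nPanel = "numeric",
            nClusters = "numeric", branchParent = "numeric",
            baseMean = "numeric", dispersion = "numeric",
            programFc = "numeric", programOnset = "numeric",
            antagonism = "numeric",
            nTFsPerProgram = "numeric", nTargetsPerProgram = "numeric",
            targetMeanFactor = "numeric", panelMeanFactor = "numeric",
            rarePanelFraction = "numeric", rarePanelMean = "numeric",
            nMaturationGenes = "numeric", enrichmentFactor = "numeric",
            postDepthRatio = "numeric", nSpikes = "numeric",
            nSpikesOnPanel = "numeric", spikeMean = "numeric",
            dropoutIntercept = "numeric", dropoutSlope = "numeric",
            tSplit = "numeric", seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nPanel > object@nGenes) msg <- c(msg, "nPanel must be <= nGenes")
  if (object@nSpikesOnPanel > object@nSpikes)
    msg <- c(msg, "nSpikesOnPanel must be <= nSpikes")
  if (object@enrichmentFactor < 1)
    msg <- c(msg, "enrichmentFactor must be >= 1")
  if (object@postDepthRatio <= 0)
    msg <- c(msg, "postDepthRatio must be positive")
  if (length(object@branchParent) != object@nClusters)
    msg <- c(msg, "branchParent must have one entry per cluster")
  if (sum(object@branchParent == 0) != 1)
    msg <- c(msg, "exactly one cluster must be the root (parent 0)")
  need <- object@nClusters * (object@nTFsPerProgram)
  if (need > object@nPanel)
    msg <- c(msg, "program TFs exceed panel size")
  need <- object@nClusters * object@nTargetsPerProgram +
    object@nMaturationGenes
  if (need > object@nGenes - object@nPanel)
    msg <- c(msg, "program targets and maturation genes exceed background genes")
  if (object@tSplit <= 0 || object@tSplit >= 1)
    msg <- c(msg, "tSplit must lie strictly inside (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated paired pre/post-capture experiment
#'
#' @slot clusterOfCell integer cluster index per cell (named).
#' @slot latentTime latent trajectory position per cell in [0, 1] (named).
#' @slot trueEdges data.frame of true regulator-target pairs with columns
#'   \code{tf}, \code{target}, \code{program}.
#' @slot enrichmentFactor the configured on-target probability multiplier.
#' @slot expectedExpression genes x cells matrix of pre-capture expected
#'   expression (negative-binomial means before zero inflation).
#' @slot branchParent parent cluster per cluster (0 for the root).
#' @slot config the \linkS4class{SimulationConfig} used.
#' @export
setClass("SimTruth",
  slots = c(clusterOfCell = "integer", latentTime = "numeric",
            trueEdges = "data.frame", enrichmentFactor = "numeric",
            expectedExpression = "matrix", branchParent = "numeric",
            config = "SimulationConfig"))

setValidity("SimTruth", function(object) {
  msg <- character()
  if (length(object@clusterOfCell) != length(object@latentTime))
    msg <- c(msg, "clusterOfCell and latentTime lengths differ")
  if (any(object@latentTime < 0 | object@latentTime > 1))
    msg <- c(msg, "latentTime must lie in [0, 1]")
  root <- which(object@branchParent == 0)
  if (length(root) == 1L && any(object@clusterOfCell == root)) {
    tRoot <- mean(object@latentTime[object@clusterOfCell == root])
    for (k in seq_along(object@branchParent)[-root])
      if (any(object@clusterOfCell == k) &&
          mean(object@latentTime[object@clusterOfCell == k]) < tRoot) {
        msg <- c(msg, "root cells must be earliest on latent time"); break
      }
  }
  if (length(msg)) msg else TRUE
})

#' Per-cell capture-performance report
#'
#' @slot perCell data.frame with per-cell on-target fractions and detected
#'   panel-gene counts, pre and post.
#' @slot perGene data.frame with per-gene mean CPMs and log2 enrichment.
#' @slot summary list of scalar summaries (medians, expressed panel genes
#'   pre/post, detected fold change, mean-expression correlation).
#' @export
setClass("CaptureReport",
  slots = c(perCell = "data.frame", perGene = "data.frame",
            summary = "list"))

#' Diffusion-map trajectory with MST lineages
#'
#' @slot coordinates cells x components matrix of diffusion coordinates.
#' @slot clusterCenters cluster centroids in diffusion space.
#' @slot mstEdges data.frame of minimum-spanning-tree edges over centroids.
#' @slot lineages list of root-to-leaf cluster paths.
#' @slot pseudotimeMatrix cells x lineages matrix of projection pseudotimes,
#'   each normalised to [0, 1] along its lineage.
#' @slot weights cells x lineages 0/1 assignment weights (nearest path).
#' @slot pseudotime consensus pseudotime (value of the assigned lineage).
#' @slot rootCluster the designated start cluster.
#' @export
setClass("TrajectoryResult",
  slots = c(coordinates = "matrix", clusterCenters = "matrix",
            mstEdges = "data.frame", lineages = "list",
            pseudotimeMatrix = "matrix", weights = "matrix",
            pseudotime = "numeric", rootCluster = "character"))
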