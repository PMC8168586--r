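# Accessors and show methods for the package's S4 classes.

#' @rdname CapturePanel-class
#' @param object,x a \linkS4class{CapturePanel}.
#' @export
setGeneric("targetGenes", function(x) standardGeneric("targetGenes"))

#' @rdname CapturePanel-class
#' @export
setMethod("targetGenes", "CapturePanel", function(x) x@targetGenes)

#' @rdname CapturePanel-class
#' @export
setGeneric("spikeIds", function(x) standardGeneric("spikeIds"))

#' @rdname CapturePanel-class
#' @export
setMethod("spikeIds", "CapturePanel", function(x) x@spikeIds)

#' @rdname CapturePanel-class
#' @export
setGeneric("spikesOnPanel", function(x) standardGeneric("spikesOnPanel"))

#' @rdname CapturePanel-class
#' @export
setMethod("spikesOnPanel", "CapturePanel", function(x) x@spikesOnPanel)

setMethod("show", "CapturePanel", function(object) {
  cat("CapturePanel:", length(object@targetGenes), "target genes,",
      length(object@spikeIds), "spike-ins (",
      length(object@spikesOnPanel), "on panel )\n")
})

#' @rdname GeneNetwork-class
#' @param x,object a \linkS4class{GeneNetwork}.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname GeneNetwork-class
#' @export
setMethod("networkNodes", "GeneNetwork", function(x) x@nodes)

#' @rdname GeneNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname GeneNetwork-class
#' @export
setMethod("networkEdges", "GeneNetwork", function(x) x@edges)

#' @rdname GeneNetwork-class
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname GeneNetwork-class
#' @export
setMethod("numNodes", "GeneNetwork", function(x) nrow(x@nodes))

#' @rdname GeneNetwork-class
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname GeneNetwork-class
#' @export
setMethod("numEdges", "GeneNetwork", function(x) nrow(x@edges))

setMethod("show", "GeneNetwork", function(object) {
  cat("GeneNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges;",
      sum(object@nodes$isTF), "TF nodes,",
      sum(!is.na(object@nodes$cluster)), "cluster-assigned\n")
})

#' Convert a GeneNetwork to an igraph graph
#'
#' @param x a \linkS4class{GeneNetwork}.
#' @return An undirected \code{igraph} graph with node attributes
#'   \code{isTF}, \code{cluster} and edge attribute \code{weight}.
#' @export
asIgraph <- function(x) {
  stopifnot(is(x, "GeneNetwork"))
  igraph::graph_from_data_frame(
    x@edges, directed = FALSE,
    vertices = x@nodes[, c("gene", "isTF", "cluster")])
}

#' @rdname ClusterResult-class
#' @param x,object a \linkS4class{ClusterResult}.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname ClusterResult-class
#' @export
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

#' @rdname ClusterResult-class
#' @export
setGeneric("degTables", function(x) standardGeneric("degTables"))

#' @rdname ClusterResult-class
#' @export
setMethod("degTables", "ClusterResult", function(x) x@degTables)

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", length(object@labels), "cells in",
      nlevels(object@labels), "clusters;",
      length(object@degTables), "DE tables\n")
})

#' @rdname SimTruth-class
#' @param x,object a \linkS4class{SimTruth}.
#' @export
setGeneric("trueEdges", function(x) standardGeneric("trueEdges"))

#' @rdname SimTruth-class
#' @export
setMethod("trueEdges", "SimTruth", function(x) x@trueEdges)

#' @rdname SimTruth-class
#' @export
setGeneric("latentTime", function(x) standardGeneric("latentTime"))

#' @rdname SimTruth-class
#' @export
setMethod("latentTime", "SimTruth", function(x) x@latentTime)

#' @rdname SimTruth-class
#' @export
setGeneric("clusterOfCell", function(x) standardGeneric("clusterOfCell"))

#' @rdname SimTruth-class
#' @export
setMethod("clusterOfCell", "SimTruth", function(x) x@clusterOfCell)

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@clusterOfCell), "cells,",
      length(unique(object@clusterOfCell)), "clusters,",
      nrow(object@trueEdges), "true regulator-target edges, E =",
      object@enrichmentFactor, "\n")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf(
    "EnrichmentResult: observed %g, null %.2f +/- %.2f, z = %s, p = %.4g (%d permutations)\n",
    object@observed, object@nullMean, object@nullSD,
    if (object@zDefined) sprintf("%.2f", object@z) else "undefined",
    object@p, as.integer(object@nPerm)))
})

#' @rdname MarkerTable-class
#' @param x,object a \linkS4class{MarkerTable}.
#' @export
setGeneric("markerSets", function(x) standardGeneric("markerSets"))

#' @rdname MarkerTable-class
#' @export
setMethod("markerSets", "MarkerTable", function(x) x@sets)

setMethod("show", "MarkerTable", function(object) {
  cat("MarkerTable:", length(object@sets), "cell types,",
      length(unlist(object@sets)), "unique markers\n")
})

setMethod("show", "CaptureReport", function(object) {
  s <- object@summary
  cat("CaptureReport over", nrow(object@perCell), "cells\n")
  cat(sprintf("  median on-target fraction: %.4f pre, %.4f post\n",
              s$medianOnTargetPre, s$medianOnTargetPost))
  cat(sprintf("  expressed panel genes: %d pre, %d post\n",
              s$nExpressedPanelPre, s$nExpressedPanelPost))
  cat(sprintf("  median detected panel genes per cell: %g pre, %g post (fold %.2f)\n",
              s$medianDetectedPre, s$medianDetectedPost, s$detectedFoldChange))
  cat(sprintf("  pre/post mean-expression correlation r = %.3f\n",
              s$meanExpressionCorrelation))
})

#' @rdname TrajectoryResult-class
#' @param x,object a \linkS4class{TrajectoryResult}.
#' @export
setGeneric("pseudotime", function(x) standardGeneric("pseudotime"))

#' @rdname TrajectoryResult-class
#' @export
setMethod("pseudotime", "TrajectoryResult", function(x) x@pseudotime)

#' @rdname TrajectoryResult-class
#' @export
setGeneric("lineages", function(x) standardGeneric("lineages"))

#' @rdname TrajectoryResult-class
#' @export
setMethod("lineages", "TrajectoryResult", function(x) x@lineages)

setMethod("show", "TrajectoryResult", function(object) {
  cat("TrajectoryResult:", nrow(object@coordinates), "cells,",
      length(object@lineages), "lineage(s) from root cluster",
      object@rootCluster, "\n")
})
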