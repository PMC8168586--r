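# Coexpression network construction, capture imputation, and
# cluster-specific subnetwork extraction.

#' Impute post-capture panel expression into the pre-capture transcriptome
#'
#' Extends the pre-capture matrix by the panel genes expressed post-capture,
#' rescaling each cell's post-capture counts by the ratio of that cell's
#' pre- to post-capture library size (per-cell rescaling preserves
#' within-cell composition). Panel-gene rows are replaced by the rescaled
#' post-capture values — post-capture is strictly more sensitive for panel
#' genes — while non-panel rows are untouched. Panel genes absent from the
#' pre-capture matrix but expressed post-capture are appended as new rows.
#'
#' @param pre,post matched count \code{SingleCellExperiment}s over the same
#'   cells, in the same order.
#' @param panel a \linkS4class{CapturePanel}.
#' @return A count \code{SingleCellExperiment} over
#'   \code{rownames(pre)} plus the post-capture-expressed panel genes; the
#'   imputed values are rescaled (non-integer) counts.
#' @export
imputeCapture <- function(pre, post, panel) {
  if (!identical(colnames(pre), colnames(post)))
    stop("pre and post matrices must contain the same cells in the same order")
  cPre <- as.matrix(SummarizedExperiment::assay(pre, "counts"))
  cPost <- as.matrix(SummarizedExperiment::assay(post, "counts"))
  preLib <- colSums(cPre)
  postLib <- colSums(cPost)
  if (any(postLib == 0)) stop("post-capture library size is zero for cell(s) ",
                              paste(colnames(post)[postLib == 0], collapse = ", "))
  panelInPost <- intersect(targetGenes(panel), rownames(cPost))
  expressed <- panelInPost[rowMeans(cPost[panelInPost, , drop = FALSE]) > 0]
  outGenes <- union(rownames(cPre), expressed)
  out <- matrix(0, length(outGenes), ncol(cPre),
                dimnames = list(outGenes, colnames(cPre)))
  out[rownames(cPre), ] <- cPre
  replaceGenes <- intersect(targetGenes(panel), outGenes)
  replaceGenes <- intersect(replaceGenes, rownames(cPost))
  out[replaceGenes, ] <- sweep(cPost[replaceGenes, , drop = FALSE], 2L,
                               preLib / postLib, "*")
  geneMeta <- data.frame(
    is_panel = outGenes %in% targetGenes(panel),
    is_spike = outGenes %in% spikeIds(panel))
  makeCountMatrix(out, geneMeta,
                  as.data.frame(SummarizedExperiment::colData(pre)))
}

#' Build a coexpression network
#'
#' An edge joins two genes when the absolute Pearson correlation of their
#' log-normalised expression across cells exceeds \code{corrThreshold}
#' (default 0.8) and the BH-adjusted two-sided correlation-test p-value is
#' at most \code{sigAlpha}. Zero-variance genes are excluded and recorded
#' in the \code{"excluded"} attribute. Edge weights are the signed
#' correlations; isolated genes remain as nodes.
#'
#' @param x normalised \code{SingleCellExperiment} (assay
#'   \code{"logcounts"}) or a genes x cells log-expression matrix.
#' @param params a \linkS4class{GRNParams}.
#' @param genes optional gene subset.
#' @return A \linkS4class{GeneNetwork}; TF flags come from the
#'   \code{is_panel} column of \code{rowData(x)} when available.
#' @export
buildNetwork <- function(x, params = grnParams(), genes = NULL) {
  logc <- logcountsOf(x)
  if (ncol(logc) < 3L) stop("need at least three cells")
  isTF <- if (is.matrix(x)) rep(FALSE, nrow(logc)) else
    SummarizedExperiment::rowData(x)$is_panel
  names(isTF) <- rownames(logc)
  if (!is.null(genes)) logc <- logc[intersect(genes, rownames(logc)), ,
                                    drop = FALSE]
  sds <- apply(logc, 1L, sd)
  excluded <- rownames(logc)[sds == 0]
  logc <- logc[sds > 0, , drop = FALSE]
  if (nrow(logc) == 0L) {
    warning("no genes left after the variance filter; empty network")
    net <- geneNetwork(character(0))
    attr(net, "excluded") <- excluded
    return(net)
  }
  n <- ncol(logc)
  r <- cor(t(logc))
  ut <- upper.tri(r)
  rv <- r[ut]
  tstat <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  padj <- p.adjust(p, method = "BH")
  sel <- abs(rv) > params@corrThreshold & padj <= params@sigAlpha
  idx <- which(ut, arr.ind = TRUE)[sel, , drop = FALSE]
  edges <- data.frame(from = rownames(logc)[idx[, 1L]],
                      to = rownames(logc)[idx[, 2L]],
                      weight = rv[sel], stringsAsFactors = FALSE)
  nodes <- data.frame(gene = rownames(logc),
                      isTF = unname(isTF[rownames(logc)]) %in% TRUE,
                      stringsAsFactors = FALSE)
  net <- geneNetwork(nodes, edges)
  attr(net, "excluded") <- excluded
  net
}

upRegulatedClaims <- function(degTabs, degPct, fdrCut) {
  # (gene, cluster, lnFC) claims from one-vs-rest and pairwise tables
  claims <- list()
  for (nm in names(degTabs)) {
    tab <- degTabs[[nm]]
    if (grepl("_vs_rest$", nm)) {
      cl <- sub("_vs_rest$", "", nm)
      up <- tab$fdr <= fdrCut & tab$lnFC > 0 & tab$pctIn >= degPct
      if (any(up))
        claims[[length(claims) + 1L]] <- data.frame(
          gene = tab$gene[up], cluster = cl, lnFC = tab$lnFC[up])
    } else if (grepl("_vs_", nm)) {
      ab <- strsplit(nm, "_vs_", fixed = TRUE)[[1L]]
      upA <- tab$fdr <= fdrCut & tab$lnFC > 0 & tab$pctIn >= degPct
      upB <- tab$fdr <= fdrCut & tab$lnFC < 0 & tab$pctOut >= degPct
      if (any(upA))
        claims[[length(claims) + 1L]] <- data.frame(
          gene = tab$gene[upA], cluster = ab[1L], lnFC = tab$lnFC[upA])
      if (any(upB))
        claims[[length(claims) + 1L]] <- data.frame(
          gene = tab$gene[upB], cluster = ab[2L], lnFC = -tab$lnFC[upB])
    }
  }
  if (!length(claims)) return(NULL)
  do.call(rbind, claims)
}

#' Extract cluster-specific subnetworks
#'
#' Candidate genes are the up-regulated DEGs (FDR at most \code{fdrCut},
#' expressed in at least \code{degPct} of the cluster's cells) from any
#' one-vs-rest or pairwise comparison; genes significant for several
#' clusters are assigned to the cluster with the highest ln fold change.
#' Unassigned TF nodes are attached to a cluster when at least
#' \code{tfNeighborFrac} of their network neighbours belong to that
#' cluster's DEG set (the best-supported cluster wins). The induced
#' subgraph on assigned nodes is taken and connected components with fewer
#' than \code{minComponent} nodes are dropped.
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @param clusters a \linkS4class{ClusterResult} with DE tables, or a named
#'   list of DE tables.
#' @param params a \linkS4class{GRNParams}.
#' @param fdrCut FDR cutoff for the DEG rule (default 0.05).
#' @return A \linkS4class{GeneNetwork} restricted to the retained nodes,
#'   with the \code{cluster} node attribute set. May be empty.
#' @export
clusterSubnetworks <- function(net, clusters, params = grnParams(),
                               fdrCut = 0.05) {
  degTabs <- if (is(clusters, "ClusterResult")) degTables(clusters)
             else clusters
  claims <- upRegulatedClaims(degTabs, params@degPct, fdrCut)
  nodes <- networkNodes(net)
  assignment <- setNames(rep(NA_character_, nrow(nodes)), nodes$gene)
  degSets <- list()
  if (!is.null(claims)) {
    best <- claims[order(claims$gene, -claims$lnFC), ]
    best <- best[!duplicated(best$gene), ]
    hit <- best$gene %in% nodes$gene
    assignment[best$gene[hit]] <- best$cluster[hit]
    degSets <- split(best$gene, best$cluster)
  }
  # attach TFs by neighbourhood composition
  edges <- networkEdges(net)
  if (nrow(edges) && length(degSets)) {
    adj <- rbind(data.frame(a = edges$from, b = edges$to),
                 data.frame(a = edges$to, b = edges$from))
    nb <- split(adj$b, adj$a)
    tfFree <- nodes$gene[nodes$isTF & is.na(assignment[nodes$gene])]
    for (g in intersect(tfFree, names(nb))) {
      fr <- vapply(degSets, function(s)
        mean(nb[[g]] %in% s), numeric(1))
      if (max(fr) >= params@tfNeighborFrac)
        assignment[g] <- names(degSets)[which.max(fr)]
    }
  }
  keep <- names(assignment)[!is.na(assignment)]
  sub <- induceSubnetwork(net, keep)
  sub@nodes$cluster <- unname(assignment[sub@nodes$gene])
  # drop small components
  if (numNodes(sub)) {
    g <- asIgraph(sub)
    comp <- igraph::components(g)
    big <- names(comp$membership)[comp$csize[comp$membership] >=
                                    params@minComponent]
    sub <- induceSubnetwork(sub, big)
  }
  methods::validObject(sub)
  sub
}

induceSubnetwork <- function(net, genes) {
  nodes <- networkNodes(net)
  nodes <- nodes[nodes$gene %in% genes, , drop = FALSE]
  edges <- networkEdges(net)
  edges <- edges[edges$from %in% genes & edges$to %in% genes, , drop = FALSE]
  geneNetwork(nodes, edges)
}

#' Node degrees and their distribution
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @return List with \code{perNode} (gene, degree), \code{histogram}
#'   (a table over observed degrees) and \code{quantiles}.
#' @export
degreeDistribution <- function(net) {
  nodes <- networkNodes(net)
  list(perNode = nodes[, c("gene", "degree")],
       histogram = table(degree = nodes$degree),
       quantiles = if (nrow(nodes)) quantile(nodes$degree) else numeric())
}
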