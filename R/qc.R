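# Cell/gene quality control and capture-performance metrics.

cellQCTable <- function(x, panel, th) {
  counts <- SummarizedExperiment::assay(x, "counts")
  spike <- rownames(x) %in% spikeIds(panel) |
    SummarizedExperiment::rowData(x)$is_spike
  lib <- Matrix::colSums(counts)
  nGenes <- Matrix::colSums(counts[!spike, , drop = FALSE] > 0)
  # complexity: fraction of counts in the cell's 200 most expressed genes
  # (ties at the boundary do not change the sum)
  dense <- as.matrix(counts)
  top200 <- apply(dense, 2L, function(v)
    sum(sort(v, decreasing = TRUE)[seq_len(min(200L, length(v)))]))
  top200Frac <- ifelse(lib > 0, top200 / lib, NA_real_)
  spikeFrac <- ifelse(lib > 0,
                      Matrix::colSums(counts[spike, , drop = FALSE]) / lib,
                      NA_real_)
  data.frame(
    cell = colnames(x),
    nGenesDetected = as.integer(nGenes),
    librarySize = lib,
    top200Fraction = top200Frac,
    spikeFraction = spikeFrac,
    passGenes = nGenes >= th@minGenesPerCell,
    passLibrary = lib >= th@minLibrarySize,
    passComplexity = !is.na(top200Frac) & top200Frac <= th@maxTop200Fraction,
    passSpike = !is.na(spikeFrac) & spikeFrac <= th@maxSpikeFraction,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter low-quality cells
#'
#' Applies the four cell rules, evaluated on the pre-capture matrix: a cell
#' is removed when it expresses fewer than \code{minGenesPerCell} genes, has
#' a library below \code{minLibrarySize} counts, has low complexity (its 200
#' most expressed genes hold strictly more than \code{maxTop200Fraction} of
#' counts), or has low endogenous RNA (spike-ins hold strictly more than
#' \code{maxSpikeFraction} of counts). The surviving cell set should then be
#' applied unchanged to the matched post-capture matrix.
#'
#' @param x pre-capture count \code{SingleCellExperiment}.
#' @param panel a \linkS4class{CapturePanel} (identifies spike-in rows).
#' @param th a \linkS4class{QCThresholds}.
#' @return List with \code{counts} (the filtered matrix, library sizes
#'   refreshed), \code{qc} (per-cell rule values and pass flags) and
#'   \code{cells} (surviving cell identifiers).
#' @export
filterCells <- function(x, panel, th = qcThresholds()) {
  qc <- cellQCTable(x, panel, th)
  qc$pass <- qc$passGenes & qc$passLibrary & qc$passComplexity & qc$passSpike
  if (!any(qc$pass)) stop("no cells passed quality control")
  keep <- qc$cell[qc$pass]
  list(counts = updateLibrarySizes(x[, keep]), qc = qc, cells = keep)
}

#' Filter lowly expressed genes
#'
#' Retains genes whose mean count across cells is strictly greater than
#' \code{minGeneMeanCount} (default 1); order is preserved. Expected to run
#' after cell filtering.
#'
#' @param x count \code{SingleCellExperiment}.
#' @param th a \linkS4class{QCThresholds}.
#' @return The filtered \code{SingleCellExperiment}.
#' @export
filterGenes <- function(x, th = qcThresholds()) {
  means <- Matrix::rowMeans(SummarizedExperiment::assay(x, "counts"))
  updateLibrarySizes(x[means > th@minGeneMeanCount, ])
}

#' Per-cell on-target read fraction
#'
#' Sum of counts on panel genes divided by the cell's library size (all
#' counts, spike-ins included in the denominator but never the numerator).
#' Cells with empty libraries get \code{NA}.
#'
#' @param x count \code{SingleCellExperiment}.
#' @param panel a \linkS4class{CapturePanel}.
#' @return List with \code{perCell} (named fractions) and \code{median}
#'   (over cells with non-empty libraries).
#' @export
onTargetFraction <- function(x, panel) {
  if (ncol(x) == 0L) stop("no cells")
  counts <- SummarizedExperiment::assay(x, "counts")
  onPanel <- rownames(x) %in% targetGenes(panel)
  lib <- Matrix::colSums(counts)
  frac <- ifelse(lib > 0,
                 Matrix::colSums(counts[onPanel, , drop = FALSE]) / lib,
                 NA_real_)
  names(frac) <- colnames(x)
  list(perCell = frac, median = median(frac, na.rm = TRUE))
}

meanCpm <- function(x) {
  counts <- SummarizedExperiment::assay(x, "counts")
  lib <- Matrix::colSums(counts)
  if (any(lib == 0))
    counts <- counts[, lib > 0, drop = FALSE]
  Matrix::rowMeans(sweep(as.matrix(counts), 2L, lib[lib > 0], "/") * 1e6)
}

#' Genewise post/pre capture enrichment
#'
#' For each gene, \code{log2((mean post CPM + 1) / (mean pre CPM + 1))},
#' with CPM computed against each cell's library size.
#'
#' @param pre,post matched count \code{SingleCellExperiment}s over the same
#'   genes and cells.
#' @return Named numeric vector of log2 enrichments.
#' @export
genewiseEnrichment <- function(pre, post) {
  if (!identical(rownames(pre), rownames(post)))
    stop("pre and post matrices must share the same gene universe")
  if (!identical(colnames(pre), colnames(post)))
    stop("pre and post matrices must share the same cells")
  log2((meanCpm(post) + 1) / (meanCpm(pre) + 1))
}

#' Summarise capture performance
#'
#' Computes the per-cell on-target fractions and detected panel-gene counts
#' for both libraries, the per-gene log2 enrichment, the number of panel
#' genes expressed (non-zero mean count) pre and post on the shared gene
#' universe, and the Pearson correlation of panel-gene
#' \code{log2(mean CPM + 1)} between libraries.
#'
#' @param pre,post matched count \code{SingleCellExperiment}s.
#' @param panel a \linkS4class{CapturePanel}.
#' @return A \linkS4class{CaptureReport}.
#' @export
captureSummary <- function(pre, post, panel) {
  if (!identical(rownames(pre), rownames(post)) ||
      !identical(colnames(pre), colnames(post)))
    stop("pre and post matrices must be aligned on genes and cells")
  onPanel <- rownames(pre) %in% targetGenes(panel)
  cPre <- SummarizedExperiment::assay(pre, "counts")
  cPost <- SummarizedExperiment::assay(post, "counts")
  detPre <- Matrix::colSums(cPre[onPanel, , drop = FALSE] > 0)
  detPost <- Matrix::colSums(cPost[onPanel, , drop = FALSE] > 0)
  otPre <- onTargetFraction(pre, panel)
  otPost <- onTargetFraction(post, panel)
  perCell <- data.frame(
    cell = colnames(pre),
    onTargetPre = otPre$perCell, onTargetPost = otPost$perCell,
    detectedPanelPre = as.integer(detPre),
    detectedPanelPost = as.integer(detPost),
    row.names = NULL)
  enr <- genewiseEnrichment(pre, post)
  cpmPre <- meanCpm(pre); cpmPost <- meanCpm(post)
  perGene <- data.frame(
    gene = rownames(pre), isPanel = onPanel,
    meanCpmPre = cpmPre, meanCpmPost = cpmPost, log2Enrichment = enr,
    row.names = NULL)
  mPre <- Matrix::rowMeans(cPre)[onPanel]
  mPost <- Matrix::rowMeans(cPost)[onPanel]
  either <- mPre > 0 | mPost > 0
  r <- if (sum(either) >= 3)
    cor(log2(cpmPre[onPanel][either] + 1), log2(cpmPost[onPanel][either] + 1))
  else NA_real_
  medPre <- median(detPre); medPost <- median(detPost)
  summary <- list(
    medianOnTargetPre = otPre$median, medianOnTargetPost = otPost$median,
    nExpressedPanelPre = sum(mPre > 0), nExpressedPanelPost = sum(mPost > 0),
    medianDetectedPre = medPre, medianDetectedPost = medPost,
    detectedFoldChange = if (medPre > 0) medPost / medPre else NA_real_,
    medianPanelLog2Enrichment = median(enr[onPanel]),
    meanExpressionCorrelation = r)
  new("CaptureReport", perCell = perCell, perGene = perGene,
      summary = summary)
}
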