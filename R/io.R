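# Readers and writers: sparse/dense count matrices, GMT gene sets, networks.

#' Assemble a count matrix container
#'
#' Builds the \linkS4class{SingleCellExperiment} used as the unit of exchange
#' throughout the package: integer (or rescaled numeric) counts in the
#' \code{"counts"} assay, per-gene flags \code{is_panel} / \code{is_spike}
#' in \code{rowData}, and per-cell library sizes in \code{colData}.
#'
#' @param counts genes x cells matrix (dense or \code{dgCMatrix}) with
#'   unique row and column names.
#' @param geneMeta optional data.frame of per-gene columns.
#' @param cellMeta optional data.frame of per-cell columns.
#' @return A \code{SingleCellExperiment}.
#' @export
makeCountMatrix <- function(counts, geneMeta = NULL, cellMeta = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and cell column names")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell identifiers")
  if (min(counts) < 0) stop("counts must be non-negative")
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  rd <- S4Vectors::DataFrame(row.names = rownames(counts))
  if (!is.null(geneMeta)) {
    if (nrow(geneMeta) != nrow(counts))
      stop("gene annotation length does not match matrix dimension")
    for (nm in setdiff(names(geneMeta), "gene_id")) rd[[nm]] <- geneMeta[[nm]]
  }
  if (is.null(rd$is_panel)) rd$is_panel <- FALSE
  if (is.null(rd$is_spike)) rd$is_spike <- FALSE
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(cellMeta)) {
    if (nrow(cellMeta) != ncol(counts))
      stop("cell annotation length does not match matrix dimension")
    for (nm in setdiff(names(cellMeta), "cell_id")) cd[[nm]] <- cellMeta[[nm]]
  }
  cd$librarySize <- Matrix::colSums(counts)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd)
}

#' Recompute per-cell library sizes
#'
#' Library size must equal the column sum of counts; call after any
#' subsetting.
#'
#' @param x a count \code{SingleCellExperiment}.
#' @return \code{x} with \code{colData(x)$librarySize} refreshed.
#' @export
updateLibrarySizes <- function(x) {
  SummarizedExperiment::colData(x)$librarySize <-
    Matrix::colSums(SummarizedExperiment::assay(x, "counts"))
  x
}

companionPaths <- function(path) {
  stem <- sub("\\.mtx$", "", path)
  list(genes = paste0(stem, ".genes.tsv"), cells = paste0(stem, ".cells.tsv"))
}

#' Read a gene x cell count matrix
#'
#' Two plain-text layouts are supported. \code{"mtx_triplet"}: a Matrix
#' Market coordinate file (1-based indices, genes as rows) with adjacent
#' companion annotation files \code{<stem>.genes.tsv} and
#' \code{<stem>.cells.tsv} (10x-style; first column holds the identifier,
#' remaining columns become row/column metadata). \code{"dense_tsv"}: a
#' tab-separated genes x cells table whose header row holds cell identifiers
#' and whose first column holds gene identifiers.
#'
#' @param path path to the \code{.mtx} or \code{.tsv} file.
#' @param format \code{"mtx_triplet"} or \code{"dense_tsv"}.
#' @return A count \code{SingleCellExperiment}; round-trips bit-exactly with
#'   \code{\link{writeCounts}}.
#' @export
readCounts <- function(path, format = c("mtx_triplet", "dense_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx_triplet") {
    cp <- companionPaths(path)
    if (!file.exists(cp$genes) || !file.exists(cp$cells))
      stop("companion gene/cell TSVs not found next to ", path)
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed Matrix Market file '",
                                           path, "': ", conditionMessage(e)))
    gn <- read.delim(cp$genes, stringsAsFactors = FALSE)
    cn <- read.delim(cp$cells, stringsAsFactors = FALSE)
    if (nrow(gn) != nrow(m))
      stop("dimension mismatch: ", nrow(gn), " annotated genes vs ",
           nrow(m), " matrix rows")
    if (nrow(cn) != ncol(m))
      stop("dimension mismatch: ", nrow(cn), " annotated cells vs ",
           ncol(m), " matrix columns")
    if (min(m) < 0) {
      lines <- readLines(path)
      body <- which(!startsWith(lines, "%"))[-1L]  # skip header + size line
      vals <- vapply(strsplit(lines[body], "[ \t]+"),
                     function(f) as.numeric(f[3L]), numeric(1))
      bad <- body[which(vals < 0)[1L]]
      stop("negative count at line ", bad, " of ", path)
    }
    m <- methods::as(m, "CsparseMatrix")
    dimnames(m) <- list(gn[[1L]], cn[[1L]])
    for (flag in c("is_panel", "is_spike"))
      if (!is.null(gn[[flag]])) gn[[flag]] <- as.logical(gn[[flag]])
    makeCountMatrix(m, geneMeta = gn, cellMeta = cn)
  } else {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("malformed dense TSV: expected gene column plus cells")
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- tab[[1L]]
    if (min(m) < 0) {
      bad <- which(apply(m, 1L, min) < 0)[1L]
      stop("negative count at line ", bad + 1L, " of ", path)
    }
    makeCountMatrix(m)
  }
}

#' Write a count matrix
#'
#' @param x a count \code{SingleCellExperiment}.
#' @param path output path (\code{.mtx} or \code{.tsv}).
#' @param format \code{"mtx_triplet"} (writes companion gene/cell TSVs) or
#'   \code{"dense_tsv"}.
#' @return \code{path}, invisibly.
#' @export
writeCounts <- function(x, path, format = c("mtx_triplet", "dense_tsv")) {
  format <- match.arg(format)
  m <- SummarizedExperiment::assay(x, "counts")
  if (format == "mtx_triplet") {
    Matrix::writeMM(methods::as(m, "CsparseMatrix"), path)
    cp <- companionPaths(path)
    gn <- data.frame(gene_id = rownames(x),
                     as.data.frame(SummarizedExperiment::rowData(x)))
    cn <- data.frame(cell_id = colnames(x),
                     as.data.frame(SummarizedExperiment::colData(x)))
    write.table(gn, cp$genes, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cn, cp$cells, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    tab <- data.frame(gene_id = rownames(x), as.matrix(m),
                      check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line holds a set name, a description, and the member genes, all
#' tab-separated. Members are deduplicated within a set; lines with fewer
#' than three fields are rejected.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors.
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": expected name, description, members")
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop("empty gene set at line ", i)
    sets[[f[[1L]]]] <- members
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional vector of set descriptions.
#' @return \code{path}, invisibly.
#' @export
writeGeneSets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, de, genes)
    paste(c(nm, de, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Write a gene network
#'
#' \code{"edge_tsv"} writes the columns \code{gene_a}, \code{gene_b},
#' \code{weight}; \code{"graphml"} preserves node attributes as well.
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @param path output path.
#' @param format \code{"edge_tsv"} or \code{"graphml"}.
#' @return \code{path}, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(is(net, "GeneNetwork"))
  if (format == "edge_tsv") {
    e <- networkEdges(net)
    names(e) <- c("gene_a", "gene_b", "weight")
    write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- asIgraph(net)
    # graphml attribute export chokes on NA character attributes
    cl <- igraph::vertex_attr(g, "cluster")
    igraph::vertex_attr(g, "cluster") <- ifelse(is.na(cl), "", cl)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a gene network
#'
#' Reconstructs a network written by \code{\link{writeNetwork}}. The edge-TSV
#' format carries no isolated nodes; GraphML round-trips nodes and
#' attributes.
#'
#' @param path input path.
#' @param format \code{"edge_tsv"} or \code{"graphml"}.
#' @return A \linkS4class{GeneNetwork}.
#' @export
readNetwork <- function(path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edge_tsv") {
    e <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_a", "gene_b", "weight") %in% names(e)))
      stop("edge TSV must have columns gene_a, gene_b, weight")
    nodes <- sort(unique(c(e$gene_a, e$gene_b)))
    geneNetwork(nodes, data.frame(from = e$gene_a, to = e$gene_b,
                                  weight = e$weight))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(gene = igraph::V(g)$name,
                        isTF = as.logical(igraph::V(g)$isTF),
                        cluster = ifelse(nzchar(igraph::V(g)$cluster),
                                         igraph::V(g)$cluster, NA_character_),
                        stringsAsFactors = FALSE)
    ed <- igraph::as_data_frame(g, what = "edges")
    geneNetwork(nodes, data.frame(from = ed$from, to = ed$to,
                                  weight = ed$weight))
  }
}
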