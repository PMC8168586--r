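# Network enrichment statistics: degree-preserving permutation test,
# Fisher target enrichment, TF-PPI gene-set tests, paired signed-rank
# comparison, and TF-target table filtering.

rewireKeepingDegrees <- function(g, swapFactor) {
  nSwap <- max(1L, swapFactor * igraph::ecount(g))
  igraph::rewire(g, igraph::keeping_degseq(niter = nSwap))
}

#' Degree-preserving network randomisation
#'
#' One double-edge-swap randomisation of a network (the permutation unit
#' used by \code{\link{neaTest}}): edge pairs are repeatedly swapped,
#' rejecting swaps that would create self-loops or multi-edges, which
#' preserves every node's degree exactly and samples uniformly from the
#' graphs with the observed degree sequence.
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @param seed RNG seed.
#' @param swapFactor swap attempts as a multiple of the edge count.
#' @return A permuted \linkS4class{GeneNetwork} (weights reset to 1).
#' @export
permuteNetwork <- function(net, seed = 1, swapFactor = 10) {
  stopifnot(is(net, "GeneNetwork"))
  set.seed(seed)
  g <- rewireKeepingDegrees(asIgraph(net), swapFactor)
  e <- igraph::as_data_frame(g, what = "edges")
  nodes <- networkNodes(net)
  geneNetwork(nodes[, c("gene", "isTF", "cluster")],
              if (nrow(e)) data.frame(from = e$from, to = e$to, weight = 1)
              else NULL)
}

#' Network enrichment analysis (degree-preserving permutation test)
#'
#' Measures the connectivity of a gene set to the rest of the network as
#' the number of edges with at least one endpoint in the set, and compares
#' it to the same statistic on randomised networks with the degree sequence
#' preserved exactly (double-edge-swap randomisation, 10 x |edges| swap
#' attempts per permutation, each permutation an independent restart from
#' the observed network). The empirical p-value uses the add-one rule
#' \eqn{p = (1 + \#\{null \ge obs\}) / (1 + B)}.
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @param geneSet character vector; must intersect the network's nodes.
#' @param nPerm number of permutations (at least 100).
#' @param seed RNG seed.
#' @param swapFactor swap attempts per permutation, as a multiple of the
#'   edge count.
#' @return An \linkS4class{EnrichmentResult}; \code{zDefined} is FALSE when
#'   the permutation null is degenerate (for example when the set covers
#'   all nodes, so every permutation gives the same statistic).
#' @export
neaTest <- function(net, geneSet, nPerm = 1000, seed = 1, swapFactor = 10) {
  stopifnot(is(net, "GeneNetwork"), nPerm >= 100)
  nodes <- networkNodes(net)$gene
  geneSet <- intersect(geneSet, nodes)
  if (!length(geneSet)) stop("gene set does not intersect the network nodes")
  g <- asIgraph(net)
  inSet <- function(graph) {
    e <- igraph::as_edgelist(graph)
    sum(e[, 1L] %in% geneSet | e[, 2L] %in% geneSet)
  }
  observed <- inSet(g)
  set.seed(seed)
  null <- vapply(seq_len(nPerm), function(i) {
    inSet(rewireKeepingDegrees(g, swapFactor))
  }, numeric(1))
  nullSD <- sd(null)
  zDefined <- is.finite(nullSD) && nullSD > 0
  new("EnrichmentResult", observed = observed, nullMean = mean(null),
      nullSD = nullSD,
      z = if (zDefined) (observed - mean(null)) / nullSD else NA_real_,
      p = (1 + sum(null >= observed)) / (1 + nPerm),
      nPerm = nPerm, seed = seed, zDefined = zDefined)
}

#' Fisher's exact test for target enrichment
#'
#' Builds the 2x2 contingency table of network membership against target
#' status. With one gene set (\code{nodesB = NULL}) membership is tested
#' against the rest of the universe; with two sets the table contrasts the
#' two networks directly (for example, the fraction of known TF targets
#' among pre-capture versus post-capture network genes).
#'
#' @param nodesA,nodesB character gene sets (\code{nodesB} optional).
#' @param targets character set of target genes.
#' @param universe gene universe containing the node sets.
#' @return List with \code{table}, \code{oddsRatio} (conditional MLE),
#'   \code{p} (two-sided exact) and \code{orDefined} (FALSE on a zero
#'   margin, where p is 1 by convention).
#' @export
fisherTargetEnrichment <- function(nodesA, nodesB = NULL, targets,
                                   universe) {
  universe <- unique(universe)
  if (!all(nodesA %in% universe))
    stop("network nodes must be contained in the universe")
  targets <- intersect(targets, universe)
  if (is.null(nodesB)) {
    inA <- universe %in% nodesA
    isT <- universe %in% targets
    tab <- matrix(c(sum(inA & isT), sum(inA & !isT),
                    sum(!inA & isT), sum(!inA & !isT)), 2L, byrow = TRUE,
                  dimnames = list(c("inNetwork", "outNetwork"),
                                  c("target", "nonTarget")))
  } else {
    if (!all(nodesB %in% universe))
      stop("network nodes must be contained in the universe")
    tab <- matrix(c(sum(nodesA %in% targets), sum(!nodesA %in% targets),
                    sum(nodesB %in% targets), sum(!nodesB %in% targets)),
                  2L, byrow = TRUE,
                  dimnames = list(c("networkA", "networkB"),
                                  c("target", "nonTarget")))
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(table = tab, oddsRatio = NA_real_, p = 1,
                orDefined = FALSE))
  ft <- fisher.test(tab)
  list(table = tab, oddsRatio = unname(ft$estimate), p = ft$p.value,
       orDefined = is.finite(ft$estimate))
}

#' TF-PPI gene-set enrichment of cluster subnetworks
#'
#' For each cluster subnetwork and each gene set (for example a
#' transcription-factor protein-protein-interaction library read from GMT),
#' an upper-tail hypergeometric overlap test against the network gene
#' universe, BH-corrected across terms within each cluster. Terms with no
#' member in the universe are skipped and recorded.
#'
#' @param subnetGenes named list of gene sets, one per cluster subnetwork.
#' @param gmt named list of term gene sets (see \code{\link{readGeneSets}}).
#' @param universe gene universe (typically all network genes).
#' @return data.frame with columns \code{cluster}, \code{term},
#'   \code{overlap}, \code{termSize}, \code{setSize}, \code{p}, \code{fdr},
#'   \code{overlapGenes}; skipped terms are in attribute \code{"skipped"}.
#' @export
tfppiEnrichment <- function(subnetGenes, gmt, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  skipped <- character()
  rows <- list()
  for (cl in names(subnetGenes)) {
    genes <- intersect(subnetGenes[[cl]], universe)
    clRows <- list()
    for (term in names(gmt)) {
      members <- intersect(gmt[[term]], universe)
      if (!length(members)) {
        skipped <- union(skipped, term)
        next
      }
      ov <- intersect(genes, members)
      clRows[[length(clRows) + 1L]] <- data.frame(
        cluster = cl, term = term, overlap = length(ov),
        termSize = length(members), setSize = length(genes),
        p = hyperTestP(length(ov), length(members), length(genes),
                       length(universe)),
        overlapGenes = paste(ov, collapse = ","),
        stringsAsFactors = FALSE)
    }
    if (length(clRows)) {
      tab <- do.call(rbind, clRows)
      tab$fdr <- p.adjust(tab$p, method = "BH")
      rows[[cl]] <- tab
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cluster = character(), term = character(),
                      overlap = integer(), termSize = integer(),
                      setSize = integer(), p = numeric(), fdr = numeric(),
                      overlapGenes = character())
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Paired comparison of per-term gene counts
#'
#' Exact two-sided Wilcoxon signed-rank test of matched per-term values
#' (for example the number of subnetwork genes per TF-PPI term pre- versus
#' post-capture). Zero differences are dropped, tied absolute differences
#' get average ranks; above 25 informative pairs a tie-corrected normal
#' approximation is used.
#'
#' @param pre,post paired numeric vectors in the same term order.
#' @return List with \code{statistic} (positive-rank sum of
#'   \code{post - pre}), \code{p}, \code{nUsed} and \code{method}.
#' @export
pairedTermComparison <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  signedRankTest(post, pre)
}

#' Filter TF-target interaction tables
#'
#' Combines regulator-target links from an evidence-weighted table (kept at
#' \code{weight >= minWeight}, default 0.1) and a coexpression-significance
#' table (kept at \code{p < maxP}, strict, default 1e-7), deduplicating
#' pairs found in both.
#'
#' @param weightTable data.frame with columns \code{tf}, \code{target},
#'   \code{weight}; may be NULL.
#' @param pTable data.frame with columns \code{tf}, \code{target},
#'   \code{p}; may be NULL.
#' @param minWeight inclusive weight threshold.
#' @param maxP exclusive p-value threshold.
#' @return data.frame with columns \code{tf}, \code{target}, \code{source}
#'   (\code{"weight"}, \code{"p"} or \code{"both"}).
#' @export
filterTfTargets <- function(weightTable = NULL, pTable = NULL,
                            minWeight = 0.1, maxP = 1e-7) {
  pick <- function(tab, cols, what) {
    if (is.null(tab)) return(NULL)
    if (!all(cols %in% names(tab)))
      stop("malformed ", what, " table: need columns ",
           paste(cols, collapse = ", "))
    if (any(!complete.cases(tab[, cols])))
      stop("malformed ", what, " table: missing values")
    tab
  }
  weightTable <- pick(weightTable, c("tf", "target", "weight"), "weight")
  pTable <- pick(pTable, c("tf", "target", "p"), "p")
  a <- if (is.null(weightTable)) NULL else
    weightTable[weightTable$weight >= minWeight, c("tf", "target")]
  b <- if (is.null(pTable)) NULL else
    pTable[pTable$p < maxP, c("tf", "target")]
  key <- function(d) paste(d$tf, d$target, sep = "\r")
  all <- rbind(a, b)
  if (is.null(all) || nrow(all) == 0L)
    return(data.frame(tf = character(), target = character(),
                      source = character()))
  out <- all[!duplicated(key(all)), , drop = FALSE]
  inA <- key(out) %in% if (is.null(a)) character() else key(a)
  inB <- key(out) %in% if (is.null(b)) character() else key(b)
  out$source <- ifelse(inA & inB, "both", ifelse(inA, "weight", "p"))
  rownames(out) <- NULL
  out
}
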