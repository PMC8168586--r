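# Marker derivation from reference expression profiles and hypergeometric
# typing of cluster DEG sets.

#' Derive cell-type markers from reference profiles
#'
#' Reference profiles are consumed as a genes x types table of mean
#' expression. Candidate markers for a type (by default, genes whose
#' expression is maximal in that type; externally derived candidate sets,
#' for example from a differential-expression run on the reference, may be
#' supplied instead) are removed when they are highly expressed in another
#' type — when any other type's expression exceeds the own-type expression
#' divided by \code{foldCutoff} (default twofold). Genes still claimed by
#' more than one type are dropped entirely, so the final marker sets are
#' unique per type.
#'
#' @param ref genes x types numeric matrix or data.frame of mean expression
#'   per type (row names are genes).
#' @param candidates optional named list (per type) of candidate marker
#'   genes; types must match the columns of \code{ref}.
#' @param foldCutoff fold difference another type may not exceed (default 2).
#' @param source label recorded in the provenance table.
#' @return A \linkS4class{MarkerTable}.
#' @examples
#' ref <- matrix(c(10, 1, 6, 1, 1, 12), nrow = 3,
#'               dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
#' markerSets(deriveMarkers(ref))  # g1 fails the twofold rule against B
#' @export
deriveMarkers <- function(ref, candidates = NULL, foldCutoff = 2,
                          source = "reference") {
  ref <- as.matrix(ref)
  if (ncol(ref) < 2L) stop("need at least two cell types in the reference")
  if (is.null(rownames(ref))) stop("reference rows must be named by gene")
  types <- colnames(ref)
  if (is.null(candidates)) {
    top <- types[max.col(ref, ties.method = "first")]
    candidates <- split(rownames(ref), factor(top, levels = types))
  } else {
    if (!all(names(candidates) %in% types))
      stop("candidate sets name unknown cell types: ",
           paste(setdiff(names(candidates), types), collapse = ", "))
  }
  sets <- lapply(types, function(ty) {
    cand <- intersect(candidates[[ty]], rownames(ref))
    if (!length(cand)) return(character())
    own <- ref[cand, ty]
    others <- ref[cand, setdiff(types, ty), drop = FALSE]
    maxOther <- apply(others, 1L, max)
    cand[maxOther <= own / foldCutoff]
  })
  names(sets) <- types
  claimed <- unlist(sets, use.names = FALSE)
  shared <- unique(claimed[duplicated(claimed)])
  sets <- lapply(sets, setdiff, shared)
  prov <- data.frame(
    type = rep(names(sets), lengths(sets)),
    gene = unlist(sets, use.names = FALSE),
    source = source, stringsAsFactors = FALSE)
  new("MarkerTable", sets = sets, provenance = prov)
}

#' Score cluster-type correspondence
#'
#' For every (cluster, type) pair, the overlap between the cluster's DEG
#' set and the type's marker set is tested with an upper-tail
#' hypergeometric test against the gene universe, with Benjamini-Hochberg
#' correction over all pairs. DEG and marker sets are intersected with the
#' universe first (the numbers actually tested are reported).
#'
#' @param degGenes named list of DEG gene sets, one per cluster.
#' @param markers a \linkS4class{MarkerTable} or a named list of marker
#'   sets.
#' @param universe character vector of genes forming the test universe.
#' @return data.frame with columns \code{cluster}, \code{type},
#'   \code{overlap}, \code{nMarkers}, \code{nDEGs}, \code{p}, \code{fdr}.
#' @export
scoreClusterTypes <- function(degGenes, markers, universe) {
  if (is(markers, "MarkerTable")) markers <- markerSets(markers)
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  rows <- list()
  for (cl in names(degGenes)) {
    degs <- intersect(degGenes[[cl]], universe)
    for (ty in names(markers)) {
      mk <- intersect(markers[[ty]], universe)
      k <- length(intersect(degs, mk))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, type = ty, overlap = k,
        nMarkers = length(mk), nDEGs = length(degs),
        p = hyperTestP(k, length(mk), length(degs), length(universe)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out
}
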