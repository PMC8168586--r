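# Pipeline orchestration: simulate -> qc -> cluster/de -> typing -> grn ->
# enrich -> pseudotime, with a summary report.

pipelineStages <- c("simulate", "qc", "cluster", "de", "typing", "grn",
                    "enrich", "pseudotime")

#' Default pipeline configuration
#'
#' A nested list of stage parameter blocks sized for the bundled synthetic
#' experiment (see \code{\link{simulationConfig}} for the generator
#' defaults). QC thresholds are scaled to the synthetic library depth
#' (thousands of counts per cell rather than the millions of a real
#' full-length library); every threshold keeps its meaning and can be
#' overridden from a YAML file via \code{\link{readPipelineConfig}}.
#'
#' @param seed global seed; all stage seeds derive from it.
#' @return Named list of stage blocks.
#' @export
defaultPipelineConfig <- function(seed = 1) {
  list(
    seed = seed,
    paths = list(),
    simulation = list(),
    qc = list(minGenesPerCell = 1000, minLibrarySize = 3000,
              maxTop200Fraction = 0.75, maxSpikeFraction = 0.14,
              minGeneMeanCount = 1),
    cluster = list(method = "hierarchical_ward", k = 3, kMax = 6,
                   nPcs = 20, nHvg = 500),
    de = list(fdrCut = 0.05, lnfcCut = 0.5, minPct = 0),
    grn = list(corrThreshold = 0.8, sigAlpha = 0.05, minComponent = 3,
               degPct = 0.5, tfNeighborFrac = 0.2),
    enrich = list(nPerm = 200),
    pseudotime = list(nComponents = 10, nNeighbors = 30, rootCluster = NULL)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys present in the file override the defaults; everything else keeps
#' its default value.
#'
#' @param path YAML file path.
#' @param seed global seed used when the file does not set one.
#' @return Configuration list.
#' @export
readPipelineConfig <- function(path, seed = 1) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(defaultPipelineConfig(seed), user)
  cfg
}

stageSeed <- function(seed, stage) {
  (as.integer(seed) + sum(utf8ToInt(stage)) * 10007L) %% 2147483647L
}

configHash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

metaHeader <- function(config) {
  sprintf("# scCaptureKit %s seed=%s config=%s",
          as.character(packageVersion("scCaptureKit")),
          config$seed, configHash(config))
}

writeStageTable <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(metaHeader(config), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derived enrichment summary of a paired capture experiment
#'
#' Combines a pre- and a post-capture report into the two headline numbers
#' of a capture experiment: the fold enrichment of the on-target read
#' fraction (post divided by pre) and the percent increase in the number
#' of expressed panel genes, with rounded display values. For example,
#' on-target fractions of 2.2% and 78.3% give a 36-fold enrichment, and an
#' increase from 585 to 731 expressed panel genes is +25%.
#'
#' @param pre,post lists with elements \code{onTarget} (on-target read
#'   fraction, any common scale) and optionally \code{nExpressed}
#'   (expressed panel genes).
#' @return List with \code{foldEnrichment}, \code{foldDisplay},
#'   \code{percentIncrease}, \code{percentDisplay} and \code{defined}
#'   (FALSE when the pre-capture fraction is zero).
#' @export
reportEnrichmentSummary <- function(pre, post) {
  if (is.numeric(pre)) pre <- list(onTarget = pre)
  if (is.numeric(post)) post <- list(onTarget = post)
  defined <- isTRUE(pre$onTarget > 0)
  fold <- if (defined) post$onTarget / pre$onTarget else NA_real_
  pct <- if (!is.null(pre$nExpressed) && !is.null(post$nExpressed) &&
             pre$nExpressed > 0)
    100 * (post$nExpressed - pre$nExpressed) / pre$nExpressed
  else NA_real_
  list(foldEnrichment = fold,
       foldDisplay = if (defined) round(fold) else NA,
       percentIncrease = pct,
       percentDisplay = if (is.na(pct)) NA else round(pct),
       defined = defined)
}

truthReferenceProfiles <- function(truth) {
  # per-cluster mean expected expression: the simulator's stand-in for a
  # bulk reference of purified cell types
  mu <- truth@expectedExpression
  cl <- clusterOfCell(truth)
  out <- vapply(sort(unique(cl)), function(k)
    rowMeans(mu[, cl == k, drop = FALSE]), numeric(nrow(mu)))
  colnames(out) <- paste0("type", sort(unique(cl)))
  out
}

truthProgramSets <- function(truth) {
  e <- trueEdges(truth)
  lapply(split(e, e$program), function(d) unique(c(d$tf, d$target)))
}

#' Run the capture analysis pipeline
#'
#' Executes the requested stages in dependency order on a synthetic
#' experiment (stage \code{"simulate"}) or on matrices supplied through
#' \code{config$paths}. Stage randomness derives from the single global
#' seed, so any stage subset is reproducible, and a rerun with the same
#' configuration and seed is identical.
#'
#' @param config configuration list (see
#'   \code{\link{defaultPipelineConfig}}).
#' @param stages subset of \code{c("simulate", "qc", "cluster", "de",
#'   "typing", "grn", "enrich", "pseudotime")}.
#' @param outdir optional output directory; when given, every stage table
#'   is written with a metadata header (package version, seed, config
#'   hash).
#' @return List with one element per executed stage plus \code{report}, a
#'   flat list of headline numbers.
#' @export
runPipeline <- function(config = defaultPipelineConfig(),
                        stages = pipelineStages, outdir = NULL) {
  stages <- match.arg(stages, pipelineStages, several.ok = TRUE)
  res <- list()
  report <- list(seed = config$seed)
  log <- function(stage, fmt, ...)
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  need <- function(what, stage) {
    if (is.null(res[[what]]))
      stop("stage '", stage, "' needs upstream stage '", what,
           "' (not run and no input configured)")
    res[[what]]
  }

  if ("simulate" %in% stages) {
    simCfg <- do.call(simulationConfig,
                      c(config$simulation,
                        list(seed = stageSeed(config$seed, "simulate"))))
    res$simulate <- simulatePrePost(simCfg)
    log("simulate", "%d genes x %d cells, E = %g",
        nrow(res$simulate$pre), ncol(res$simulate$pre),
        simCfg@enrichmentFactor)
  } else if (!is.null(config$paths$pre)) {
    pre <- readCounts(config$paths$pre, format = "mtx_triplet")
    post <- readCounts(config$paths$post, format = "mtx_triplet")
    panelGenes <- readLines(config$paths$panel)
    rd <- SummarizedExperiment::rowData(pre)
    res$simulate <- list(
      pre = pre, post = post,
      panel = capturePanel(panelGenes,
                           rownames(pre)[rd$is_spike %in% TRUE]),
      truth = NULL)
  }

  if ("qc" %in% stages) {
    sim <- need("simulate", "qc")
    th <- do.call(qcThresholds, config$qc)
    fc <- filterCells(sim$pre, sim$panel, th)
    post <- updateLibrarySizes(sim$post[, fc$cells])
    preG <- filterGenes(fc$counts, th)
    res$qc <- list(pre = preG, post = post, preAllGenes = fc$counts,
                   qcTable = fc$qc, thresholds = th)
    report$cellsPassingQC <- length(fc$cells)
    report$genesPassingQC <- nrow(preG)
    log("qc", "%d/%d cells, %d/%d genes retained",
        length(fc$cells), ncol(sim$pre), nrow(preG), nrow(sim$pre))
    # capture metrics on the full gene universe over the surviving cells
    cap <- captureSummary(fc$counts, post, sim$panel)
    res$capture <- cap
    s <- cap@summary
    es <- reportEnrichmentSummary(
      list(onTarget = s$medianOnTargetPre,
           nExpressed = s$nExpressedPanelPre),
      list(onTarget = s$medianOnTargetPost,
           nExpressed = s$nExpressedPanelPost))
    report$onTargetFractionPre <- s$medianOnTargetPre
    report$onTargetFractionPost <- s$medianOnTargetPost
    report$foldEnrichmentOnTarget <- es$foldEnrichment
    report$nExpressedPanelPre <- s$nExpressedPanelPre
    report$nExpressedPanelPost <- s$nExpressedPanelPost
    report$percentIncreaseExpressedPanel <- es$percentIncrease
    report$medianDetectedPanelPre <- s$medianDetectedPre
    report$medianDetectedPanelPost <- s$medianDetectedPost
    report$detectedPanelFoldChange <- s$detectedFoldChange
    report$meanExpressionCorrelation <- s$meanExpressionCorrelation
    if (!is.null(outdir)) {
      writeStageTable(fc$qc, file.path(outdir, "qc_cells.tsv"), config)
      writeStageTable(cap@perCell,
                      file.path(outdir, "capture_cells.tsv"), config)
      writeStageTable(cap@perGene,
                      file.path(outdir, "capture_report.tsv"), config)
    }
  }

  if (any(c("cluster", "de", "typing", "grn", "enrich",
            "pseudotime") %in% stages)) {
    qc <- need("qc", "cluster")
    res$norm <- normalizeLog(qc$pre)
  }

  if ("cluster" %in% stages) {
    cl <- do.call(clusterCells,
                  c(list(x = res$norm,
                         seed = stageSeed(config$seed, "cluster")),
                    config$cluster))
    res$cluster <- cl
    report$nClusters <- nlevels(clusterLabels(cl))
    log("cluster", "%d clusters over %d cells", report$nClusters,
        length(clusterLabels(cl)))
    if (!is.null(outdir))
      writeStageTable(data.frame(cell = names(clusterLabels(cl)),
                                 cluster = as.character(clusterLabels(cl))),
                      file.path(outdir, "clusters.tsv"), config)
  }

  if ("de" %in% stages) {
    cl <- need("cluster", "de")
    params <- do.call(deParams, config$de)
    de <- differentialExpression(res$norm, clusterLabels(cl),
                                 "one_vs_rest", params = params)
    labs <- levels(clusterLabels(cl))
    if (length(labs) > 1L) {
      for (i in seq_along(labs)[-length(labs)])
        for (j in seq((i + 1L), length(labs))) {
          pair <- differentialExpression(res$norm, clusterLabels(cl),
                                         "pair", groups = labs[c(i, j)],
                                         params = params)
          de@degTables <- c(de@degTables, degTables(pair))
        }
    }
    res$de <- de
    nSig <- vapply(degTables(de), function(t) sum(t$significant),
                   integer(1))
    report$nSignificantDEGs <- sum(nSig[grepl("_vs_rest$",
                                              names(nSig))])
    log("de", "%d tables, %d one-vs-rest significant genes",
        length(degTables(de)), report$nSignificantDEGs)
    if (!is.null(outdir))
      for (nm in names(degTables(de)))
        writeStageTable(degTables(de)[[nm]],
                        file.path(outdir, sprintf("deg_%s.tsv", nm)),
                        config)
  }

  if ("typing" %in% stages) {
    de <- need("de", "typing")
    truth <- res$simulate$truth
    if (is.null(truth)) {
      log("typing", "no reference profiles available; skipped")
    } else {
      ref <- truthReferenceProfiles(truth)
      markers <- deriveMarkers(ref, source = "simulated reference")
      degSets <- lapply(degTables(de)[grepl("_vs_rest$",
                                            names(degTables(de)))],
                        function(t) t$gene[t$significant & t$lnFC > 0])
      names(degSets) <- sub("_vs_rest$", "", names(degSets))
      typing <- scoreClusterTypes(degSets, markers, rownames(res$norm))
      res$typing <- list(markers = markers, typing = typing)
      report$nTypedClusters <- length(unique(
        typing$cluster[typing$fdr <= 0.05]))
      log("typing", "%d x %d cluster/type tests", length(degSets),
          length(markerSets(markers)))
      if (!is.null(outdir))
        writeStageTable(typing, file.path(outdir, "typing.tsv"), config)
    }
  }

  if (any(c("grn", "enrich", "pseudotime") %in% stages)) {
    qc <- need("qc", "grn")
    sim <- res$simulate
    res$imputed <- imputeCapture(qc$pre, qc$post, sim$panel)
    res$normImputed <- normalizeLog(res$imputed)
  }

  if ("grn" %in% stages) {
    de <- need("de", "grn")
    params <- do.call(grnParams, config$grn)
    netPre <- buildNetwork(res$norm, params)
    netImp <- buildNetwork(res$normImputed, params)
    deImp <- differentialExpression(res$normImputed,
                                    clusterLabels(res$cluster),
                                    "one_vs_rest",
                                    params = do.call(deParams, config$de))
    subPre <- clusterSubnetworks(netPre, de, params)
    subImp <- clusterSubnetworks(netImp, deImp, params)
    res$grn <- list(pre = netPre, imputed = netImp,
                    subnetPre = subPre, subnetImputed = subImp,
                    deImputed = deImp, params = params)
    report$networkNodesPre <- numNodes(netPre)
    report$networkEdgesPre <- numEdges(netPre)
    report$networkNodesImputed <- numNodes(netImp)
    report$networkEdgesImputed <- numEdges(netImp)
    log("grn", "pre %d/%d nodes/edges, imputed %d/%d",
        numNodes(netPre), numEdges(netPre), numNodes(netImp),
        numEdges(netImp))
    if (!is.null(outdir)) {
      writeNetwork(netPre, file.path(outdir, "network_pre.tsv"))
      writeNetwork(netImp, file.path(outdir, "network_imputed.tsv"))
      writeStageTable(networkNodes(subImp),
                      file.path(outdir, "subnetwork_nodes.tsv"), config)
    }
  }

  if ("enrich" %in% stages) {
    grn <- need("grn", "enrich")
    sim <- res$simulate
    tfs <- targetGenes(sim$panel)
    nPerm <- config$enrich$nPerm
    neaPre <- neaTest(grn$pre, tfs, nPerm = nPerm,
                      seed = stageSeed(config$seed, "enrich"))
    neaImp <- neaTest(grn$imputed, tfs, nPerm = nPerm,
                      seed = stageSeed(config$seed, "enrich"))
    res$enrich <- list(neaPre = neaPre, neaImputed = neaImp)
    report$neaPPre <- neaPre@p
    report$neaPImputed <- neaImp@p
    if (!is.null(sim$truth)) {
      targets <- unique(trueEdges(sim$truth)$target)
      universe <- union(rownames(res$normImputed), targets)
      fish <- fisherTargetEnrichment(networkNodes(grn$pre)$gene,
                                     networkNodes(grn$imputed)$gene,
                                     targets, universe)
      gmt <- truthProgramSets(sim$truth)
      names(gmt) <- paste0("program", names(gmt), "_regulon")
      subGenes <- function(net) split(networkNodes(net)$gene,
                                      networkNodes(net)$cluster)
      ppiPre <- tfppiEnrichment(subGenes(grn$subnetPre), gmt,
                                networkNodes(grn$pre)$gene)
      ppiImp <- tfppiEnrichment(subGenes(grn$subnetImputed), gmt,
                                networkNodes(grn$imputed)$gene)
      cmp <- NULL
      if (!is.null(ppiPre) && !is.null(ppiImp)) {
        key <- function(d) paste(d$cluster, d$term)
        shared <- intersect(key(ppiPre), key(ppiImp))
        if (length(shared) >= 2L)
          cmp <- pairedTermComparison(
            ppiPre$overlap[match(shared, key(ppiPre))],
            ppiImp$overlap[match(shared, key(ppiImp))])
      }
      res$enrich$fisherTargets <- fish
      res$enrich$tfppiPre <- ppiPre
      res$enrich$tfppiImputed <- ppiImp
      res$enrich$pairedComparison <- cmp
      report$targetFisherP <- fish$p
      report$targetOddsRatio <- fish$oddsRatio
      if (!is.null(cmp)) report$tfppiPairedP <- cmp$p
    }
    log("enrich", "NEA p: pre %.4g, imputed %.4g", neaPre@p, neaImp@p)
  }

  if ("pseudotime" %in% stages) {
    cl <- need("cluster", "pseudotime")
    coords <- diffusionMap(res$normImputed,
                           nComponents = config$pseudotime$nComponents,
                           nNeighbors = config$pseudotime$nNeighbors)
    root <- config$pseudotime$rootCluster
    if (is.null(root)) {
      truth <- res$simulate$truth
      if (is.null(truth))
        stop("stage 'pseudotime' needs a configured root cluster")
      rootK <- which(truth@branchParent == 0)
      labs <- clusterLabels(cl)
      rootCells <- names(clusterOfCell(truth))[clusterOfCell(truth) == rootK]
      root <- names(which.max(table(labs[intersect(names(labs),
                                                   rootCells)])))
    }
    traj <- fitLineages(coords, clusterLabels(cl), root)
    res$pseudotime <- traj
    report$nLineages <- length(lineages(traj))
    report$rootCluster <- root
    log("pseudotime", "%d lineage(s) from cluster %s",
        report$nLineages, root)
    if (!is.null(outdir)) {
      writeStageTable(data.frame(cell = names(pseudotime(traj)),
                                 pseudotime = pseudotime(traj)),
                      file.path(outdir, "pseudotime.tsv"), config)
      writeStageTable(data.frame(coords), file.path(outdir, "coords.tsv"),
                      config)
    }
  }

  res$report <- report
  if (!is.null(outdir)) {
    rep <- data.frame(metric = names(report),
                      value = vapply(report, function(v)
                        paste(format(v), collapse = ","), character(1)))
    writeStageTable(rep, file.path(outdir, "report.tsv"), config)
  }
  res
}
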