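# Synthetic paired pre/post-capture generator.
#
# Pre-capture counts are cluster- and trajectory-structured negative
# binomials with mean-dependent zero inflation. Capture is modelled as a
# probability re-weighting of the cell's expected transcript pool: panel
# genes (and on-panel spike-ins) have their sampling probability multiplied
# by the enrichment factor E, the pool is renormalised, and the post-capture
# library is a multinomial resample at postDepthRatio times the pre-capture
# depth, subject to the same mean-dependent zero inflation evaluated at the
# expected post-capture count. With E = 1 and ratio = 1 the two libraries
# are statistically exchangeable in their means; with large E the expected
# post-capture counts of panel genes are large, their dropout probability
# collapses and capture rescues genes invisible pre-capture.

#' Configure the paired pre/post-capture simulator
#'
#' Defaults describe a desk-scale experiment: 300 cells, 2000 genes of which
#' 150 form the capture panel ("TFs"), three clusters on a branching
#' trajectory (one root progenitor state, two leaves), 92 constant spike-ins
#' of which 56 are on the panel, and post-capture libraries four times
#' deeper than pre-capture.
#'
#' @param nCells,nGenes,nPanel,nClusters experiment dimensions.
#' @param branchParent parent cluster per cluster (0 marks the root);
#'   default a root with two leaves.
#' @param baseMean expected counts of an unremarkable expressed gene.
#' @param dispersion negative-binomial size parameter.
#' @param programFc multiplicative effect of a fully active cluster program.
#' @param programOnset discrete component of program activation at branch
#'   commitment; the remainder ramps log-linearly along latent time within
#'   the branch.
#' @param antagonism strength with which committed cells down-regulate the
#'   program of a sibling branch (0 = none, 1 = mirror of the own-branch
#'   activation); fate programs of diverging branches are mutually
#'   exclusive, which gives the trajectory a genuinely branched geometry.
#' @param nTFsPerProgram,nTargetsPerProgram panel TFs and background target
#'   genes per cluster program; every TF-target pair within a program is a
#'   true regulatory edge.
#' @param targetMeanFactor mean multiplier of program-target and maturation
#'   genes (well-expressed markers).
#' @param panelMeanFactor mean multiplier of panel genes (TFs are lowly
#'   expressed).
#' @param rarePanelFraction,rarePanelMean fraction of the panel made of
#'   near-silent genes and their mean; these are invisible pre-capture and
#'   recovered by capture.
#' @param nMaturationGenes background genes ramping along latent time in all
#'   cells (a maturation signature shared across branches).
#' @param enrichmentFactor on-target sampling-probability multiplier E.
#' @param postDepthRatio post/pre library-size ratio (default 4).
#' @param nSpikes,nSpikesOnPanel,spikeMean spike-in design (92 species, 56
#'   covered by probes, constant mean per cell).
#' @param dropoutIntercept,dropoutSlope logit-linear zero-inflation versus
#'   log2 expected count; the default slope -1 with intercept -1 gives ~27%
#'   dropout at mean 0.5 and ~7% at mean 2.
#' @param tSplit latent time of branch commitment.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nCells = 300, nGenes = 2000, nPanel = 150,
                             nClusters = 3, branchParent = NULL,
                             baseMean = 2, dispersion = 5, programFc = 4,
                             programOnset = 0.5, antagonism = 1,
                             nTFsPerProgram = 5,
                             nTargetsPerProgram = 20, targetMeanFactor = 10,
                             panelMeanFactor = 1, rarePanelFraction = 1 / 3,
                             rarePanelMean = 0.002, nMaturationGenes = 40,
                             enrichmentFactor = 100, postDepthRatio = 4,
                             nSpikes = 92, nSpikesOnPanel = 56,
                             spikeMean = 0.3, dropoutIntercept = -1,
                             dropoutSlope = -1, tSplit = 0.45, seed = 1) {
  if (is.null(branchParent))
    branchParent <- if (nClusters == 1) 0 else c(0, rep(1, nClusters - 1))
  new("SimulationConfig", nCells = nCells, nGenes = nGenes, nPanel = nPanel,
      nClusters = nClusters, branchParent = branchParent,
      baseMean = baseMean, dispersion = dispersion, programFc = programFc,
      programOnset = programOnset, antagonism = antagonism,
      nTFsPerProgram = nTFsPerProgram,
      nTargetsPerProgram = nTargetsPerProgram,
      targetMeanFactor = targetMeanFactor,
      panelMeanFactor = panelMeanFactor,
      rarePanelFraction = rarePanelFraction, rarePanelMean = rarePanelMean,
      nMaturationGenes = nMaturationGenes,
      enrichmentFactor = enrichmentFactor, postDepthRatio = postDepthRatio,
      nSpikes = nSpikes, nSpikesOnPanel = nSpikesOnPanel,
      spikeMean = spikeMean, dropoutIntercept = dropoutIntercept,
      dropoutSlope = dropoutSlope, tSplit = tSplit, seed = seed)
}

#' The heavy-dropout network benchmark scenario
#'
#' A designated simulator configuration for studying the benefit of capture
#' imputation on network inference: panel TFs are four-fold more lowly
#' expressed than at default and zero inflation is severe, so pre-capture TF
#' measurements are mostly noise, while cluster programs are strong enough
#' (eight-fold, tight dispersion, well-expressed targets) that the
#' |r| > 0.8 edge rule is attainable from ~300 cells on clean measurements.
#'
#' @param seed RNG seed.
#' @param enrichmentFactor on-target probability multiplier (default 100).
#' @return A \linkS4class{SimulationConfig}.
#' @export
grnBenchmarkConfig <- function(seed = 1, enrichmentFactor = 100) {
  simulationConfig(programFc = 8, dispersion = 10, panelMeanFactor = 0.25,
                   targetMeanFactor = 25, dropoutIntercept = 1.5,
                   enrichmentFactor = enrichmentFactor, seed = seed)
}

dropoutProb <- function(mu, config) {
  plogis(config@dropoutIntercept + config@dropoutSlope * log2(mu + 1))
}

clusterDepths <- function(branchParent) {
  depth <- rep(NA_integer_, length(branchParent))
  depth[branchParent == 0] <- 0L
  while (anyNA(depth)) {
    for (k in which(is.na(depth))) {
      p <- branchParent[k]
      if (!is.na(depth[p])) depth[k] <- depth[p] + 1L
    }
  }
  depth
}

simLayout <- function(config) {
  nTF <- config@nClusters * config@nTFsPerProgram
  nRare <- min(floor(config@rarePanelFraction * config@nPanel),
               config@nPanel - nTF)
  panel <- sprintf("TF%03d", seq_len(config@nPanel))
  background <- sprintf("G%04d", seq_len(config@nGenes - config@nPanel))
  spikes <- sprintf("ERCC-%03d", seq_len(config@nSpikes))
  chunk <- function(pool, each) {
    lapply(seq_len(config@nClusters), function(k)
      if (each > 0) pool[(k - 1L) * each + seq_len(each)] else character())
  }
  progTF <- chunk(panel, config@nTFsPerProgram)
  rare <- if (nRare > 0) panel[(config@nPanel - nRare + 1):config@nPanel]
          else character()
  nTgt <- config@nClusters * config@nTargetsPerProgram
  progTarget <- chunk(background, config@nTargetsPerProgram)
  maturation <- if (config@nMaturationGenes > 0)
    background[nTgt + seq_len(config@nMaturationGenes)] else character()
  list(panel = panel, background = background, spikes = spikes,
       progTF = progTF, progTarget = progTarget, rare = rare,
       maturation = maturation,
       spikesOnPanel = spikes[seq_len(config@nSpikesOnPanel)])
}

simExpectedMeans <- function(config, cluster, t, layout) {
  genes <- c(layout$panel, layout$background, layout$spikes)
  mu <- matrix(config@baseMean, length(genes), config@nCells,
               dimnames = list(genes, names(cluster)))
  mu[layout$panel, ] <- config@baseMean * config@panelMeanFactor
  if (length(layout$rare)) mu[layout$rare, ] <- config@rarePanelMean
  mu[layout$spikes, ] <- config@spikeMean
  depth <- clusterDepths(config@branchParent)
  seg <- if (max(depth) > 0) (1 - config@tSplit) / max(depth) else 1
  # own-branch activation per cell: onset jump at commitment plus a
  # log-linear ramp along latent time within the branch
  actOwn <- numeric(config@nCells)
  for (k in seq_len(config@nClusters)) {
    member <- cluster == k
    ramp <- if (depth[k] == 0L) {
      (config@tSplit - t[member]) / config@tSplit
    } else {
      start <- config@tSplit + (depth[k] - 1L) * seg
      (t[member] - start) / seg
    }
    actOwn[member] <- config@programOnset +
      (1 - config@programOnset) * ramp
  }
  for (k in seq_len(config@nClusters)) {
    member <- cluster == k
    a <- ifelse(member, actOwn, 0)
    if (depth[k] > 0L) {
      # committed cells of sibling branches repress this fate program
      sibling <- !member & depth[cluster] > 0L
      a[sibling] <- -config@antagonism * actOwn[sibling]
    }
    fcA <- config@programFc^a
    base <- config@baseMean * config@panelMeanFactor
    mu[layout$progTF[[k]], ] <- rep(base, length(layout$progTF[[k]])) %o% fcA
    base <- config@baseMean * config@targetMeanFactor
    mu[layout$progTarget[[k]], ] <-
      rep(base, length(layout$progTarget[[k]])) %o% fcA
  }
  if (length(layout$maturation))
    mu[layout$maturation, ] <-
      rep(config@baseMean * config@targetMeanFactor,
          length(layout$maturation)) %o% config@programFc^t
  mu
}

#' Simulate a paired pre/post-capture experiment
#'
#' Generates pre-capture zero-inflated negative-binomial counts over a
#' branching latent trajectory, then the matched post-capture libraries by
#' enrichment-weighted multinomial resampling (see the package vignette for
#' the generative model). Deterministic under the configured seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return List with elements \code{pre} and \code{post} (count
#'   \code{SingleCellExperiment}s over the same cells, spike-ins included as
#'   rows), \code{panel} (a \linkS4class{CapturePanel}) and \code{truth}
#'   (a \linkS4class{SimTruth}).
#' @examples
#' sim <- simulatePrePost(simulationConfig(nCells = 50, nGenes = 200,
#'                                         nPanel = 30, seed = 7))
#' sim$truth
#' @export
simulatePrePost <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)
  layout <- simLayout(config)
  cells <- sprintf("cell%04d", seq_len(config@nCells))
  cluster <- sample(seq_len(config@nClusters), config@nCells, replace = TRUE)
  names(cluster) <- cells
  depth <- clusterDepths(config@branchParent)
  seg <- if (max(depth) > 0) (1 - config@tSplit) / max(depth) else 1
  t <- numeric(config@nCells)
  for (k in seq_len(config@nClusters)) {
    member <- cluster == k
    if (depth[k] == 0L) {
      lo <- 0; hi <- if (config@nClusters == 1) 1 else config@tSplit
    } else {
      lo <- config@tSplit + (depth[k] - 1L) * seg; hi <- lo + seg
    }
    t[member] <- runif(sum(member), lo, hi)
  }
  names(t) <- cells
  mu <- simExpectedMeans(config, cluster, t, layout)
  d <- dropoutProb(mu, config)
  pre <- matrix(rnbinom(length(mu), mu = mu, size = config@dispersion),
                nrow(mu), dimnames = dimnames(mu))
  pre <- pre * matrix(rbinom(length(mu), 1L, 1 - d), nrow(mu))

  boost <- rep(1, nrow(mu))
  names(boost) <- rownames(mu)
  boost[layout$panel] <- config@enrichmentFactor
  boost[layout$spikesOnPanel] <- config@enrichmentFactor
  q <- mu * boost
  q <- sweep(q, 2L, colSums(q), "/")
  nPost <- round(config@postDepthRatio * colSums(pre))
  post <- vapply(seq_len(config@nCells),
                 function(j) rmultinom(1L, nPost[j], q[, j])[, 1L],
                 numeric(nrow(mu)))
  dimnames(post) <- dimnames(mu)
  mPost <- sweep(q, 2L, nPost, "*")
  post <- post * matrix(rbinom(length(post), 1L,
                               1 - dropoutProb(mPost, config)), nrow(post))

  geneMeta <- data.frame(
    is_panel = rownames(mu) %in% layout$panel,
    is_spike = rownames(mu) %in% layout$spikes)
  cellMeta <- data.frame(cluster = cluster, latentTime = t)
  preSce <- makeCountMatrix(pre, geneMeta, cellMeta)
  postSce <- makeCountMatrix(post, geneMeta, cellMeta)
  edges <- do.call(rbind, lapply(seq_len(config@nClusters), function(k)
    expand.grid(tf = layout$progTF[[k]], target = layout$progTarget[[k]],
                program = k, stringsAsFactors = FALSE)))
  truth <- new("SimTruth", clusterOfCell = as.integer(cluster),
               latentTime = t, trueEdges = edges,
               enrichmentFactor = config@enrichmentFactor,
               expectedExpression = mu, branchParent = config@branchParent,
               config = config)
  truth@clusterOfCell <- setNames(truth@clusterOfCell, cells)
  panel <- capturePanel(layout$panel, layout$spikes, layout$spikesOnPanel)
  list(pre = preSce, post = postSce, panel = panel, truth = truth)
}

#' Ground-truth regulatory network
#'
#' The undirected network over the simulator's true regulator-target pairs,
#' with unit weights; used as the recovery oracle for network inference.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @return A \linkS4class{GeneNetwork}.
#' @export
truthNetwork <- function(truth) {
  e <- trueEdges(truth)
  nodes <- unique(c(e$tf, e$target))
  net <- geneNetwork(
    data.frame(gene = nodes, isTF = nodes %in% e$tf),
    if (nrow(e)) data.frame(from = e$tf, to = e$target, weight = 1) else NULL)
  net
}

#' Genes belonging to any cluster program
#'
#' @param truth a \linkS4class{SimTruth}.
#' @return Character vector of program TFs and targets.
#' @export
programGenes <- function(truth) {
  e <- trueEdges(truth)
  unique(c(e$tf, e$target))
}

truthExpectedCounts <- function(truth, which = c("pre", "post")) {
  which <- match.arg(which)
  config <- truth@config
  mu <- truth@expectedExpression
  preExp <- mu * (1 - dropoutProb(mu, config))
  if (which == "pre") return(preExp)
  layout <- simLayout(config)
  boost <- rep(1, nrow(mu))
  names(boost) <- rownames(mu)
  boost[layout$panel] <- config@enrichmentFactor
  boost[layout$spikesOnPanel] <- config@enrichmentFactor
  q <- mu * boost
  q <- sweep(q, 2L, colSums(q), "/")
  nPost <- config@postDepthRatio * colSums(preExp)
  m <- sweep(q, 2L, nPost, "*")
  m * (1 - dropoutProb(m, config))
}

#' Closed-form expected on-target read fraction
#'
#' The expectation of the per-cell fraction of counts on panel genes
#' (spike-ins excluded from the numerator), computed from the generative
#' model rather than from sampled counts; used to check the capture model
#' against its own closed form.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param which \code{"pre"} or \code{"post"}.
#' @return List with \code{perCell}, \code{mean} and \code{median}.
#' @export
expectedOnTargetFraction <- function(truth, which = c("pre", "post")) {
  which <- match.arg(which)
  expc <- truthExpectedCounts(truth, which)
  layout <- simLayout(truth@config)
  frac <- colSums(expc[layout$panel, , drop = FALSE]) / colSums(expc)
  list(perCell = frac, mean = mean(frac), median = median(frac))
}

#' Closed-form expected genewise log2 enrichment
#'
#' The log2 ratio of expected mean post- to pre-capture CPM (pseudocount 1
#' on both), per gene, from the generative model.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @return Named numeric vector over all genes (spike-ins included).
#' @export
expectedLog2Enrichment <- function(truth) {
  preExp <- truthExpectedCounts(truth, "pre")
  postExp <- truthExpectedCounts(truth, "post")
  preCpm <- rowMeans(sweep(preExp, 2L, colSums(preExp), "/") * 1e6)
  postCpm <- rowMeans(sweep(postExp, 2L, colSums(postExp), "/") * 1e6)
  log2((postCpm + 1) / (preCpm + 1))
}
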