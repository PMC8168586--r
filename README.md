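# scCaptureKit

Analysis of targeted capture enrichment in paired single-cell RNA-seq
libraries.

## The problem

Standard scRNA-seq drops out lowly expressed genes — transcription
factors above all — so the regulators that define cell identity and
differentiation are largely invisible. Hybridisation capture re-enriches
a sequencing library with probes against a gene panel (e.g. ~1000 TFs
plus a subset of the ERCC spike-ins) and sequences the *same cells*
again, yielding a paired pre-/post-capture experiment in which on-target
reads rise from a few percent to most of the library.

`scCaptureKit` is the downstream toolbox for such experiments, for
computational biologists working with paired count matrices:

* **QC and capture metrics** — the four cell rules (detected genes,
  library size, top-200 complexity, spike-in content), the strict
  mean-count > 1 gene rule, per-cell on-target fractions, per-gene CPM
  enrichment `log2((post + 1)/(pre + 1))`, detected-panel-gene counts.
* **Clustering and DE** — size-factor log normalisation, Ward/Louvain
  clustering on scaled PCA, exact tie-aware Wilcoxon rank-sum DE with
  BH FDR and natural-log fold changes.
* **Cell typing** — reference marker derivation with the twofold
  cross-type cutoff and unique-marker rule, upper-tail hypergeometric
  scoring of cluster/type overlaps.
* **Networks** — coexpression networks (|Pearson r| > 0.8 on
  log-normalised expression, BH-significant), *capture imputation*
  (panel rows replaced by per-cell library-rescaled post-capture
  values), cluster-specific subnetwork rules, degree-preserving
  permutation enrichment (NEA), Fisher target enrichment, TF-PPI
  gene-set tests, exact paired signed-rank comparisons.
* **Pseudotime** — deterministic diffusion maps, MST lineages over
  cluster centroids from a designated root cluster, projection
  pseudotime in [0, 1], rolling-mean expression profiles.
* **Synthetic ground truth** — a paired pre/post generator with known
  clusters, branching latent trajectory, TF→target network and
  configurable enrichment factor *E*; capture is multinomial resampling
  with on-target probabilities multiplied by *E*, under mean-dependent
  zero inflation, so closed-form expectations are available
  (`expectedOnTargetFraction()`, `expectedLog2Enrichment()`).

## Worked example

```r
library(scCaptureKit)

sim <- simulatePrePost(simulationConfig(seed = 1))  # 2000 genes + 92 spike-ins x 300 cells
captureSummary(sim$pre, sim$post, sim$panel)
#> CaptureReport over 300 cells
#>   median on-target fraction: 0.0285 pre, 0.7153 post
#>   expressed panel genes: 124 pre, 150 post
#>   median detected panel genes per cell: 76 pre, 106 post (fold 1.39)
#>   pre/post mean-expression correlation r = 0.998
```

At the default enrichment factor *E* = 100, capture lifts the on-target
fraction from ~3% to ~72% of each cell's reads, recovers the 26 panel
genes too rare to be seen pre-capture (+21% expressed panel genes), and
raises the median per-cell panel detection 1.4-fold — while per-gene
mean expression stays almost perfectly log-linear between the libraries
(r = 0.998), i.e. capture enriches without distorting relative levels.

The headline summary of a real experiment is computed the same way from
its printed fractions and expressed-gene counts:

```r
reportEnrichmentSummary(list(onTarget = 2.2,  nExpressed = 585),
                        list(onTarget = 78.3, nExpressed = 731))
#> $foldEnrichment  35.6     $foldDisplay  36
#> $percentIncrease 25.0     $percentDisplay 25
```

An on-target fraction rising from 2.2% to 78.3% is a 36-fold enrichment;
585 → 731 expressed panel genes is a 25% increase.

The full pipeline (simulate → QC → cluster → DE → typing → GRN →
enrichment → pseudotime) runs from one seed-bearing configuration:

```r
res <- runPipeline(defaultPipelineConfig(seed = 1), outdir = "out")
res$report   # flat list: QC counts, enrichment folds, network sizes, lineages
```

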