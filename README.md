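# rnadecay

Quantify — and correct for — the distortion that *ex vivo* RNA
degradation introduces into RNA-seq experiments.

When tissue sits unprocessed before RNA extraction, transcripts decay at
gene-specific rates. Because RNA-seq measures relative abundance at fixed
sequencing depth, this reshapes expression estimates, sample clustering
and differential-expression (DE) calls. `rnadecay` provides, as tested
Bioconductor-style components:

* a **ground-truth simulator** of degradation time courses
  (`simulateDegradation()`): gene-specific first-order decay, RIN tied to
  each sample's degradation state, a constant-mass exogenous spike-in,
  per-individual expression effects, and negative-binomial sequencing
  noise, all recorded as ground truth in a `SummarizedExperiment`;
* **per-gene decay-rate estimation** from the log-linear decay model
  `ln y(t) = B0 − k·t + ε`, fitted on quantile-normalized RPKM pooled
  across individuals (`fitDecayRates()`), with Storey q-values
  (`computeQvalues()`) and classification of significantly fast / slow
  degraders at a chosen FDR (`classifyDecay()`), plus transcript-feature
  associations (`featureDecayAssociation()`, `biotypeEnrichment()`);
* **RIN-aware differential expression** under three strategies: naive NB
  GLM, NB GLM with a linear RIN covariate (`nbGlmTest()`), and Gaussian
  tests on RIN-residualized expression (`regressOutRin()`,
  `deOnResiduals()`), compared side by side by `deStrategySummary()`;
* **normalization utilities**: without-replacement depth subsampling
  (`subsampleCounts()`), exon-union gene models (`collapseGeneModel()`),
  RPKM (`computeRPKM()`), quantile normalization (`quantileNormalize()`)
  and TMM factors (`tmmFactors()`);
* **sample diagnostics**: PCA with covariate association, Spearman
  correlation clustering, library-complexity metrics and gene
  presence/absence tables over the time course.

The slope of the decay fit is reported relative to the genome-wide mean
rate (quantile normalization makes the mean slope exactly 0), so negative
slopes mark transcripts degraded faster than average and positive slopes
slower ones — the convention used throughout.

## A worked example

```r
library(rnadecay)

cfg <- SimConfig(nGenes = 2000, seed = 42)
sim <- simulateDegradation(cfg)
sim
#> DegradationExperiment: 2000 genes x 15 libraries
#>   decay classes: average=1396, fast=296, slow=308
#>   time points (h): 0, 12, 24, 48, 84
#>   RIN range: 3.74-9.53

counts <- SummarizedExperiment::assay(sim)
meta   <- sampleMeta(sim)
truth  <- as.data.frame(groundTruth(sim))

rpkm   <- computeRPKM(counts, truth)
qn     <- quantileNormalize(rpkm)
tested <- expressedGeneSet(qn, threshold = 0.3, rule = "all")
length(tested)
#> [1] 1964

fits <- classifyDecay(fitDecayRates(qn[tested, ], meta), alpha = 0.01)
table(estimated = fits$decay_class,
      planted = truth[fits$gene_id, "decay_class_true"])
#>          planted
#> estimated average fast slow
#>   average     710   39   15
#>   fast        337  227    0
#>   slow        341    4  291
mean(fits$slope)
#> [1] -8e-05
```

Of the 2,000 simulated genes, 1,964 pass the 0.3-RPKM expression filter
in every library. The planted fast and slow degraders are recovered on
the correct side (227/296 fast and 291/308 slow genes classified
correctly, with essentially no fast/slow confusion), and the mean fitted
slope is ~0, as quantile normalization guarantees. Many genes planted at
exactly the average rate are also called significant: with 30% of the
transcriptome shifting rank, rank-based normalization genuinely moves the
remaining genes relative to the mean — the same behaviour that makes most
genes in a real degraded time course test significant. The methods
vignette discusses this property in detail.

```r
lexpr <- quantileNormalize(counts, log2First = TRUE, keepLog = TRUE)
de <- deStrategySummary(counts, meta, lexpr,
                        timeContrasts  = list(c(0, 84)),
                        indivContrasts = list(c("ind1", "ind3")),
                        fdr = 0.05)
de$summary
#>   strategy                contrast n_de overlap_pct
#> 1      glm            time 84 vs 0  503        8.95
#> 2  glm+rin            time 84 vs 0    0          NA
#> 3 residual            time 84 vs 0    0          NA
#> 4      glm individual ind3 vs ind1   38      100.00
#> 5  glm+rin individual ind3 vs ind1  160       85.00
#> 6 residual individual ind3 vs ind1  133       84.96
```

The degradation confound in one table: comparing 0 h against 84 h, the
naive GLM calls 503 genes DE while adding RIN to the model absorbs the
entire signal (0 genes). Between individuals the pattern reverses —
treating all libraries as replicates drowns the biology (38 genes), while
the RIN covariate (160) and RIN-residualization (133) recover it;
`overlap_pct` is the overlap with the 10% most variable genes across
individuals at 0 h.

An end-to-end run writing every artifact as TSV:

```r
pc <- pipelineConfig("out_dir", sim = SimConfig(nGenes = 2000), seed = 1)
runPipeline(pc)
```

or, from a shell, `Rscript inst/scripts/run-pipeline.R --out out_dir
--seed 1 [--config cfg.yaml]` (also accepts real data via
`countsPath`/`metadataPath`/`annotationPath`).

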