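# MethylModule

MethylModule is an R package for asking, from a CpG beta-value cohort,
a systems-level question: *which genes change methylation between
biological states, do they co-localize into a network module, and how
do those changes relate to the methylation signatures of diseases?*
The motivating use case is immune-cell methylation across pregnancy —
a setting where cell-type composition shifts between groups and
several autoimmune diseases are known to be modulated — but every
stage is generic.

It is aimed at computational biologists who want the full chain as
tested, composable functions rather than a monolithic script:

1. **Preprocessing** — five probe-level QC filters (detection p > 0.01,
   bead count < 3, no CpG at the probed site, SNP proximity,
   multi-mapping) applied in a fixed, audited order; BMIQ-style
   beta-mixture quantile normalization of Infinium type II probes;
   beta/M transforms, `M = log2(beta / (1 - beta))`.
2. **Reference-free deconvolution** — constrained NMF
   `B ~ mu %*% t(omega)` (profiles `mu` in [0,1], proportion rows
   `omega` on the simplex) by exact alternating constrained least
   squares, with an extreme-profile identifiability convention and
   bootstrapped-deviance selection of the number of cell types K.
3. **Differential methylation** — per-probe linear models on M-values
   adjusted for the inferred proportions (limma empirical-Bayes
   moderation), BH FDR, and DMP calling by the joint criterion
   q < 0.05 and |Δβ| > 0.05; gene-level direction calls by majority.
4. **Network modules** — STRING-dialect ingestion (combined score
   ≥ 900), four module detectors (MCODE, DIAMOnD, Clique Sum,
   Correlation Clique), a ≥ 3-of-4 consensus module, and a
   permutation test on the harmonic-average shortest-path distance of
   seed genes.
5. **Disease relevance** — divisive subgroup selection for
   heterogeneous case/control cohorts, Fisher fold-enrichment of gene
   and CpG sets on explicit backgrounds, and Pearson/Spearman
   correlation of paired per-CpG effects as a directionality verdict.
6. **Synthetic data** — a first-class generator
   (`simulationConfig()`, `simulateCohort()`, `simulateNetwork()`,
   `simulateDiseaseCohort()`) that emits cohorts, networks and disease
   datasets with full ground-truth tables for every planted signal,
   so the whole chain is verifiable at desk scale.

## Worked example

```r
library(MethylModule)

cfg <- pipelineConfig(outDir = "demo_run", seed = 42)
res <- runPipeline(cfg)
str(res$summary$colocalization)
#> List of 3
#>  $ dObs     : num 3.07
#>  $ dNullMean: num 3.37
#>  $ p        : num 0.00498
```

The run simulates a 12/11/12-sample, 2000-probe cohort with two latent
cell types and 100 planted effects (|Δβ| drawn from 0.05–0.15),
filters 76 planted QC artifacts (1924 probes retained), selects K = 2,
calls 93 T2-vs-NP DMPs (84 DMGs), and builds a 9-gene consensus module
(all of DMG origin) whose seed genes sit significantly closer in the
simulated PPI network than random gene sets of equal size (harmonic
distance 3.07 against a null mean of 3.37, permutation p ≈ 0.005).
Three simulated disease cohorts with planted effect signs (−1, −1, +1)
relative to the pregnancy effects come back with fold enrichments of
the module CpGs among the disease DMPs around 7 (p < 1e-6) and Pearson
correlations of the paired effects of −0.98, −0.98 and +0.99 — the
sign pattern matching what was planted. Every number above is read off
`demo_run/summary.json`; all intermediate tables (DMPs, DMGs, per-
method modules, selection reports) are written alongside it.

Individual stages compose just as well without the pipeline wrapper:

```r
sim <- simulateCohort(simulationConfig(seed = 1))
ds  <- filterProbes(sim$dataset)
dec <- refFreeDecompose(ds, k = 2, seed = 1)
dmp <- dmpTable(ds, cellProportions(dec))
```

## Notes

The methods vignette (`vignettes/methylmodule-methods.Rmd`) documents
the generative model behind the synthetic cohorts, the deconvolution
identifiability convention, the K-selection construction, every
threshold with its default, and known limitations.
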