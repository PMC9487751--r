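---
title: "MethylModule: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MethylModule: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MethylModule)
```

MethylModule implements an analysis chain for CpG beta-value cohorts:
probe-level quality filtering, BMIQ-style normalization, reference-free
cell-type deconvolution, cell-composition-adjusted differential
methylation, consensus network-module detection over a protein-protein
interaction (PPI) graph, and a disease-relevance layer (divisive
subgroup selection, Fisher enrichment, effect-direction correlation).
This vignette explains the models behind each stage, the parameters
that matter, and the choices made where the design was genuinely open.
Every stage is testable at desk scale against a synthetic-data
generator with complete ground-truth bookkeeping.

## The synthetic cohorts

The generator emulates a three-group methylation study — non-pregnant
(NP, n = 12), first trimester (T1, n = 11) and second trimester (T2,
n = 12) — profiled on a bimodal beta scale, driven by two latent cell
types (a naive/memory analogue).

**Latent methylomes.** `simulateProfiles()` draws one base methylome
from a three-state mixture (low `Beta(4,20)`, intermediate
`Beta(10,10)`, high `Beta(20,4)`; weights 0.4/0.2/0.4), giving the
canonical bimodal-with-shoulder distribution of array betas, clipped to
[0.01, 0.99]. A configurable fraction of probes (default 30%) differs
between cell types by at least 0.2 — the distinguishing loci that make
deconvolution possible.

**Mixing proportions.** Per-sample proportions are Dirichlet around
group means (NP 0.65/0.35, T1 0.60/0.40, T2 0.45/0.55 — the memory-like
type expands across gestation). The Dirichlet precision defaults to 8,
giving a per-sample SD of roughly 0.13 and cohort-wide fractions
spanning about 0.1–0.9. This wide inter-individual spread matches what
flow cytometry shows for naive/memory fractions across adults, and it
is what renders the reference-free factorization well-conditioned
(below).

**Observation noise.** Betas are drawn from
`Beta(m * nu, (1 - m) * nu)` around the generating mean `m`, with
`nu = 200` by default — a within-group SD of about 0.02–0.035,
typical for 450K-style arrays. The noiseless limit `nu = Inf` returns
the means exactly. Neither figure is stated by the motivating study
design, so both are calibrated defaults, documented here and frozen.

**Planted effects.** Effects are planted for the T2-vs-NP contrast as a
per-observation logit-scale offset chosen so the generating mean of
every affected T2 observation shifts by exactly the probe's planted
delta-beta (magnitudes drawn uniformly from 0.05–0.15 by default, or a
configured constant; two thirds hypermethylated). Disease cohorts
inherit each shared probe's magnitude with a configurable relative
sign, so paired effect vectors retain the magnitude spread a
correlation needs. Only mid-range
(0.18–0.82), composition-neutral probes are eligible: on a probe whose
latent profiles differ between cell types, the raw group-mean
difference would additionally contain the composition shift — which is
precisely the confounder the model adjusts away, and is planted and
tested separately. With this construction the ground-truth delta-beta
equals the expectation difference of the generating means exactly.

**QC artifacts** are planted on disjoint probe sets (detection-p
failures, bead count 2, missing CpG, SNP proximity, multi-mapping) at
configurable rates, so the five-filter report can be audited against
the truth by simple conservation of counts.

**The network.** A preferential-attachment background (connected,
scale-free; starting from a single edge, each node attaches `m = 2`
targets, hence `1 + m (n - 2)` edges) carries a planted clique on genes
drawn from the effect genes, plus `coLocalizeEffects` (default 0.5)
extra edges per effect gene among the effect genes. The clique is the
dense module the detection algorithms must find; the extra edges give
the whole differentially-methylated gene set the broad co-localization
that the seed-distance permutation test presumes of disease genes.

**Disease cohorts** reuse the pregnancy methylomes. Case effects sit on
a configurable subset of the pregnancy effect probes with sign
`effectSign` times the pregnancy sign; `floor(overlapFraction *
nControls)` controls receive case-like generating means and are flagged
in the truth — the non-separable subgroup the divisive selection step
is meant to remove.

What the generator does *not* emulate: raw intensities and their
chip/position batch structure, the Infinium type I/II scale bias
(betas are emitted on one common scale; see BMIQ below), genomic
autocorrelation of methylation, and annotation errors. Passing tests
therefore demonstrate the correctness and calibration of the chain
under its own model assumptions, not robustness to those artifacts.

## Probe filtering and transforms

Five rules in a fixed order (detection p > 0.01 in any sample — the
per-sample fraction is configurable; bead count < 3; no CpG at the
probed site; SNP proximity; multi-mapping), each counted among probes
surviving the earlier rules, so counts are order-dependent and the
order is part of the contract. X-chromosome probes are retained by
default, as appropriate for single-sex cohorts. M-values use the base-2
logit with clipping constant 1e-3; the inverse transform recovers
clipped betas exactly.

## BMIQ-style normalization

`bmiqNormalize()` fits a three-state beta mixture (EM with weighted
method-of-moments updates; tolerance 1e-6, at most 500 iterations) to
the type I and type II probe populations of each sample, then maps type
II onto the type I scale: the unmethylated and methylated states are
quantile-matched through their fitted beta CDFs, and the intermediate
range is bridged linearly between the state handover points (located
where the posterior argmax changes). The map is monotone by
construction, so within-sample rank order is preserved and output stays
in [0, 1]; degenerate fits fall back to the identity with a warning.

The packaged pipeline leaves this step off by default: the synthetic
cohorts are emitted on a single common scale, and remapping an
already-harmonized cohort can only inject per-sample map noise — at
desk-scale probe counts the EM fits are loose enough that this coherent
noise registers as a spurious extra cell type in the K selection.
Enable it for real Infinium cohorts, which do carry the type II
compression the method exists to correct.

## Reference-free deconvolution

`refFreeDecompose()` factorizes the beta matrix as
`B ~ mu %*% t(omega)` with `mu` in [0,1] (latent cell-type methylomes)
and `omega` rows on the simplex (per-sample proportions), by
alternating exact constrained least squares. Both block solves share
one design across probes (or samples), so each active-set pattern needs
a single small solve: exact and fast for the small K of cell-type
mixtures. The residual sum of squares is non-increasing per outer
iteration; five random restarts keep the lowest deviance.

**Identifiability.** Any invertible remix of the factors that keeps
`omega` on the simplex and `mu` in bounds fits equally well, so the
factorization is only identified up to that family; in practice the
iterates drift toward over-dispersed proportions. The package pins the
solution at the *extreme-profile* endpoint: profiles are stretched
apart (an exact 2-variable linear program per column pair) until they
touch the [0,1] bounds — the anchor assumption that each cell type is
essentially unmethylated or methylated at its distinguishing CpGs,
which is how real reference methylomes look. The transform preserves
the fit; a final proportion update re-polishes the solution. Under the
generator's defaults this reduces the proportion recovery error from
MAE ≈ 0.15 (with correlation already > 0.99) to MAE < 0.05.

**Choosing K.** `selectK()` refits the model on bootstrap resamples of
the samples (probes fixed) and scores each refit by the
profiled-normal deviance `n * sum_i log(rss_i / n)`; the selected K
minimizes the *variance* of this deviance across resamples, with ties
to the smaller K. The logic: with too few components, heterogeneous
lack-of-fit fluctuates strongly with the resample; with too many, the
surplus component chases resample-specific noise; at the true K the
refits are stable. Keeping the full fit fixed and merely re-evaluating
its residuals on resamples degenerates (the criterion then always
prefers more components, which absorb the most variable samples), so
the refit-per-resample construction is essential. Selection runs on
the 2000 most variable probes with 16 resamples by default; on default
two-type cohorts it selects K = 2 in at least 9 of 10 seeds.

## Differential methylation

Per-probe linear models on M-values with group indicators and K−1 of
the K proportion columns (the simplex makes the full block collinear
with the intercept; the dropped column is configurable), fitted by
limma with empirical-Bayes variance moderation (a plain-OLS switch
exists; with a single probe or equal residual variances the moderated
and ordinary statistics coincide). Contrasts are fixed: T1_vs_NP,
T2_vs_NP, T2_vs_T1. Delta-beta is the raw difference of group mean
betas on the normalized scale — deliberately *unadjusted*, matching
its role as an effect-size filter. A probe is a DMP iff its BH q-value
is strictly below 0.05 *and* |delta-beta| strictly exceeds 0.05;
direction is the sign of delta-beta. Genes with at least one DMP are
DMGs, directed by majority; ties are broken by the direction of the
smallest-q member DMP (the stated tie-break; the source wording on
ties is self-contradictory, so this is a documented package decision).
Probes annotated to several genes count for each.

The composition adjustment carries real power costs: group membership
and inferred proportions are correlated by design (composition shifts
across gestation), so part of any group effect is absorbed. At the
default calibration, planted |delta-beta| = 0.10 effects are recovered
with sensitivity ≥ 80% at n = 12 per group. Conversely, when group
differences are driven *only* by mixing-proportion shifts, the
adjusted model calls essentially nothing while the unadjusted model
calls hundreds — the property that motivates deconvolution in the
first place. Note that an over-estimated K is not benign: a surplus
component can align with the group contrast and absorb a true effect
entirely, which is why the selection step matters.

Classical MDS (`cmdscale` on Euclidean distances over the 1000 most
variable probes) provides the unsupervised view; variance explained is
reported as eigenvalue over the sum of positive eigenvalues.

## Network modules

The PPI layer ingests STRING-dialect edge lists, keeping combined
scores ≥ 900 ("highest confidence"), collapsing duplicate pairs to the
maximum score.

Four detection algorithms are implemented natively on igraph
primitives:

* **MCODE** (Bader–Hogue): vertex weight = core number of the highest
  k-core of the open neighbourhood times that k-core's density;
  complexes grown from the highest-weight unused vertex admitting
  neighbours with weight ≥ (1−vwp)·seed weight (vwp = 0.2); haircut
  on, fluff off; module = union of seed-containing complexes above the
  score cutoff.
* **DIAMOnD**: iteratively adds the candidate with the smallest
  hypergeometric tail probability for its connectivity to the current
  member set; ties by higher in-set degree, then lower total degree,
  then lexicographic id; seed links can be up-weighted by alpha.
* **Clique Sum**: maximal cliques (size ≥ 3) tested for seed
  enrichment by the one-sided Fisher (hypergeometric tail) test,
  Bonferroni-corrected over the enumerated cliques; module = union of
  significant cliques. An enumeration budget guards against dense
  graphs.
* **Correlation Clique**: a stochastic consensus — each iteration
  retains every edge with probability (score/1000) times the mean
  seed-score factor of its endpoints (non-seeds contribute a 0.5
  baseline), tests maximal cliques of the sampled graph for seed
  enrichment, and marks genes in passing cliques; the module is the
  set of genes present in at least half the iterations. The published
  description of this algorithm leaves the edge-probability formula
  open; this reconstruction keeps every constant in the configuration.

The **consensus module** is the set of genes returned by at least 3 of
the 4 methods, with per-gene membership booleans, a seed (DMG) origin
flag and the methylation direction of seed-origin genes.

**Co-localization.** Distance between two genes is the shortest-path
length in edges (adjacent genes are at distance 1, so a clique attains
the minimum). The harmonic average `n_pairs / sum(1/d)` treats
unreachable pairs as contributing 0. The null re-samples uniformly
random node sets of equal size; the permutation p-value uses the
plus-one convention, so p is never exactly 0. The alternative reading
of distance (intermediate-node count) is selectable.

## Disease relevance

`vistaSubgroups()` is a divisive-selection surrogate: starting from the
full case/control cohort it repeatedly evaluates removal of each
removable sample (controls only by default, matching the use case of
control contamination; "either" is available), accepts the removal
that maximally improves the separation score, and stops when nothing
improves or a removal budget (default half the removable samples) is
reached. The score is the DMP count between the retained groups at the
q < 0.05, |delta-beta| > 0.05 criterion; equal-count states are
ordered by the summed −log10 q of the called DMPs, which prevents the
greedy search from stalling on count plateaus while leaving null
cohorts essentially untouched. Retained groups never drop below 3
samples; candidate ties break by sample id, so the procedure is
deterministic.

Enrichment uses the plain 2×2 Fisher machinery on an explicit
background universe (fold enrichment `FE = (a/(a+b)) / ((a+c)/N)`,
two-sided exact p); the background is always reported because FE
depends on it. The CpG-level variant also returns the overlap ids,
which feed the directionality test: Pearson (t-based p) and Spearman
correlations of the paired per-CpG effects, with the sign as the
verdict. Disease cohorts run through the identical
filter → deconvolution → model chain, with single-sex filtering
expressed as a sample-sheet predicate.

## The pipeline

`runPipeline(pipelineConfig(...))` executes the whole chain on a
synthetic cohort and writes every intermediate table, a manifest
(package version, seed, parameters) and a summary JSON. All randomness
derives from one master seed through a documented splitting scheme, so
two runs with the same seed produce byte-identical summaries. Default
problem sizes (2000 probes, 400 genes, 12/11/12 samples, three disease
cohorts of 20+20) keep a full run under a minute; they are desk-scale
stand-ins chosen so that every stage retains enough power for its
planted signal, and all of them scale up through the configuration.
The deconvolution K selected on the pregnancy cohort is reused for the
disease cohorts, mirroring a single cell-type model across analyses.

## Known limitations

* The deconvolution anchor convention is exactly right only when each
  cell type truly has boundary-methylated distinguishing CpGs; for
  cell types distinguished only by intermediate methylation the
  proportions remain identified only up to the mixing family.
* The bootstrapped-deviance K criterion separates K = 2 from K = 3 by
  a modest margin at desk scale; expect occasional over-selection on
  small cohorts.
* The Correlation Clique edge-probability model is a parameterized
  reconstruction, not a reference implementation.
* The greedy divisive subgroup search is a surrogate with the score
  and removable class exposed; it is not the published VIStA code.
* Beta-mixture normalization assumes three well-separated methylation
  states per design type; exotic distributions fall back to identity.
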