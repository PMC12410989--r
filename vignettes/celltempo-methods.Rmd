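---
title: "celltempo: models, protocols and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{celltempo: models, protocols and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the estimators it
implements, the assumptions behind them, the knobs that matter, what the
synthetic-data generator does and does not emulate, and the choices made
where the design was genuinely open. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## The question and the estimator

The package quantifies, per neuronal cell type, how far genome-wide gene
expression has diverged between species, and relates that divergence to
the cell type's abundance. The central difficulty is that abundance and
measurement precision are confounded: a rare type contributes fewer nuclei
and fewer reads, and naive pseudobulk distances between species shrink as
depth grows. The divergence protocol therefore equalizes everything that
scales with abundance before measuring anything:

1. **Cell equalization.** Within each (cell type, species) stratum,
   exactly `cells_per_type` nuclei are drawn without replacement; strata
   below the threshold are excluded. Canonical values are 250 at the
   coarse (subclass) level and 50 at the fine (subtype) level.
2. **Pseudobulk.** Counts are summed across the sampled nuclei, restricted
   to one-to-one protein-coding non-mitochondrial orthologs so that
   cross-species vectors are positionally comparable. Gene identifiers are
   opaque strings; cross-species joining happens only through the ortholog
   map, because symbols drift between annotation releases.
3. **Read equalization.** Every included profile is downsampled to the
   minimum total across *all* (type, species) profiles of the comparison,
   by multivariate hypergeometric sampling — the read-level analogue of
   sampling without replacement. (A with-replacement multinomial mode
   exists but is not the default.)
4. **Filtering.** A gene is dropped for a cell type iff it has fewer than
   `min_counts` (default 25) counts in both species *or* less than
   `min_cpm` (default 1) CPM in both species; a gene may therefore pass in
   one cell type and fail in another.
5. **Distance.** The default metric is the Spearman correlation distance
   1 − ρ on log2(CPM + 1). Because Spearman distance is rank-based it is
   invariant to the pseudocount and to any monotone transform, which the
   test suite asserts; the pseudocount matters only for the Euclidean and
   L1 metrics.

The whole procedure runs `n_iterations` times (default 100), each
iteration on its own seed substream, and medians over iterations are
reported. The per-type median distance is then correlated (Spearman,
two-sided) with the pair-averaged cell-type proportions, whose
denominators include only the cell types passing the same
`cells_per_type` threshold; an all-profiled-cells denominator is available
by flag. An even number of iterations takes the mean of the two central
order statistics, i.e. `stats::median`.

**P-values for the correlation.** Cell-type counts sit near the boundary
where exact and approximate Spearman P-values diverge (10–17 types). When
the inputs are tie-free the package uses `stats::cor.test`'s
permutation-complete exact distribution (n ≤ 9) or its AS89 approximation
of it (n ≥ 10); with ties it falls back to the asymptotic t
approximation. The null-calibration study below checks the resulting
median-P honesty empirically.

**Representative iteration.** Scatterplots need one concrete iteration.
The selection rule is deterministic: (1) the first iteration whose ρ and P
both equal the medians; else (2) among the ρ values nearest the median ρ,
the value attained by the most iterations wins and the first iteration
attaining it is shown; (3) remaining ties go to the lowest index. The
conventional description of stage 2 is ambiguous about whether P participates
in the nearest-value choice; this implementation matches on ρ only, which
reproduces the worked 22-vs-19-iteration example either way, and the rule
is oracle-tested against an independent restatement.

## Branch decomposition and lineage polarization

With an outgroup, pairwise distances from a single iteration's shared
downsampling decompose as branch1 = (d12 + d1O − d2O)/2 and
branch2 = (d12 + d2O − d1O)/2, an algebraic identity with
branch1 + branch2 = d12. Three-species runs use one shared gene mask per
cell type (genes passing the pairwise filter in all three pairs) and one
shared equalized total, so the three distances are commensurable. Negative
branch estimates — possible whenever noise breaks the triangle
inequality — are *retained and flagged*, not clipped: clipping would bias
the means reported across iterations upward.

Per-gene polarization uses the log2 fold-change triple. A gene is
*ambiguous* when both outgroup fold-changes exceed the ingroup-pair
fold-change in magnitude. Two variants then assign derived lineages: the
`as_printed` variant calls a gene ingroup1-derived when |lfc(1,O)| >
|lfc(1,2)| (with genes matching neither clause also treated as ambiguous,
making the rule exhaustive), while `outgroup_proximity` calls
ingroup1-derived when the outgroup sits closer to ingroup2 — the standard
parsimony reading. The two differ on real data; both are implemented, the
variant is recorded in the output, and no guess is made about which is
"right". Similarly, the DE prefilter ahead of polarization is
configurable (ingroup-pair DE by default; an outgroup-pair variant is
exposed) because descriptions of that filter in the field are ambiguous.

## Stratification

Expression strata are terciles of the average CPM between the two compared
species, recomputed per cell type; τ strata use the specificity index
τ = Σᵢ(1 − xᵢ/maxᵢxᵢ)/(N−1) computed on per-type CPM separately per
species and averaged over the pair (τ is scale-invariant per gene, so the
CPM choice only fixes a common normalization; raw pseudobulk sums would
change τ where library totals differ). Constraint strata use fixed s_het
cut-points 0.1 and 0.01 followed by seeded downsampling to equal bin
sizes. The expression-matched pairing procedure is implemented exactly as
specified — cross-bin pairs, |log2 FC| threshold (0.05 for expression
control, 0.01 for τ control, 0.1 in gene-set scans), sign partition,
seeded shuffle, greedy deduplication with first occurrence winning, zero
fold-change pairs kept, and ± categories downsampled to equal size — with
"zero fold-change" read as exact equality (a tolerance flag exists).
Pairs are canonicalized (sorted by gene ids) before the seeded stage so
that runs are reproducible and independently re-implementable. Stratified
divergence defaults to the Euclidean metric: within a tercile the dynamic
range is compressed and correlation distances become unstable.

## Population variability and variance ranks

Interindividual variability per cell type follows the same equalization
logic within one species: fixed nuclei per (individual, type), per-
individual read equalization across types, a mean-count filter (default
25), CPM, and the mean Spearman distance of each individual to the
unweighted mean profile, medianed over iterations. Demographic filters
(ancestry, age, condition) are a metadata predicate applied upstream, not
hard-coded. Variance ranks normalize a focal gene's cross-individual
variance to the 100 genes nearest in mean expression (focal gene excluded,
ties broken by stable gene-id order) — an order statistic, hence invariant
to global rescaling — and species are compared by paired t-test. Variance
is computed on CPM by default with a log-CPM flag, the conventional choice
being unstated.

## Directional sign tests

The DE interface is deliberately pluggable. The default internal backend
is a two-group negative-binomial Wald test on per-individual pseudobulks
with library-size offsets and method-of-moments dispersion shrunk 75%
toward a lowess mean-dispersion trend; a Welch t on log2(CPM+1) and an
`external_table` ingester (for results from dedicated DE packages,
including shrunken fold-changes) complete the set. The backends are
documented tools in their own right, not emulations of any particular
package, and no test depends on backend-specific values.

The sign test restricts to significant genes (BH-FDR < 0.05), drops
zero-fold-change genes (they carry no sign information), and compares the
number of down-regulated set members to the empirical background — the
frequency of negative fold-changes among *all* significant genes,
including the set's own members, the convention this package adopts; on
large simulations, excluding the set changes results by less than
reporting precision, which a test asserts. The two-sided P is the
minimum-likelihood convention (`stats::binom.test`). Fold enrichment is
reported as the odds ratio (n_down/n_up)/(bg_down/bg_up) — symmetric, and
log2 of it is the natural volcano axis — with a risk-ratio variant by
flag and a Haldane-corrected value alongside whenever a margin is zero.
The ASE analogue tests allelic directions from hybrid cells; the internal
backend tests per-sample log2 allelic ratios against zero, collapsing to
hybrid-line means when at least three lines exist (stratified blocking)
and treating samples as exchangeable otherwise, with the
covariate-adjusted external route available for externally computed pipelines.
The derived-lineage coupling builds the 2×2 (derived lineage × allelic
direction) table and reports the classical ad/bc odds ratio with the exact
two-sided P; `fisher.test`'s conditional-MLE odds ratio is deliberately
not used because the convention reported alongside such tables is the cross-product ratio.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes:
ancestral per-(gene, type) log2 expression (gene baseline SD 1.5, type
effect SD 0.75, so τ spans its range); per-lineage Normal shifts with SD
σ_c·b_l where σ_c = σ₀·p_c^(−γ) plants the abundance-divergence law on
the log2 scale (making noise-free distances analytically computable for
oracle tests); optional directional shifts (mean μ_S, shared across types)
in a designated gene set on one lineage; per-individual effects; cells
drawn with multinomial gene counts from a base-2 softmax of the profile,
lognormal library sizes, type from the configured proportions; and hybrid
ASE with negative-binomial totals and beta-binomial allele counts
(overdispersion ρ = 0.01, mild extra-binomial noise typical of ASE
replicates) whose mean is the logistic of the per-gene cis effect,
coupled to planted shifts by κ for biased-set genes. All randomness flows
from one root seed via `substream_seed()`; any species or component is
reproducible in isolation.

What it does **not** emulate: ambient RNA, doublets, UMI duplication,
batch effects, cell-type misassignment, or compositional shifts between
individuals. Passing recovery tests therefore show that the estimators
invert the generator's assumptions, not that real atlases satisfy them;
the robustness-grid and within-dataset design of the real analyses carry
that burden.

One compositional caveat the generator makes visible: because profiles
pass through a softmax, planting a +1 log2 shift on a large fraction of
expression mass depresses measured fold-changes of all genes slightly;
recovery tests use small planted sets so the distortion is negligible.

## Validation studies and the problem sizes chosen

The exported `*_study()` functions freeze the package's validation
protocols; the test suite and `scripts/acceptance.R` share them.

- **Recovery** (`recovery_study`): the generator defaults — 2,000 genes,
  12 types log-spaced 0.3→0.005, γ = 1, σ₀ = 0.01, 30,000 cells and 4
  individuals per species — with 100 cells per type (so every planted
  type qualifies) and 100 iterations. Expected outcome: strongly negative
  median ρ with small P, and per-type medians rank-ordering with the
  planted σ_c.
- **Null calibration** (`null_calibration_study`): γ = 0 with deep
  per-iteration sampling (50 cells per type, ~800 reads per cell, 250
  genes, σ₀ = 0.5). Deep sampling makes the between-type variation that
  drives each iteration's ρ essentially fixed across iterations, so the
  median P behaves like a single honest null draw; shallow designs
  attenuate median ρ toward 0 and make the median P conservative — a
  property of medians over resampling iterations worth knowing when
  interpreting real-data medians.
- **Fairness** (`fairness_study`): identical σ for every type (γ = 0)
  with proportions spanning 60-fold across 16 types, *no individual
  effects*, and deliberately shallow sampling (15 cells per type). This
  isolates protocol-induced abundance bias: individual-composition noise
  is a genuine biological signal (rarer strata sample fewer distinct
  nuclei per individual), is assessed by the variability module, and
  would otherwise be conflated with sampling unfairness. Shallow sampling
  makes iteration noise dominate the small fixed between-type variation,
  so the median ρ of an unbiased protocol concentrates near zero.
- **Selection power** (`planted_selection_study`): a 50-gene set with
  mean allelic shift −0.3 (SD 0.1) against 50 neutral same-sized sets,
  under organoid-like ASE conditions (8 samples, 4 lines, depth ~500,
  ρ = 0.01, background cis SD 0.7 — strong enough cis divergence that
  FDR-significant genes are plentiful, as in real hybrid data).

Sizes were fixed once as the smallest designs that leave comfortable
statistical margins for the properties they probe, and are stated here so
that reruns are interpretable; they are the package's study conditions,
not tuning knobs.

## Numerical choices and degenerate inputs

- Count downsampling draws the complement (reads removed) when fewer than
  half the reads are dropped — the same multivariate hypergeometric law,
  cheaper.
- Each iteration's cell and count downsampling share one substream
  (seed, iteration); whether these should re-randomize jointly or
  separately is a genuinely open protocol choice, and it is
  configurable in principle via the seed plumbing.
- Correlation distances on a constant vector raise a named error;
  `run_divergence` records NA for that (type, iteration) instead of
  aborting the run.
- Strata smaller than `cells_per_type`, types absent from one species,
  and blacklisted (immune) labels are excluded before iteration; an empty
  qualifying set is a named error.
- Ties in tercile binning and nearest-mean neighborhoods break by stable
  gene-id order; equalized s_het bins downsample with the caller's seed.
- Genes with zero totals (ASE) or all-zero profiles (τ) are excluded and
  reported as NA rather than imputed.

## Known limitations

Branch decomposition assumes additive distances on independent branches;
correlation distances violate additivity mildly, so branch estimates are
comparative indices rather than calibrated lengths (the recovery test
uses squared Euclidean distances, which are additive under the
generator's Normal shifts). The internal DE and ASE backends are
intentionally simple; for publication-grade fold-change shrinkage, feed
an external table. The hdf5 container dialect is not read on this
install; matrices arrive via the mtx+tsv dialect. Real-data concerns —
cross-dataset batch effects, unstable immune proportions, subtype
granularity — are handled by exclusion and within-dataset design, not
modeled.
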