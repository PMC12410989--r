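# celltempo

Cell-type abundance and the tempo of neuronal gene-expression evolution.

`celltempo` is an R package for comparative single-nucleus RNA-seq: it asks
whether more abundant neuronal cell types evolve their gene expression more
slowly than rare ones, and whether particular gene sets show the directional
expression shifts expected under polygenic lineage-specific selection. It is
aimed at evolutionary genomicists working with multi-species cortical
snRNA-seq atlases (counts + cell annotations), hybrid-cell allele-specific
expression (ASE) tables, and curated gene sets (GMT), and at methodologists
who want every stage testable against simulations with planted ground
truth.

## What it computes

**Downsampling-equalized divergence.** For each cell type *c* and species
pair, the pipeline repeatedly (default 100 iterations) samples an equal
number of cells per (type, species) stratum without replacement, sums them
into pseudobulk profiles restricted to one-to-one protein-coding
non-mitochondrial orthologs, downsamples every profile's reads (multivariate
hypergeometric) to the global minimum total, filters genes that have fewer
than 25 counts in both species or under 1 CPM in both species, and measures
divergence as the Spearman correlation distance

> d(c) = 1 − ρ( log2 CPM_species1, log2 CPM_species2 )

(Pearson, Euclidean and L1 metrics, and a no-transform mode, are available;
a full robustness grid over cells-per-type ∈ {50,100,250,500}, count filter
∈ {5,10,25,50}, CPM filter ∈ {1,5}, transform, and metric is one call).
Per-type divergence is then correlated with the pair-averaged cell-type
proportions across iterations, reporting the median Spearman ρ and P and a
deterministically chosen representative iteration for plotting.

**Branch decomposition.** With an outgroup *O* and ingroups 1, 2, pairwise
distances polarize onto lineage branches by three-taxon parsimony:

> branch1 = (d12 + d1O − d2O) / 2,  branch2 = (d12 + d2O − d1O) / 2,

so branch1 + branch2 = d12 exactly. Acceleration is branch1/branch2;
per-gene changes are polarized into derived lineages from log2 fold-change
triples (two rule variants exposed).

**Stratification.** Genes can be binned by expression terciles, by the
specificity index τ = Σᵢ(1 − x̂ᵢ)/(N−1) averaged over the species pair, or by
constraint (s_het cut-points 0.1/0.01 with seeded size equalization), with
an expression-matched pairing procedure (|log2 FC| thresholds 0.05/0.01)
for controlled comparisons; stratified runs default to Euclidean distance.

**Population variability.** Within-species interindividual variability per
cell type (mean Spearman distance of each individual's equalized pseudobulk
to the cross-individual mean) and mean-matched variance ranks (fraction of
the 100 nearest-mean genes with smaller variance, compared across species
by paired t-test).

**Directional sign tests.** A pluggable DE interface (internal NB-Wald and
Welch log-CPM backends, or an external table) feeds binomial sign tests of
down- vs up-regulated significant set members against the empirical
background frequency, gene-set collection scans with BH-FDR, hybrid-ASE
directionality tests, a Fisher exact coupling of derived lineage to allelic
direction, category splits, and a variant-count balance test with binomial
thinning.

**Synthetic data.** `sim_config()`/`simulate_dataset()` generate
multi-species cell matrices and ASE tables in which the per-type shift
scale is σ_c = σ₀ · p_c^(−γ), gene sets can carry planted directional
shifts coupled to cis effects, and all randomness flows from one root seed
through documented substreams — so recovery, calibration, fairness and
power are all testable offline.

## Worked example

```r
library(celltempo)
p <- exp(seq(log(0.3), log(0.02), length.out = 8)); p <- p / sum(p)
names(p) <- sprintf("t%02d", 1:8)
cfg <- sim_config(n_genes = 800, cell_type_proportions = p, gamma = 1,
                  sigma0 = 0.02, n_cells = 8000, n_individuals = 3, seed = 7)
sim <- simulate_dataset(cfg, with_ase = FALSE)
sim$cm
#> cell_matrix: 24000 cells x 800 genes; 3 species, 8 subclasses

params <- divergence_params(cells_per_type = 50, n_iterations = 20, seed = 1)
dt <- run_divergence(sim$cm, sim$ortholog_map, params,
                     species_pair = c("speciesA", "speciesB"))
head(dt$medians)
#>   cell_type      species_pair median_distance
#> 1       t01 speciesA:speciesB      0.05744136
#> 2       t02 speciesA:speciesB      0.05572232
#> 3       t03 speciesA:speciesB      0.07128928
#> 4       t04 speciesA:speciesB      0.08125724
#> 5       t05 speciesA:speciesB      0.11270880
#> 6       t06 speciesA:speciesB      0.20255959

props <- estimate_proportions(sim$cm, min_cells = 50,
                              species_pair = c("speciesA", "speciesB"))
correlate(props, dt)
#> correlation_result: median rho = -0.988, median P = 0.000223 (8 types, 20 iterations)
```

Median per-type distance rises as the generating proportion falls (t01 is
the most abundant type, t08 the rarest), and the abundance-divergence
correlation recovers the planted inverse relationship (γ = 1) as a strongly
negative median ρ with its median P across the 20 downsampling iterations.

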