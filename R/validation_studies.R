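# Built-in validation studies: fixed simulation protocols exercising the
# pipeline end to end. Each returns the quantities a calibration or
# recovery analysis needs; the test suite and the acceptance script share
# these definitions so the study conditions are stated once.

#' Recovery study: planted abundance-divergence relationship
#'
#' The standard recovery simulation (the [sim_config()] defaults: 2,000
#' genes, 12 cell types with proportions log-spaced 0.3 to 0.005, gamma = 1,
#' 30,000 cells and 4 individuals per species) followed by the divergence
#' protocol (100 cells per type so every planted type qualifies, 100
#' iterations, Spearman distance) and the abundance correlation.
#'
#' @param seed Root seed.
#' @param n_iterations Downsampling iterations.
#' @return List: `median_rho`, `median_p`, `n_types`, `rank_recovery`
#'   (Spearman correlation between per-type median distance and the planted
#'   noise-free divergence).
#' @export
recovery_study <- function(seed, n_iterations = 100) {
  cfg <- sim_config(seed = seed)
  prof <- simulate_expression_profiles(cfg)
  cm <- simulate_cells(prof, cfg,
                       species_subset = c(cfg$species[["ingroup1"]],
                                          cfg$species[["ingroup2"]]))
  pair <- unname(cfg$species[c("ingroup1", "ingroup2")])
  params <- divergence_params(cells_per_type = 100,
                              n_iterations = n_iterations,
                              seed = substream_seed(seed, 7001))
  dt <- run_divergence(cm, NULL, params, pair)
  props <- estimate_proportions(cm, min_cells = 100, species_pair = pair)
  cr <- correlate(props, dt)
  td <- true_divergence(prof$truth)
  med <- setNames(dt$medians$median_distance, dt$medians$cell_type)
  shared <- intersect(names(td), names(med))
  list(median_rho = cr$median_rho, median_p = cr$median_p,
       n_types = cr$n_types,
       rank_recovery = cor(td[shared], med[shared], method = "spearman"))
}

#' Null-calibration study: no abundance-divergence relationship
#'
#' One replicate of the gamma = 0 design used to check that the pipeline's
#' median P-values are honest when every cell type shares the same planted
#' divergence scale: 10 types with proportions log-spaced 0.25 to 0.02,
#' 250 genes, sigma0 = 0.5, 4,000 cells and 3 individuals per species;
#' 50 cells per type, 10 iterations. Deep per-iteration sampling keeps the
#' median correlation close to a single draw from its null distribution.
#'
#' @param seed Root seed for the replicate.
#' @return List: `median_rho`, `median_p`.
#' @export
null_calibration_study <- function(seed) {
  p <- exp(seq(log(0.25), log(0.02), length.out = 10))
  p <- p / sum(p)
  names(p) <- sprintf("t%02d", 1:10)
  cfg <- sim_config(n_genes = 250, cell_type_proportions = p, gamma = 0,
                    sigma0 = 0.5, n_cells = 4000, n_individuals = 3,
                    individual_effect_sd = 0.05,
                    library_size_log_mean = log(800), seed = seed)
  prof <- simulate_expression_profiles(cfg)
  cm <- simulate_cells(prof, cfg,
                       species_subset = c("speciesA", "speciesB"))
  params <- divergence_params(cells_per_type = 50, n_iterations = 10,
                              seed = substream_seed(seed, 7002))
  dt <- run_divergence(cm, NULL, params, c("speciesA", "speciesB"))
  pr <- estimate_proportions(cm, min_cells = 50,
                             species_pair = c("speciesA", "speciesB"))
  cr <- correlate(pr, dt)
  list(median_rho = cr$median_rho, median_p = cr$median_p)
}

#' Fairness study: equalization removes abundance bias
#'
#' One replicate of the equal-divergence design probing whether the
#' downsampling protocol itself induces a spurious abundance-divergence
#' trend: 16 types spanning a 60-fold proportion range (0.24 to 0.004,
#' renormalized), identical shift scale sigma0 = 0.15 for every type
#' (gamma = 0), 500 genes, 15,000 cells per species, no individual effects
#' (so only protocol-induced bias is visible), 15 cells per type, 15
#' iterations. Shallow per-iteration sampling dominates the fixed
#' between-type variation, so the median correlation concentrates near 0
#' when the protocol is unbiased.
#'
#' @param seed Root seed for the replicate.
#' @return List: `median_rho`, `median_p`.
#' @export
fairness_study <- function(seed) {
  p <- exp(seq(log(0.24), log(0.004), length.out = 16))
  p <- p / sum(p)
  names(p) <- sprintf("t%02d", 1:16)
  cfg <- sim_config(n_genes = 500, cell_type_proportions = p, gamma = 0,
                    sigma0 = 0.15, n_cells = 15000, n_individuals = 3,
                    individual_effect_sd = 0,
                    library_size_log_mean = log(600), seed = seed)
  prof <- simulate_expression_profiles(cfg)
  cm <- simulate_cells(prof, cfg,
                       species_subset = c("speciesA", "speciesB"))
  params <- divergence_params(cells_per_type = 15, n_iterations = 15,
                              seed = substream_seed(seed, 7003))
  dt <- run_divergence(cm, NULL, params, c("speciesA", "speciesB"))
  pr <- estimate_proportions(cm, min_cells = 15,
                             species_pair = c("speciesA", "speciesB"))
  cr <- correlate(pr, dt)
  list(median_rho = cr$median_rho, median_p = cr$median_p)
}

#' Neutral differential-expression fixture for sign-test calibration
#'
#' A single-cell-type simulation with substantial undirected expression
#' divergence (sigma0 = 0.5 on both lineages, 3,000 genes, 4 individuals
#' per species), from which per-individual pseudobulk DE supplies many
#' significant genes with no set-level directionality.
#'
#' @param seed Root seed.
#' @return A `de_result` from the Welch log-CPM backend.
#' @export
neutral_de_study <- function(seed) {
  cfg <- sim_config(n_genes = 3000, cell_type_proportions = c(only = 1),
                    cell_type_classes = c(only = "excitatory"),
                    gamma = 0, sigma0 = 0.5, n_cells = 6000,
                    n_individuals = 4, individual_effect_sd = 0.1,
                    library_size_log_mean = log(1000), seed = seed)
  prof <- simulate_expression_profiles(cfg)
  cm <- simulate_cells(prof, cfg,
                       species_subset = c("speciesA", "speciesB"))
  pb <- pseudobulk_by_individual(cm, c("speciesA", "speciesB"), "only")
  differential_expression(pb$counts, pb$group, backend = "welch_logcpm")
}

#' Neutral hybrid-ASE fixture for sign-test calibration
#'
#' Hybrid allelic counts with symmetric cis divergence (cis_sd = 0.7, 3,000
#' genes, no planted set), yielding many genes with significant allelic
#' imbalance but no directional bias.
#'
#' @param seed Root seed.
#' @return An `ase_direction` table.
#' @export
neutral_ase_study <- function(seed) {
  cfg <- sim_config(n_genes = 3000, cell_type_proportions = c(only = 1),
                    cell_type_classes = c(only = "excitatory"),
                    n_cells = 10, seed = seed)
  prof <- simulate_expression_profiles(cfg)
  ase_direction(simulate_ase(prof$truth, cfg)$ase)
}

#' Planted-selection ASE study: directional shift in one gene set
#'
#' One replicate of the selection-detection design: 2,000 genes, a planted
#' set of `set_size` genes with mean allelic log2 shift `mean_shift`
#' (SD 0.1) coupled to the ingroup1 lineage (kappa = 1), hybrid ASE under
#' the default organoid-like conditions (8 samples over 4 lines, negative-
#' binomial depth with mean 500, beta-binomial overdispersion 0.01,
#' background cis SD 0.7). Runs the ASE sign test on the planted set and a
#' scan against `n_neutral_sets` random same-sized sets.
#'
#' @param seed Root seed for the replicate.
#' @param set_size Planted set size.
#' @param mean_shift Planted mean allelic log2 shift.
#' @param n_neutral_sets Random competitor sets in the scan.
#' @return List: `p` (planted-set sign-test P), `n_down`, `n_up`,
#'   `planted_first` (planted set attains the smallest scan P).
#' @export
planted_selection_study <- function(seed, set_size = 50,
                                    mean_shift = -0.3,
                                    n_neutral_sets = 50) {
  cfg <- sim_config(n_genes = 2000, cell_type_proportions = c(only = 1),
                    cell_type_classes = c(only = "excitatory"),
                    gamma = 0, sigma0 = 0.3, n_cells = 10,
                    n_individuals = 2, seed = seed,
                    biased_set = list(genes = set_size,
                                      lineage = "ingroup1",
                                      mean_shift = mean_shift, sd = 0.1))
  prof <- simulate_expression_profiles(cfg)
  ad <- ase_direction(simulate_ase(prof$truth, cfg)$ase)
  st <- ase_sign_test(ad, prof$truth$biased_genes)
  pool <- setdiff(ad$gene_id, prof$truth$biased_genes)
  sets <- c(list(planted = prof$truth$biased_genes),
            with_seed(substream_seed(seed, 7004), {
              setNames(lapply(seq_len(n_neutral_sets),
                              function(i) sample(pool, set_size)),
                       sprintf("neutral%02d", seq_len(n_neutral_sets)))
            }))
  sc <- scan_gene_sets(ad, sets, min_size = set_size)
  list(p = st$p, n_down = st$n_down, n_up = st$n_up,
       planted_first = identical(sc$set[which.min(sc$p)], "planted"))
}
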