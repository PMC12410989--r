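# Shared small fixtures built in code.

tiny_cell_matrix <- function() {
  counts <- matrix(c(1, 0, 2, 0,
                     0, 3, 0, 1,
                     4, 0, 0, 2), nrow = 3, byrow = TRUE)
  meta <- data.frame(
    cell_id = c("c1", "c2", "c3"),
    species = c("spA", "spA", "spB"),
    individual = c("i1", "i2", "i3"),
    subclass = c("T1", "T1", "T1"),
    subtype = c("T1.1", "T1.1", "T1.1"),
    stringsAsFactors = FALSE
  )
  cell_matrix(counts, paste0("g", 1:4), meta)
}

small_sim <- function(seed = 1, n_genes = 300, n_types = 6,
                      n_cells = 2500, gamma = 1, sigma0 = 0.03,
                      with_ase = FALSE, ...) {
  p <- exp(seq(log(0.3), log(0.03), length.out = n_types))
  p <- p / sum(p)
  names(p) <- sprintf("t%02d", seq_len(n_types))
  cfg <- sim_config(n_genes = n_genes, cell_type_proportions = p,
                    gamma = gamma, sigma0 = sigma0, n_cells = n_cells,
                    n_individuals = 3,
                    library_size_log_mean = log(600), seed = seed, ...)
  simulate_dataset(cfg, with_ase = with_ase)
}

sim_pair <- c("speciesA", "speciesB")
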