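# Synthetic multi-species snRNA-seq and hybrid-ASE generator with planted
# ground truth. Emulates the statistical structure the analysis assumes:
# multinomial per-cell sampling from species/cell-type/individual log2
# expression profiles, lineage shifts whose scale grows as cell-type
# proportion shrinks (sigma_c = sigma0 * p_c^-gamma), planted directional
# shifts in a designated gene set, and beta-binomial allelic imbalance
# coupled to the planted cis effects.

#' Simulation configuration
#'
#' Defaults define the standard recovery-scale simulation: 2,000 genes,
#' 12 cell types with proportions log-spaced from 0.3 down to 0.005
#' (renormalized to sum to 1), two ingroup species plus an outgroup,
#' 30,000 cells and 4 individuals per species.
#'
#' @param n_genes Number of genes.
#' @param species Named character vector with entries `ingroup1`, `ingroup2`
#'   and optionally `outgroup` giving species labels.
#' @param branch_lengths Named numeric vector (same names as `species`) in
#'   expression-divergence units; a lineage's per-gene shift SD is
#'   `sigma_c * branch_length`.
#' @param cell_type_proportions Named numeric vector of proportions summing
#'   to 1 (within 1e-9).
#' @param cell_type_classes Named character vector mapping each cell type to
#'   a class label (e.g. excitatory/inhibitory).
#' @param gamma Divergence exponent; per-type shift scale is
#'   `sigma0 * p_c^(-gamma)`. `gamma = 0` makes all types share `sigma0`.
#' @param sigma0 Baseline shift SD (log2 units) for a type with proportion 1.
#' @param n_cells Cells per species.
#' @param n_individuals Individuals per species.
#' @param library_size_log_mean,library_size_log_sd Lognormal library-size
#'   parameters (natural-log scale).
#' @param individual_effect_sd SD of per-(gene, type, individual) log2 offsets.
#' @param gene_base_sd SD of per-gene baseline log2 expression.
#' @param type_effect_sd SD of per-(gene, type) log2 deviations; controls how
#'   cell-type specific expression is (hence the tau distribution).
#' @param biased_set Optional list with `genes` (ids or an integer count to
#'   pick), `lineage` (`"ingroup1"` or `"ingroup2"`), `mean_shift` (log2) and
#'   `sd`; these genes receive a directional shift on that lineage, shared
#'   across cell types.
#' @param ase List of hybrid-ASE parameters: `n_samples`, `n_lines`,
#'   `depth_mean` and `depth_size` (negative-binomial total counts),
#'   `rho` (beta-binomial overdispersion), `kappa` (coupling of cis effects
#'   to planted lineage shifts for biased-set genes), `cis_sd` (SD of
#'   background cis effects, log2), `cis_noise_sd` (residual noise on coupled
#'   cis effects).
#' @param seed Root seed; all randomness flows from it via documented
#'   substreams.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       species = c(ingroup1 = "speciesA",
                                   ingroup2 = "speciesB",
                                   outgroup = "speciesC"),
                       branch_lengths = c(ingroup1 = 1, ingroup2 = 1,
                                          outgroup = 2),
                       cell_type_proportions = NULL,
                       cell_type_classes = NULL,
                       gamma = 1,
                       sigma0 = 0.01,
                       n_cells = 30000,
                       n_individuals = 4,
                       library_size_log_mean = log(1000),
                       library_size_log_sd = 0.35,
                       individual_effect_sd = 0.05,
                       gene_base_sd = 1.5,
                       type_effect_sd = 0.75,
                       biased_set = NULL,
                       ase = list(),
                       seed = 1) {
  if (is.null(cell_type_proportions)) {
    p <- exp(seq(log(0.3), log(0.005), length.out = 12))
    p <- p / sum(p)
    names(p) <- sprintf("type%02d", seq_along(p))
    cell_type_proportions <- p
  }
  if (is.null(names(cell_type_proportions))) {
    names(cell_type_proportions) <-
      sprintf("type%02d", seq_along(cell_type_proportions))
  }
  if (any(cell_type_proportions <= 0)) {
    stop("cell type proportions must be positive")
  }
  if (abs(sum(cell_type_proportions) - 1) > 1e-9) {
    stop("cell type proportions must sum to 1 (within 1e-9)")
  }
  if (gamma < 0) stop("gamma must be >= 0")
  if (sigma0 <= 0) stop("sigma0 must be > 0")
  if (is.null(seed)) stop("seed must be set")
  if (is.null(cell_type_classes)) {
    n_t <- length(cell_type_proportions)
    cls <- rep(c("excitatory", "inhibitory"),
               c(ceiling(n_t / 2), floor(n_t / 2)))
    cell_type_classes <- setNames(cls, names(cell_type_proportions))
  }
  if (!all(names(cell_type_proportions) %in% names(cell_type_classes))) {
    stop("cell_type_classes must cover every cell type")
  }
  stopifnot(all(c("ingroup1", "ingroup2") %in% names(species)))
  ase_defaults <- list(n_samples = 8, n_lines = 4, depth_mean = 500,
                       depth_size = 5, rho = 0.01, kappa = 1,
                       cis_sd = 0.7, cis_noise_sd = 0.05)
  ase <- modifyList(ase_defaults, ase)
  cfg <- list(
    n_genes = n_genes, species = species, branch_lengths = branch_lengths,
    cell_type_proportions = cell_type_proportions,
    cell_type_classes = cell_type_classes,
    gamma = gamma, sigma0 = sigma0, n_cells = n_cells,
    n_individuals = n_individuals,
    library_size_log_mean = library_size_log_mean,
    library_size_log_sd = library_size_log_sd,
    individual_effect_sd = individual_effect_sd,
    gene_base_sd = gene_base_sd, type_effect_sd = type_effect_sd,
    biased_set = biased_set, ase = ase, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

sim_gene_ids <- function(config) sprintf("g%05d", seq_len(config$n_genes))

#' Simulate per-(species, cell type, individual) log2 expression profiles
#'
#' Ancestral log2 expression per (gene, type) is drawn once; each lineage
#' adds Normal(0, sigma_c * branch_length) shifts per gene and type, except
#' biased-set genes on their designated lineage, which add a directional
#' Normal(mean_shift, sd) shift shared across cell types. Individual effects
#' are added per (gene, type, individual).
#'
#' @param config A [sim_config()].
#' @return List with `profiles` (per species, an array gene x type x
#'   individual of log2 expression), `species_profiles` (noise-free gene x
#'   type log2 expression per species) and `truth` (class `sim_truth`:
#'   `sigma_c`, per-lineage shift matrices `delta`, biased-set membership and
#'   shared biased shifts).
#' @export
simulate_expression_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$n_genes
  types <- names(config$cell_type_proportions)
  n_t <- length(types)
  gene_ids <- sim_gene_ids(config)
  sigma_c <- config$sigma0 * config$cell_type_proportions^(-config$gamma)

  ancestral <- with_seed(substream_seed(config$seed, 1), {
    base <- rnorm(g, mean = 3, sd = config$gene_base_sd)
    base + matrix(rnorm(g * n_t, sd = config$type_effect_sd), g, n_t)
  })
  dimnames(ancestral) <- list(gene_ids, types)

  biased <- config$biased_set
  biased_genes <- character(0)
  biased_shift <- NULL
  if (!is.null(biased)) {
    biased_genes <- if (is.numeric(biased$genes) && length(biased$genes) == 1) {
      with_seed(substream_seed(config$seed, 2),
                sample(gene_ids, biased$genes))
    } else as.character(biased$genes)
    biased_shift <- with_seed(
      substream_seed(config$seed, 3),
      setNames(rnorm(length(biased_genes), biased$mean_shift,
                     biased$sd %||% 0), biased_genes)
    )
  }

  lineages <- names(config$species)
  delta <- list()
  for (k in seq_along(lineages)) {
    l <- lineages[[k]]
    b <- config$branch_lengths[[l]]
    d <- with_seed(substream_seed(config$seed, 10 + k), {
      matrix(rnorm(g * n_t), g, n_t) *
        matrix(rep(sigma_c * b, each = g), g, n_t)
    })
    dimnames(d) <- list(gene_ids, types)
    if (!is.null(biased) && identical(biased$lineage, l)) {
      d[biased_genes, ] <- matrix(rep(biased_shift, n_t),
                                  length(biased_genes), n_t)
    }
    delta[[l]] <- d
  }

  species_profiles <- lapply(lineages, function(l) ancestral + delta[[l]])
  names(species_profiles) <- config$species[lineages]

  profiles <- list()
  for (k in seq_along(lineages)) {
    l <- lineages[[k]]
    sp <- config$species[[l]]
    arr <- array(NA_real_, dim = c(g, n_t, config$n_individuals),
                 dimnames = list(gene_ids, types, NULL))
    for (i in seq_len(config$n_individuals)) {
      ind_eff <- with_seed(
        substream_seed(config$seed, 100 + 20 * k + i),
        matrix(rnorm(g * n_t, sd = config$individual_effect_sd), g, n_t)
      )
      arr[, , i] <- species_profiles[[sp]] + ind_eff
    }
    profiles[[sp]] <- arr
  }

  truth <- structure(list(
    sigma_c = sigma_c,
    delta = delta,
    ancestral = ancestral,
    species_profiles = species_profiles,
    biased_genes = biased_genes,
    biased_shift = biased_shift,
    gene_ids = gene_ids,
    config = config
  ), class = "sim_truth")

  list(profiles = profiles, species_profiles = species_profiles,
       truth = truth)
}

#' Noise-free per-type divergence implied by the planted truth
#'
#' Distance between the two ingroup species' noise-free log2 profiles,
#' computed per cell type. With `gamma > 0` this is strictly increasing as
#' the type proportion decreases (in expectation), the monotone structure
#' the pipeline must recover.
#'
#' @param truth A `sim_truth`.
#' @param metric `"euclidean"` or `"spearman_distance"`.
#' @return Named numeric vector, one distance per cell type.
#' @export
true_divergence <- function(truth, metric = "euclidean") {
  cfg <- truth$config
  sp1 <- cfg$species[["ingroup1"]]
  sp2 <- cfg$species[["ingroup2"]]
  x <- truth$species_profiles[[sp1]]
  y <- truth$species_profiles[[sp2]]
  vapply(colnames(x), function(ct) {
    if (metric == "euclidean") sqrt(sum((x[, ct] - y[, ct])^2))
    else 1 - cor(x[, ct], y[, ct], method = "spearman")
  }, 0)
}

#' Simulate cells by multinomial sampling from expression profiles
#'
#' Each cell draws its type from the configured proportions, its individual
#' uniformly, a lognormal library size, and gene counts from a multinomial
#' whose probabilities are the base-2 softmax of the cell's (species, type,
#' individual) log2 expression profile.
#'
#' @param profiles Output of [simulate_expression_profiles()] (the `profiles`
#'   element), or the full list.
#' @param config The same [sim_config()].
#' @param species_subset Optional species labels to simulate (default all);
#'   each species uses its own seed substream, so a subset reproduces that
#'   species of the full run exactly.
#' @return A [cell_matrix()] covering the selected species.
#' @export
simulate_cells <- function(profiles, config, species_subset = NULL) {
  if (!is.null(profiles$profiles)) profiles <- profiles$profiles
  gene_ids <- sim_gene_ids(config)
  types <- names(config$cell_type_proportions)
  n_t <- length(types)
  n_g <- config$n_genes
  species_labels <- unname(config$species)
  if (!is.null(species_subset)) {
    stopifnot(all(species_subset %in% species_labels))
  }

  all_i <- list(); all_j <- list(); all_x <- list()
  meta_list <- list()
  row_offset <- 0L
  for (si in seq_along(species_labels)) {
    sp <- species_labels[[si]]
    if (!is.null(species_subset) && !(sp %in% species_subset)) next
    arr <- profiles[[sp]]
    seed_sp <- substream_seed(config$seed, 1000 + si)
    res <- with_seed(seed_sp, {
      type_idx <- sample.int(n_t, config$n_cells, replace = TRUE,
                             prob = config$cell_type_proportions)
      ind_idx <- sample.int(config$n_individuals, config$n_cells,
                            replace = TRUE)
      libs <- pmax(1L, as.integer(round(rlnorm(
        config$n_cells, config$library_size_log_mean,
        config$library_size_log_sd))))
      # one read-level multinomial draw per (type, individual) group;
      # consecutive blocks of a group's reads belong to its cells, which
      # yields exact independent per-cell multinomials
      ti_l <- list(); tj_l <- list(); tx_l <- list(); gi <- 0L
      for (ci in seq_len(n_t)) for (ii in seq_len(config$n_individuals)) {
        cells_g <- which(type_idx == ci & ind_idx == ii)
        if (!length(cells_g)) next
        v <- 2^(arr[, ci, ii] - max(arr[, ci, ii]))
        p <- v / sum(v)
        L <- libs[cells_g]
        draws <- sample.int(n_g, sum(L), replace = TRUE, prob = p)
        cellrep <- rep.int(seq_along(cells_g), L)
        m <- Matrix::sparseMatrix(i = cellrep, j = draws, x = 1,
                                  dims = c(length(cells_g), n_g))
        trip <- Matrix::summary(m)
        gi <- gi + 1L
        ti_l[[gi]] <- cells_g[trip$i]
        tj_l[[gi]] <- trip$j
        tx_l[[gi]] <- trip$x
      }
      list(type_idx = type_idx, ind_idx = ind_idx,
           i = unlist(ti_l, use.names = FALSE),
           j = unlist(tj_l, use.names = FALSE),
           x = unlist(tx_l, use.names = FALSE))
    })
    all_i[[length(all_i) + 1L]] <- row_offset + res$i
    all_j[[length(all_j) + 1L]] <- res$j
    all_x[[length(all_x) + 1L]] <- res$x
    meta_list[[length(meta_list) + 1L]] <- data.frame(
      cell_id = sprintf("%s_c%06d", sp, seq_len(config$n_cells)),
      species = sp,
      individual = sprintf("%s_ind%d", sp, res$ind_idx),
      subclass = types[res$type_idx],
      subtype = paste0(types[res$type_idx], ".1"),
      class = unname(config$cell_type_classes[types[res$type_idx]]),
      stringsAsFactors = FALSE
    )
    row_offset <- row_offset + config$n_cells
  }
  counts <- Matrix::sparseMatrix(
    i = unlist(all_i, use.names = FALSE),
    j = unlist(all_j, use.names = FALSE),
    x = as.double(unlist(all_x, use.names = FALSE)),
    dims = c(row_offset, n_g)
  )
  cell_matrix(counts, gene_ids, do.call(rbind, meta_list))
}

#' Simulate hybrid allele-specific expression counts
#'
#' Per-gene cis effects (log2 allelic fold-changes, allele of `ingroup1`
#' over allele of `ingroup2`) are `kappa * planted_shift + noise` for
#' biased-set genes and Normal(0, cis_sd) otherwise. Per (gene, sample),
#' total counts are negative binomial and allele-1 counts beta-binomial with
#' mean `2^cis / (1 + 2^cis)` and overdispersion `rho`.
#'
#' @param truth A `sim_truth` from [simulate_expression_profiles()].
#' @param config The same [sim_config()].
#' @return List with `ase` (an `ase_table`) and `cis` (named true cis
#'   effects); `cis` is also attached to the returned truth via
#'   `attr(, "cis")`.
#' @export
simulate_ase <- function(truth, config = truth$config) {
  gene_ids <- truth$gene_ids
  g <- length(gene_ids)
  a <- config$ase
  cis <- with_seed(substream_seed(config$seed, 2001), {
    v <- rnorm(g, 0, a$cis_sd)
    names(v) <- gene_ids
    if (length(truth$biased_genes)) {
      v[truth$biased_genes] <- a$kappa * truth$biased_shift +
        rnorm(length(truth$biased_genes), 0, a$cis_noise_sd)
    }
    v
  })
  tab <- with_seed(substream_seed(config$seed, 2002), {
    n_s <- a$n_samples
    lines <- sprintf("line%d", ((seq_len(n_s) - 1L) %% a$n_lines) + 1L)
    p_h <- 2^cis / (1 + 2^cis)
    shape1 <- p_h * (1 - a$rho) / a$rho
    shape2 <- (1 - p_h) * (1 - a$rho) / a$rho
    recs <- vector("list", n_s)
    for (s in seq_len(n_s)) {
      total <- rnbinom(g, mu = a$depth_mean, size = a$depth_size)
      q <- rbeta(g, shape1, shape2)
      a1 <- rbinom(g, total, q)
      recs[[s]] <- data.frame(
        gene_id = gene_ids,
        sample = sprintf("s%02d", s),
        line = lines[s],
        timepoint = "d100",
        allele1_count = a1,
        allele2_count = total - a1,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, recs)
  })
  list(ase = ase_table(tab), cis = cis)
}

#' Identity ortholog map for simulated data
#'
#' Simulated gene ids are shared across species; the map has one column per
#' species, all protein-coding and non-mitochondrial.
#'
#' @param config A [sim_config()].
#' @return An `ortholog_map`.
#' @export
sim_ortholog_map <- function(config) {
  gene_ids <- sim_gene_ids(config)
  cols <- setNames(rep(list(gene_ids), length(config$species)),
                   unname(config$species))
  map <- as.data.frame(cols, stringsAsFactors = FALSE,
                       check.names = FALSE)
  map$protein_coding <- TRUE
  map$mitochondrial <- FALSE
  ortholog_map(map)
}

#' Run the full generator: profiles, cells, ASE, truth
#'
#' @param config A [sim_config()].
#' @param with_cells Simulate the cell matrix (the expensive part).
#' @param with_ase Simulate the hybrid ASE table.
#' @return List with `cm`, `ase`, `cis`, `truth`, `ortholog_map`, `config`.
#' @export
simulate_dataset <- function(config, with_cells = TRUE, with_ase = TRUE) {
  prof <- simulate_expression_profiles(config)
  cm <- if (with_cells) simulate_cells(prof$profiles, config) else NULL
  ase <- NULL; cis <- NULL
  if (with_ase) {
    sim_a <- simulate_ase(prof$truth, config)
    ase <- sim_a$ase; cis <- sim_a$cis
  }
  list(cm = cm, ase = ase, cis = cis, truth = prof$truth,
       ortholog_map = sim_ortholog_map(config), config = config)
}

#' Write a simulated dataset to disk in the package's on-disk dialects
#'
#' Cell matrix as mtx+tsv, ASE table and ortholog map as TSV, truth as
#' TSV + JSON.
#'
#' @param sim Output of [simulate_dataset()].
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(sim$cm)) {
    write_cell_matrix(sim$cm, file.path(path, "matrix"))
  }
  if (!is.null(sim$ase)) {
    write_ase_table(sim$ase, file.path(path, "ase.tsv"))
  }
  write_ortholog_map(sim$ortholog_map, file.path(path, "orthologs.tsv"))
  truth_tab <- data.frame(
    cell_type = names(sim$truth$sigma_c),
    sigma_c = unname(sim$truth$sigma_c),
    proportion = unname(sim$config$cell_type_proportions)
  )
  write.table(truth_tab, file.path(path, "truth_cell_types.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = sim$config$seed,
         gamma = sim$config$gamma,
         sigma0 = sim$config$sigma0,
         biased_genes = sim$truth$biased_genes,
         n_genes = sim$config$n_genes),
    file.path(path, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
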