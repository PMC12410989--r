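# Downsampling-equalized per-cell-type expression divergence between species.
# Protocol per iteration: downsample cells within each (cell type, species)
# stratum to a fixed number, pseudobulk, downsample pseudobulk counts to the
# minimum total across all included (type, species) profiles, filter genes,
# transform, and compute a distance. Medians are taken over iterations.

#' Divergence estimation parameters
#'
#' @param cells_per_type Cells sampled per (type, species) stratum; strata
#'   below this are excluded. Canonical values are 50, 100, 250, 500
#'   (250 at subclass level, 50 at subtype level by convention).
#' @param min_counts Gene filter: a gene is removed for a cell type if it has
#'   fewer than `min_counts` counts in both species.
#' @param min_cpm As above, on the CPM scale; the two rules are OR-combined.
#' @param transform `"log2"` (log2(CPM + pseudocount)) or `"none"`. The
#'   pseudocount is irrelevant to the rank-based default metric.
#' @param log_pseudocount Pseudocount under the log2 transform.
#' @param metric One of `"spearman_distance"`, `"pearson_distance"`,
#'   `"euclidean"`, `"l1"`.
#' @param n_iterations Independent downsampling iterations (default 100).
#' @param seed Root seed; iteration i uses substream (seed, i).
#' @param count_mode `"hypergeometric"` (reads sampled without replacement,
#'   the default) or `"multinomial"` (with replacement).
#' @param blacklist Cell-type labels excluded from comparisons (e.g. immune
#'   populations, whose proportions are not stable).
#' @return List of class `divergence_params`.
#' @export
divergence_params <- function(cells_per_type = 250,
                              min_counts = 25,
                              min_cpm = 1,
                              transform = c("log2", "none"),
                              log_pseudocount = 1,
                              metric = c("spearman_distance",
                                         "pearson_distance",
                                         "euclidean", "l1"),
                              n_iterations = 100,
                              seed = 1,
                              count_mode = c("hypergeometric",
                                             "multinomial"),
                              blacklist = c("Micro-PVM", "Micro/PVM",
                                            "Immune")) {
  transform <- match.arg(transform)
  metric <- match.arg(metric)
  count_mode <- match.arg(count_mode)
  stopifnot(cells_per_type >= 1, n_iterations >= 1)
  structure(list(cells_per_type = as.integer(cells_per_type),
                 min_counts = min_counts, min_cpm = min_cpm,
                 transform = transform, log_pseudocount = log_pseudocount,
                 metric = metric, n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), count_mode = count_mode,
                 blacklist = blacklist),
            class = "divergence_params")
}

meta_level <- function(cm, level = c("subclass", "subtype")) {
  level <- match.arg(level)
  labels <- cm$cell_meta[[level]]
  if (level == "subtype" && anyNA(labels)) {
    stop_named("celltempo_missing_metadata",
               "subtype labels are missing for some cells")
  }
  labels
}

#' Downsample cells within one (cell type, species) stratum
#'
#' Samples exactly `n` cells without replacement; deterministic given `seed`.
#'
#' @param cm A [cell_matrix()].
#' @param cell_type,species Stratum labels.
#' @param n Cells to retain.
#' @param seed Seed.
#' @param level Clustering granularity to match `cell_type` against.
#' @return A [cell_matrix()] subset of exactly `n` cells.
#' @export
downsample_cells <- function(cm, cell_type, species, n, seed,
                             level = "subclass") {
  labels <- meta_level(cm, level)
  idx <- which(labels == cell_type & cm$cell_meta$species == species)
  if (length(idx) < n) {
    stop_named("celltempo_insufficient_cells",
               "stratum (", cell_type, ", ", species, ") has ",
               length(idx), " cells, fewer than n = ", n)
  }
  take <- if (length(idx) == n) idx else
    with_seed(seed, idx[sample.int(length(idx), n)])
  cell_matrix(cm$counts[take, , drop = FALSE], cm$gene_ids,
              cm$cell_meta[take, , drop = FALSE])
}

# Aligned gene indices: for each species, the column indices in cm$counts of
# the one-to-one protein-coding non-mitochondrial orthologs, ordered by
# ortholog record. Returns list(record_ids, index = named list per species).
aligned_gene_index <- function(cm, ortholog_map, species) {
  if (is.null(ortholog_map)) {
    idx <- setNames(rep(list(seq_along(cm$gene_ids)), length(species)),
                    species)
    return(list(record_ids = cm$gene_ids, index = idx))
  }
  keep <- rep(TRUE, nrow(ortholog_map))
  if ("protein_coding" %in% names(ortholog_map)) {
    keep <- keep & ortholog_map$protein_coding
  }
  if ("mitochondrial" %in% names(ortholog_map)) {
    keep <- keep & !ortholog_map$mitochondrial
  }
  map <- as.data.frame(ortholog_map)[keep, , drop = FALSE]
  sp_cols <- intersect(attr(ortholog_map, "species_cols") %||% names(map),
                       names(map))
  missing_sp <- setdiff(species, sp_cols)
  if (length(missing_sp)) {
    stop_named("celltempo_unknown_species",
               "ortholog map lacks species column(s): ",
               paste(missing_sp, collapse = ", "))
  }
  pos <- lapply(species, function(sp) match(map[[sp]], cm$gene_ids))
  ok <- Reduce(`&`, lapply(pos, function(p) !is.na(p)))
  if (!any(ok)) {
    stop_named("celltempo_empty_ortholog_intersection",
               "no ortholog-map genes found in the matrix for all species")
  }
  idx <- setNames(lapply(pos, function(p) p[ok]), species)
  list(record_ids = map[[species[[1]]]][ok], index = idx)
}

#' Pseudobulk expression profiles
#'
#' Sums counts across all cells within each (cell type, species) group,
#' restricted to one-to-one protein-coding non-mitochondrial orthologs and
#' with gene order aligned across species via the ortholog map.
#'
#' @param cm A [cell_matrix()] (typically a downsampled subset).
#' @param ortholog_map An `ortholog_map`, or NULL when gene ids are already
#'   shared across species.
#' @param level Clustering granularity.
#' @return List of class `pseudobulk_profiles`: `counts` (genes x profiles
#'   matrix, rows named by ortholog record), `meta` (data frame with
#'   `cell_type`, `species`, `total_counts`).
#' @export
pseudobulk <- function(cm, ortholog_map = NULL, level = "subclass") {
  labels <- meta_level(cm, level)
  species <- sort(unique(cm$cell_meta$species))
  ag <- aligned_gene_index(cm, ortholog_map, species)
  groups <- unique(data.frame(cell_type = labels,
                              species = cm$cell_meta$species,
                              stringsAsFactors = FALSE))
  groups <- groups[order(groups$cell_type, groups$species), , drop = FALSE]
  mat <- matrix(0, nrow = length(ag$record_ids), ncol = nrow(groups))
  for (k in seq_len(nrow(groups))) {
    rows <- which(labels == groups$cell_type[k] &
                    cm$cell_meta$species == groups$species[k])
    cols <- ag$index[[groups$species[k]]]
    mat[, k] <- Matrix::colSums(cm$counts[rows, cols, drop = FALSE])
  }
  rownames(mat) <- ag$record_ids
  groups$total_counts <- colSums(mat)
  structure(list(counts = mat, meta = groups),
            class = "pseudobulk_profiles")
}

#' Downsample pseudobulk profiles to a common total
#'
#' Each profile's reads are sampled without replacement (multivariate
#' hypergeometric) down to `target`, the minimum total across profiles by
#' default, so every profile in a comparison carries identical total counts.
#'
#' @param profiles A `pseudobulk_profiles`.
#' @param target Total to downsample to; defaults to the minimum.
#' @param seed Seed.
#' @param mode `"hypergeometric"` or `"multinomial"` (with replacement).
#' @return A `pseudobulk_profiles` with equalized totals.
#' @export
downsample_counts <- function(profiles, target = NULL, seed = 1,
                              mode = c("hypergeometric", "multinomial")) {
  mode <- match.arg(mode)
  totals <- profiles$meta$total_counts
  if (is.null(target)) target <- min(totals)
  if (any(totals < target)) {
    stop_named("celltempo_insufficient_counts",
               "target exceeds the total counts of some profile")
  }
  out <- profiles
  with_seed(seed, {
    for (k in seq_len(ncol(profiles$counts))) {
      x <- profiles$counts[, k]
      if (mode == "hypergeometric") {
        out$counts[, k] <- downsample_count_vector(x, target)
      } else {
        out$counts[, k] <- rmultinom(1L, target, x / sum(x))[, 1L]
      }
    }
  })
  out$meta$total_counts <- colSums(out$counts)
  out
}

#' Two-species gene filter
#'
#' A gene is removed for a cell type iff it has fewer than `min_counts`
#' counts in both species OR fewer than `min_cpm` CPM in both species; a
#' gene failing in one cell type can still pass in another.
#'
#' @param x,y Count vectors of the two species for one cell type (equalized
#'   totals).
#' @param min_counts,min_cpm Filter thresholds.
#' @return Logical mask of genes kept.
#' @export
filter_genes <- function(x, y, min_counts = 25, min_cpm = 1) {
  cx <- x * 1e6 / sum(x)
  cy <- y * 1e6 / sum(y)
  low_counts <- x < min_counts & y < min_counts
  low_cpm <- cx < min_cpm & cy < min_cpm
  !(low_counts | low_cpm)
}

#' Expression distance between two profiles
#'
#' @param x,y CPM-scaled expression vectors of equal length (>= 3).
#' @param metric `"spearman_distance"` (1 - Spearman's rho, average ranks for
#'   ties), `"pearson_distance"` (1 - Pearson's r), `"euclidean"`, `"l1"`.
#' @param transform `"log2"` or `"none"`; applied to both vectors before
#'   euclidean/l1 (rank-based metrics are unaffected).
#' @param log_pseudocount Pseudocount for the log2 transform.
#' @return Non-negative distance; correlation distances lie in [0, 2].
#' @export
expression_distance <- function(x, y,
                                metric = c("spearman_distance",
                                           "pearson_distance",
                                           "euclidean", "l1"),
                                transform = c("log2", "none"),
                                log_pseudocount = 1) {
  metric <- match.arg(metric)
  transform <- match.arg(transform)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) {
    stop_named("celltempo_too_few_genes",
               "need at least 3 genes to compute a distance")
  }
  if (transform == "log2") {
    x <- log2(x + log_pseudocount)
    y <- log2(y + log_pseudocount)
  }
  if (metric %in% c("spearman_distance", "pearson_distance")) {
    if (sd(x) == 0 || sd(y) == 0) {
      stop_named("celltempo_constant_vector",
                 "correlation distance undefined for a constant vector")
    }
    method <- if (metric == "spearman_distance") "spearman" else "pearson"
    return(1 - cor(x, y, method = method))
  }
  if (metric == "euclidean") return(sqrt(sum((x - y)^2)))
  sum(abs(x - y))
}

included_cell_types <- function(cm, species_pair, params,
                                level = "subclass") {
  labels <- meta_level(cm, level)
  tab <- table(labels, cm$cell_meta$species)
  types <- rownames(tab)
  types <- setdiff(types, params$blacklist)
  ok <- vapply(types, function(ct) {
    all(species_pair %in% colnames(tab)) &&
      all(tab[ct, species_pair] >= params$cells_per_type)
  }, TRUE)
  types[ok]
}

#' Run the downsampling-equalized divergence protocol
#'
#' For each iteration: downsample cells per (type, species), pseudobulk,
#' downsample counts to the global minimum across all included (type,
#' species) profiles, filter genes per cell type, transform, and compute the
#' configured distance. Per-type medians over iterations are recorded along
#' with all iteration-level values.
#'
#' @param cm A [cell_matrix()] holding both species.
#' @param ortholog_map An `ortholog_map` or NULL for shared gene ids.
#' @param params A [divergence_params()].
#' @param species_pair Character vector of two species labels.
#' @param level Clustering granularity.
#' @param gene_subset Optional: character vector, or named list (per cell
#'   type) of gene ids to restrict distances to, applied after the gene
#'   filter; cell types left with fewer than `min_stratum_genes` genes get
#'   NA distances.
#' @param min_stratum_genes Minimum genes for a restricted stratum.
#' @return List of class `divergence_table`: `values` (long data frame:
#'   cell_type, species_pair, iteration, distance, n_genes), `medians`,
#'   `params`, `cell_types`.
#' @export
run_divergence <- function(cm, ortholog_map = NULL, params = divergence_params(),
                           species_pair, level = "subclass",
                           gene_subset = NULL, min_stratum_genes = 50) {
  stopifnot(length(species_pair) == 2)
  types <- included_cell_types(cm, species_pair, params, level)
  if (!length(types)) {
    stop_named("celltempo_no_qualifying_types",
               "no cell type has >= ", params$cells_per_type,
               " cells in both species")
  }
  labels <- meta_level(cm, level)
  ag <- aligned_gene_index(cm, ortholog_map, species_pair)
  strata <- list()
  for (ct in types) for (sp in species_pair) {
    strata[[paste(ct, sp, sep = "\r")]] <-
      which(labels == ct & cm$cell_meta$species == sp)
  }
  n_types <- length(types)
  counts_t <- Matrix::t(cm$counts)  # genes x cells; column slicing is fast
  subset_idx <- NULL
  if (!is.null(gene_subset) && !is.list(gene_subset)) {
    gene_subset <- setNames(rep(list(gene_subset), n_types), types)
  }

  res <- vector("list", params$n_iterations)
  for (iter in seq_len(params$n_iterations)) {
    iter_seed <- substream_seed(params$seed, iter)
    res[[iter]] <- with_seed(iter_seed, {
      takes <- vector("list", 2L * n_types)
      for (ti in seq_len(n_types)) for (si in 1:2) {
        idx <- strata[[paste(types[ti], species_pair[si], sep = "\r")]]
        takes[[(ti - 1L) * 2L + si]] <-
          if (length(idx) == params$cells_per_type) idx else
            idx[sample.int(length(idx), params$cells_per_type)]
      }
      ind <- Matrix::sparseMatrix(
        i = unlist(takes), j = rep(seq_along(takes), lengths(takes)),
        x = 1, dims = c(ncol(counts_t), length(takes)))
      prof_all <- as.matrix(counts_t %*% ind)
      prof <- matrix(0, nrow = length(ag$record_ids), ncol = 2L * n_types)
      for (ti in seq_len(n_types)) for (si in 1:2) {
        k <- (ti - 1L) * 2L + si
        prof[, k] <- prof_all[ag$index[[species_pair[si]]], k]
      }
      totals <- colSums(prof)
      target <- min(totals)
      for (k in seq_len(ncol(prof))) {
        prof[, k] <- if (params$count_mode == "hypergeometric") {
          downsample_count_vector(prof[, k], target)
        } else {
          rmultinom(1L, as.integer(target), prof[, k] / sum(prof[, k]))[, 1L]
        }
      }
      out <- data.frame(cell_type = types,
                        species_pair = paste(species_pair, collapse = ":"),
                        iteration = iter,
                        distance = NA_real_, n_genes = NA_integer_,
                        stringsAsFactors = FALSE)
      for (ti in seq_len(n_types)) {
        x <- prof[, (ti - 1L) * 2L + 1L]
        y <- prof[, (ti - 1L) * 2L + 2L]
        mask <- filter_genes(x, y, params$min_counts, params$min_cpm)
        if (!is.null(gene_subset)) {
          keep_genes <- gene_subset[[types[ti]]]
          mask <- mask & (ag$record_ids %in% keep_genes)
          if (sum(mask) < min_stratum_genes) next
        }
        if (sum(mask) < 3) next
        d <- tryCatch(
          expression_distance(cpm(x)[mask], cpm(y)[mask],
                              metric = params$metric,
                              transform = params$transform,
                              log_pseudocount = params$log_pseudocount),
          celltempo_constant_vector = function(e) NA_real_)
        out$distance[ti] <- d
        out$n_genes[ti] <- sum(mask)
      }
      out
    })
  }
  values <- do.call(rbind, res)
  med <- aggregate(distance ~ cell_type + species_pair, data = values,
                   FUN = median, na.action = stats::na.omit)
  names(med)[names(med) == "distance"] <- "median_distance"
  structure(list(values = values, medians = med, params = params,
                 cell_types = types, level = level),
            class = "divergence_table")
}

#' @export
print.divergence_table <- function(x, ...) {
  cat("divergence_table:", length(x$cell_types), "cell types,",
      x$params$n_iterations, "iterations,", x$params$metric, "\n")
  print(x$medians)
  invisible(x)
}

#' Robustness grid over analysis parameters
#'
#' Re-runs divergence + abundance correlation for every combination of the
#' supplied parameter axes and returns one row per combination with the
#' median correlation outcome. Failures in individual cells of the grid are
#' recorded and the run continues.
#'
#' @param cm A [cell_matrix()].
#' @param ortholog_map Ortholog map or NULL.
#' @param grid Data frame of parameter combinations (columns among
#'   `cells_per_type`, `min_counts`, `min_cpm`, `transform`, `metric`), e.g.
#'   from [expand.grid()]; defaults to the canonical 4 x 4 x 2 x 2 x 4 grid.
#' @param species_pair Two species labels.
#' @param n_iterations,seed Shared iteration settings.
#' @param level Clustering granularity.
#' @return Data frame: one row per combination with `median_rho`, `median_p`,
#'   `n_types`, `error` (NA unless that cell failed).
#' @export
robustness_grid <- function(cm, ortholog_map = NULL, grid = NULL,
                            species_pair, n_iterations = 10, seed = 1,
                            level = "subclass") {
  if (is.null(grid)) {
    grid <- expand.grid(cells_per_type = c(50, 100, 250, 500),
                        min_counts = c(5, 10, 25, 50),
                        min_cpm = c(1, 5),
                        transform = c("log2", "none"),
                        metric = c("spearman_distance", "pearson_distance",
                                   "euclidean", "l1"),
                        stringsAsFactors = FALSE)
  }
  stopifnot(nrow(grid) >= 1)
  out <- grid
  out$median_rho <- NA_real_
  out$median_p <- NA_real_
  out$n_types <- NA_integer_
  out$error <- NA_character_
  for (r in seq_len(nrow(grid))) {
    res <- tryCatch({
      p <- divergence_params(
        cells_per_type = grid$cells_per_type[r] %||% 250,
        min_counts = grid$min_counts[r] %||% 25,
        min_cpm = grid$min_cpm[r] %||% 1,
        transform = as.character(grid$transform[r] %||% "log2"),
        metric = as.character(grid$metric[r] %||% "spearman_distance"),
        n_iterations = n_iterations, seed = seed)
      dt <- run_divergence(cm, ortholog_map, p, species_pair, level)
      props <- estimate_proportions(cm, level = level,
                                    min_cells = p$cells_per_type,
                                    species_pair = species_pair,
                                    blacklist = p$blacklist)
      cr <- correlate(props, dt)
      list(rho = cr$median_rho, p = cr$median_p, n = length(dt$cell_types))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error[r] <- conditionMessage(res)
    } else {
      out$median_rho[r] <- res$rho
      out$median_p[r] <- res$p
      out$n_types[r] <- res$n
    }
  }
  out
}
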