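# Within-species, cross-individual cell-type expression variability and
# mean-matched gene-level variance ranks.

#' Interindividual expression variability per cell type
#'
#' For one species: restrict to individuals with at least `min_nuclei` cells
#' in every listed cell type; per iteration, pseudobulk `n_downsample`
#' nuclei per (individual, type), equalize total counts across types within
#' each individual, filter genes with mean counts across individuals below
#' `min_mean_counts` per type, CPM-normalize, and take the mean Spearman
#' correlation distance of each individual's profile to the unweighted mean
#' profile across individuals. The median over iterations is reported.
#'
#' @param cm A [cell_matrix()] of a single species (or pre-filtered by a
#'   metadata predicate).
#' @param cell_types Cell types to use; NULL selects types where at least
#'   `min_individuals` individuals reach `min_nuclei`.
#' @param min_nuclei Per-(individual, type) cell threshold (default 50).
#' @param n_downsample Nuclei sampled per (individual, type) (default 50).
#' @param min_mean_counts Gene filter on mean counts across individuals.
#' @param n_iterations,seed Iteration settings.
#' @param min_individuals Minimum qualifying individuals.
#' @param level Clustering granularity.
#' @return List of class `variability_table`: `values` (cell_type,
#'   iteration, variability), `medians`, `individuals`.
#' @export
interindividual_variability <- function(cm, cell_types = NULL,
                                        min_nuclei = 50, n_downsample = 50,
                                        min_mean_counts = 25,
                                        n_iterations = 100, seed = 1,
                                        min_individuals = 3,
                                        level = "subclass") {
  if (length(unique(cm$cell_meta$species)) != 1) {
    stop("interindividual_variability expects a single-species matrix")
  }
  labels <- meta_level(cm, level)
  tab <- table(cm$cell_meta$individual, labels)
  if (is.null(cell_types)) {
    ok <- colSums(tab >= min_nuclei) >= min_individuals
    cell_types <- colnames(tab)[ok]
  }
  if (!length(cell_types)) {
    stop_named("celltempo_no_qualifying_types", "no qualifying cell types")
  }
  inds <- rownames(tab)[apply(
    tab[, cell_types, drop = FALSE] >= min_nuclei, 1, all)]
  if (length(inds) < min_individuals) {
    stop_named("celltempo_too_few_individuals",
               "only ", length(inds), " individual(s) have >= ",
               min_nuclei, " nuclei in every cell type")
  }
  counts_t <- Matrix::t(cm$counts)
  strata <- list()
  for (ind in inds) for (ct in cell_types) {
    strata[[paste(ind, ct, sep = "\r")]] <-
      which(cm$cell_meta$individual == ind & labels == ct)
  }
  n_i <- length(inds); n_t <- length(cell_types)
  res <- vector("list", n_iterations)
  for (iter in seq_len(n_iterations)) {
    res[[iter]] <- with_seed(substream_seed(seed, iter), {
      # genes x (individual, type) pseudobulks of n_downsample nuclei
      pb <- array(0, dim = c(ncol(cm$counts), n_i, n_t))
      for (ii in seq_len(n_i)) for (ti in seq_len(n_t)) {
        idx <- strata[[paste(inds[ii], cell_types[ti], sep = "\r")]]
        take <- if (length(idx) == n_downsample) idx else
          idx[sample.int(length(idx), n_downsample)]
        pb[, ii, ti] <- Matrix::rowSums(counts_t[, take, drop = FALSE])
      }
      # equalize totals across cell types within each individual
      for (ii in seq_len(n_i)) {
        totals <- colSums(pb[, ii, , drop = TRUE])
        target <- min(totals)
        for (ti in seq_len(n_t)) {
          pb[, ii, ti] <- downsample_count_vector(pb[, ii, ti], target)
        }
      }
      out <- data.frame(cell_type = cell_types, iteration = iter,
                        variability = NA_real_, stringsAsFactors = FALSE)
      for (ti in seq_len(n_t)) {
        m <- pb[, , ti]
        keep <- rowMeans(m) >= min_mean_counts
        if (sum(keep) < 3) next
        m <- m[keep, , drop = FALSE]
        m <- sweep(m, 2, colSums(m), "/") * 1e6
        centroid <- rowMeans(m)
        d <- vapply(seq_len(n_i), function(ii)
          1 - cor(m[, ii], centroid, method = "spearman"), 0)
        out$variability[ti] <- mean(d)
      }
      out
    })
  }
  values <- do.call(rbind, res)
  med <- aggregate(variability ~ cell_type, data = values, FUN = median,
                   na.action = stats::na.omit)
  names(med)[names(med) == "variability"] <- "median_variability"
  structure(list(values = values, medians = med, individuals = inds,
                 cell_types = cell_types),
            class = "variability_table")
}

#' Correlate interindividual variability with cell-type proportion
#'
#' Per-iteration Spearman correlation of per-type variability against
#' proportions, reusing the correlation machinery (medians, representative
#' iteration).
#'
#' @param variability A `variability_table`.
#' @param proportions A `proportion_table` or data frame with `cell_type`
#'   and `proportion`.
#' @return A `correlation_result` (flagged when variability is constant).
#' @export
correlate_variability_with_proportion <- function(variability, proportions) {
  v <- variability$values
  names(v)[names(v) == "variability"] <- "distance"
  correlate(proportions, v)
}

#' Mean-matched variance ranks and the cross-species paired test
#'
#' For each focal gene and species, the variance of its expression across
#' individuals is ranked against the `n_neighbors` genes with the closest
#' mean expression (focal gene excluded; ties in mean distance broken by
#' stable gene-id order): the statistic is the fraction of neighbors with
#' smaller variance. Species are then compared with a paired two-sided
#' t-test across focal genes.
#'
#' @param cpm_by_species List of two matrices (genes x individuals) of
#'   per-individual pseudobulk CPM, one per species, shared rownames.
#' @param focal_genes Focal gene ids (e.g. a disorder-linked set).
#' @param n_neighbors Neighborhood size (default 100).
#' @return List of class `variance_rank`: `ranks` (gene, fraction per
#'   species), `t_test` (paired p, mean difference species1 - species2,
#'   direction), `n_dropped`.
#' @export
variance_rank_normalize <- function(cpm_by_species, focal_genes,
                                    n_neighbors = 100) {
  stopifnot(length(cpm_by_species) == 2)
  shared <- intersect(rownames(cpm_by_species[[1]]),
                      rownames(cpm_by_species[[2]]))
  if (length(shared) < n_neighbors + 1) {
    stop_named("celltempo_too_few_genes",
               "need more than ", n_neighbors, " quantified genes")
  }
  focal <- intersect(focal_genes, shared)
  n_dropped <- length(setdiff(focal_genes, focal))
  if (n_dropped) {
    message("variance_rank_normalize: dropped ", n_dropped,
            " focal gene(s) not quantified in both species")
  }
  frac <- sapply(cpm_by_species, function(m) {
    m <- m[shared, , drop = FALSE]
    mu <- rowMeans(m)
    v <- apply(m, 1, var)
    ids <- rownames(m)
    vapply(focal, function(g) {
      d <- abs(mu - mu[g])
      ord <- order(d, ids)
      ord <- ord[ids[ord] != g]
      nb <- ord[seq_len(min(n_neighbors, length(ord)))]
      mean(v[nb] < v[g])
    }, 0)
  })
  if (is.null(dim(frac))) frac <- matrix(frac, nrow = 1,
                                         dimnames = list(focal, NULL))
  diff_means <- frac[, 1] - frac[, 2]
  tt <- if (length(focal) >= 2 && sd(diff_means) > 0) {
    t.test(frac[, 1], frac[, 2], paired = TRUE)
  } else NULL
  structure(list(
    ranks = data.frame(gene_id = focal, species1 = frac[, 1],
                       species2 = frac[, 2], stringsAsFactors = FALSE),
    t_test = list(
      p = if (is.null(tt)) NA_real_ else tt$p.value,
      mean_diff = mean(diff_means),
      direction = if (mean(diff_means) < 0) "species1_less_variable"
                  else if (mean(diff_means) > 0) "species1_more_variable"
                  else "null"),
    n_dropped = n_dropped
  ), class = "variance_rank")
}

#' Per-individual pseudobulk CPM for one cell type
#'
#' Helper feeding [variance_rank_normalize()]: sums counts per individual
#' within one cell type and CPM-normalizes.
#'
#' @param cm A [cell_matrix()].
#' @param species Species label.
#' @param cell_type Cell type label.
#' @param level Clustering granularity.
#' @return Matrix genes x individuals of CPM.
#' @export
individual_pseudobulk_cpm <- function(cm, species, cell_type,
                                      level = "subclass") {
  labels <- meta_level(cm, level)
  rows <- which(cm$cell_meta$species == species & labels == cell_type)
  if (!length(rows)) {
    stop_named("celltempo_no_qualifying_types",
               "no cells for (", species, ", ", cell_type, ")")
  }
  inds <- sort(unique(cm$cell_meta$individual[rows]))
  counts_t <- Matrix::t(cm$counts)
  m <- sapply(inds, function(ind) {
    r <- rows[cm$cell_meta$individual[rows] == ind]
    v <- Matrix::rowSums(counts_t[, r, drop = FALSE])
    v * 1e6 / sum(v)
  })
  rownames(m) <- cm$gene_ids
  m
}
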