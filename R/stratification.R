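# Gene stratification by expression level, cell-type specificity (tau) and
# constraint (s_het), with the expression-matched pairing procedure, and
# re-running divergence/correlation within strata.

#' Cell-type specificity index tau
#'
#' tau_g = sum_i (1 - x_i / max_i x_i) / (N - 1) over N cell types, computed
#' on normalized expression (CPM of per-type pseudobulk) separately for each
#' species and averaged across the species pair. tau = 0 for uniform
#' expression, 1 for expression confined to a single type. Genes with
#' all-zero expression in a species have undefined tau and are excluded
#' (NA).
#'
#' @param expr_by_species List of two matrices (genes x cell types) of
#'   normalized expression, one per species, with shared rownames.
#' @return Named numeric vector of pair-averaged tau values (NA where
#'   undefined).
#' @export
compute_tau <- function(expr_by_species) {
  stopifnot(length(expr_by_species) == 2)
  taus <- lapply(expr_by_species, function(m) {
    if (ncol(m) < 2) stop("tau requires >= 2 cell types")
    mx <- apply(m, 1, max)
    t_g <- rowSums(1 - m / mx) / (ncol(m) - 1)
    t_g[mx == 0] <- NA_real_
    t_g
  })
  genes <- intersect(names(taus[[1]]), names(taus[[2]]))
  out <- (taus[[1]][genes] + taus[[2]][genes]) / 2
  out
}

#' Per-cell-type normalized pseudobulk expression for tau
#'
#' Convenience: pseudobulk each species across cell types passing the cell
#' count threshold, CPM-normalize each type's profile, and return the
#' per-species matrices [compute_tau()] expects.
#'
#' @param cm A [cell_matrix()].
#' @param species_pair Two species labels.
#' @param min_cells Cell-count threshold per (type, species).
#' @param level Clustering granularity.
#' @param ortholog_map Optional ortholog map.
#' @return List of two genes x types CPM matrices.
#' @export
tau_input_profiles <- function(cm, species_pair, min_cells = 250,
                               level = "subclass", ortholog_map = NULL) {
  labels <- meta_level(cm, level)
  tab <- table(labels, cm$cell_meta$species)
  types <- rownames(tab)[apply(
    tab[, species_pair, drop = FALSE] >= min_cells, 1, all)]
  if (length(types) < 2) {
    stop_named("celltempo_no_qualifying_types",
               "tau requires >= 2 cell types passing the cell threshold")
  }
  ag <- aligned_gene_index(cm, ortholog_map, species_pair)
  counts_t <- Matrix::t(cm$counts)
  out <- lapply(species_pair, function(sp) {
    m <- sapply(types, function(ct) {
      rows <- which(labels == ct & cm$cell_meta$species == sp)
      v <- Matrix::rowSums(counts_t[, rows, drop = FALSE])[ag$index[[sp]]]
      v * 1e6 / sum(v)
    })
    rownames(m) <- ag$record_ids
    m
  })
  names(out) <- species_pair
  out
}

#' Bin genes by a metric
#'
#' Tercile metrics (`expression_tercile`, `tau_tercile`) rank genes by value
#' (ties broken by stable gene-id order) and split into high/moderate/low
#' bins whose sizes differ by at most one. `s_het_fixed` applies the fixed
#' cut-points 0.1 and 0.01 (high > 0.1; moderate in (0.01, 0.1]; low <=
#' 0.01) and then downsamples bins (seeded) to a common size.
#'
#' @param values Named numeric vector (finite).
#' @param metric_kind One of `"expression_tercile"`, `"tau_tercile"`,
#'   `"s_het_fixed"`.
#' @param seed Seed for the s_het equalization.
#' @return Data frame of class `gene_strata`: `gene_id`, `value`, `bin`
#'   (`high`/`moderate`/`low`); attribute `equalized`.
#' @export
bin_by_metric <- function(values,
                          metric_kind = c("expression_tercile",
                                          "tau_tercile", "s_het_fixed"),
                          seed = 1) {
  metric_kind <- match.arg(metric_kind)
  values <- values[!is.na(values)]
  if (length(values) < 3) {
    stop_named("celltempo_too_few_genes", "need >= 3 genes to bin")
  }
  if (any(!is.finite(values))) stop("values must be finite")
  genes <- names(values)
  equalized <- FALSE
  if (metric_kind == "s_het_fixed") {
    bin <- ifelse(values > 0.1, "high",
                  ifelse(values > 0.01, "moderate", "low"))
    sizes <- table(factor(bin, levels = c("high", "moderate", "low")))
    target <- min(sizes)
    keep <- with_seed(seed, {
      unlist(lapply(c("high", "moderate", "low"), function(b) {
        idx <- which(bin == b)
        if (length(idx) > target) sample(idx, target) else idx
      }))
    })
    out <- data.frame(gene_id = genes[keep], value = unname(values[keep]),
                      bin = bin[keep], stringsAsFactors = FALSE)
    equalized <- TRUE
  } else {
    ord <- order(-values, genes)
    n <- length(values)
    base <- n %/% 3
    sizes <- rep(base, 3)
    extra <- n - 3 * base
    if (extra >= 1) sizes[1] <- sizes[1] + 1
    if (extra == 2) sizes[2] <- sizes[2] + 1
    bin <- rep(c("high", "moderate", "low"), sizes)
    out <- data.frame(gene_id = genes[ord], value = unname(values[ord]),
                      bin = bin, stringsAsFactors = FALSE)
  }
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_strata", "data.frame")
  attr(out, "equalized") <- equalized
  attr(out, "metric_kind") <- metric_kind
  out
}

#' Expression-matched gene pairing between bins
#'
#' Implements the matched-control procedure: form all cross-bin gene pairs,
#' keep pairs with |log2 fold-change| below the threshold, partition by the
#' sign of the fold-change, shuffle (seeded), greedily remove pairs reusing
#' a gene (first occurrence wins), keep all zero-fold-change pairs, and
#' downsample the positive and negative categories to equal size.
#'
#' @param high_genes,other_genes Character vectors (bins to match across).
#' @param expression Named numeric vector of expression values covering both
#'   bins.
#' @param lfc_threshold Absolute log2 fold-change cap (0.05 for expression
#'   control, 0.01 for tau control by convention).
#' @param seed Seed for shuffling and downsampling.
#' @return List of class `matched_pairs`: `pairs` (gene_high, gene_other,
#'   lfc), counts `n_neg`, `n_pos`, `n_zero`.
#' @export
match_expression_pairs <- function(high_genes, other_genes, expression,
                                   lfc_threshold = 0.05, seed = 1) {
  high_genes <- intersect(high_genes, names(expression))
  other_genes <- intersect(other_genes, names(expression))
  eh <- expression[high_genes]
  eo <- expression[other_genes]
  # candidate pairs via sorted window rather than the full cross product
  ord <- order(eo)
  eo_sorted <- eo[ord]
  pairs_h <- character(0); pairs_o <- character(0); pairs_lfc <- numeric(0)
  ratio <- 2^lfc_threshold
  for (i in seq_along(eh)) {
    lo <- eh[i] / ratio; hi <- eh[i] * ratio
    from <- findInterval(lo, eo_sorted, left.open = TRUE) + 1L
    to <- findInterval(hi, eo_sorted)
    if (from > to) next
    js <- ord[from:to]
    lfc <- log2(eh[i] / eo[js])
    keep <- abs(lfc) < lfc_threshold
    if (!any(keep)) next
    pairs_h <- c(pairs_h, rep(high_genes[i], sum(keep)))
    pairs_o <- c(pairs_o, names(eo)[js][keep])
    pairs_lfc <- c(pairs_lfc, lfc[keep])
  }
  empty <- function() {
    warning("no expression-matched pairs survive the threshold")
    structure(list(pairs = data.frame(gene_high = character(0),
                                      gene_other = character(0),
                                      lfc = numeric(0)),
                   n_neg = 0L, n_pos = 0L, n_zero = 0L),
              class = "matched_pairs")
  }
  if (!length(pairs_h)) return(empty())
  df <- data.frame(gene_high = pairs_h, gene_other = pairs_o,
                   lfc = pairs_lfc, stringsAsFactors = FALSE)
  df <- df[order(df$gene_high, df$gene_other), , drop = FALSE]
  result <- with_seed(seed, {
    df <- df[sample.int(nrow(df)), , drop = FALSE]
    seen <- new.env(parent = emptyenv())
    keep <- logical(nrow(df))
    for (r in seq_len(nrow(df))) {
      g1 <- df$gene_high[r]; g2 <- df$gene_other[r]
      if (is.null(seen[[g1]]) && is.null(seen[[g2]])) {
        keep[r] <- TRUE
        seen[[g1]] <- TRUE
        seen[[g2]] <- TRUE
      }
    }
    df <- df[keep, , drop = FALSE]
    neg <- df[df$lfc < 0, , drop = FALSE]
    pos <- df[df$lfc > 0, , drop = FALSE]
    zer <- df[df$lfc == 0, , drop = FALSE]
    m <- min(nrow(neg), nrow(pos))
    if (nrow(neg) > m) neg <- neg[sample.int(nrow(neg), m), , drop = FALSE]
    if (nrow(pos) > m) pos <- pos[sample.int(nrow(pos), m), , drop = FALSE]
    out <- rbind(zer, neg, pos)
    rownames(out) <- NULL
    list(pairs = out, n_neg = nrow(neg), n_pos = nrow(pos),
         n_zero = nrow(zer))
  })
  if (!nrow(result$pairs)) return(empty())
  structure(result, class = "matched_pairs")
}

#' Per-cell-type average-expression values for stratification
#'
#' Average CPM between the two compared species, computed per cell type from
#' full (non-downsampled) pseudobulks.
#'
#' @param cm A [cell_matrix()].
#' @param species_pair Two species labels.
#' @param level Clustering granularity.
#' @param ortholog_map Optional ortholog map.
#' @param min_cells Types below this cell count in either species are
#'   skipped.
#' @return Named list per cell type of named vectors (average CPM).
#' @export
expression_by_cell_type <- function(cm, species_pair, level = "subclass",
                                    ortholog_map = NULL, min_cells = 1) {
  labels <- meta_level(cm, level)
  tab <- table(labels, cm$cell_meta$species)
  types <- rownames(tab)[apply(
    tab[, species_pair, drop = FALSE] >= min_cells, 1, all)]
  ag <- aligned_gene_index(cm, ortholog_map, species_pair)
  counts_t <- Matrix::t(cm$counts)
  out <- lapply(types, function(ct) {
    v <- lapply(species_pair, function(sp) {
      rows <- which(labels == ct & cm$cell_meta$species == sp)
      x <- Matrix::rowSums(counts_t[, rows, drop = FALSE])[ag$index[[sp]]]
      x * 1e6 / sum(x)
    })
    setNames((v[[1]] + v[[2]]) / 2, ag$record_ids)
  })
  names(out) <- types
  out
}

#' Divergence-abundance correlation within gene strata
#'
#' Recomputes the divergence protocol restricted to each stratum's genes
#' (per cell type) and correlates with proportions. The distance metric
#' defaults to Euclidean for stratified runs, since restricted dynamic range
#' inflates correlation distances.
#'
#' @param cm A [cell_matrix()].
#' @param ortholog_map Ortholog map or NULL.
#' @param strata Either a `gene_strata` data frame (stratification shared
#'   across cell types) or a named list per bin of per-cell-type gene lists.
#' @param params A [divergence_params()]; metric is forced to `metric`.
#' @param species_pair Two species labels.
#' @param proportions Optional precomputed `proportion_table`.
#' @param level Clustering granularity.
#' @param metric Distance metric for stratified runs.
#' @param min_stratum_genes Cell types with fewer stratum genes after
#'   filtering are dropped from that stratum's correlation.
#' @return Named list per bin of `correlation_result`s, each with the
#'   stratified `divergence_table` attached as attribute `divergence`.
#' @export
stratified_correlation <- function(cm, ortholog_map = NULL, strata,
                                   params = divergence_params(),
                                   species_pair, proportions = NULL,
                                   level = "subclass",
                                   metric = "euclidean",
                                   min_stratum_genes = 50) {
  params$metric <- metric
  if (is.null(proportions)) {
    proportions <- estimate_proportions(cm, level = level,
                                        min_cells = params$cells_per_type,
                                        species_pair = species_pair,
                                        blacklist = params$blacklist)
  }
  bins <- if (inherits(strata, "gene_strata")) {
    split(strata$gene_id, strata$bin)
  } else strata
  out <- lapply(names(bins), function(b) {
    dt <- run_divergence(cm, ortholog_map, params, species_pair,
                         level = level, gene_subset = bins[[b]],
                         min_stratum_genes = min_stratum_genes)
    cr <- correlate(proportions, dt)
    attr(cr, "divergence") <- dt
    cr
  })
  names(out) <- names(bins)
  out
}
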