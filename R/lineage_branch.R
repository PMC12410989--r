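# Three-taxon parsimony: decompose pairwise divergence onto lineage branches
# with an outgroup, compute acceleration ratios, and polarize per-gene
# expression changes into derived lineages.

#' Pairwise divergence triple under one shared downsampling
#'
#' Runs the divergence protocol jointly for (ingroup1, ingroup2, outgroup):
#' per iteration, cells are downsampled for all three species, pseudobulk
#' totals are equalized across every included (type, species) profile, and
#' the three pairwise distances per cell type are computed on one shared
#' gene mask (genes passing the two-species filter in all three pairs).
#'
#' @param cm A [cell_matrix()] holding the three species.
#' @param ortholog_map Ortholog map or NULL.
#' @param params A [divergence_params()].
#' @param ingroup1,ingroup2,outgroup Species labels.
#' @param level Clustering granularity.
#' @return Data frame of class `divergence_triple`: `cell_type`,
#'   `iteration`, `d12` (ingroup1-ingroup2), `d1o` (ingroup1-outgroup),
#'   `d2o` (ingroup2-outgroup).
#' @export
run_divergence_triple <- function(cm, ortholog_map = NULL,
                                  params = divergence_params(),
                                  ingroup1, ingroup2, outgroup,
                                  level = "subclass") {
  species <- c(ingroup1, ingroup2, outgroup)
  labels <- meta_level(cm, level)
  tab <- table(labels, cm$cell_meta$species)
  types <- setdiff(rownames(tab), params$blacklist)
  ok <- vapply(types, function(ct)
    all(species %in% colnames(tab)) &&
      all(tab[ct, species] >= params$cells_per_type), TRUE)
  types <- types[ok]
  if (!length(types)) {
    stop_named("celltempo_no_qualifying_types",
               "no cell type has >= ", params$cells_per_type,
               " cells in all three species")
  }
  ag <- aligned_gene_index(cm, ortholog_map, species)
  strata <- list()
  for (ct in types) for (sp in species) {
    strata[[paste(ct, sp, sep = "\r")]] <-
      which(labels == ct & cm$cell_meta$species == sp)
  }
  counts_t <- Matrix::t(cm$counts)
  n_types <- length(types)
  pairs <- list(d12 = c(1L, 2L), d1o = c(1L, 3L), d2o = c(2L, 3L))
  res <- vector("list", params$n_iterations)
  for (iter in seq_len(params$n_iterations)) {
    res[[iter]] <- with_seed(substream_seed(params$seed, iter), {
      takes <- vector("list", 3L * n_types)
      for (ti in seq_len(n_types)) for (si in 1:3) {
        idx <- strata[[paste(types[ti], species[si], sep = "\r")]]
        takes[[(ti - 1L) * 3L + si]] <-
          if (length(idx) == params$cells_per_type) idx else
            idx[sample.int(length(idx), params$cells_per_type)]
      }
      ind <- Matrix::sparseMatrix(
        i = unlist(takes), j = rep(seq_along(takes), lengths(takes)),
        x = 1, dims = c(ncol(counts_t), length(takes)))
      prof_all <- as.matrix(counts_t %*% ind)
      prof <- matrix(0, nrow = length(ag$record_ids), ncol = 3L * n_types)
      for (ti in seq_len(n_types)) for (si in 1:3) {
        k <- (ti - 1L) * 3L + si
        prof[, k] <- prof_all[ag$index[[species[si]]], k]
      }
      target <- min(colSums(prof))
      for (k in seq_len(ncol(prof))) {
        prof[, k] <- downsample_count_vector(prof[, k], target)
      }
      out <- data.frame(cell_type = types, iteration = iter,
                        d12 = NA_real_, d1o = NA_real_, d2o = NA_real_,
                        stringsAsFactors = FALSE)
      for (ti in seq_len(n_types)) {
        cols <- (ti - 1L) * 3L + 1:3
        mask <- rep(TRUE, nrow(prof))
        for (pr in pairs) {
          mask <- mask & filter_genes(prof[, cols[pr[1]]],
                                      prof[, cols[pr[2]]],
                                      params$min_counts, params$min_cpm)
        }
        if (sum(mask) < 3) next
        for (pn in names(pairs)) {
          pr <- pairs[[pn]]
          d <- tryCatch(
            expression_distance(cpm(prof[, cols[pr[1]]])[mask],
                                cpm(prof[, cols[pr[2]]])[mask],
                                metric = params$metric,
                                transform = params$transform,
                                log_pseudocount = params$log_pseudocount),
            celltempo_constant_vector = function(e) NA_real_)
          out[[pn]][ti] <- d
        }
      }
      out
    })
  }
  out <- do.call(rbind, res)
  attr(out, "species") <- setNames(species,
                                   c("ingroup1", "ingroup2", "outgroup"))
  class(out) <- c("divergence_triple", "data.frame")
  out
}

#' Parsimony decomposition of pairwise divergence onto the two ingroup branches
#'
#' For each (cell type, iteration) triple of distances d12 (ingroup pair),
#' d1o and d2o (each ingroup vs outgroup):
#' branch1 = (d12 + d1o - d2o) / 2 and branch2 = (d12 + d2o - d1o) / 2,
#' so that branch1 + branch2 = d12 exactly. Negative branch estimates
#' (possible when the triangle inequality fails under noise) are retained
#' and flagged rather than clipped, since clipping would bias the means
#' reported over iterations.
#'
#' @param triple A `divergence_triple` or data frame with `cell_type`,
#'   `iteration`, `d12`, `d1o`, `d2o`.
#' @return List of class `branch_divergence`: `values` (per cell type and
#'   iteration: branch1, branch2, negative-estimate flag) and `summary`
#'   (per-type means over iterations plus `acceleration_ratio` =
#'   branch1/branch2).
#' @export
branch_decompose <- function(triple) {
  v <- as.data.frame(triple)
  v$branch1 <- (v$d12 + v$d1o - v$d2o) / 2
  v$branch2 <- (v$d12 + v$d2o - v$d1o) / 2
  v$negative_flag <- !is.na(v$branch1) & !is.na(v$branch2) &
    (v$branch1 < 0 | v$branch2 < 0)
  agg <- aggregate(cbind(branch1, branch2) ~ cell_type, data = v,
                   FUN = mean, na.action = stats::na.omit)
  agg$acceleration_ratio <- ifelse(agg$branch2 == 0, NA_real_,
                                   agg$branch1 / agg$branch2)
  agg$any_negative <- vapply(agg$cell_type, function(ct)
    any(v$negative_flag[v$cell_type == ct]), TRUE)
  structure(list(values = v, summary = agg), class = "branch_divergence")
}

#' Ranked acceleration report
#'
#' Cell types ranked by the acceleration ratio (branch1 divergence over
#' branch2 divergence), optionally with the ratio of branch1 divergence to
#' within-species variability.
#'
#' @param branches A `branch_divergence` (or its `summary` data frame).
#' @param variability Optional named numeric vector: per-cell-type
#'   within-species variability (e.g. median distance-to-centroid).
#' @return Data frame sorted by `acceleration_ratio` descending, with
#'   `variability_ratio` when supplied; zero denominators yield NA with
#'   `undefined_flag`.
#' @export
acceleration_report <- function(branches, variability = NULL) {
  s <- if (inherits(branches, "branch_divergence")) branches$summary
       else branches
  out <- s
  out$undefined_flag <- is.na(out$acceleration_ratio) |
    out$branch2 <= 0 | out$branch1 < 0
  if (!is.null(variability)) {
    v <- variability[out$cell_type]
    out$variability_ratio <- ifelse(!is.na(v) & v > 0, out$branch1 / v,
                                    NA_real_)
    out$undefined_flag <- out$undefined_flag |
      (!is.na(v) & v == 0) | is.na(v)
  }
  out[order(-out$acceleration_ratio, out$cell_type), , drop = FALSE]
}

#' Polarize per-gene expression changes into derived lineages
#'
#' A gene is ambiguous when both outgroup fold-changes exceed the ingroup
#' pair fold-change in absolute value. After removing ambiguous genes, the
#' `as_printed` variant labels a gene ingroup1-derived when the absolute
#' ingroup1-outgroup fold-change exceeds the absolute ingroup-pair
#' fold-change (and ingroup2-derived in the mirrored case); genes matching
#' neither clause are also called ambiguous so the rule is exhaustive. The
#' `outgroup_proximity` variant instead labels a gene ingroup1-derived when
#' the outgroup is closer to ingroup2 (|d2o fold-change| < |d1o
#' fold-change|), the standard parsimony reading.
#'
#' @param lfc_12 Named vector of log2 fold-changes ingroup1 vs ingroup2.
#' @param lfc_1o Named vector, ingroup1 vs outgroup.
#' @param lfc_2o Named vector, ingroup2 vs outgroup.
#' @param rule_variant `"as_printed"` or `"outgroup_proximity"`.
#' @return Data frame of class `lineage_assignment`: `gene_id`, `label`
#'   (`ingroup1_derived`, `ingroup2_derived`, `ambiguous`), `rule_variant`.
#' @export
assign_lineage <- function(lfc_12, lfc_1o, lfc_2o,
                           rule_variant = c("as_printed",
                                            "outgroup_proximity")) {
  rule_variant <- match.arg(rule_variant)
  genes <- intersect(intersect(names(lfc_12), names(lfc_1o)),
                     names(lfc_2o))
  skipped <- setdiff(unique(c(names(lfc_12), names(lfc_1o),
                              names(lfc_2o))), genes)
  if (length(skipped)) {
    message("assign_lineage: skipped ", length(skipped),
            " gene(s) missing a fold-change")
  }
  a12 <- abs(lfc_12[genes]); a1o <- abs(lfc_1o[genes])
  a2o <- abs(lfc_2o[genes])
  ambiguous <- a1o > a12 & a2o > a12
  label <- rep("ambiguous", length(genes))
  if (rule_variant == "as_printed") {
    label[!ambiguous & a1o > a12] <- "ingroup1_derived"
    label[!ambiguous & a2o > a12 & !(a1o > a12)] <- "ingroup2_derived"
  } else {
    label[!ambiguous & a2o < a1o] <- "ingroup1_derived"
    label[!ambiguous & a1o < a2o] <- "ingroup2_derived"
  }
  out <- data.frame(gene_id = genes, label = label,
                    rule_variant = rule_variant,
                    stringsAsFactors = FALSE)
  class(out) <- c("lineage_assignment", "data.frame")
  out
}

#' Paired comparison of outgroup proximity to the two ingroups
#'
#' Tests whether the outgroup's expression is systematically closer to one
#' ingroup across a gene set (paired two-sided Wilcoxon signed-rank on
#' |lfc ingroup1-outgroup| vs |lfc ingroup2-outgroup|). The outgroup lying
#' closer to ingroup2 indicates greater divergence on the ingroup1 lineage.
#'
#' @param abs_1o,abs_2o Named vectors of absolute log2 fold-changes for the
#'   same genes.
#' @param min_n Below this many genes only descriptive output is returned.
#' @return List: `n`, `median_diff` (|1o| - |2o|), `direction`, `p`
#'   (NA when descriptive only).
#' @export
compare_outgroup_proximity <- function(abs_1o, abs_2o, min_n = 5) {
  genes <- intersect(names(abs_1o), names(abs_2o))
  if (!length(genes)) stop("no shared genes")
  d <- abs_1o[genes] - abs_2o[genes]
  md <- median(d)
  direction <- if (md > 0) "outgroup_closer_to_ingroup2"
               else if (md < 0) "outgroup_closer_to_ingroup1"
               else "null"
  p <- NA_real_
  if (length(genes) >= min_n) {
    p <- if (all(d == 0)) 1 else suppressWarnings(
      wilcox.test(abs_1o[genes], abs_2o[genes], paired = TRUE))$p.value
  }
  list(n = length(genes), median_diff = unname(md),
       direction = direction, p = p)
}
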