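# Cell-type proportion estimation and its correlation with per-type
# divergence across downsampling iterations.

#' Estimate cell-type proportions for a species pair
#'
#' Restricts to cell types with at least `min_cells` cells in each species
#' of the pair (matching the divergence run's inclusion rule), computes
#' per-species proportions with denominators over included types only, and
#' averages the two species' proportions per type.
#'
#' @param cm A [cell_matrix()].
#' @param level Clustering granularity.
#' @param min_cells Inclusion threshold; should equal the divergence run's
#'   `cells_per_type`.
#' @param species_pair Two species labels.
#' @param blacklist Cell-type labels to exclude.
#' @param all_cells_denominator If TRUE, denominators are all profiled cells
#'   of the species rather than included types only.
#' @return Data frame of class `proportion_table`: `cell_type`, per-species
#'   proportions, `proportion` (pair average).
#' @export
estimate_proportions <- function(cm, level = "subclass", min_cells = 250,
                                 species_pair,
                                 blacklist = character(0),
                                 all_cells_denominator = FALSE) {
  labels <- meta_level(cm, level)
  tab <- table(labels, cm$cell_meta$species)
  types <- setdiff(rownames(tab), blacklist)
  ok <- vapply(types, function(ct) all(tab[ct, species_pair] >= min_cells),
               TRUE)
  types <- types[ok]
  if (!length(types)) {
    stop_named("celltempo_no_qualifying_types",
               "no cell type reaches min_cells = ", min_cells,
               " in both species")
  }
  p1 <- tab[types, species_pair[1]]
  p2 <- tab[types, species_pair[2]]
  if (all_cells_denominator) {
    d1 <- sum(tab[, species_pair[1]]); d2 <- sum(tab[, species_pair[2]])
  } else {
    d1 <- sum(p1); d2 <- sum(p2)
  }
  out <- data.frame(cell_type = types,
                    prop_species1 = as.numeric(p1) / d1,
                    prop_species2 = as.numeric(p2) / d2,
                    stringsAsFactors = FALSE)
  out$proportion <- (out$prop_species1 + out$prop_species2) / 2
  rownames(out) <- NULL
  class(out) <- c("proportion_table", "data.frame")
  attr(out, "species_pair") <- species_pair
  out
}

#' Correlate cell-type proportions with divergence across iterations
#'
#' Computes the two-sided Spearman correlation between pair-averaged
#' proportions and per-type distance within every iteration, then reports
#' the medians of rho and of P (taken independently) and the representative
#' iteration for plotting.
#'
#' @param proportions A `proportion_table` (or any data frame with
#'   `cell_type` and `proportion`).
#' @param divergence A `divergence_table` (or a long data frame with
#'   `cell_type`, `iteration`, `distance`).
#' @param min_types Fewer shared cell types than this flags the result.
#' @return List of class `correlation_result`: `iterations` (rho, p per
#'   iteration), `median_rho`, `median_p`, `representative_iteration`,
#'   `n_types`, `flag`.
#' @export
correlate <- function(proportions, divergence, min_types = 5) {
  values <- if (inherits(divergence, "divergence_table")) divergence$values
            else divergence
  shared <- intersect(unique(values$cell_type), proportions$cell_type)
  prop <- setNames(proportions$proportion, proportions$cell_type)[shared]
  iters <- sort(unique(values$iteration))
  rho <- rep(NA_real_, length(iters))
  pval <- rep(NA_real_, length(iters))
  for (k in seq_along(iters)) {
    sub <- values[values$iteration == iters[k] &
                    values$cell_type %in% shared, ]
    d <- setNames(sub$distance, sub$cell_type)[shared]
    ok <- !is.na(d)
    if (sum(ok) >= 3 && sd(d[ok]) > 0 && sd(prop[ok]) > 0) {
      st <- spearman_test(prop[ok], d[ok])
      rho[k] <- st$rho
      pval[k] <- st$p
    }
  }
  flag <- if (length(shared) < min_types) {
    paste0("only ", length(shared), " shared cell types (< ", min_types, ")")
  } else if (all(is.na(rho))) "correlation undefined (constant input)"
  else NA_character_
  it_df <- data.frame(iteration = iters, rho = rho, p = pval)
  res <- structure(list(
    iterations = it_df,
    median_rho = median(rho, na.rm = TRUE),
    median_p = median(pval, na.rm = TRUE),
    representative_iteration = NA_integer_,
    n_types = length(shared),
    cell_types = shared,
    flag = flag
  ), class = "correlation_result")
  if (any(!is.na(rho))) {
    res$representative_iteration <- select_representative_iteration(res)
  }
  res
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "correlation_result: median rho = %.3f, median P = %.3g (%d types, %d iterations)\n",
    x$median_rho, x$median_p, x$n_types, nrow(x$iterations)))
  if (!is.na(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}

#' Select the representative iteration for plotting
#'
#' Three-stage deterministic rule: (1) the first iteration whose rho and P
#' both equal the medians; (2) otherwise, among the rho values nearest the
#' median rho, the value attained by the most iterations wins and the first
#' iteration with that value is chosen; (3) remaining ties are broken by the
#' lowest iteration number.
#'
#' @param result A `correlation_result` (or data frame with `rho`, `p`).
#' @return Iteration index (1-based position in the iteration table).
#' @export
select_representative_iteration <- function(result) {
  it <- if (inherits(result, "correlation_result")) result$iterations
        else result
  ok <- which(!is.na(it$rho) & !is.na(it$p))
  if (!length(ok)) return(NA_integer_)
  rho <- it$rho[ok]; p <- it$p[ok]
  tol <- 1e-12
  med_r <- median(rho); med_p <- median(p)
  both <- which(abs(rho - med_r) < tol & abs(p - med_p) < tol)
  if (length(both)) return(ok[both[1]])
  d <- abs(rho - med_r)
  nearest <- which(d - min(d) < tol)
  vals <- rho[nearest]
  counts <- vapply(vals, function(v) sum(abs(rho - v) < tol), 0L)
  best <- vals[counts == max(counts)]
  hit <- which(vapply(rho, function(r) any(abs(r - best) < tol), TRUE))
  ok[hit[1]]
}

#' Correlation restricted to one cell-type class
#'
#' As [correlate()], on the cell types belonging to the given class
#' (e.g. excitatory-only or inhibitory-only).
#'
#' @param proportions,divergence As in [correlate()].
#' @param classes Named character vector mapping cell type to class label.
#' @param class Class to keep.
#' @param min_types Flag threshold passed to [correlate()].
#' @return A `correlation_result`.
#' @export
correlate_within_class <- function(proportions, divergence, classes, class,
                                   min_types = 5) {
  keep <- names(classes)[classes == class]
  props <- proportions[proportions$cell_type %in% keep, , drop = FALSE]
  values <- if (inherits(divergence, "divergence_table")) divergence$values
            else divergence
  values <- values[values$cell_type %in% keep, , drop = FALSE]
  correlate(props, values, min_types = min_types)
}
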