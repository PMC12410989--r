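# Per-gene expression direction calls between species, directional binomial
# sign tests with empirical backgrounds, gene-set scans with FDR control,
# coupling of lineage polarization to hybrid ASE via Fisher's exact test,
# category splits, and the TSS-variant balance correction.

#' Per-individual pseudobulk counts for one cell type
#'
#' Sums counts per (species, individual) within a cell type, the input
#' expected by [differential_expression()].
#'
#' @param cm A [cell_matrix()].
#' @param species_pair Two species labels (order fixes the sign convention).
#' @param cell_type Cell type, or NULL for all cells.
#' @param level Clustering granularity.
#' @return List: `counts` (genes x samples), `group` (species factor).
#' @export
pseudobulk_by_individual <- function(cm, species_pair, cell_type = NULL,
                                     level = "subclass") {
  labels <- meta_level(cm, level)
  keep <- cm$cell_meta$species %in% species_pair
  if (!is.null(cell_type)) keep <- keep & labels == cell_type
  idx <- which(keep)
  key <- paste(cm$cell_meta$species[idx], cm$cell_meta$individual[idx],
               sep = "\r")
  ukey <- sort(unique(key))
  ind <- Matrix::sparseMatrix(i = idx, j = match(key, ukey), x = 1,
                              dims = c(nrow(cm$counts), length(ukey)))
  counts <- as.matrix(Matrix::t(cm$counts) %*% ind)
  rownames(counts) <- cm$gene_ids
  sp <- vapply(strsplit(ukey, "\r", fixed = TRUE), `[`, "", 1)
  colnames(counts) <- vapply(strsplit(ukey, "\r", fixed = TRUE), `[`, "", 2)
  list(counts = counts, group = factor(sp, levels = species_pair))
}

#' Differential expression between two species
#'
#' Pluggable backends over per-individual pseudobulk counts. The default
#' `nb_wald` is a two-group negative-binomial Wald test with library-size
#' offsets and method-of-moments per-gene dispersion shrunk toward a
#' mean-dispersion trend; `welch_logcpm` is a Welch t-test on log2(CPM + 1);
#' `external_table` ingests a precomputed table (e.g. from a dedicated DE
#' package) so published fold-changes can be used verbatim. Sign convention:
#' positive log2 fold-change means higher expression in species 1 (the
#' first group level).
#'
#' @param counts Matrix genes x samples of pseudobulk counts.
#' @param group Factor/vector of length ncol(counts) with two levels;
#'   level 1 is species 1.
#' @param backend `"nb_wald"`, `"welch_logcpm"` or `"external_table"`.
#' @param external For `external_table`: data frame with `gene_id`, `lfc`,
#'   `p`.
#' @param fdr_cutoff Significance threshold on BH-FDR.
#' @param shrink_weight Weight of the trend in dispersion shrinkage
#'   (nb_wald).
#' @return Data frame of class `de_result`: `gene_id`, `lfc`, `p`, `fdr`,
#'   `significant`; attribute `backend`.
#' @export
differential_expression <- function(counts = NULL, group = NULL,
                                    backend = c("nb_wald", "welch_logcpm",
                                                "external_table"),
                                    external = NULL, fdr_cutoff = 0.05,
                                    shrink_weight = 0.75) {
  backend <- match.arg(backend)
  if (backend == "external_table") {
    stopifnot(all(c("gene_id", "lfc", "p") %in% names(external)))
    out <- data.frame(gene_id = external$gene_id, lfc = external$lfc,
                      p = external$p, stringsAsFactors = FALSE)
  } else {
    group <- factor(group)
    stopifnot(nlevels(group) == 2, ncol(counts) == length(group))
    if (min(table(group)) < 2) {
      stop_named("celltempo_too_few_samples",
                 "internal backends need >= 2 samples per species; ",
                 "use backend = 'external_table' for precomputed results")
    }
    g1 <- group == levels(group)[1]
    libs <- colSums(counts)
    if (backend == "welch_logcpm") {
      lc <- log2(sweep(counts, 2, libs, "/") * 1e6 + 1)
      n1 <- sum(g1); n2 <- sum(!g1)
      m1 <- rowMeans(lc[, g1, drop = FALSE])
      m2 <- rowMeans(lc[, !g1, drop = FALSE])
      v1 <- apply(lc[, g1, drop = FALSE], 1, var)
      v2 <- apply(lc[, !g1, drop = FALSE], 1, var)
      se2 <- v1 / n1 + v2 / n2
      tstat <- (m1 - m2) / sqrt(se2)
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
      p <- 2 * pt(-abs(tstat), df)
      p[!is.finite(tstat)] <- 1
      out <- data.frame(gene_id = rownames(counts), lfc = m1 - m2, p = p,
                        stringsAsFactors = FALSE)
    } else {
      s1 <- sum(libs[g1]); s2 <- sum(libs[!g1])
      y1 <- rowSums(counts[, g1, drop = FALSE])
      y2 <- rowSums(counts[, !g1, drop = FALSE])
      q1 <- (y1 + 0.5) / s1
      q2 <- (y2 + 0.5) / s2
      lfc <- log2(q1 / q2)
      # method-of-moments dispersion from Pearson-style residuals,
      # pooled across groups, shrunk toward a lowess mean trend
      mu <- outer(q1, libs * 0); mu[, g1] <- outer(q1, libs[g1])
      mu[, !g1] <- outer(q2, libs[!g1])
      resid2 <- (counts - mu)^2
      n <- ncol(counts)
      phi_raw <- pmax(0, (rowSums(resid2) - rowSums(mu)) /
                        rowSums(mu^2)) * n / max(1, n - 2)
      mean_cpm <- (y1 + y2) / (s1 + s2) * 1e6
      lx <- log10(mean_cpm + 0.1)
      tr <- stats::lowess(lx, phi_raw, f = 0.5)
      phi_trend <- pmax(0, stats::approx(tr$x, tr$y, xout = lx, rule = 2,
                                         ties = "ordered")$y)
      phi <- (1 - shrink_weight) * phi_raw + shrink_weight * phi_trend
      v1 <- 1 / (q1 * s1) + phi * sum(libs[g1]^2) / s1^2
      v2 <- 1 / (q2 * s2) + phi * sum(libs[!g1]^2) / s2^2
      se <- sqrt(v1 + v2) / log(2)
      tstat <- lfc / se
      p <- 2 * pt(-abs(tstat), df = max(1, n - 2))
      out <- data.frame(gene_id = rownames(counts), lfc = lfc, p = p,
                        stringsAsFactors = FALSE)
    }
  }
  out <- out[order(out$gene_id), , drop = FALSE]
  out$fdr <- p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_cutoff
  rownames(out) <- NULL
  attr(out, "backend") <- backend
  attr(out, "fdr_cutoff") <- fdr_cutoff
  class(out) <- c("de_result", "data.frame")
  out
}

#' Directional binomial sign test on a gene set
#'
#' Restricts to significant genes (FDR below the cutoff, nonzero
#' fold-change), counts down- vs up-regulated set members, and tests the
#' down count against the empirical background probability — the frequency
#' of negative fold-changes among all significant genes — with a two-sided
#' binomial test (minimum-likelihood two-sided convention, as implemented
#' by [stats::binom.test()]). Fold enrichment is the odds ratio
#' (n_down/n_up) / (bg_down/bg_up); a risk-ratio variant is available.
#'
#' @param de A `de_result` (or `ase_direction` output).
#' @param gene_set Character vector of member gene ids.
#' @param fdr_cutoff Significance threshold (default 0.05).
#' @param background_p Optional override of the background probability.
#' @param enrichment `"odds_ratio"` (default) or `"risk_ratio"`.
#' @param set_name Label for the output row.
#' @return One-row data frame of class `sign_test_result`: `set`, `n_down`,
#'   `n_up`, `background_p`, `fold_enrichment` (NA-flagged when a margin is
#'   zero, with `fold_enrichment_haldane` always finite), `p`, `flag`.
#' @export
sign_test <- function(de, gene_set, fdr_cutoff = 0.05,
                      background_p = NULL,
                      enrichment = c("odds_ratio", "risk_ratio"),
                      set_name = "set") {
  enrichment <- match.arg(enrichment)
  sig <- de[!is.na(de$fdr) & de$fdr < fdr_cutoff & de$lfc != 0, ]
  bg_down <- sum(sig$lfc < 0)
  bg_up <- sum(sig$lfc > 0)
  if (is.null(background_p)) {
    background_p <- if (bg_down + bg_up > 0) bg_down / (bg_down + bg_up)
                    else NA_real_
  }
  mem <- sig[sig$gene_id %in% gene_set, ]
  n_down <- sum(mem$lfc < 0)
  n_up <- sum(mem$lfc > 0)
  n <- n_down + n_up
  if (n == 0 || is.na(background_p)) {
    out <- data.frame(set = set_name, n_down = n_down, n_up = n_up,
                      background_p = background_p,
                      fold_enrichment = NA_real_,
                      fold_enrichment_haldane = NA_real_,
                      p = NA_real_, flag = "no significant set members",
                      stringsAsFactors = FALSE)
    class(out) <- c("sign_test_result", "data.frame")
    return(out)
  }
  p <- binom.test(n_down, n, background_p)$p.value
  fe_h <- if (enrichment == "odds_ratio") {
    ((n_down + 0.5) / (n_up + 0.5)) / ((bg_down + 0.5) / (bg_up + 0.5))
  } else {
    ((n_down + 0.5) / (n + 1)) / (background_p + 0.5 / (bg_down + bg_up))
  }
  fe <- if (enrichment == "odds_ratio") {
    if (n_up == 0 || bg_up == 0 || bg_down == 0) NA_real_
    else (n_down / n_up) / (bg_down / bg_up)
  } else {
    if (background_p == 0) NA_real_ else (n_down / n) / background_p
  }
  out <- data.frame(set = set_name, n_down = n_down, n_up = n_up,
                    background_p = background_p, fold_enrichment = fe,
                    fold_enrichment_haldane = fe_h, p = p,
                    flag = if (is.na(fe)) "zero margin" else NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("sign_test_result", "data.frame")
  out
}

#' Scan a gene-set collection with directional sign tests
#'
#' One [sign_test()] per set (after `min_size` filtering), BH-FDR across
#' sets, with volcano-ready columns. Optional controls: remove a reference
#' set's members from every scanned set (pleiotropy control), or replace
#' each set by its expression-matched subset with the background computed
#' from the matched partner genes (expression control via
#' [match_expression_pairs()], threshold 0.1 by convention).
#'
#' @param de A `de_result` (or ASE directions).
#' @param collection `gene_set_collection` or named list of gene-id vectors.
#' @param min_size Minimum set size (default 100).
#' @param fdr_cutoff Per-gene significance threshold.
#' @param overlap_removal Optional character vector: reference set whose
#'   members are removed from every scanned set.
#' @param expression_matched If TRUE, apply the matched-pair control.
#' @param expression Named expression values (required when matching).
#' @param lfc_threshold Matching threshold (default 0.1).
#' @param seed Seed for matching.
#' @return Data frame: one `sign_test_result` row per set plus
#'   `log2_fold_enrichment`, `neg_log10_p`, `fdr`.
#' @export
scan_gene_sets <- function(de, collection, min_size = 100,
                           fdr_cutoff = 0.05, overlap_removal = NULL,
                           expression_matched = FALSE, expression = NULL,
                           lfc_threshold = 0.1, seed = 1) {
  sets <- lapply(collection, as.character)
  sets <- sets[vapply(sets, length, 1L) >= min_size]
  if (!length(sets)) stop("no sets pass min_size")
  rows <- vector("list", length(sets))
  for (k in seq_along(sets)) {
    genes <- sets[[k]]
    if (!is.null(overlap_removal)) genes <- setdiff(genes, overlap_removal)
    background_p <- NULL
    if (expression_matched) {
      stopifnot(!is.null(expression))
      partner_pool <- setdiff(names(expression), sets[[k]])
      mp <- suppressWarnings(match_expression_pairs(
        genes, partner_pool, expression, lfc_threshold = lfc_threshold,
        seed = substream_seed(seed, k)))
      genes <- mp$pairs$gene_high
      partners <- mp$pairs$gene_other
      sig <- de[!is.na(de$fdr) & de$fdr < fdr_cutoff & de$lfc != 0, ]
      pd <- sum(sig$lfc < 0 & sig$gene_id %in% partners)
      pu <- sum(sig$lfc > 0 & sig$gene_id %in% partners)
      if (pd + pu > 0) background_p <- pd / (pd + pu)
    }
    rows[[k]] <- sign_test(de, genes, fdr_cutoff = fdr_cutoff,
                           background_p = background_p,
                           set_name = names(sets)[k])
  }
  out <- do.call(rbind, rows)
  out$log2_fold_enrichment <- log2(out$fold_enrichment_haldane)
  out$neg_log10_p <- -log10(out$p)
  out$fdr <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Allelic expression direction per gene
#'
#' Internal backend: per-sample log2 allelic ratio
#' log2((allele1 + 0.5) / (allele2 + 0.5)), tested against zero with a
#' one-sample t-test. Hybrid-line blocking is handled by stratified testing:
#' with at least `min_lines_for_blocking` lines, per-line mean ratios are
#' the test units, otherwise samples are. Genes with zero total counts in
#' all samples are excluded.
#'
#' @param ase An `ase_table`.
#' @param fdr_cutoff Significance threshold on BH-FDR.
#' @param min_lines_for_blocking Minimum distinct lines to collapse on.
#' @param external Optional precomputed table (`gene_id`, `lfc`, `p`), e.g.
#'   from a DE package run with the line as a covariate.
#' @return Data frame of class `ase_direction` (and `de_result`-compatible):
#'   `gene_id`, `lfc` (allelic log2 ratio, positive = higher from the
#'   species-1 allele), `p`, `fdr`, `significant`, `direction`.
#' @export
ase_direction <- function(ase, fdr_cutoff = 0.05,
                          min_lines_for_blocking = 3, external = NULL) {
  if (!is.null(external)) {
    out <- differential_expression(backend = "external_table",
                                   external = external,
                                   fdr_cutoff = fdr_cutoff)
    out$direction <- ifelse(out$lfc < 0, "down", ifelse(out$lfc > 0, "up",
                                                        "none"))
    class(out) <- c("ase_direction", class(out))
    return(out)
  }
  if (length(unique(ase$sample)) < 2) {
    stop_named("celltempo_too_few_samples", "need >= 2 samples")
  }
  genes <- sort(unique(ase$gene_id))
  samples <- sort(unique(ase$sample))
  a1 <- matrix(0, length(genes), length(samples),
               dimnames = list(genes, samples))
  a2 <- a1
  a1[cbind(match(ase$gene_id, genes), match(ase$sample, samples))] <-
    ase$allele1_count
  a2[cbind(match(ase$gene_id, genes), match(ase$sample, samples))] <-
    ase$allele2_count
  keep <- rowSums(a1 + a2) > 0
  a1 <- a1[keep, , drop = FALSE]; a2 <- a2[keep, , drop = FALSE]
  ratios <- log2((a1 + 0.5) / (a2 + 0.5))
  line_of <- ase$line[match(samples, ase$sample)]
  lines <- unique(line_of)
  if (length(lines) >= min_lines_for_blocking) {
    units <- sapply(lines, function(l)
      rowMeans(ratios[, line_of == l, drop = FALSE]))
  } else {
    units <- ratios
  }
  n <- ncol(units)
  m <- rowMeans(units)
  s <- apply(units, 1, sd)
  tstat <- m / (s / sqrt(n))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  p[!is.finite(tstat)] <- 1
  out <- data.frame(gene_id = rownames(units), lfc = m, p = p,
                    stringsAsFactors = FALSE)
  out$fdr <- p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < fdr_cutoff
  out$direction <- ifelse(out$lfc < 0, "down",
                          ifelse(out$lfc > 0, "up", "none"))
  rownames(out) <- NULL
  attr(out, "backend") <- "ratio_t"
  attr(out, "fdr_cutoff") <- fdr_cutoff
  class(out) <- c("ase_direction", "de_result", "data.frame")
  out
}

#' Directional sign test on hybrid ASE
#'
#' [sign_test()] applied to allelic directions, with the background taken
#' from all genes with significant allelic imbalance.
#'
#' @inheritParams sign_test
#' @param ase_dir An `ase_direction`.
#' @return A `sign_test_result` row.
#' @export
ase_sign_test <- function(ase_dir, gene_set, fdr_cutoff = 0.05,
                          set_name = "set") {
  sign_test(ase_dir, gene_set, fdr_cutoff = fdr_cutoff,
            set_name = set_name)
}

#' Fisher's exact test coupling derived lineage to allelic direction
#'
#' Builds the 2x2 table of (ingroup1-derived vs ingroup2-derived) x (down-
#' vs up-regulated from the species-1 allele) and applies the exact
#' two-sided test. The odds ratio reported is the classical cross-product
#' ad/bc; a zero margin flags it and the Haldane-corrected value is always
#' reported alongside. Optionally prefilters to genes whose expression
#' fold-change signs agree between the tissue comparison and the ASE data.
#'
#' @param assignments A `lineage_assignment` (gene_id, label).
#' @param ase_dir An `ase_direction`.
#' @param counts Alternatively, a 2x2 matrix of counts
#'   (rows: ingroup1/ingroup2-derived; columns: down/up) used directly.
#' @param invivo_lfc Named tissue log2 fold-changes for the sign-agreement
#'   prefilter.
#' @param prefilter_sign_agreement Apply the prefilter (requires
#'   `invivo_lfc`).
#' @param significant_only Restrict to genes with significant ASE.
#' @return List of class `fisher_result`: `table`, `odds_ratio`,
#'   `odds_ratio_haldane`, `p`, `flag`, `n`.
#' @export
derived_lineage_fisher <- function(assignments = NULL, ase_dir = NULL,
                                   counts = NULL, invivo_lfc = NULL,
                                   prefilter_sign_agreement = FALSE,
                                   significant_only = TRUE) {
  if (is.null(counts)) {
    stopifnot(!is.null(assignments), !is.null(ase_dir))
    d <- merge(as.data.frame(assignments),
               as.data.frame(ase_dir)[, c("gene_id", "lfc", "significant")],
               by = "gene_id")
    if (significant_only) d <- d[d$significant, , drop = FALSE]
    d <- d[d$label %in% c("ingroup1_derived", "ingroup2_derived") &
             d$lfc != 0, , drop = FALSE]
    if (prefilter_sign_agreement) {
      stopifnot(!is.null(invivo_lfc))
      iv <- invivo_lfc[d$gene_id]
      d <- d[!is.na(iv) & sign(iv) == sign(d$lfc), , drop = FALSE]
    }
    counts <- matrix(c(
      sum(d$label == "ingroup1_derived" & d$lfc < 0),
      sum(d$label == "ingroup1_derived" & d$lfc > 0),
      sum(d$label == "ingroup2_derived" & d$lfc < 0),
      sum(d$label == "ingroup2_derived" & d$lfc > 0)),
      nrow = 2, byrow = TRUE,
      dimnames = list(c("ingroup1_derived", "ingroup2_derived"),
                      c("down", "up")))
  }
  counts <- as.matrix(counts)
  a <- counts[1, 1]; b <- counts[1, 2]; c_ <- counts[2, 1]; d_ <- counts[2, 2]
  or <- if (b == 0 || c_ == 0) NA_real_ else (a * d_) / (b * c_)
  or_h <- ((a + 0.5) * (d_ + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  p <- if (sum(counts) == 0) NA_real_ else fisher.test(counts)$p.value
  structure(list(table = counts, odds_ratio = or,
                 odds_ratio_haldane = or_h, p = p,
                 flag = if (is.na(or)) "zero margin" else NA_character_,
                 n = sum(counts)),
            class = "fisher_result")
}

#' Down-regulation proportions across gene categories
#'
#' Partitions significant genes into set-in-category, set-not-in-category
#' and category-not-in-set (set members removed from category lists and
#' vice versa), reports the proportion down-regulated in each, and tests
#' set-in-category counts with a binomial test whose background is the
#' down-proportion among category genes not in the set.
#'
#' @param de A `de_result`.
#' @param gene_set Focal set (e.g. disorder-linked genes).
#' @param categories Named list of category gene-id vectors.
#' @param fdr_cutoff Significance threshold.
#' @return Data frame: one row per category with partition sizes,
#'   down-proportions, binomial `p`, `flag` for empty partitions.
#' @export
category_split_test <- function(de, gene_set, categories,
                                fdr_cutoff = 0.05) {
  sig <- de[!is.na(de$fdr) & de$fdr < fdr_cutoff & de$lfc != 0, ]
  prop_down <- function(genes) {
    sub <- sig[sig$gene_id %in% genes, ]
    n <- nrow(sub)
    list(n = n, n_down = sum(sub$lfc < 0),
         prop = if (n > 0) sum(sub$lfc < 0) / n else NA_real_)
  }
  rows <- lapply(names(categories), function(nm) {
    cat_genes <- categories[[nm]]
    set_in <- intersect(gene_set, cat_genes)
    set_not_in <- setdiff(gene_set, cat_genes)
    cat_not_set <- setdiff(cat_genes, gene_set)
    a <- prop_down(set_in); b <- prop_down(set_not_in)
    c_ <- prop_down(cat_not_set)
    p <- if (a$n > 0 && !is.na(c_$prop) && c_$prop > 0 && c_$prop < 1) {
      binom.test(a$n_down, a$n, c_$prop)$p.value
    } else NA_real_
    data.frame(category = nm,
               n_set_in = a$n, prop_set_in_down = a$prop,
               n_set_not_in = b$n, prop_set_not_in_down = b$prop,
               n_cat_not_set = c_$n, prop_cat_not_set_down = c_$prop,
               p = p,
               flag = if (a$n == 0 || c_$n == 0) "empty partition"
                      else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Lineage balance of TSS-proximal derived variants with downsampling
#'
#' Corrects for unequal genome-wide derived-variant totals by binomially
#' thinning the lineage with the larger total (keeping each variant with
#' probability total_other / total_larger), then compares per-gene counts
#' over the gene set with a paired two-sided t-test.
#'
#' @param counts1,counts2 Named per-gene derived-variant counts near the TSS
#'   for lineage 1 and lineage 2.
#' @param total1,total2 Genome-wide derived-variant totals per lineage.
#' @param gene_set Genes to test.
#' @param seed Seed for the thinning.
#' @return List: `p`, `mean_diff` (lineage1 - lineage2 after thinning),
#'   `thin_fraction`, `swapped` (TRUE when lineage 2 was thinned instead).
#' @export
tss_variant_balance <- function(counts1, counts2, total1, total2, gene_set,
                                seed = 1) {
  genes <- intersect(intersect(names(counts1), names(counts2)), gene_set)
  if (length(genes) < 2) stop("need >= 2 set genes with counts")
  swapped <- FALSE
  if (total1 < total2) {
    message("tss_variant_balance: lineage 2 has the larger total; ",
            "thinning direction swapped")
    swapped <- TRUE
    tmp <- counts1; counts1 <- counts2; counts2 <- tmp
    tmpt <- total1; total1 <- total2; total2 <- tmpt
  }
  f <- total2 / total1
  x1 <- with_seed(seed, rbinom(length(genes), counts1[genes], f))
  x2 <- counts2[genes]
  d <- x1 - x2
  p <- if (sd(d) == 0) 1 else t.test(x1, x2, paired = TRUE)$p.value
  list(p = p, mean_diff = mean(d), thin_fraction = f, swapped = swapped)
}
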