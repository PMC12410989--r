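de_fixture <- function(seed = 42, n_genes = 2000, sigma0 = 0.5,
                       biased_set = NULL) {
  cfg <- sim_config(n_genes = n_genes, cell_type_proportions = c(only = 1),
                    cell_type_classes = c(only = "excitatory"),
                    gamma = 0, sigma0 = sigma0, n_cells = 4000,
                    n_individuals = 4, individual_effect_sd = 0.1,
                    library_size_log_mean = log(1000), seed = seed,
                    biased_set = biased_set)
  prof <- simulate_expression_profiles(cfg)
  cm <- simulate_cells(prof, cfg, species_subset = sim_pair)
  pb <- pseudobulk_by_individual(cm, sim_pair, "only")
  list(pb = pb, truth = prof$truth, cfg = cfg)
}

test_that("differential expression recovers planted fold-changes", {
  # small planted set (keeps the softmax compositional distortion
  # negligible) on an otherwise quiet background, so the only true
  # between-species signal is the planted 2-fold shift; recovery is
  # asserted for genes expressed well enough to be quantifiable
  fx <- de_fixture(seed = 71, sigma0 = 1e-3,
                   biased_set = list(genes = 30, lineage = "ingroup1",
                                     mean_shift = 1, sd = 0.05))
  expressed <- rowMeans(fx$pb$counts) >= 100
  planted <- intersect(fx$truth$biased_genes,
                       rownames(fx$pb$counts)[expressed])
  expect_gt(length(planted), 15)
  for (b in c("nb_wald", "welch_logcpm")) {
    de <- differential_expression(fx$pb$counts, fx$pb$group, backend = b)
    lfc <- setNames(de$lfc, de$gene_id)[planted]
    expect_gt(mean(abs(lfc - 1) < 0.3), 0.9)
    expect_gt(mean(de$significant[de$gene_id %in% planted]), 0.8)
  }
})

test_that("differential expression is null-calibrated on identical groups", {
  fx <- de_fixture(seed = 72, sigma0 = 1e-4)
  for (b in c("nb_wald", "welch_logcpm")) {
    de <- differential_expression(fx$pb$counts, fx$pb$group, backend = b)
    expect_lt(abs(mean(de$lfc)), 0.05)
    frac <- mean(de$p < 0.05, na.rm = TRUE)
    expect_gt(frac, 0.01); expect_lt(frac, 0.09)
  }
  expect_error(differential_expression(fx$pb$counts[, c(1, 5)],
                                       fx$pb$group[c(1, 5)]),
               class = "celltempo_too_few_samples")
})

test_that("external DE tables round-trip and get BH-FDR", {
  ext <- data.frame(gene_id = c("b", "a", "c"), lfc = c(1, -2, 0.5),
                    p = c(0.2, 0.001, 0.04))
  de <- differential_expression(backend = "external_table", external = ext)
  expect_equal(de$gene_id, c("a", "b", "c"))
  expect_equal(de$lfc, c(-2, 1, 0.5))
  expect_equal(de$fdr, ref_bh(de$p))
})

test_that("BH-FDR equals the reference step-up procedure exactly", {
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(3:200, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), ref_bh(p), tolerance = 1e-15)
  }
})

test_that("sign test handles symmetric, one-sided, and empty cases", {
  de <- structure(data.frame(
    gene_id = sprintf("g%03d", 1:40),
    lfc = c(rep(-1, 10), rep(1, 10), rep(-1, 10), rep(1, 10)),
    p = 1e-6, fdr = 1e-6, significant = TRUE), class = c("de_result",
                                                         "data.frame"))
  bal <- sign_test(de, sprintf("g%03d", 1:20))
  expect_equal(bal$fold_enrichment, 1)
  expect_equal(bal$p, 1)
  # all-down set: closed form 2 * 0.5^20 under a balanced background
  allg <- structure(data.frame(
    gene_id = sprintf("h%03d", 1:140),
    lfc = c(rep(-1, 20), rep(-1, 50), rep(1, 70)),
    p = 1e-6, fdr = 1e-6, significant = TRUE),
    class = c("de_result", "data.frame"))
  res <- sign_test(allg, sprintf("h%03d", 1:20), background_p = 0.5)
  expect_equal(res$p, min(1, 2 * 0.5^20 - 0.5^20 * 0), tolerance = 1e-6)
  expect_equal(res$n_down, 20); expect_equal(res$n_up, 0)
  expect_equal(res$flag, "zero margin")
  expect_true(is.finite(res$fold_enrichment_haldane))
  # no significant members -> flagged null
  none <- sign_test(de, "absent_gene")
  expect_equal(none$flag, "no significant set members")
  # reduces to symmetric binomial when background_p = 0.5
  expect_equal(sign_test(allg, sprintf("h%03d", 1:20),
                         background_p = 0.5)$p,
               binom.test(20, 20, 0.5)$p.value)
})

test_that("zero-lfc genes carry no sign information", {
  de <- structure(data.frame(
    gene_id = c("a", "b", "c", "d"), lfc = c(0, 0, -1, 1),
    p = 1e-6, fdr = 1e-6, significant = TRUE),
    class = c("de_result", "data.frame"))
  res <- sign_test(de, c("a", "b", "c", "d"))
  expect_equal(res$n_down + res$n_up, 2)
})

test_that("gene-set scan: identity, overlap removal, planted-set ranking", {
  fx <- de_fixture(seed = 73)
  de <- differential_expression(fx$pb$counts, fx$pb$group,
                                backend = "welch_logcpm")
  set.seed(1)
  sets <- setNames(lapply(1:5, function(i) sample(de$gene_id, 120)),
                   paste0("s", 1:5))
  sc <- scan_gene_sets(de, sets, min_size = 100)
  expect_equal(nrow(sc), 5)
  single <- sign_test(de, sets$s1, set_name = "s1")
  expect_equal(sc$p[sc$set == "s1"], single$p)
  expect_equal(sc$n_down[sc$set == "s1"], single$n_down)
  # removing a set from itself leaves an empty row, not an error
  sc2 <- scan_gene_sets(de, sets["s1"], min_size = 100,
                        overlap_removal = sets$s1)
  expect_equal(sc2$flag, "no significant set members")
  expect_equal(sc$fdr, ref_bh(sc$p))
})

test_that("ASE directions recover forced ratios and planted cis effects", {
  tab <- ase_table(data.frame(
    gene_id = rep(c("g1", "g2"), each = 4),
    sample = rep(paste0("s", 1:4), 2), line = rep(c("l1", "l2"), 4),
    allele1_count = c(30, 30, 30, 30, 10, 10, 10, 10),
    allele2_count = c(10, 10, 10, 10, 10, 10, 10, 10)))
  ad <- ase_direction(tab)
  expect_equal(ad$lfc[ad$gene_id == "g1"], log2(30.5 / 10.5),
               tolerance = 1e-9)
  expect_equal(ad$lfc[ad$gene_id == "g2"], 0, tolerance = 1e-9)
  expect_equal(ad$direction[ad$gene_id == "g2"], "none")

  cfg <- sim_config(n_genes = 1200, cell_type_proportions = c(only = 1),
                    cell_type_classes = c(only = "excitatory"),
                    n_cells = 10, seed = 74,
                    biased_set = list(genes = 40, lineage = "ingroup1",
                                      mean_shift = -0.5, sd = 0.1))
  pr <- simulate_expression_profiles(cfg)
  asim <- simulate_ase(pr$truth, cfg)
  ad2 <- ase_direction(asim$ase)
  expect_gt(cor(ad2$lfc, asim$cis[ad2$gene_id], method = "spearman"), 0.8)
  st <- ase_sign_test(ad2, pr$truth$biased_genes)
  expect_lt(st$p, 0.05)
  expect_gt(st$n_down, st$n_up)
})

test_that("Fisher coupling reproduces the classical odds ratio and exact P", {
  tab <- matrix(c(27, 5, 9, 10), 2, 2, byrow = TRUE)
  fr <- derived_lineage_fisher(counts = tab)
  expect_equal(fr$odds_ratio, 6.0)
  expect_equal(fr$p, ref_fisher_p(tab), tolerance = 1e-9)
  expect_lt(abs(fr$p - 0.010), 0.001)
  # identical rows -> OR 1, P 1
  same <- derived_lineage_fisher(counts = matrix(c(8, 3, 8, 3), 2, 2,
                                                 byrow = TRUE))
  expect_equal(same$odds_ratio, 1)
  expect_equal(same$p, 1)
  # random tables with n <= 40 against full enumeration
  set.seed(10)
  for (i in 1:40) {
    t4 <- matrix(rmultinom(1, sample(8:40, 1), rep(0.25, 4)), 2, 2)
    fr_i <- derived_lineage_fisher(counts = t4)
    expect_equal(fr_i$p, ref_fisher_p(t4), tolerance = 1e-9)
  }
  # zero margin flagged, Haldane value present
  zm <- derived_lineage_fisher(counts = matrix(c(5, 0, 2, 0), 2, 2,
                                               byrow = TRUE))
  expect_equal(zm$flag, "zero margin")
  expect_true(is.finite(zm$odds_ratio_haldane))
})

test_that("Fisher coupling assembles its table from assignments and ASE", {
  asn <- data.frame(
    gene_id = sprintf("g%02d", 1:20),
    label = rep(c("ingroup1_derived", "ingroup2_derived"), each = 10))
  ad <- structure(data.frame(
    gene_id = sprintf("g%02d", 1:20),
    lfc = c(rep(-1, 8), rep(1, 2), rep(-1, 4), rep(1, 6)),
    p = 1e-5, fdr = 1e-5, significant = TRUE),
    class = c("ase_direction", "de_result", "data.frame"))
  fr <- derived_lineage_fisher(asn, ad)
  expect_equal(unname(fr$table[1, ]), c(8, 2))
  expect_equal(unname(fr$table[2, ]), c(4, 6))
  # sign-agreement prefilter drops discordant genes
  iv <- setNames(c(rep(-1, 19), 1), sprintf("g%02d", 1:20))
  fr2 <- derived_lineage_fisher(asn, ad, invivo_lfc = iv,
                                prefilter_sign_agreement = TRUE)
  expect_equal(sum(fr2$table), sum(sign(iv) == sign(ad$lfc)))
})

test_that("category split reports comparable proportions under uniform bias", {
  set.seed(12)
  ids <- sprintf("g%04d", 1:900)
  de <- structure(data.frame(
    gene_id = ids, lfc = ifelse(runif(900) < 0.5, -1, 1),
    p = 1e-5, fdr = 1e-5, significant = TRUE),
    class = c("de_result", "data.frame"))
  gene_set <- sample(ids, 200)
  de$lfc[de$gene_id %in% gene_set] <-
    ifelse(runif(200) < 0.8, -1, 1)  # uniform down-bias in the set
  cats <- list(synaptic = sample(ids, 300), tf_cr = sample(ids, 250))
  res <- category_split_test(de, gene_set, cats)
  expect_equal(nrow(res), 2)
  expect_true(all(res$prop_set_in_down > res$prop_cat_not_set_down))
  expect_lt(abs(res$prop_set_in_down[1] - res$prop_set_in_down[2]), 0.2)
  empty <- category_split_test(de, gene_set, list(none = "absent"))
  expect_equal(empty$flag, "empty partition")
})

test_that("TSS variant balance thins correctly and detects planted excess", {
  ids <- sprintf("g%03d", 1:300)
  set.seed(13)
  c2 <- setNames(rpois(300, 10), ids)
  # equal totals: thinning is the identity in expectation, P near 1 when
  # counts are identical
  res0 <- tss_variant_balance(c2, c2, 5000, 5000, ids, seed = 1)
  expect_equal(res0$thin_fraction, 1)
  expect_equal(res0$p, 1)
  # planted 2x excess in lineage 1 for the set
  c1 <- setNames(rpois(300, 20), ids)
  hits <- 0
  for (r in 1:50) {
    cc1 <- setNames(rpois(300, 20), ids)
    cc2 <- setNames(rpois(300, 10), ids)
    # genome-wide totals equal -> the per-set excess should be detected
    res <- tss_variant_balance(cc1, cc2, 8000, 8000, sample(ids, 200),
                               seed = r)
    if (res$p < 0.05 && res$mean_diff > 0) hits <- hits + 1
  }
  expect_gte(hits, 45)
  # swapped totals direction
  expect_message(
    res_sw <- tss_variant_balance(c2, c1, 4000, 8000, ids, seed = 2),
    "swapped")
  expect_true(res_sw$swapped)
})

test_that("background probability is insensitive to excluding the set's
           own genes on large simulations", {
  fx <- de_fixture(seed = 76, n_genes = 3000)
  de <- differential_expression(fx$pb$counts, fx$pb$group,
                                backend = "welch_logcpm")
  set.seed(8)
  gene_set <- sample(de$gene_id, 150)
  with_set <- sign_test(de, gene_set)
  sig <- de[de$significant & de$lfc != 0 & !(de$gene_id %in% gene_set), ]
  bg_excl <- sum(sig$lfc < 0) / nrow(sig)
  without_set <- sign_test(de, gene_set, background_p = bg_excl)
  expect_lt(abs(with_set$background_p - bg_excl), 0.02)
  expect_lt(abs(log10(with_set$p) - log10(without_set$p)), 0.5)
})

test_that("expression-matched scan uses matched partners as background", {
  fx <- de_fixture(seed = 75)
  de <- differential_expression(fx$pb$counts, fx$pb$group,
                                backend = "welch_logcpm")
  expr <- setNames(rowMeans(fx$pb$counts) + 1, rownames(fx$pb$counts))
  set.seed(3)
  sets <- list(sA = sample(de$gene_id, 150))
  sc <- scan_gene_sets(de, sets, min_size = 100, expression_matched = TRUE,
                       expression = expr, lfc_threshold = 0.5)
  expect_equal(nrow(sc), 1)
  expect_true(is.finite(sc$p) || !is.na(sc$flag))
})
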