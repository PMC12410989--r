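test_that("downsample_cells samples exactly n without replacement", {
  sim <- small_sim(seed = 1, n_genes = 40, n_cells = 500, n_types = 3)
  cm <- sim$cm
  ct <- "t01"
  n_avail <- sum(cm$cell_meta$subclass == ct &
                   cm$cell_meta$species == "speciesA")
  sub <- downsample_cells(cm, ct, "speciesA", 20, seed = 4)
  expect_equal(nrow(sub$counts), 20)
  expect_equal(anyDuplicated(sub$cell_meta$cell_id), 0L)
  # identity when the stratum has exactly n cells
  sub2 <- downsample_cells(cm, ct, "speciesA", n_avail, seed = 4)
  expect_equal(nrow(sub2$counts), n_avail)
  # boundary: one short
  expect_error(downsample_cells(cm, ct, "speciesA", n_avail + 1, seed = 4),
               class = "celltempo_insufficient_cells")
  # n = 1 over many seeds: inclusion is uniform across cells
  idx <- which(cm$cell_meta$subclass == ct &
                 cm$cell_meta$species == "speciesA")
  picks <- vapply(1:800, function(s)
    downsample_cells(cm, ct, "speciesA", 1, seed = s)$cell_meta$cell_id, "")
  tab <- table(factor(picks, levels = cm$cell_meta$cell_id[idx]))
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.01)
})

test_that("pseudobulk sums counts and respects the ortholog map", {
  cm <- tiny_cell_matrix()
  pb <- pseudobulk(cm)
  # spA cells c1, c2 -> [1,3,2,1]
  spA <- pb$counts[, pb$meta$species == "spA"]
  expect_equal(unname(spA), c(1, 3, 2, 1))
  expect_equal(pb$meta$total_counts, colSums(pb$counts))

  map <- ortholog_map(data.frame(spA = c("g1", "g3"), spB = c("g1", "g3")))
  pb2 <- pseudobulk(cm, map)
  expect_equal(rownames(pb2$counts), c("g1", "g3"))
  map_bad <- ortholog_map(data.frame(spA = "zz", spB = "zz"))
  expect_error(pseudobulk(cm, map_bad),
               class = "celltempo_empty_ortholog_intersection")
})

test_that("pseudobulk is additive over any partition of cells", {
  sim <- small_sim(seed = 6, n_genes = 50, n_cells = 300, n_types = 2)
  cm <- sim$cm
  full <- pseudobulk(cm)
  set.seed(1)
  split_id <- sample(c(TRUE, FALSE), nrow(cm$counts), replace = TRUE)
  halves <- lapply(list(split_id, !split_id), function(w) {
    idx <- which(w)
    pseudobulk(cell_matrix(cm$counts[idx, , drop = FALSE], cm$gene_ids,
                           cm$cell_meta[idx, , drop = FALSE]))
  })
  key <- paste(full$meta$cell_type, full$meta$species)
  for (k in seq_along(key)) {
    tot <- numeric(nrow(full$counts))
    for (h in halves) {
      hk <- paste(h$meta$cell_type, h$meta$species)
      j <- match(key[k], hk)
      if (!is.na(j)) tot <- tot + h$counts[, j]
    }
    expect_equal(unname(full$counts[, k]), unname(tot))
  }
})

test_that("count downsampling follows the multivariate hypergeometric law", {
  expect_equal(downsample_count_vector(c(10L, 0L), 5L), c(5L, 0L))
  x <- c(6L, 4L)
  expect_equal(sum(downsample_count_vector(x, 5L)), 5L)
  set.seed(99)
  draws <- replicate(8000, downsample_count_vector(x, 5L)[1])
  # hypergeometric mean 5 * 6/10 = 3, variance 5*(6/10)*(4/10)*(5/9)
  expect_lt(abs(mean(draws) - 3), 0.03)
  expect_lt(abs(var(draws) - 5 * 0.6 * 0.4 * 5 / 9), 0.03)
  # against R's own hypergeometric sampler on the two-gene case
  set.seed(7)
  ref <- rhyper(8000, 6, 4, 5)
  expect_gt(suppressWarnings(ks.test(draws, ref))$p.value, 0.01)
  expect_error(downsample_count_vector(c(1L, 1L), 5L), "exceeds")
})

test_that("downsample_counts equalizes profile totals exactly", {
  sim <- small_sim(seed = 2, n_genes = 60, n_cells = 400, n_types = 2)
  pb <- pseudobulk(sim$cm)
  ds <- downsample_counts(pb, seed = 3)
  expect_true(all(ds$meta$total_counts == min(pb$meta$total_counts)))
  expect_true(all(ds$counts <= pb$counts))
  # identity at target = total
  one <- pseudobulk(tiny_cell_matrix())
  same <- downsample_counts(one, target = min(one$meta$total_counts),
                            seed = 1)
  expect_true(all(same$meta$total_counts == min(one$meta$total_counts)))
  expect_error(downsample_counts(pb, target = max(pb$meta$total_counts) + 1),
               class = "celltempo_insufficient_counts")
})

test_that("gene filter applies the printed two-rule logic", {
  # counts (30, 3): passes count rule via species 1 -> kept
  x <- c(30, 24, 100, 2)
  y <- c(3, 24, 50, 1)
  mask <- filter_genes(x, y, min_counts = 25, min_cpm = 1)
  expect_true(mask[1])
  expect_false(mask[2])  # 24 in both species, boundary
  # oracle equivalence on simulator output
  sim <- small_sim(seed = 8, n_genes = 200, n_cells = 600, n_types = 2)
  pb <- downsample_counts(pseudobulk(sim$cm), seed = 1)
  xa <- pb$counts[, 1]; xb <- pb$counts[, 2]
  expect_equal(unname(filter_genes(xa, xb, 25, 1)),
               ref_filter(xa, xb, 25, 1))
  expect_equal(unname(filter_genes(xa, xb, 10, 5)),
               ref_filter(xa, xb, 10, 5))
})

test_that("expression distances match brute-force references to 1e-12", {
  set.seed(123)
  for (i in 1:25) {
    x <- rexp(50) * 1000
    y <- rexp(50) * 1000
    for (m in c("spearman_distance", "pearson_distance", "euclidean",
                "l1")) {
      for (tr in c("log2", "none")) {
        expect_equal(expression_distance(x, y, metric = m, transform = tr),
                     ref_distance(x, y, m, tr), tolerance = 1e-12)
      }
    }
  }
  x <- c(1, 2, 3, 4)
  expect_equal(expression_distance(x, x, "spearman_distance"), 0)
  expect_equal(expression_distance(x, rev(x), "spearman_distance"), 2)
  expect_error(expression_distance(x, rep(2, 4), "spearman_distance"),
               class = "celltempo_constant_vector")
  expect_error(expression_distance(1:2, 1:2, "euclidean"),
               class = "celltempo_too_few_genes")
})

test_that("spearman distance is invariant to monotone transforms of CPM", {
  set.seed(5)
  x <- rexp(80) * 500; y <- rexp(80) * 500
  d1 <- expression_distance(x, y, "spearman_distance", transform = "none")
  d2 <- expression_distance(sqrt(x), sqrt(y), "spearman_distance",
                            transform = "none")
  d3 <- expression_distance(x, y, "spearman_distance", transform = "log2",
                            log_pseudocount = 7)
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_equal(d1, d3, tolerance = 1e-12)
})

test_that("run_divergence is deterministic and equalizes every iteration", {
  sim <- small_sim(seed = 4, n_genes = 150, n_cells = 1200, n_types = 4)
  params <- divergence_params(cells_per_type = 30, n_iterations = 3,
                              seed = 17, min_counts = 5)
  a <- run_divergence(sim$cm, sim$ortholog_map, params, sim_pair)
  b <- run_divergence(sim$cm, sim$ortholog_map, params, sim_pair)
  expect_identical(a$values, b$values)
  expect_true(all(a$values$distance >= 0, na.rm = TRUE))
  expect_true(all(a$values$distance <= 2, na.rm = TRUE))
  expect_equal(nrow(a$values), 4 * 3)
  # a cell type present in only one species is excluded
  cm2 <- sim$cm
  drop <- cm2$cell_meta$subclass == "t04" &
    cm2$cell_meta$species == "speciesB"
  cm2 <- cell_matrix(cm2$counts[!drop, ], cm2$gene_ids,
                     cm2$cell_meta[!drop, ])
  d2 <- run_divergence(cm2, NULL, params, sim_pair)
  expect_false("t04" %in% d2$cell_types)
  expect_error(run_divergence(sim$cm, NULL,
                              divergence_params(cells_per_type = 10000),
                              sim_pair),
               class = "celltempo_no_qualifying_types")
})

test_that("planted divergence increases measured distance for every type", {
  null_sim <- small_sim(seed = 31, n_genes = 250, n_cells = 1500,
                        n_types = 4, gamma = 0, sigma0 = 1e-4)
  div_sim <- small_sim(seed = 31, n_genes = 250, n_cells = 1500,
                       n_types = 4, gamma = 0, sigma0 = 0.5)
  params <- divergence_params(cells_per_type = 50, n_iterations = 5,
                              seed = 2, min_counts = 5)
  d0 <- run_divergence(null_sim$cm, NULL, params, sim_pair)
  d1 <- run_divergence(div_sim$cm, NULL, params, sim_pair)
  m0 <- setNames(d0$medians$median_distance, d0$medians$cell_type)
  m1 <- setNames(d1$medians$median_distance, d1$medians$cell_type)
  shared <- intersect(names(m0), names(m1))
  expect_true(all(m1[shared] > m0[shared]))
})

test_that("robustness grid returns one row per combination", {
  sim <- small_sim(seed = 12, n_genes = 120, n_cells = 1500, n_types = 5,
                   sigma0 = 0.1)
  grid <- expand.grid(cells_per_type = c(20, 40), min_counts = c(5, 10),
                      stringsAsFactors = FALSE)
  out <- robustness_grid(sim$cm, NULL, grid, sim_pair, n_iterations = 2,
                         seed = 1)
  expect_equal(nrow(out), 4)
  expect_true(all(is.na(out$error)))
  expect_true(all(out$median_rho < 0))
  # canonical grid cardinality (no run, just the expansion rule)
  full <- expand.grid(cells_per_type = c(50, 100, 250, 500),
                      min_counts = c(5, 10, 25, 50), min_cpm = c(1, 5),
                      transform = c("log2", "none"),
                      metric = c("spearman_distance", "pearson_distance",
                                 "euclidean", "l1"))
  expect_equal(nrow(full), 256)
})
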