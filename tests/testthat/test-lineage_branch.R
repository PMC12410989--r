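test_that("branch decomposition follows the parsimony formulas exactly", {
  tr <- data.frame(cell_type = "A", iteration = 1,
                   d12 = 0.10, d1o = 0.12, d2o = 0.06)
  bd <- branch_decompose(tr)
  expect_equal(bd$values$branch1, 0.08)
  expect_equal(bd$values$branch2, 0.02)
  # symmetric outgroup distances split the pair divergence in half
  tr2 <- data.frame(cell_type = "A", iteration = 1,
                    d12 = 0.4, d1o = 0.3, d2o = 0.3)
  bd2 <- branch_decompose(tr2)
  expect_equal(bd2$values$branch1, bd2$values$branch2)
  expect_equal(bd2$values$branch1, 0.2)
})

test_that("branch additivity and relabeling symmetry hold on random triples", {
  set.seed(3)
  n <- 10000
  tr <- data.frame(cell_type = "A", iteration = seq_len(n),
                   d12 = runif(n), d1o = runif(n), d2o = runif(n))
  bd <- branch_decompose(tr)
  expect_true(all(abs(bd$values$branch1 + bd$values$branch2 -
                        tr$d12) < 1e-12))
  swapped <- branch_decompose(
    data.frame(cell_type = "A", iteration = seq_len(n), d12 = tr$d12,
               d1o = tr$d2o, d2o = tr$d1o))
  expect_equal(swapped$values$branch1, bd$values$branch2, tolerance = 1e-12)
  expect_equal(swapped$values$branch2, bd$values$branch1, tolerance = 1e-12)
})

test_that("branch recovery from an asymmetric-branch simulation", {
  # plant ingroup1 branch twice as long; noise-free profiles, euclidean
  p <- c(a = 0.5, b = 0.3, c = 0.2)
  cfg <- sim_config(n_genes = 3000, cell_type_proportions = p, gamma = 0,
                    sigma0 = 0.3, n_cells = 10, seed = 5,
                    branch_lengths = c(ingroup1 = 2, ingroup2 = 1,
                                       outgroup = 3))
  pr <- simulate_expression_profiles(cfg)
  sp <- pr$species_profiles
  d <- function(x, y, ct) sqrt(sum((x[, ct] - y[, ct])^2))
  tr <- do.call(rbind, lapply(names(p), function(ct) data.frame(
    cell_type = ct, iteration = 1,
    d12 = d(sp$speciesA, sp$speciesB, ct)^2,
    d1o = d(sp$speciesA, sp$speciesC, ct)^2,
    d2o = d(sp$speciesB, sp$speciesC, ct)^2)))
  # squared euclidean distances are additive along independent branches,
  # so recovered branches match the planted squared-shift expectations
  bd <- branch_decompose(tr)
  g <- cfg$n_genes
  for (ct in names(p)) {
    s <- bd$summary[bd$summary$cell_type == ct, ]
    sigma <- 0.3
    expect_lt(abs(s$branch1 / (g * (2 * sigma)^2) - 1), 0.1)
    expect_lt(abs(s$branch2 / (g * sigma^2) - 1), 0.1)
  }
  expect_true(all(abs(bd$summary$acceleration_ratio - 4) < 0.6))
})

test_that("acceleration report ranks the doubled-branch type first", {
  s <- data.frame(cell_type = c("x", "y", "z"),
                  branch1 = c(0.2, 0.1, 0.1), branch2 = c(0.1, 0.1, 0.1))
  s$acceleration_ratio <- s$branch1 / s$branch2
  rep_ <- acceleration_report(s, variability = c(x = 0.05, y = 0.05,
                                                 z = 0))
  expect_equal(rep_$cell_type[1], "x")
  expect_equal(rep_$variability_ratio[1], 4)
  expect_true(rep_$undefined_flag[rep_$cell_type == "z"])
  # equal branches -> all ratios 1
  s2 <- data.frame(cell_type = c("x", "y"), branch1 = c(.1, .2),
                   branch2 = c(.1, .2))
  s2$acceleration_ratio <- s2$branch1 / s2$branch2
  expect_true(all(acceleration_report(s2)$acceleration_ratio == 1))
  # negative branch flagged
  tr <- data.frame(cell_type = "n", iteration = 1, d12 = 0.1, d1o = 0.05,
                   d2o = 0.3)
  bd <- branch_decompose(tr)
  expect_true(bd$values$negative_flag)
  expect_true(acceleration_report(bd)$undefined_flag)
})

test_that("lineage assignment applies ambiguity and variant rules", {
  lfc12 <- c(g1 = 0.5, g2 = 0.8, g3 = 0.2)
  lfc1o <- c(g1 = 0.9, g2 = 0.9, g3 = 0.1)
  lfc2o <- c(g1 = 0.8, g2 = 0.1, g3 = 0.1)
  for (v in c("as_printed", "outgroup_proximity")) {
    asn <- assign_lineage(lfc12, lfc1o, lfc2o, rule_variant = v)
    lab <- setNames(asn$label, asn$gene_id)
    expect_equal(unname(lab["g1"]), "ambiguous")
    expect_equal(unname(lab["g2"]), "ingroup1_derived")
  }
  # exhaustive and mutually exclusive on random triples
  set.seed(8)
  r12 <- setNames(rnorm(500), paste0("r", 1:500))
  r1o <- setNames(rnorm(500), paste0("r", 1:500))
  r2o <- setNames(rnorm(500), paste0("r", 1:500))
  for (v in c("as_printed", "outgroup_proximity")) {
    asn <- assign_lineage(r12, r1o, r2o, rule_variant = v)
    expect_equal(nrow(asn), 500)
    expect_true(all(asn$label %in% c("ingroup1_derived", "ingroup2_derived",
                                     "ambiguous")))
  }
  # genes missing a fold-change are skipped with a message
  expect_message(assign_lineage(c(g1 = 1, g9 = 1), lfc1o, lfc2o), "skipped")
})

test_that("planted ingroup1 shifts are recovered as ingroup1-derived", {
  cfg <- sim_config(n_genes = 2000, cell_type_proportions = c(only = 1),
                    cell_type_classes = c(only = "excitatory"),
                    gamma = 0, sigma0 = 0.05, n_cells = 10, seed = 19,
                    biased_set = list(genes = 150, lineage = "ingroup1",
                                      mean_shift = -1, sd = 0.2))
  pr <- simulate_expression_profiles(cfg)
  sp <- pr$species_profiles
  lfc12 <- setNames(sp$speciesA[, 1] - sp$speciesB[, 1], pr$truth$gene_ids)
  lfc1o <- setNames(sp$speciesA[, 1] - sp$speciesC[, 1], pr$truth$gene_ids)
  lfc2o <- setNames(sp$speciesB[, 1] - sp$speciesC[, 1], pr$truth$gene_ids)
  asn <- assign_lineage(lfc12, lfc1o, lfc2o,
                        rule_variant = "outgroup_proximity")
  lab <- setNames(asn$label, asn$gene_id)[pr$truth$biased_genes]
  expect_gt(mean(lab == "ingroup1_derived"), 0.8)
})

test_that("outgroup proximity comparison reports direction and P", {
  h <- setNames(rep(0.7, 20), paste0("g", 1:20))
  g <- setNames(rep(0.2, 20), paste0("g", 1:20))
  res <- compare_outgroup_proximity(h, g)
  expect_equal(res$direction, "outgroup_closer_to_ingroup2")
  expect_lt(res$p, 0.001)
  res_eq <- compare_outgroup_proximity(h, h)
  expect_equal(res_eq$p, 1)
  expect_equal(res_eq$direction, "null")
  res_small <- compare_outgroup_proximity(h[1:3], g[1:3])
  expect_true(is.na(res_small$p))
})

test_that("triple divergence shares the downsampling and decomposes sensibly", {
  p <- c(x = 0.6, y = 0.4)
  cfg <- sim_config(n_genes = 200, cell_type_proportions = p,
                    cell_type_classes = c(x = "excitatory",
                                          y = "inhibitory"),
                    gamma = 0, sigma0 = 0.4, n_cells = 1200,
                    n_individuals = 2, seed = 23,
                    branch_lengths = c(ingroup1 = 2, ingroup2 = 1,
                                       outgroup = 2),
                    library_size_log_mean = log(600))
  sim <- simulate_dataset(cfg, with_ase = FALSE)
  params <- divergence_params(cells_per_type = 60, n_iterations = 4,
                              seed = 7, min_counts = 5)
  tr <- run_divergence_triple(sim$cm, NULL, params, "speciesA", "speciesB",
                              "speciesC")
  expect_equal(nrow(tr), 2 * 4)
  expect_true(all(tr$d12 >= 0 & tr$d1o >= 0 & tr$d2o >= 0))
  bd <- branch_decompose(tr)
  # the doubled ingroup1 branch dominates
  expect_true(all(bd$summary$branch1 > bd$summary$branch2))
})
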