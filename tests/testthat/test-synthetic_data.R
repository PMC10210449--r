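# synthetic data generator: configuration invariants, analytic truth,
# determinism, and distributional recovery

test_that("sim_config validates its invariants", {
  expect_error(sim_config(10, 2, type_proportions_female = c(0.6, 0.6)),
               "summing to 1")
  expect_error(sim_config(10, 2, baseline_means = matrix(1, 3, 2)),
               "must be 10 x 2")
  expect_error(sim_config(10, 2, dropout_rate = 1.5), "dropout_rate")
  expect_error(sim_config(10, 2, regulatory_fraction = -0.1),
               "regulatory_fraction")
  expect_error(sim_config(10, 2, nb_dispersion = -1), "dispersions")
})

test_that("expected_bulk_lfc reproduces the closed-form mixture oracle", {
  # gene 1: means (10, 0), pi_f = (.5, .5), pi_m = (.25, .75)
  #   -> mixture means 5 vs 2.5 -> lfc = log2(2) = 1 (hand computed)
  cfg <- sim_config(n_genes = 3, n_cell_types = 2,
                    baseline_means = rbind(c(10, 0), c(6, 6), c(0, 4)),
                    type_proportions_female = c(0.5, 0.5),
                    type_proportions_male = c(0.25, 0.75), seed = 1)
  lfc <- expected_bulk_lfc(cfg)
  expect_equal(lfc$expected_lfc[1], 1.0)
  # gene 2 equal in both types: lfc 0 by symmetry of the mixture
  expect_equal(lfc$expected_lfc[2], 0)
  # gene 3: log2((.5*4)/(.75*4)) (hand computed)
  expect_equal(lfc$expected_lfc[3], log2(0.5 / 0.75))
  expect_false(any(lfc$sex_limited))
})

test_that("no effects and equal proportions give all-zero expected lfc", {
  cfg <- sim_config(n_genes = 40, n_cell_types = 3, seed = 2)
  expect_equal(expected_bulk_lfc(cfg)$expected_lfc, rep(0, 40))
})

test_that("genes confined to a sex-limited cell type are flagged", {
  cfg <- sim_config(n_genes = 2, n_cell_types = 2,
                    baseline_means = rbind(c(5, 0), c(1, 1)),
                    type_proportions_female = c(0.4, 0.6),
                    type_proportions_male = c(0, 1), seed = 1)
  lfc <- expected_bulk_lfc(cfg)
  expect_identical(lfc$expected_lfc[1], Inf)
  expect_true(lfc$sex_limited[1])
  expect_false(lfc$sex_limited[2])
})

test_that("simulate_counts dimensions and determinism", {
  cfg <- sim_config(n_genes = 50, n_cell_types = 2,
                    n_replicates_per_sex = 3, cells_per_sample = 100,
                    seed = 3)
  sim <- simulate_counts(cfg)
  expect_identical(dim(sim$counts), c(50L, 600L))
  expect_identical(nrow(sim$metadata), 600L)
  expect_identical(sim$metadata$cell_id, colnames(sim$counts))
  sim2 <- simulate_counts(cfg)
  expect_identical(as.matrix(sim$counts), as.matrix(sim2$counts))
  expect_identical(sim$metadata, sim2$metadata)
  expect_identical(sim$truth, sim2$truth)
})

test_that("per-(gene,type) empirical means recover configured NB means", {
  # 6,000 cells per type, library scaling off so cell mean == baseline
  base <- matrix(c(1, 3, 8, 20, 2, 6, 15, 40), 4, 2)
  cfg <- sim_config(n_genes = 4, n_cell_types = 2,
                    n_replicates_per_sex = 1, cells_per_sample = 12000,
                    baseline_means = base, libsize_logsd = 0, seed = 4)
  sim <- simulate_counts(cfg)
  for (k in 1:2) {
    cells <- sim$metadata$cell_type == paste0("type", k)
    expect_gt(sum(cells), 5000)
    emp <- Matrix::rowMeans(sim$counts[, cells])
    expect_lt(max(abs(emp - base[, k]) / base[, k]), 0.05)
  }
})

test_that("empirical bulk lfc converges to the analytic expectation", {
  base <- rbind(c(10, 0), c(8, 8), c(2, 12))
  cfg <- sim_config(n_genes = 3, n_cell_types = 2,
                    n_replicates_per_sex = 1, cells_per_sample = 50000,
                    baseline_means = base,
                    type_proportions_female = c(0.5, 0.5),
                    type_proportions_male = c(0.25, 0.75),
                    libsize_logsd = 0, seed = 5)
  sim <- simulate_counts(cfg)
  truth <- sim$truth$expected_bulk_lfc
  f <- sim$metadata$sex == "female"
  emp <- log2(Matrix::rowMeans(sim$counts[, f]) /
                Matrix::rowMeans(sim$counts[, !f]))
  expect_lt(max(abs(emp - truth$expected_lfc)), 0.1)
})

test_that("empirical cell-type proportions match the configured vectors", {
  pf <- c(0.55, 0.35, 0.10); pm <- c(0.25, 0.25, 0.50)
  cfg <- sim_config(n_genes = 5, n_cell_types = 3,
                    n_replicates_per_sex = 2, cells_per_sample = 4000,
                    type_proportions_female = pf, type_proportions_male = pm,
                    seed = 6)
  sim <- simulate_counts(cfg)
  for (sex in c("female", "male")) {
    p <- if (sex == "female") pf else pm
    sub <- sim$metadata[sim$metadata$sex == sex, ]
    n <- nrow(sub)
    emp <- as.vector(table(factor(sub$cell_type,
                                  levels = paste0("type", 1:3)))) / n
    expect_lt(max(abs(emp - p) / sqrt(p * (1 - p) / n)), 4.5)
  }
})

test_that("regulatory effects are symmetric and enter the truth tables", {
  cfg <- sim_config(n_genes = 100, n_cell_types = 2,
                    regulatory_fraction = 0.2, regulatory_lfc = 2,
                    seed = 7)
  expect_length(cfg$regulatory_genes, 20)
  lfc <- expected_bulk_lfc(cfg)
  # equal proportions, effect in every type: expected bulk lfc is exactly
  # +/- regulatory_lfc for flagged genes, 0 otherwise
  flagged <- seq_len(100) %in% cfg$regulatory_genes
  expect_equal(abs(lfc$expected_lfc[flagged]), rep(2, 20))
  expect_equal(lfc$expected_lfc[!flagged], rep(0, 80))
  sim <- simulate_counts(cfg)
  expect_setequal(unique(sim$truth$regulatory_genes$gene_id),
                  cfg$gene_ids[flagged])
  # regulatory and abundance-driven truth sets are disjoint
  expect_length(intersect(sim$truth$expected_abundance_driven,
                          sim$truth$regulatory_genes$gene_id), 0)
})

test_that("dropout thins counts monotonically", {
  cfg0 <- sim_config(n_genes = 40, n_cell_types = 1, cells_per_sample = 200,
                     n_replicates_per_sex = 1, seed = 8)
  cfg1 <- sim_config(n_genes = 40, n_cell_types = 1, cells_per_sample = 200,
                     n_replicates_per_sex = 1, dropout_rate = 0.5, seed = 8)
  s0 <- simulate_counts(cfg0); s1 <- simulate_counts(cfg1)
  expect_lt(sum(s1$counts), sum(s0$counts))
  expect_gt(mean(as.matrix(s1$counts) == 0), mean(as.matrix(s0$counts) == 0))
})

test_that("simulate_divergence follows its binomial design", {
  cfg <- sim_config(10, 1, omega_by_group = c(zero = 0, one = 1), p_s = 1,
                    seed = 9)
  dv <- simulate_divergence(cfg, 900, 300,
                            groups = rep(c("zero", "one"), 5))
  # omega = 0 -> no nonsynonymous substitutions at all
  expect_true(all(dv$DN[dv$group == "zero"] == 0))
  # p_s = 1, omega = 1 -> saturation: dN = dS = 1 for every gene
  expect_true(all(dv$dN[dv$group == "one"] == 1))
  expect_true(all(dv$dS == 1))
  expect_error(simulate_divergence(
    sim_config(4, 1, omega_by_group = c(g = 3), p_s = 0.5, seed = 1),
    900, 300), "exceeds 1")
  expect_error(simulate_divergence(cfg, 0, 300), "must be > 0")
})

test_that("write_sim round-trips the count matrix", {
  sim <- quick_sim(seed = 10, n_genes = 20, cells = 30)
  dir <- withr::local_tempdir()
  write_sim(sim, dir, sim_config(20, 2, seed = 10))
  m <- read_counts(file.path(dir, "counts"))
  expect_identical(as.matrix(m), as.matrix(sim$counts))
  meta <- read_metadata(file.path(dir, "metadata.tsv"), m)
  expect_identical(meta$cell_id, sim$metadata$cell_id)
  expect_true(file.exists(file.path(dir, "config.txt")))
})
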