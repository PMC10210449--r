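# group-aggregated dN/dS: point estimates, bootstrap, permutation, letters

test_that("validation and the saturation filter", {
  d <- make_div(DN = c(1, 5, 19), DS = c(1, 25, 19), N = 100, S = 10)
  v <- validate_divergence(d)
  expect_equal(v$dS, c(0.1, 2.5, 1.9))
  expect_identical(formals(filter_saturated)$ds_max, 2)
  expect_message(f <- filter_saturated(d), "1 gene")
  expect_identical(f$gene, c("g1", "g3"))
  # boundary: dS exactly 2 is retained (strict inequality removes)
  d2 <- make_div(DN = 0, DS = 20, N = 10, S = 10)
  expect_silent(f2 <- filter_saturated(d2))
  expect_identical(nrow(f2), 1L)
  expect_error(validate_divergence(make_div(1, 1, 0, 10)), "N and S")
  bad <- make_div(2, 1, 100, 50); bad$dN <- 0.5
  expect_error(validate_divergence(bad), "inconsistent")
})

test_that("group_rates matches hand-summed aggregates", {
  # single gene: d_N = 2/100, d_S = 1/50, omega = 1
  g1 <- group_rates(make_div(2, 1, 100, 50))
  expect_equal(g1$d_N, 0.02); expect_equal(g1$d_S, 0.02)
  expect_equal(g1$omega, 1)
  # two genes, hand summation: d_N = 2/200, d_S = 4/100, omega = 0.25
  d <- make_div(DN = c(2, 0), DS = c(1, 3), N = c(100, 100), S = c(50, 50))
  g2 <- group_rates(d)
  expect_equal(g2$d_N, 0.01); expect_equal(g2$d_S, 0.04)
  expect_equal(g2$omega, 0.25)
  # duplication leaves ratios unchanged; scaling every gene leaves them too
  g2k <- group_rates(d[rep(1:2, 5), ])
  expect_equal(g2k$omega, g2$omega)
  dk <- make_div(DN = c(6, 0), DS = c(3, 9), N = 300, S = 150)
  expect_equal(group_rates(dk)$omega, g2$omega)
  expect_equal(group_rates(dk)$d_N, g2$d_N)
  # no synonymous substitutions: omega undefined, flagged
  g0 <- group_rates(make_div(3, 0, 100, 50))
  expect_true(is.na(g0$omega)); expect_false(g0$omega_defined)
})

test_that("bootstrap intervals behave", {
  expect_error(bootstrap_ci(make_div(1, 1, 10, 10), B = 0), "B must be")
  # identical genes: zero-width interval at the point estimate
  d <- make_div(DN = rep(2, 8), DS = rep(1, 8), N = 100, S = 50)
  b <- bootstrap_ci(d, B = 200, seed = 1)
  expect_equal(b$ci_omega, c(1, 1))
  expect_equal(b$ci_dn, c(0.02, 0.02))
  # seed reproducibility
  set.seed(51)
  d2 <- make_div(DN = rpois(50, 5), DS = rpois(50, 8) + 1, N = 300, S = 100)
  b1 <- bootstrap_ci(d2, B = 300, seed = 7)
  b2 <- bootstrap_ci(d2, B = 300, seed = 7)
  expect_identical(b1$ci_omega, b2$ci_omega)
  # point estimate inside the interval, across seeds
  for (s in 1:10) {
    bs <- bootstrap_ci(d2, B = 200, seed = s)
    expect_true(bs$ci_omega[1] <= bs$omega && bs$omega <= bs$ci_omega[2])
    expect_true(bs$ci_dn[1] <= bs$d_N && bs$d_N <= bs$ci_dn[2])
    expect_true(bs$ci_ds[1] <= bs$d_S && bs$d_S <= bs$ci_ds[2])
  }
})

test_that("aggregated omega recovers the generating ratio", {
  cfg <- sim_config(2, 2, omega_by_group = c(g = 0.5), p_s = 0.1, seed = 52)
  dv <- simulate_divergence(cfg, 900, 300, n_genes = 2000)
  om <- group_rates(dv)$omega
  expect_gte(om, 0.45); expect_lte(om, 0.55)
})

test_that("permutation test: degenerate and strong-effect cases", {
  d <- make_div(DN = c(2, 5, 1), DS = c(3, 4, 2), N = 100, S = 50)
  # copies of each other: observed difference 0 -> p = 1
  pt <- permutation_test(d, d, B = 200, seed = 1)
  expect_equal(pt$observed_diff, 0)
  expect_equal(pt$p_value, 1)
  # p bounded below by 1/(B+1)
  cfg <- sim_config(2, 2, omega_by_group = c(a = 0.2, b = 1.0), p_s = 0.1,
                    seed = 53)
  dv <- simulate_divergence(cfg, 900, 300, n_genes = 1000,
                            groups = rep(c("a", "b"), each = 500))
  pt2 <- permutation_test(dv[dv$group == "a", ], dv[dv$group == "b", ],
                          B = 1000, seed = 2)
  expect_gte(pt2$p_value, 1 / 1001)
  expect_lte(pt2$p_value, 0.01)
  # dn and ds statistics run and differ appropriately
  ptn <- permutation_test(dv[dv$group == "a", ], dv[dv$group == "b", ],
                          B = 500, statistic = "dn", seed = 3)
  expect_lte(ptn$p_value, 0.01)
  pts <- permutation_test(dv[dv$group == "a", ], dv[dv$group == "b", ],
                          B = 500, statistic = "ds", seed = 4)
  expect_gte(pts$p_value, 0.05)  # same synonymous law in both groups
  expect_error(permutation_test(d[0, ], d, B = 10), "nonempty")
})

test_that("one-sided alternatives order consistently", {
  set.seed(54)
  a <- make_div(DN = rpois(100, 9), DS = rpois(100, 10) + 1, N = 300, S = 100)
  b <- make_div(DN = rpois(100, 3), DS = rpois(100, 10) + 1, N = 300, S = 100)
  pg <- permutation_test(a, b, B = 500, seed = 5, alternative = "greater")
  pl <- permutation_test(a, b, B = 500, seed = 5, alternative = "less")
  expect_lt(pg$p_value, 0.05)
  expect_gt(pl$p_value, 0.9)
})

test_that("compare_categories reproduces group structure and letters", {
  set.seed(55)
  n <- 400
  cats <- data.frame(
    gene_id = paste0("g", 1:n),
    category = rep(c("unbiased", "bulk_only", "bulk_and_cell", "cell_only"),
                   each = 100),
    direction = c(rep("n/a", 100), rep(c("female", "male"), 150)),
    stringsAsFactors = FALSE)
  # slow genes everywhere except fast bulk_and_cell genes
  omega <- ifelse(cats$category == "bulk_and_cell", 1.0, 0.15)
  DN <- rbinom(n, 900, omega * 0.1); DS <- rbinom(n, 300, 0.1)
  div <- make_div(DN = DN, DS = DS, N = 900, S = 300,
                  gene = cats$gene_id)
  tab <- suppressMessages(
    compare_categories(cats, div, B = 300, seed = 6))
  expect_true(all(c("unbiased", "bulk_and_cell_female", "cell_only_male")
                  %in% tab$group))
  # bulk_level groups are the union of their bulk_only/bulk_and_cell parts
  expect_equal(tab$n_genes[tab$group == "bulk_level_female"],
               tab$n_genes[tab$group == "bulk_only_female"] +
                 tab$n_genes[tab$group == "bulk_and_cell_female"])
  fast <- grepl("bulk_and_cell", tab$group)
  expect_true(all(tab$omega[fast] > 0.7))
  expect_true(all(tab$omega[tab$group == "unbiased"] < 0.3))
  # fast groups share no letter with the unbiased group
  lu <- strsplit(tab$letters[tab$group == "unbiased"], "")[[1]]
  for (g in which(fast)) {
    lg <- strsplit(tab$letters[g], "")[[1]]
    expect_length(intersect(lu, lg), 0)
  }
  # equal-omega groups share a letter (unbiased vs bulk_only, both slow)
  lb <- strsplit(tab$letters[tab$group == "bulk_only_female"], "")[[1]]
  expect_gt(length(intersect(lu, lb)), 0)
})

test_that("compact letters satisfy their defining property", {
  # deterministic p matrix: groups 1-2 equal, 3 different from both
  pm <- matrix(1, 3, 3); pm[1, 3] <- pm[3, 1] <- 0.001
  pm[2, 3] <- pm[3, 2] <- 0.001
  lets <- scSexBias:::.compact_letters(pm, alpha = 0.05)
  l <- strsplit(lets, "")
  expect_gt(length(intersect(l[[1]], l[[2]])), 0)
  expect_length(intersect(l[[1]], l[[3]]), 0)
  expect_length(intersect(l[[2]], l[[3]]), 0)
})
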