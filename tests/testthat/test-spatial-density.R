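test_that("recentering translates coordinates and is an involution", {
  p <- point_pattern(cbind(x_um = c(5, 7), y_um = c(5, -2), z_um = c(0, 3)),
                     group = "B", animal = "b2", section = "s3")
  expect_identical(recenter_pattern(p, c(0, 0, 0))$coords, p$coords)
  one <- point_pattern(cbind(x_um = 5, y_um = 5, z_um = 0))
  expect_equal(unname(recenter_pattern(one, c(5, 5, 0))$coords[1, ]), c(0, 0, 0))
  back <- recenter_pattern(recenter_pattern(p, c(3, -4, 1)), c(-3, 4, -1))
  expect_equal(back$coords, p$coords)
  expect_identical(back$group, "B")
  expect_error(recenter_pattern(p, c(NA, 0)), "finite")
})

test_that("the unit-square worked example gives 1/pi at the center", {
  p <- point_pattern(cbind(x_um = c(0, 1, 0, 1), y_um = c(0, 0, 1, 1)))
  g <- grid_spec(c(0, 1), c(0, 1), spacing = 0.5)
  dm <- knn_density_map(p, g, k = 2)
  ctr <- which(g$nodes[, 1] == 0.5 & g$nodes[, 2] == 0.5)
  expect_equal(dm$values[ctr], 1 / pi)  # d_2 = sqrt(1/2), 2/(4*pi*0.5)
})

test_that("kNN density matches the brute-force distance-sort oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(30:200, 1)
    p <- runif_pattern(n)
    g <- grid_spec(c(-900, 900), c(-900, 900), spacing = 300)
    for (k in c(1, 2, 8)) {
      got <- knn_density_map(p, g, k = k)$values
      want <- oracle_knn_density(p$coords, g$nodes, k, n, g$spacing / 2)
      expect_lt(max(abs(got - want)), 1e-9)
    }
  }
})

test_that("kNN density scales as 1/s^2 under coordinate scaling", {
  set.seed(7)
  p <- runif_pattern(100)
  g <- grid_spec(c(-500, 500), c(-500, 500), spacing = 250)
  s <- 3
  ps <- point_pattern(p$coords * s)
  gs <- grid_spec(c(-500, 500) * s, c(-500, 500) * s, spacing = 250 * s)
  expect_equal(knn_density_map(ps, gs)$values,
               knn_density_map(p, g)$values / s^2)
})

test_that("homogeneous-pattern error follows the estimator's sampling law", {
  # for a homogeneous pattern the node estimate behaves as k/Gamma(k)
  # (inverse-gamma): at k = 8 the median relative error is ~0.238,
  # independent of n -- the irreducible noise of the k = 8 estimator
  set.seed(30)
  p <- point_pattern(cbind(x_um = runif(1000), y_um = runif(1000)))
  g <- grid_spec(c(0.2, 0.8), c(0.2, 0.8), spacing = 0.05)
  f <- knn_density_map(p, g, k = 8)$values
  # normalized density: 1/n per cell over the unit square -> truth = 1
  oracle_median <- median(abs(8 / rgamma(2e5, 8, 1) - 1))
  expect_lt(abs(median(abs(f - 1)) - oracle_median), 0.05)
  expect_lt(abs(mean(f) - 1), 0.1)
})

test_that("undersized patterns and groups are rejected with informative errors", {
  p5 <- runif_pattern(5)
  g <- grid_spec(spacing = 500)
  expect_error(knn_density_map(p5, g, k = 8), "5 cells.*k = 8")
  expect_error(density_pvalue_map(list(p5), list(p5, p5), g, k = 2),
               "at least 2 patterns")
  expect_error(density_pvalue_map(list(p5, p5), list(p5, p5), g, k = 8),
               "smallest pattern")
})

test_that("identical groups give delta 0 and p 1 everywhere", {
  set.seed(2)
  pats <- replicate(3, runif_pattern(60), simplify = FALSE)
  pv <- density_pvalue_map(pats, pats, grid_spec(spacing = 250), k = 8)
  expect_true(all(pv$delta == 0))
  expect_true(all(pv$p == 1))
  expect_identical(sum(pv$mask_B_gt_A), 0L)
})

test_that("animal-level 3 vs 3 permutation enumerates exactly 20 arrangements", {
  coh <- gen_cohort_patterns(cohort_spec(seed = 6))
  gr <- split_cohort(coh)
  pv <- density_pvalue_map(gr$A, gr$B, grid_spec(spacing = 250),
                           unit = "animal")
  expect_true(pv$exhaustive)
  expect_identical(pv$B_perm, 20L)       # C(6,3)
  expect_equal(min(pv$p), 0.1)           # two-sided floor 2/20
  expect_true(all(abs(pv$p * 20 - round(pv$p * 20)) < 1e-9))
})

test_that("swapping the groups negates delta and preserves p", {
  coh <- gen_cohort_patterns(cohort_spec(seed = 17))
  gr <- split_cohort(coh)
  g <- grid_spec(spacing = 200)
  # exhaustive mode: the arrangement set is symmetric, so p is unchanged
  ab <- density_pvalue_map(gr$A, gr$B, g, unit = "animal")
  ba <- density_pvalue_map(gr$B, gr$A, g, unit = "animal")
  expect_true(ab$exhaustive)
  expect_equal(ba$delta, -ab$delta)
  expect_equal(ba$p, ab$p)
  expect_identical(ba$mask_B_gt_A, ab$mask_A_gt_B)
  # sampled mode: same property up to Monte-Carlo resampling error
  abs_ <- density_pvalue_map(gr$A, gr$B, g, B_perm = 1999, seed = 5)
  bas <- density_pvalue_map(gr$B, gr$A, g, B_perm = 1999, seed = 5)
  expect_equal(bas$delta, -abs_$delta)
  expect_lt(max(abs(bas$p - abs_$p)), 0.08)
})

test_that("sampled permutation converges to the exhaustive distribution", {
  coh <- gen_cohort_patterns(cohort_spec(n_sections_per_animal = 1, seed = 9))
  gr <- split_cohort(coh)             # 3 vs 3 sections: 20 arrangements
  g <- grid_spec(spacing = 250)
  ex <- density_pvalue_map(gr$A, gr$B, g)
  expect_true(ex$exhaustive)
  sam <- density_pvalue_map(gr$A, gr$B, g, B_perm = 4000, seed = 1,
                            exhaustive_cap = 1)
  expect_false(sam$exhaustive)
  expect_lt(max(abs(sam$p - ex$p)), 0.06)
})

test_that("permutation p-values are valid under the null", {
  # exchangeable patterns: rejection rate at alpha never exceeds alpha by
  # more than Monte-Carlo error (pooled over nodes and seeds)
  rates <- sapply(1:6, function(s) {
    coh <- gen_cohort_patterns(cohort_spec(excess_ratio = 0, seed = 400 + s))
    gr <- split_cohort(coh)
    pv <- density_pvalue_map(gr$A, gr$B, grid_spec(spacing = 100),
                             B_perm = 199, seed = s)
    c(mean(pv$p <= 0.01), mean(pv$p <= 0.05), mean(pv$p <= 0.1))
  })
  avg <- rowMeans(rates)
  expect_lt(avg[1], 0.01 + 0.015)
  expect_lt(avg[2], 0.05 + 0.025)
  expect_lt(avg[3], 0.10 + 0.035)
})

test_that("significant-region accounting covers the degenerate cases", {
  set.seed(2)
  pats <- replicate(3, runif_pattern(60), simplify = FALSE)
  pv <- density_pvalue_map(pats, pats, grid_spec(spacing = 250), k = 8)
  sr <- significant_region_area(pv, direction = "B>A")
  expect_identical(sr$area_um2, 0)
  expect_true(sr$empty)
  expect_true(all(is.na(sr$centroid)))
  expect_error(significant_region_area(pv, alpha = 1.5), "alpha")
  # alpha near 1: both direction masks together tile (almost) the whole grid
  coh <- gen_cohort_patterns(cohort_spec(excess_ratio = 0, seed = 3))
  gr <- split_cohort(coh)
  pv2 <- density_pvalue_map(gr$A, gr$B, grid_spec(spacing = 250),
                            B_perm = 99, seed = 2)
  hi <- significant_region_area(pv2, alpha = 1 - 1e-12, direction = "B>A")
  lo <- significant_region_area(pv2, alpha = 1 - 1e-12, direction = "A>B")
  # the limit covers every node carrying a direction (delta != 0) whose p is
  # below 1; exact ties in the group means belong to neither mask
  expect_identical(hi$node_count + lo$node_count,
                   sum(pv2$p < 1 & pv2$delta != 0))
  expect_gte(hi$node_count + lo$node_count, 0.95 * nrow(pv2$grid$nodes))
})

test_that("a planted annulus excess is recovered where it was planted", {
  coh <- gen_cohort_patterns(cohort_spec(excess_ratio = 1, seed = 77))
  gr <- split_cohort(coh)
  pv <- density_pvalue_map(gr$A, gr$B, grid_spec(), seed = 77)
  jr <- mask_annulus_jaccard(pv, c(300, 500))
  expect_gte(jr$jaccard, 0.3)
  expect_gte(jr$mean_radius_um, 300)
  expect_lte(jr$mean_radius_um, 500)
  sr <- significant_region_area(pv, direction = "B>A")
  expect_gt(sr$node_count, 0)
})
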