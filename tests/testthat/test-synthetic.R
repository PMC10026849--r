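test_that("cohort generator is deterministic and validates its spec", {
  s <- cohort_spec(seed = 11)
  c1 <- gen_cohort_patterns(s)
  c2 <- gen_cohort_patterns(s)
  expect_identical(c1, c2)
  expect_length(c1$patterns, 2 * 3 * 3)
  expect_error(cohort_spec(cells_per_section_mean = -5), "> 0")
  expect_error(cohort_spec(annulus = c(500, 300)), "r_inner")
  expect_error(cohort_spec(n_animals_per_group = 0), "at least one")
})

test_that("a null cohort draws both groups from one intensity", {
  coh <- gen_cohort_patterns(cohort_spec(excess_ratio = 0, seed = 5))
  expect_identical(coh$ground_truth$expected_annulus_count_A,
                   coh$ground_truth$expected_annulus_count_B)
  gr <- split_cohort(coh)
  nA <- vapply(gr$A, n_cells, integer(1))
  nB <- vapply(gr$B, n_cells, integer(1))
  # both Poisson(200): group means within 3 SE of the common mean
  se <- sqrt(200 / 9)
  expect_lt(abs(mean(nA) - 200), 3 * se)
  expect_lt(abs(mean(nB) - 200), 3 * se)
})

test_that("annulus excess doubles the expected annulus count for group B", {
  # excess_ratio = 1 with ~200 cells/section baseline: annulus mean in B is
  # ~2x that in A; compare both groups to the analytic Poisson expectations
  spec <- cohort_spec(n_animals_per_group = 10, n_sections_per_animal = 3,
                      excess_ratio = 1, seed = 21)
  coh <- gen_cohort_patterns(spec)
  gr <- split_cohort(coh)
  in_ann <- function(p) {
    r <- sqrt(rowSums(p$coords[, 1:2]^2))
    sum(r >= 300 & r <= 500)
  }
  cntA <- vapply(gr$A, in_ann, numeric(1))
  cntB <- vapply(gr$B, in_ann, numeric(1))
  muA <- coh$ground_truth$expected_annulus_count_A
  muB <- coh$ground_truth$expected_annulus_count_B
  expect_equal(muB, 2 * muA)
  expect_lt(abs(mean(cntA) - muA), 3 * sqrt(muA / length(cntA)))
  expect_lt(abs(mean(cntB) - muB), 3 * sqrt(muB / length(cntB)))
})

test_that("per-section counts behave like Poisson counts", {
  spec <- cohort_spec(n_animals_per_group = 30, n_sections_per_animal = 3,
                      excess_ratio = 0, seed = 8)
  n <- vapply(gen_cohort_patterns(spec)$patterns, n_cells, integer(1))
  m <- length(n)
  expect_lt(abs(mean(n) - 200), 3 * sqrt(200 / m))
  # Poisson: variance equals the mean; SE of the sample variance ~ sqrt(2/m)*var
  expect_lt(abs(var(n) - 200), 3 * sqrt(2 / m) * 200 + 3 * sqrt(200 / m))
})

test_that("vessel network generator records its own ground truth", {
  v1 <- gen_vessel_network(n_branches = 1, seed = 4)
  expect_identical(v1$junction_count, 0L)  # a single path has no branch point
  v <- gen_vessel_network(n_branches = 6, seed = 4)
  p1 <- v$nodes[v$segments[, 1], ]
  p2 <- v$nodes[v$segments[, 2], ]
  expect_equal(v$total_length_um, sum(sqrt(rowSums((p2 - p1)^2))))
  expect_identical(v, gen_vessel_network(n_branches = 6, seed = 4))
  expect_error(gen_vessel_network(step = 0), "step")
  expect_error(gen_vessel_network(n_branches = 0), "n_branches")
})

test_that("vessel attraction shapes the nearest-neighbor distances", {
  v <- gen_vessel_network(n_branches = 8, seed = 2)
  # weight 1, vanishing decay: every cell sits on the centerline
  tight <- gen_opc_positions(v, attraction_spec(n_cells = 100,
                                                attraction_weight = 1,
                                                decay_length_um = 1e-9, seed = 3))
  d <- nearest_vessel_distances(tight$pattern, v)
  expect_lt(max(d$distance_um), 1e-6)
  # weight 0.5: the vessel channel is stochastically closer than uniform
  half <- gen_opc_positions(v, attraction_spec(n_cells = 400,
                                               attraction_weight = 0.5,
                                               decay_length_um = 10, seed = 3))
  dh <- nearest_vessel_distances(half$pattern, v)$distance_um
  expect_setequal(unique(half$channel), c("vessel", "uniform"))
  wt <- wilcox.test(dh[half$channel == "vessel"], dh[half$channel == "uniform"],
                    alternative = "less")
  expect_lt(wt$p.value, 1e-6)
  # weight 0 equals a uniform Monte-Carlo baseline drawn the same way
  none <- gen_opc_positions(v, attraction_spec(n_cells = 300,
                                               attraction_weight = 0, seed = 9))
  expect_true(all(none$channel == "uniform"))
  d0 <- nearest_vessel_distances(none$pattern, v)$distance_um
  set.seed(101)
  base <- runif_pattern(300)
  db <- nearest_vessel_distances(base, v)$distance_um
  expect_gt(wilcox.test(d0, db)$p.value, 0.01)
  expect_error(gen_opc_positions(v, attraction_spec(attraction_weight = 1.5)),
               "attraction_weight")
})

test_that("fiber generator hits the target g-ratio and respects geometry", {
  f <- gen_fiber_set(300, mean_g = 0.80, seed = 13)
  expect_true(all(f$fiber_diameter_um >= f$axon_diameter_um))
  expect_lt(abs(gratio_stats(f)$mean_g - 0.80), 0.01)
  f0 <- gen_fiber_set(50, mean_g = 0.77, sd_g = 0, seed = 1)
  expect_equal(f0$axon_diameter_um / f0$fiber_diameter_um, rep(0.77, 50))
  expect_error(gen_fiber_set(10, mean_g = 1.2), "mean_g")
  expect_identical(gen_fiber_set(100, seed = 2), gen_fiber_set(100, seed = 2))
})

test_that("section-area generator matches the ellipsoid closed forms", {
  # noise-free odd sampling has a plane through the center: area = pi*a*b
  s <- gen_section_areas(c(500, 350, 500), 40, 5, noise_cv = 0, seed = 1)
  expect_equal(max(s$areas_um2), pi * 500 * 350)
  # full coverage: the Riemann sum of area*spacing approximates 4/3 pi a b c
  full <- gen_section_areas(c(500, 350, 500), 40, 25, noise_cv = 0, seed = 1)
  truth <- attr(full, "ground_truth")
  expect_equal(truth$true_volume_um3, 4 / 3 * pi * 500 * 350 * 500)
  riemann <- sum(full$areas_um2) * 40
  expect_lt(abs(riemann / truth$true_volume_um3 - 1), 0.01)
  expect_identical(gen_section_areas(seed = 3), gen_section_areas(seed = 3))
  # planes beyond the ellipsoid give area 0, retained
  out <- gen_section_areas(c(500, 350, 100), 80, 9, noise_cv = 0)
  expect_true(any(out$areas_um2 == 0))
})

test_that("voxel-mask pairs achieve the requested overlap fraction", {
  sub <- gen_voxel_masks(overlap_fraction = 1, seed = 5)
  expect_true(all(sub$vessel$mask[sub$marker$mask]))   # B inside A
  dis <- gen_voxel_masks(overlap_fraction = 0, seed = 5)
  expect_false(any(dis$vessel$mask & dis$marker$mask))
  half <- gen_voxel_masks(overlap_fraction = 0.5, seed = 5)
  got <- colocalization_percent(half$marker, half$vessel)$percent
  expect_lt(abs(got - 50), 100 / half$ground_truth$n_marker)  # one-voxel rounding
  expect_error(gen_voxel_masks(overlap_fraction = 1, n_marker = 10^6),
               "unattainable")
})

test_that("seed substreams are stable and distinct", {
  expect_identical(substream_seed(7, "cohort"), substream_seed(7, "cohort"))
  expect_false(substream_seed(7, "cohort") == substream_seed(7, "fibers"))
  expect_error(substream_seed(7, "nope"), "substream")
})
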