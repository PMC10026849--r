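test_that("g-ratio statistics follow their closed forms", {
  f <- fiber_set(axon_diameter_um = c(0.8, 1.0), fiber_diameter_um = c(1.0, 1.0))
  gs <- gratio_stats(f)
  expect_equal(gs$table$g, c(0.8, 1.0))
  expect_equal(gs$table$myelin_thickness_um, c(0.1, 0))
  expect_identical(gs$n_rejected, 0L)
  # axon > fiber records are rejected with a report, not silently kept
  bad <- fiber_set(axon_diameter_um = c(0.8, 1.2), fiber_diameter_um = c(1.0, 1.0))
  expect_identical(nrow(bad), 1L)
  expect_identical(gratio_stats(bad)$n_rejected, 1L)
  expect_error(gratio_stats(fiber_set(numeric(0), numeric(0))), "empty")
  expect_equal(equivalent_diameter(pi), 2)
})

test_that("generator calibration is recovered by gratio_stats", {
  gA <- gratio_stats(gen_fiber_set(300, mean_g = 0.80, seed = 51))
  gB <- gratio_stats(gen_fiber_set(300, mean_g = 0.88, seed = 52))
  expect_lt(abs(gA$mean_g - 0.80), 0.01)
  expect_lt(abs(gB$mean_g - 0.88), 0.01)
})

test_that("skeleton metrics recover rendered ground truth", {
  vg <- vessel_graph(cbind(x_um = c(-100, 100), y_um = c(0, 0)), rbind(c(1, 2)))
  img <- render_vessel_raster(vg, extent = c(-120, 120, -30, 30), diameter_um = 8)
  m <- vessel_raster_metrics(img, c(40, 255), min_component = 20)
  expect_lt(abs(m$total_length_um - 200) / 200, 0.05)
  expect_identical(m$junction_count, 0L)
  nodesY <- cbind(x_um = c(0, 0, -60, 60), y_um = c(-80, 0, 70, 70))
  vgY <- vessel_graph(nodesY, rbind(c(1, 2), c(2, 3), c(2, 4)))
  imgY <- render_vessel_raster(vgY, extent = c(-90, 90, -110, 100), diameter_um = 8)
  mY <- vessel_raster_metrics(imgY, c(40, 255), min_component = 20)
  expect_identical(mY$junction_count, 1L)
  expect_lt(abs(mY$total_length_um - vgY$total_length_um) /
              vgY$total_length_um, 0.08)
  expect_warning(blank <- vessel_raster_metrics(matrix(0, 40, 40), c(40, 255),
                                                min_component = 20),
                 "foreground")
  expect_equal(blank$total_length_um, 0)
  expect_identical(blank$junction_count, 0L)
})

test_that("skeleton length is stable across tube diameters in the band", {
  # end erosion during thinning is O(tube radius), so the invariance holds
  # for tubes much longer than their diameter
  vg <- vessel_graph(cbind(x_um = c(-400, 400), y_um = c(60, -60)), rbind(c(1, 2)))
  true_len <- vg$total_length_um
  lens <- sapply(c(6, 12, 20, 32), function(d) {
    img <- render_vessel_raster(vg, extent = c(-430, 430, -110, 110), diameter_um = d)
    vessel_raster_metrics(img, c(40, 255), min_component = 20)$total_length_um
  })
  expect_true(all(abs(lens - true_len) / true_len <= 0.05))
})

test_that("the width band-pass suppresses out-of-band structures", {
  img <- matrix(0, 60, 120)
  img[29:32, 10:110] <- 255          # 4 px wide tube: below the 5-40 band
  m <- suppressWarnings(vessel_raster_metrics(img, c(40, 255), min_component = 10))
  expect_equal(m$total_length_um, 0)
  img2 <- matrix(0, 60, 120)
  img2[27:34, 10:110] <- 255         # 8 px wide: inside the band
  m2 <- vessel_raster_metrics(img2, c(40, 255), min_component = 10)
  expect_gt(m2$total_length_um, 80)
})

test_that("connected-component labeling matches the flood-fill oracle", {
  set.seed(23)
  for (rep in 1:4) {
    m3 <- array(runif(16^3) < 0.22, dim = c(16, 16, 16))
    got <- label_components(m3)
    want <- oracle_flood_fill(m3)
    # same partition: component ids may differ, memberships may not
    expect_identical(got > 0, want > 0)
    expect_identical(max(got), max(want))
    key <- paste(got[m3], want[m3])
    expect_identical(length(unique(key)), max(got))
  }
})

test_that("vessel volume applies the 30 um^3 particle filter", {
  m <- array(FALSE, c(20, 20, 20))
  m[1:10, 1, 1] <- TRUE                       # 10 voxels < 30 um^3: dropped
  expect_equal(vessel_volume_from_mask(voxel_mask(m, 1)), 0)
  m2 <- array(FALSE, c(20, 20, 20))
  m2[1:4, 1:4, 1:4] <- TRUE                   # 64-voxel cube survives
  expect_equal(vessel_volume_from_mask(voxel_mask(m2, 1)), 64)
  m3 <- array(FALSE, c(30, 30, 4))
  m3[1:10, 1:4, 1] <- TRUE                    # 40 voxels, kept
  m3[20:29, 25:26, 1] <- TRUE                 # 20 voxels, dropped
  expect_equal(vessel_volume_from_mask(voxel_mask(m3, 1)), 40)
  # voxel size scales physical volume: 8 um^3/voxel makes 10 voxels pass
  expect_equal(vessel_volume_from_mask(voxel_mask(m, 2)), 80)
})

test_that("colocalization percentages follow their definition", {
  A <- array(FALSE, c(10, 10, 4)); A[2:6, 2:6, 1:2] <- TRUE
  B <- array(FALSE, c(10, 10, 4)); B[3:4, 3:4, 1] <- TRUE
  expect_equal(colocalization_percent(voxel_mask(B), voxel_mask(A))$percent, 100)
  D <- array(FALSE, c(10, 10, 4)); D[8:9, 8:9, 4] <- TRUE
  expect_equal(colocalization_percent(voxel_mask(D), voxel_mask(A))$percent, 0)
  self <- colocalization_percent(voxel_mask(A), voxel_mask(A))
  expect_equal(self$percent, 100)
  empty <- colocalization_percent(voxel_mask(array(FALSE, c(10, 10, 4))),
                                  voxel_mask(A))
  expect_true(is.na(empty$percent))
  expect_false(empty$defined)
  expect_error(colocalization_percent(voxel_mask(array(FALSE, c(5, 5, 2))),
                                      voxel_mask(A)), "shape")
})

test_that("object areas drop sub-threshold particles", {
  m <- array(FALSE, c(20, 20, 5))
  m[1:10, 1:10, 1:5] <- TRUE                   # 500 voxels
  expect_identical(nrow(object_areas(voxel_mask(m), min_voxels = 800)), 0L)
  m2 <- array(FALSE, c(20, 20, 5))
  m2[1:10, 1:20, 1:5] <- TRUE                  # 1000 voxels
  tab <- object_areas(voxel_mask(m2), min_voxels = 800)
  expect_identical(tab$n_voxels, 1000L)
  expect_equal(tab$size_um, 1000)
  # mixed sizes agree with the flood-fill oracle partition
  set.seed(9)
  mm <- array(runif(14^3) < 0.3, dim = c(14, 14, 14))
  tab2 <- object_areas(voxel_mask(mm), min_voxels = 5)
  want <- oracle_flood_fill(mm)
  sz <- sort(as.integer(table(want[want > 0])))
  expect_identical(sort(tab2$n_voxels), sz[sz >= 5])
})

test_that("radial profiles recover constant and ramp images", {
  flat <- matrix(7, 50, 50)
  pr <- radial_intensity_profile(flat, c(25, 25), bin_width_um = 5,
                                 max_radius_um = 20)
  expect_true(all(pr$mean_intensity == 7))
  # intensity = radius: annulus means sit at (approximately) bin midpoints
  xs <- (1:80 - 0.5); r <- sqrt(outer((xs - 40)^2, (xs - 40)^2, "+"))
  pr2 <- radial_intensity_profile(r, c(40, 40), bin_width_um = 5,
                                  max_radius_um = 30)
  mids <- (pr2$r_lo_um + pr2$r_hi_um) / 2
  expect_lt(max(abs(pr2$mean_intensity - mids)), 1)
  # truncation and empty annuli are flagged, not silently dropped
  pr3 <- radial_intensity_profile(flat, c(2, 2), bin_width_um = 20,
                                  max_radius_um = 200)
  expect_true(any(pr3$truncated))
  expect_true(any(is.na(pr3$mean_intensity) & pr3$n_pixels == 0))
  expect_error(radial_intensity_profile(flat, c(-5, 0), 5, 10), "inside")
})
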