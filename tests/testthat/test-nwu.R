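atlas8 <- function() default_atlas(grid_shape = c(8, 8, 8),
                                   voxel_spacing = c(2, 2, 2),
                                   brain_radii = c(7, 7, 7))

mask_on <- function(template, idx) {
  m <- template
  m$data <- array(0, dim(template$data))
  m$data[idx] <- 1
  m
}

test_that("mirroring reflects world x and is an exact involution", {
  atlas <- small_atlas()
  tmpl <- atlas$template
  # single voxel at a known positive-x world position
  pts <- nwuct:::grid_world_coords(tmpl)
  i <- which(pts[, 1] > 8 & pts[, 1] < 13 & abs(pts[, 2]) < 2 & abs(pts[, 3]) < 2)[1]
  m <- mask_on(tmpl, i)
  mm <- mirror_mask(m, atlas)
  j <- which(mm$data == 1)
  expect_length(j, 1)
  expect_equal(pts[j, ], pts[i, ] * c(-1, 1, 1), ignore_attr = TRUE)
  # involution
  expect_identical(mirror_mask(mm, atlas)$data, m$data)
  # conservation of voxel count on a real lesion mask
  ph <- generate_phantom(small_phantom_config(seed = 9))
  les <- ph$seg_followup$lesion_mask
  expect_lt(abs(sum(mirror_mask(les, atlas)$data) - sum(les$data)) /
              sum(les$data), 0.01)
  # a midplane-symmetric mask maps to itself
  sym <- tmpl
  sym$data <- (abs(pts[, 2]) < 20 & abs(pts[, 3]) < 20 & abs(pts[, 1]) < 20) * 1
  dim(sym$data) <- dim(tmpl$data)
  expect_identical(mirror_mask(sym, atlas)$data, sym$data)
  # geometry mismatch is an error
  expect_error(mirror_mask(mask_on(atlas8()$template, 3), atlas), "atlas grid")
})

test_that("hemorrhage subtraction is lesion AND NOT hemorrhage", {
  tmpl <- atlas8()$template
  les <- mask_on(tmpl, 1:100)
  hem_empty <- mask_on(tmpl, integer(0))
  expect_identical(make_nonhemorrhagic(lesion_seg(les, hem_empty))$data,
                   les$data)
  hem_all <- les
  expect_true(all(make_nonhemorrhagic(lesion_seg(les, hem_all))$data == 0))
  hem20 <- mask_on(tmpl, 41:60)
  expect_equal(sum(make_nonhemorrhagic(lesion_seg(les, hem20))$data), 80)
})

test_that("the HU band keeps 20 and 80 inclusive and rejects bad bounds", {
  tmpl <- atlas8()$template
  vol <- tmpl
  vol$data[] <- 35
  vol$data[1:10] <- c(15, 19.99, 20, 25, 50, 79, 80, 80.01, 85, 100)
  roi <- mask_on(tmpl, 1:10)
  banded <- apply_hu_band(vol, roi)
  expect_equal(sum(banded$data), 5)  # 20, 25, 50, 79, 80 survive
  expect_equal(which(banded$data == 1), 3:7)
  expect_error(apply_hu_band(vol, roi, lo = 50, hi = 50), "lo must be")
  # an ROI of ordinary parenchyma is untouched
  roi2 <- mask_on(tmpl, 200:300)
  expect_identical(apply_hu_band(vol, roi2)$data, roi2$data)
})

test_that("the NWU formula and its error cases are exact", {
  tmpl <- atlas8()$template
  vol <- tmpl
  vol$data[] <- 30
  vol$data[1:8] <- 27
  les <- mask_on(tmpl, 1:8)
  ref <- mask_on(tmpl, 101:108)
  m <- compute_nwu(vol, les, ref)
  expect_equal(m$nwu_percent, 10)
  expect_equal(m$d_ischemic, 27)
  expect_equal(m$d_preischemic, 30)
  expect_equal(m$n_lesion_voxels, 8)
  # identical densities give exactly zero
  expect_equal(compute_nwu(vol, ref, ref)$nwu_percent, 0)
  # formula identity holds on stored fields
  expect_equal(m$nwu_percent, (1 - m$d_ischemic / m$d_preischemic) * 100)
  expect_error(compute_nwu(vol, mask_on(tmpl, integer(0)), ref), "empty lesion")
  expect_error(compute_nwu(vol, les, mask_on(tmpl, integer(0))), "empty reference")
})

test_that("compute_nwu matches a brute-force voxel loop", {
  set.seed(14)
  tmpl <- atlas8()$template
  vol <- tmpl
  vol$data[] <- rnorm(length(vol$data), 35, 4)
  les <- mask_on(tmpl, sample(length(vol$data), 40))
  ref <- mask_on(tmpl, sample(length(vol$data), 40))
  expect_equal(compute_nwu(vol, les, ref)$nwu_percent,
               nwu_bruteforce(vol, les, ref), tolerance = 1e-13)
})

test_that("noise-free phantoms with perfect masks return injected NWU exactly", {
  cfg <- small_phantom_config(brain_hu_sd = 0, true_uptake = 0.15)
  ph <- generate_phantom(cfg)
  atlas <- small_atlas()
  res <- run_nwu_pipeline(ph$baseline, list(`24h` = ph$followup),
                          list(baseline = ph$seg_baseline,
                               `24h` = ph$seg_followup), atlas, align = FALSE)
  expect_equal(res$measurements[["24h"]]$nwu_percent, 15, tolerance = 1e-6)
})

test_that("measured NWU increases strictly with injected uptake", {
  atlas <- small_atlas()
  vals <- sapply(c(0.05, 0.1, 0.2, 0.3), function(u) {
    ph <- generate_phantom(small_phantom_config(true_uptake = u, seed = 31))
    nwuct:::measure_timepoint(ph$followup, ph$seg_followup, atlas)$nwu_percent
  })
  expect_true(all(diff(vals) > 0))
})

test_that("hemorrhage exclusion removes the hyperdense bias", {
  cfg <- small_phantom_config(true_uptake = 0.15, seed = 18,
                              hemorrhage_spec = list(center = c(27, 6, 3),
                                                     radii = c(6, 6, 6)))
  ph <- generate_phantom(cfg)
  atlas <- small_atlas()
  with_excl <- nwuct:::measure_timepoint(ph$followup, ph$seg_followup, atlas,
                                         exclude_hemorrhage = TRUE)
  without <- nwuct:::measure_timepoint(ph$followup, ph$seg_followup, atlas,
                                       exclude_hemorrhage = FALSE)
  expect_gt(with_excl$nwu_percent, without$nwu_percent)
  expect_lt(abs(with_excl$nwu_percent - 15), 1)
})

test_that("a three-timepoint subject yields the injected NWU progression", {
  ser <- phantom_series(small_phantom_config(brain_hu_sd = 0),
                        uptakes = c(0.05, 0.10, 0.15))
  res <- run_nwu_pipeline(ser$baseline, ser$followups, ser$segs, small_atlas(),
                          align = FALSE)
  expect_equal(res$delta$value, c(5, 10), tolerance = 1e-6)
  expect_equal(res$nwu_table$nwu_percent, c(5, 10, 15), tolerance = 1e-6)
})

test_that("midline-crossing lesions flag the reduced reference and still measure", {
  cfg <- small_phantom_config(lesion_center = c(8, 6, 3),
                              lesion_radii = c(16, 14, 12),
                              allow_midline_crossing = TRUE, brain_hu_sd = 0,
                              true_uptake = 0.2)
  ph <- generate_phantom(cfg)
  m <- nwuct:::measure_timepoint(ph$followup, ph$seg_followup, small_atlas())
  expect_true("midline_overlap" %in% m$qc_flags)
  expect_true(is.finite(m$nwu_percent))
  expect_gt(m$nwu_percent, 0)
})
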