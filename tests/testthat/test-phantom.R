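test_that("zero uptake gives equal lesion and contralateral densities", {
  ph <- generate_phantom(small_phantom_config(true_uptake = 0, brain_hu_sd = 0))
  les <- ph$followup$data[ph$seg_followup$lesion_mask$data == 1]
  atlas <- small_atlas()
  mir <- mirror_mask(ph$seg_followup$lesion_mask, atlas)
  contra <- ph$followup$data[mir$data == 1]
  expect_equal(mean(les), mean(contra))
  expect_equal(ph$truth$nwu_percent, 0)
})

test_that("the density drop is exactly (1 - uptake) of contralateral tissue", {
  ph <- generate_phantom(small_phantom_config(true_uptake = 0.10,
                                              brain_hu_mean = 30,
                                              brain_hu_sd = 0))
  les <- ph$followup$data[ph$seg_followup$lesion_mask$data == 1]
  expect_equal(unique(les), 27)
  atlas <- small_atlas()
  mir <- mirror_mask(ph$seg_followup$lesion_mask, atlas)
  expect_equal(unique(ph$followup$data[mir$data == 1]), 30)
})

test_that("default noise keeps brain voxels inside the 20-80 HU band", {
  ph <- generate_phantom(small_phantom_config(seed = 21))
  for (vol in list(ph$baseline, ph$followup)) {
    brain <- vol$data > -1000
    expect_true(all(vol$data[brain] >= 20 & vol$data[brain] <= 80))
  }
})

test_that("generation is seed-deterministic, bit for bit", {
  a <- generate_phantom(small_phantom_config(seed = 5))
  b <- generate_phantom(small_phantom_config(seed = 5))
  expect_identical(a$followup$data, b$followup$data)
  expect_identical(a$seg_followup$lesion_mask$data, b$seg_followup$lesion_mask$data)
  d <- generate_phantom(small_phantom_config(seed = 6))
  expect_false(identical(a$followup$data, d$followup$data))
})

test_that("invalid geometry is rejected and odd hemorrhages are flagged", {
  expect_error(small_phantom_config(lesion_center = c(200, 0, 0)),
               "outside the image grid")
  expect_error(small_phantom_config(true_uptake = 0.7), "true_uptake")
  expect_error(small_phantom_config(lesion_center = c(5, 6, 3)), "midline")
  cfg <- small_phantom_config(hemorrhage_spec = list(center = c(27, 30, 3),
                                                     radii = c(5, 5, 5)))
  expect_warning(ph <- generate_phantom(cfg), "beyond the lesion")
  expect_true(ph$truth$hemorrhage_outside_lesion)
})

test_that("misalignment moves the follow-up anatomy by the stated transform", {
  mis <- affine3d(translation = c(7, 0, 0))
  cfg <- small_phantom_config(brain_hu_sd = 0, misalignment = mis)
  ph <- generate_phantom(cfg)
  # follow-up anatomy appears shifted by -7 mm in x relative to baseline:
  # centre of mass of the lesion mask moves accordingly
  com <- function(mask) {
    pts <- nwuct:::grid_world_coords(mask)
    colSums(pts * as.vector(mask$data)) / sum(mask$data)
  }
  shift <- com(ph$seg_followup$lesion_mask) - com(ph$seg_baseline$lesion_mask)
  expect_equal(shift[1], -7, tolerance = 0.8)  # half-voxel discretization
  expect_equal(shift[2], 0, tolerance = 0.8)
})

test_that("the atlas template is left-right symmetric about x = 0", {
  atlas <- small_atlas()
  flipped <- resample_volume(atlas$template, mirror_affine_x(),
                             atlas$template, "nearest")
  expect_identical(flipped$data, atlas$template$data)
})
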