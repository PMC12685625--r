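rigid <- reg_settings(metric = "nmi", dof = "rigid")

test_that("registering a volume to itself returns the identity", {
  ph <- generate_phantom(small_phantom_config(seed = 2))
  tf <- register_affine(ph$baseline, ph$baseline, rigid)
  expect_true(max(abs(tf$translation)) < 0.1)
  expect_true(max(abs(tf$matrix - diag(3))) < 0.1 * pi / 180 + 1e-3)
})

test_that("a known translation is recovered within half a millimetre", {
  mis <- affine3d(translation = c(5, -3, 2))
  ph <- generate_phantom(small_phantom_config(brain_hu_sd = 2, seed = 3,
                                              misalignment = mis))
  tf <- register_affine(ph$followup, ph$baseline, rigid)
  expect_true(all(abs(tf$translation - c(5, -3, 2)) < 0.5))
})

test_that("forward and backward registrations compose to the identity", {
  mis <- params_to_affine(translation = c(4, -2, 1),
                          angles = c(0.02, -0.01, 0.03))
  ph <- generate_phantom(small_phantom_config(brain_hu_sd = 2, seed = 4,
                                              misalignment = mis))
  t_ab <- register_affine(ph$followup, ph$baseline, rigid)
  t_ba <- register_affine(ph$baseline, ph$followup, rigid)
  round_trip <- compose_affine(t_ab, t_ba)
  expect_true(max(abs(round_trip$translation)) < 1.0)
  expect_true(max(abs(round_trip$matrix - diag(3))) < 0.02)
})

test_that("resampling honours its contracts", {
  ph <- generate_phantom(small_phantom_config(seed = 5))
  # identity onto the same grid: input returned unchanged
  out <- resample_volume(ph$baseline, identity_affine(), ph$baseline)
  expect_identical(out$data, ph$baseline$data)
  # masks stay binary through an arbitrary transform
  tr <- params_to_affine(c(3, 1, -2), c(0.05, 0.02, -0.04))
  m <- resample_volume(ph$seg_followup$lesion_mask, tr, ph$baseline,
                       "nearest", is_mask = TRUE)
  expect_true(all(m$data %in% c(0, 1)))
  # linear interpolation of a mask is refused
  expect_error(resample_volume(ph$seg_followup$lesion_mask, tr, ph$baseline,
                               "linear", is_mask = TRUE), "nearest")
  # mask volume preserved within 5% under a small rotation
  rot <- params_to_affine(angles = c(0, 0, 4 * pi / 180))
  mr <- resample_volume(ph$seg_followup$lesion_mask, rot, ph$baseline,
                        "nearest", is_mask = TRUE)
  v0 <- sum(ph$seg_followup$lesion_mask$data)
  expect_lt(abs(sum(mr$data) - v0) / v0, 0.05)
})

test_that("resampling through the identity is idempotent", {
  ph <- generate_phantom(small_phantom_config(seed = 6))
  once <- resample_volume(ph$baseline, identity_affine(), ph$baseline)
  twice <- resample_volume(once, identity_affine(), ph$baseline)
  expect_identical(twice$data, once$data)
})

test_that("patient alignment restores a misaligned follow-up", {
  # standard-resolution grid: at 3.5 mm voxels the nearest-neighbour mask
  # discretization alone caps Dice near 0.88 even for a perfect transform
  mis <- nwuct:::subject_misalignment(5, 3, seed = 77)
  cfg <- phantom_config(brain_hu_sd = 2, misalignment = mis, seed = 7)
  ph <- generate_phantom(cfg)
  atlas <- default_atlas()
  aligned <- align_patient(ph$baseline, list(`24h` = ph$followup),
                           list(baseline = ph$seg_baseline,
                                `24h` = ph$seg_followup), atlas, rigid)
  expect_named(aligned$volumes, c("baseline", "24h"))
  expect_true(same_grid(aligned$volumes[["24h"]], atlas$template))

  # lesion-mask Dice against the ground-truth atlas-space mask
  truth_mask <- ph$seg_baseline$lesion_mask
  got <- aligned$segs[["24h"]]$lesion_mask
  dice <- 2 * sum(truth_mask$data * got$data) /
    (sum(truth_mask$data) + sum(got$data))
  expect_gt(dice, 0.9)

  # alignment shrinks the within-brain HU discrepancy
  brain <- ph$baseline$data > -1000
  before <- mean(abs(ph$followup$data[brain] - ph$baseline$data[brain]))
  after <- mean(abs(aligned$volumes[["24h"]]$data[brain] -
                      ph$baseline$data[brain]))
  expect_lt(after, before)
})

test_that("inputs already in atlas space pass through within tolerance", {
  ph <- generate_phantom(small_phantom_config(seed = 8))
  atlas <- small_atlas()
  aligned <- align_patient(ph$baseline, list(`24h` = ph$followup),
                           list(baseline = ph$seg_baseline,
                                `24h` = ph$seg_followup), atlas, rigid)
  brain <- ph$baseline$data > -1000
  expect_lt(mean(abs(aligned$volumes$baseline$data[brain] -
                       ph$baseline$data[brain])), 1.5)
})
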