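#' Configuration for a synthetic head-CT phantom
#'
#' The phantom is a single axially aligned brain ellipsoid centred on the
#' world origin, so the midsagittal plane lies exactly at x = 0 and every
#' voxel has a homologous contralateral partner. The ischemic lesion is an
#' ellipsoid whose follow-up density is reduced by the factor
#' `1 - true_uptake` relative to homologous contralateral tissue: the injected
#' ground-truth net water uptake is `100 * true_uptake` percent. An optional
#' hyperdense hemorrhage blob and an optional rigid/affine misalignment of
#' the follow-up acquisition complete the model. Outside the brain the volume
#' is air (-1000 HU).
#'
#' @param grid_shape voxels per axis.
#' @param voxel_spacing mm per axis.
#' @param brain_hu_mean mean parenchymal density, HU.
#' @param brain_hu_sd additive Gaussian acquisition noise, HU. The default
#'   keeps brain voxels inside the 20-80 HU band with probability > 0.999
#'   (35 +/- 2 HU: band edges are > 7 SD away).
#' @param brain_radii semi-axes of the brain ellipsoid, mm.
#' @param lesion_center,lesion_radii lesion ellipsoid, world mm.
#' @param true_uptake fractional density drop in [0, 0.5]; ground-truth
#'   NWU is `100 * true_uptake` %.
#' @param baseline_uptake fractional drop already present at baseline
#'   (default 0: no visible early hypodensity).
#' @param hemorrhage_spec optional `list(center=, radii=, hu=)` hyperdense
#'   blob (default HU 70 when only center/radii given).
#' @param misalignment optional [affine3d()] mapping follow-up world
#'   coordinates into baseline world coordinates; when set, the follow-up is
#'   acquired on a grid misaligned by its inverse, and registration must
#'   recover it.
#' @param allow_midline_crossing permit a lesion that crosses x = 0 (used to
#'   exercise the bilateral-lesion reference cleanup); otherwise the lesion
#'   must sit strictly within one hemisphere and inside the brain.
#' @param seed integer RNG seed; generation is fully seed-deterministic.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(50, 60, 44),
                           voxel_spacing = c(3, 3, 3),
                           brain_hu_mean = 35, brain_hu_sd = 2,
                           brain_radii = c(62, 78, 52),
                           lesion_center = c(32, 8, 4),
                           lesion_radii = c(20, 17, 15),
                           true_uptake = 0.15, baseline_uptake = 0,
                           hemorrhage_spec = NULL, misalignment = NULL,
                           allow_midline_crossing = FALSE, seed = 1L) {
  stopifnot(length(grid_shape) == 3L, length(voxel_spacing) == 3L,
            all(grid_shape >= 8), all(voxel_spacing > 0))
  if (true_uptake < 0 || true_uptake > 0.5)
    stop("phantom_config: true_uptake must lie in [0, 0.5]")
  if (baseline_uptake < 0 || baseline_uptake > 0.5)
    stop("phantom_config: baseline_uptake must lie in [0, 0.5]")
  if (!is.null(hemorrhage_spec)) {
    stopifnot(is.list(hemorrhage_spec), !is.null(hemorrhage_spec$center),
              !is.null(hemorrhage_spec$radii))
    if (is.null(hemorrhage_spec$hu)) hemorrhage_spec$hu <- 70
  }
  if (!is.null(misalignment)) stopifnot(inherits(misalignment, "affine3d"))
  cfg <- list(grid_shape = as.integer(grid_shape), voxel_spacing = voxel_spacing,
              brain_hu_mean = brain_hu_mean, brain_hu_sd = brain_hu_sd,
              brain_radii = brain_radii, lesion_center = lesion_center,
              lesion_radii = lesion_radii, true_uptake = true_uptake,
              baseline_uptake = baseline_uptake, hemorrhage_spec = hemorrhage_spec,
              misalignment = misalignment,
              allow_midline_crossing = allow_midline_crossing,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_geometry(cfg)
  cfg
}

# Ellipsoid membership for world points (N x 3).
in_ellipsoid <- function(points, center, radii) {
  rowSums(sweep(sweep(points, 2, center), 2, radii, "/")^2) <= 1
}

validate_phantom_geometry <- function(cfg) {
  extent <- (cfg$grid_shape - 1) * cfg$voxel_spacing / 2
  if (any(abs(cfg$lesion_center) + cfg$lesion_radii > extent))
    stop("phantom_config: lesion extends outside the image grid")
  # lesion fully inside the brain ellipsoid: sufficient check on the scaled
  # bounding sphere of the lesion
  corners <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  pts <- sweep(sweep(corners, 2, cfg$lesion_radii, "*"), 2, cfg$lesion_center, "+")
  if (!all(in_ellipsoid(pts, c(0, 0, 0), cfg$brain_radii)))
    warning("phantom_config: lesion bounding box reaches outside the brain ellipsoid")
  if (!cfg$allow_midline_crossing &&
      abs(cfg$lesion_center[1]) < cfg$lesion_radii[1])
    stop("phantom_config: lesion crosses the midline; set allow_midline_crossing")
  invisible(cfg)
}

# Noise-free tissue mean at anatomy-space world points.
phantom_mean_hu <- function(cfg, points, uptake) {
  hu <- rep(-1000, nrow(points))
  brain <- in_ellipsoid(points, c(0, 0, 0), cfg$brain_radii)
  hu[brain] <- cfg$brain_hu_mean
  les <- brain & in_ellipsoid(points, cfg$lesion_center, cfg$lesion_radii)
  hu[les] <- cfg$brain_hu_mean * (1 - uptake)
  if (!is.null(cfg$hemorrhage_spec)) {
    h <- cfg$hemorrhage_spec
    hem <- brain & in_ellipsoid(points, h$center, h$radii)
    hu[hem] <- h$hu
  }
  hu
}

#' Generate a baseline/follow-up phantom pair with known water uptake
#'
#' The baseline scan carries `baseline_uptake` (default none); the follow-up
#' carries `true_uptake`. When `misalignment` is set the follow-up is rendered
#' on a grid whose anatomy is displaced by the inverse transform, i.e. the
#' stored transform maps follow-up world points back onto baseline anatomy,
#' which is exactly what [register_affine()] must recover. Acquisition noise
#' is drawn i.i.d. per scan after the geometric transform, as for a real
#' repeated acquisition.
#'
#' @param config A [phantom_config()].
#' @return A list with `baseline` and `followup` (`ct_volume`), `seg_baseline`
#'   and `seg_followup` ([lesion_seg()] in each scan's native space), and
#'   `truth` (injected NWU %, per-region mean densities, hemorrhage flag).
#' @examples
#' ph <- generate_phantom(phantom_config(true_uptake = 0.1, brain_hu_sd = 0))
#' ph$truth$nwu_percent  # 10
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  blank <- ct_volume(array(0, config$grid_shape), config$voxel_spacing)
  pts <- grid_world_coords(blank)

  render <- function(uptake, transform, timepoint, with_noise = TRUE) {
    p <- if (is.null(transform)) pts else apply_affine(transform, pts)
    mu <- phantom_mean_hu(config, p, uptake)
    brain <- mu > -1000
    if (with_noise && config$brain_hu_sd > 0)
      mu[brain] <- mu[brain] + stats::rnorm(sum(brain), 0, config$brain_hu_sd)
    vol <- ct_volume(array(mu, config$grid_shape), config$voxel_spacing,
                     blank$affine, subject_id = "phantom", timepoint = timepoint)
    les <- in_ellipsoid(p, config$lesion_center, config$lesion_radii) &
           in_ellipsoid(p, c(0, 0, 0), config$brain_radii)
    hem <- rep(FALSE, nrow(p))
    if (!is.null(config$hemorrhage_spec))
      hem <- in_ellipsoid(p, config$hemorrhage_spec$center,
                          config$hemorrhage_spec$radii) &
             in_ellipsoid(p, c(0, 0, 0), config$brain_radii)
    mk <- function(m) ct_volume(array(m * 1, config$grid_shape),
                                config$voxel_spacing, blank$affine,
                                "phantom", timepoint)
    list(vol = vol, seg = lesion_seg(mk(les), mk(hem)))
  }

  base <- render(config$baseline_uptake, NULL, "baseline")
  # misalignment maps follow-up world -> baseline world, so the follow-up
  # voxel at world w shows the baseline anatomy at misalignment(w)
  fu <- render(config$true_uptake, config$misalignment, "24h")

  hem_flag <- FALSE
  if (!is.null(config$hemorrhage_spec)) {
    h <- config$hemorrhage_spec
    box_lo <- config$lesion_center - config$lesion_radii
    box_hi <- config$lesion_center + config$lesion_radii
    hem_flag <- any(h$center - h$radii < box_lo | h$center + h$radii > box_hi)
    if (hem_flag)
      warning("generate_phantom: hemorrhage extends beyond the lesion bounding region")
  }

  truth <- list(
    nwu_percent = 100 * config$true_uptake,
    baseline_nwu_percent = 100 * config$baseline_uptake,
    d_ischemic = config$brain_hu_mean * (1 - config$true_uptake),
    d_preischemic = config$brain_hu_mean,
    hemorrhage_outside_lesion = hem_flag,
    seed = config$seed)

  list(baseline = base$vol, followup = fu$vol,
       seg_baseline = base$seg, seg_followup = fu$seg, truth = truth)
}

#' Generate a full three-timepoint phantom subject
#'
#' One subject with baseline, 24-h and 1-week scans sharing one lesion
#' geometry but increasing water uptake, ready for [run_nwu_pipeline()].
#'
#' @param config A [phantom_config()]; its `baseline_uptake` is used for the
#'   baseline scan and its `misalignment` (if any) for both follow-ups.
#' @param uptakes length-3 fractional uptakes at baseline/24 h/1 week.
#' @return List with `baseline`, `followups` (list of two `ct_volume`s) and
#'   `segs` (named list of [lesion_seg()] per timepoint) plus `truth`.
#' @export
phantom_series <- function(config, uptakes = c(0.05, 0.10, 0.15)) {
  stopifnot(length(uptakes) == 3L)
  cfg_b <- config; cfg_b$baseline_uptake <- uptakes[1]
  cfg_b$true_uptake <- uptakes[2]
  ph24 <- generate_phantom(cfg_b)
  cfg_w <- config; cfg_w$baseline_uptake <- uptakes[1]
  cfg_w$true_uptake <- uptakes[3]; cfg_w$seed <- config$seed + 1L
  ph1w <- generate_phantom(cfg_w)
  fu1w <- ph1w$followup; fu1w$timepoint <- "1week"
  s1w <- ph1w$seg_followup
  s1w$lesion_mask$timepoint <- s1w$hemorrhage_mask$timepoint <- "1week"
  list(baseline = ph24$baseline,
       followups = list(`24h` = ph24$followup, `1week` = fu1w),
       segs = list(baseline = ph24$seg_baseline, `24h` = ph24$seg_followup,
                   `1week` = s1w),
       truth = list(nwu_percent = 100 * uptakes,
                    delta = c(`24h` = 100 * (uptakes[2] - uptakes[1]),
                              `1week` = 100 * (uptakes[3] - uptakes[1]))))
}

#' The symmetric reference atlas
#'
#' A noise-free brain phantom on the standard grid, left-right symmetric with
#' its midsagittal plane at world x = 0. Any symmetric template on a grid
#' whose x coordinates are symmetric about 0 may be substituted.
#'
#' @param grid_shape,voxel_spacing,brain_hu_mean,brain_radii as in
#'   [phantom_config()].
#' @return An `atlas_space` list with fields `template` (`ct_volume`) and
#'   `midplane_x` (fixed at 0).
#' @export
default_atlas <- function(grid_shape = c(50, 60, 44), voxel_spacing = c(3, 3, 3),
                          brain_hu_mean = 35, brain_radii = c(62, 78, 52)) {
  blank <- ct_volume(array(0, grid_shape), voxel_spacing)
  pts <- grid_world_coords(blank)
  hu <- rep(-1000, nrow(pts))
  hu[in_ellipsoid(pts, c(0, 0, 0), brain_radii)] <- brain_hu_mean
  template <- ct_volume(array(hu, grid_shape), voxel_spacing, blank$affine,
                        subject_id = "atlas", timepoint = NA_character_)
  structure(list(template = template, midplane_x = 0), class = "atlas_space")
}
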