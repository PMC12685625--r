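#' Read and write CT volumes and masks as NIfTI
#'
#' Geometry (voxel spacing and the voxel-to-world affine) is preserved
#' through the round trip; masks are validated to contain only 0/1 and, when
#' a parent volume is given, to share its grid exactly.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param subject_id,timepoint optional labels attached on read.
#' @return A `ct_volume`.
#' @export
read_volume <- function(path, subject_id = NA_character_,
                        timepoint = NA_character_) {
  if (!file.exists(path)) stop("read_volume: no such file: ", path)
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4, 4))
  data <- as.array(img)
  if (length(dim(data)) == 4L && dim(data)[4] == 1L)
    data <- array(data, dim(data)[1:3])
  ct_volume(data, RNifti::pixdim(img)[1:3], aff, subject_id, timepoint)
}

#' @param parent optional `ct_volume` whose grid the mask must match.
#' @rdname read_volume
#' @export
read_mask <- function(path, parent = NULL, subject_id = NA_character_,
                      timepoint = NA_character_) {
  m <- read_volume(path, subject_id, timepoint)
  vals <- unique(as.vector(m$data))
  bad <- setdiff(vals, c(0, 1))
  if (length(bad))
    stop("read_mask: non-binary mask values: ",
         paste(utils::head(sort(bad), 5), collapse = ", "))
  if (!is.null(parent) && !same_grid(m, parent))
    stop("read_mask: mask geometry does not match the declared parent volume")
  m
}

#' @param vol A `ct_volume` to write.
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Serialize / restore a transform as JSON
#' @param transform An `affine3d`.
#' @param path JSON file path.
#' @return `read_transform` returns an `affine3d`.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(list(matrix4x4 = affine_to_matrix(transform)), path,
                       digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)$matrix4x4
  matrix_to_affine(matrix(unlist(m), 4, 4, byrow = is.null(dim(m))))
}

#' Run configuration for the end-to-end synthetic pipeline
#'
#' @param out_dir output directory (created if absent).
#' @param n_subjects number of synthetic subjects imaged as phantoms.
#' @param hu_band HU band, default `c(20, 80)`.
#' @param m,mice_iterations imputation settings.
#' @param missing_rate MCAR rate injected into the simulated covariates.
#' @param register run the registration step (`FALSE` generates phantoms
#'   already in atlas space and skips it).
#' @param misalign_mm,misalign_deg follow-up misalignment magnitude injected
#'   when `register = TRUE`.
#' @param phantom,cohort [phantom_config()]-style and
#'   [cohort_sim_config()]-style base configurations.
#' @param settings [reg_settings()].
#' @param seed master seed; all stage seeds derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, n_subjects = 20L, hu_band = c(20, 80),
                       m = 5L, mice_iterations = 10L, missing_rate = 0.1,
                       register = FALSE, misalign_mm = 3, misalign_deg = 2,
                       phantom = phantom_config(), cohort = cohort_sim_config(),
                       settings = reg_settings(), seed = 1L) {
  if (hu_band[1] >= hu_band[2]) stop("run_config: HU band lo must be < hi")
  if (m < 1) stop("run_config: m must be >= 1")
  structure(list(out_dir = out_dir, n_subjects = as.integer(n_subjects),
                 hu_band = hu_band, m = as.integer(m),
                 mice_iterations = as.integer(mice_iterations),
                 missing_rate = missing_rate, register = register,
                 misalign_mm = misalign_mm, misalign_deg = misalign_deg,
                 phantom = phantom, cohort = cohort, settings = settings,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Small deterministic misalignment for subject i: translation of norm mm,
# rotation of deg degrees about a seed-determined axis.
subject_misalignment <- function(mm, deg, seed) {
  set.seed(seed)
  tdir <- stats::rnorm(3); tdir <- tdir / sqrt(sum(tdir^2))
  adir <- stats::rnorm(3); adir <- adir / sqrt(sum(adir^2))
  params_to_affine(translation = tdir * mm,
                   angles = adir * deg * pi / 180)
}

#' End-to-end synthetic run
#'
#' Simulates a cohort, images each of the first `n_subjects` patients as a
#' three-timepoint phantom whose injected uptakes are that patient's
#' simulated NWU trajectory, measures NWU back from the images through the
#' full pipeline, substitutes the measured values into the cohort, injects
#' missingness, imputes, and fits the univariable/multivariable model set.
#' Artifacts (`nwu.csv`, `cohort.csv`, `results.json`, `manifest.json`) are
#' written under `config$out_dir`; the manifest records the seed, a config
#' hash and the package version, and every QC flag is logged.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `nwu`, `cohort`, `models`, `manifest`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  atlas <- default_atlas(config$phantom$grid_shape, config$phantom$voxel_spacing,
                         brain_hu_mean = config$phantom$brain_hu_mean,
                         brain_radii = config$phantom$brain_radii)
  ccfg <- config$cohort
  ccfg$seed <- config$seed
  sim <- simulate_cohort(ccfg)
  cohort <- sim$cohort
  n_img <- min(config$n_subjects, nrow(cohort))
  nwu_rows <- list()
  flags <- character()
  for (i in seq_len(n_img)) {
    # image this patient: uptakes are the simulated NWU values (capped to
    # the phantom's valid range)
    up <- pmin(pmax(c(cohort$nwu_bl[i], cohort$nwu_24h[i],
                      cohort$nwu_1wk[i]) / 100, 0), 0.5)
    pcfg <- config$phantom
    pcfg$seed <- config$seed * 1000L + i
    if (config$register)
      pcfg$misalignment <- subject_misalignment(config$misalign_mm,
                                                config$misalign_deg,
                                                pcfg$seed + 500L)
    subj <- phantom_series(pcfg, uptakes = up)
    subj$baseline$subject_id <- cohort$subject_id[i]
    for (tp in names(subj$followups))
      subj$followups[[tp]]$subject_id <- cohort$subject_id[i]
    res <- run_nwu_pipeline(subj$baseline, subj$followups, subj$segs, atlas,
                            settings = config$settings,
                            hu_band = config$hu_band,
                            align = config$register)
    res$nwu_table$subject_id <- cohort$subject_id[i]
    nwu_rows[[i]] <- res$nwu_table
    fl <- res$nwu_table$qc_flags[res$nwu_table$qc_flags != ""]
    if (length(fl)) flags <- c(flags, sprintf("%s: %s", cohort$subject_id[i], fl))
    cohort$nwu_bl[i] <- res$measurements$baseline$nwu_percent
    cohort$nwu_24h[i] <- res$measurements[["24h"]]$nwu_percent
    cohort$nwu_1wk[i] <- res$measurements[["1week"]]$nwu_percent
  }
  nwu <- do.call(rbind, nwu_rows)
  if (config$missing_rate > 0)
    cohort <- inject_missingness(cohort, config$missing_rate,
                                 seed = config$seed + 7L)
  imps <- mice_impute(cohort, m = config$m,
                      iterations = config$mice_iterations,
                      seed = config$seed + 11L)
  models <- if (config$m >= 2) run_table2(imps)
            else run_table2(imps$imputations[[1]])
  manifest <- list(seed = config$seed,
                   config_hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("nwuct")),
                   n_subjects_imaged = n_img, qc_flags = flags)
  utils::write.csv(nwu, file.path(config$out_dir, "nwu.csv"), row.names = FALSE)
  utils::write.csv(cohort, file.path(config$out_dir, "cohort.csv"),
                   row.names = FALSE)
  jsonlite::write_json(models$results, file.path(config$out_dir, "results.json"),
                       dataframe = "rows", digits = 10)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(nwu = nwu, cohort = cohort, models = models,
                 manifest = manifest))
}

# Stable content hash of a config (structure + numbers, not environments).
config_hash <- function(config) {
  strip <- rapply(config, function(x) if (is.function(x)) NULL else x,
                  how = "replace")
  s <- paste(deparse(strip), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}
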