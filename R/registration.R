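#' Settings for affine registration
#'
#' @param metric similarity metric: `"nmi"` (normalized mutual information,
#'   robust to the intra-lesion density changes between timepoints) or
#'   `"mse"` (mean squared HU difference).
#' @param dof `"rigid"` (6 parameters) or `"affine"` (12: rigid + per-axis
#'   scale and shear). `"affine"` runs a rigid stage first and refines.
#' @param levels integer decimation factors of the multi-resolution schedule,
#'   coarse to fine; each level smooths at full resolution (Gaussian,
#'   `sigma = factor/2` voxels) before decimating, so edge positions survive
#'   coarsening.
#' @param maxit per-level iteration caps for the Nelder-Mead optimizer.
#' @param bins histogram bins for the NMI metric.
#' @param snap_tol translation (mm) below which, together with a linear part
#'   within 1e-4 of identity, the result is snapped to the exact identity:
#'   sub-hundredth-millimetre transforms are far below voxel resolution and
#'   snapping lets already-aligned inputs pass through untouched.
#' @return A `reg_settings` list.
#' @export
reg_settings <- function(metric = c("nmi", "mse"), dof = c("rigid", "affine"),
                         levels = c(4L, 2L), maxit = c(400L, 300L),
                         bins = 32L, snap_tol = 0.01) {
  metric <- match.arg(metric)
  dof <- match.arg(dof)
  stopifnot(length(levels) == length(maxit), all(levels >= 1))
  structure(list(metric = metric, dof = dof, levels = as.integer(levels),
                 maxit = as.integer(maxit), bins = as.integer(bins),
                 snap_tol = snap_tol),
            class = "reg_settings")
}

# Separable Gaussian smoothing (kernel truncated at 2 sigma, replicated
# edges); sigma in voxels.
smooth3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(2 * sigma))
  x <- -r:r
  w <- exp(-x^2 / (2 * sigma^2)); w <- w / sum(w)
  conv_dim <- function(a, dm) {
    out <- array(0, dim(a)); n <- dim(a)[dm]
    for (s in seq_along(x)) {
      src <- pmin(pmax(seq_len(n) + x[s], 1L), n)
      idx <- switch(dm, list(src, TRUE, TRUE), list(TRUE, src, TRUE),
                    list(TRUE, TRUE, src))
      out <- out + w[s] * a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    }
    out
  }
  conv_dim(conv_dim(conv_dim(a, 1L), 2L), 3L)
}

# One pyramid level: smooth at full resolution, then decimate.
pyramid_level <- function(vol, factor) {
  v <- vol
  v$data <- smooth3d(v$data, factor / 2)
  downsample_volume(v, factor)
}

# Intensity centre of mass in world coordinates (foreground = above -200 HU).
com_world <- function(vol) {
  w <- pmax(vol$data + 200, 0)
  if (sum(w) == 0) w <- vol$data - min(vol$data) + 1e-9
  pts <- grid_world_coords(vol)
  colSums(pts * as.vector(w)) / sum(w)
}

neg_nmi <- function(a, b, bins, ra, rb) {
  ia <- pmin(pmax(floor((a - ra[1]) / (ra[2] - ra[1]) * bins) + 1, 1), bins)
  ib <- pmin(pmax(floor((b - rb[1]) / (rb[2] - rb[1]) * bins) + 1, 1), bins)
  joint <- tabulate((ib - 1L) * bins + ia, nbins = bins * bins)
  p <- joint / sum(joint)
  px <- rowSums(matrix(p, bins, bins)); py <- colSums(matrix(p, bins, bins))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hxy <- ent(p)
  if (hxy == 0) return(-2)
  -(ent(px) + ent(py)) / hxy
}

#' Affine registration of one CT volume onto another
#'
#' Estimates the transform mapping `moving`-space world points into
#' `fixed`-space world points by minimizing the similarity metric over a
#' rigid (optionally full affine) parameterization, with centre-of-mass
#' initialization and a coarse-to-fine multi-resolution schedule. The
#' optimizer is deterministic (Nelder-Mead, fixed schedule, no stochastic
#' metric sampling), so identical inputs and settings always give identical
#' transforms.
#'
#' @param moving,fixed `ct_volume`s that overlap in world space.
#' @param settings A [reg_settings()].
#' @return An [affine3d()] (moving world -> fixed world) with attributes
#'   `metric` (final metric value) and `converged`.
#' @export
register_affine <- function(moving, fixed, settings = reg_settings()) {
  stopifnot(inherits(moving, "ct_volume"), inherits(fixed, "ct_volume"))
  center <- as.vector(fixed$affine %*% c((dim(fixed$data) - 1) / 2, 1))[1:3]
  t0 <- com_world(moving) - com_world(fixed)

  n_par <- if (settings$dof == "affine") 12L else 6L
  make_map <- function(p) {
    # p parameterizes the fixed -> moving resampling map
    params_to_affine(translation = p[1:3], angles = p[4:6], center = center,
                     log_scales = if (n_par > 6) p[7:9] else c(0, 0, 0),
                     shears = if (n_par > 6) p[10:12] else c(0, 0, 0))
  }

  p0 <- p <- c(t0, rep(0, n_par - 3))
  init_metric <- NA_real_
  final <- NA_real_
  conv <- TRUE
  for (lev in seq_along(settings$levels)) {
    f <- pyramid_level(fixed, settings$levels[lev])
    m <- pyramid_level(moving, settings$levels[lev])
    pts <- grid_world_coords(f)
    fvals <- as.vector(f$data)
    ra <- range(fvals); rb <- range(moving$data)
    if (diff(ra) == 0) ra <- ra + c(-1, 1)
    if (diff(rb) == 0) rb <- rb + c(-1, 1)
    obj <- function(par) {
      mv <- sample_volume(m, apply_affine(make_map(par), pts), "linear",
                          fill = -1000)
      if (settings$metric == "mse") mean((mv - fvals)^2)
      else neg_nmi(fvals, mv, settings$bins, ra, rb)
    }
    if (lev == length(settings$levels)) init_metric <- obj(p0)
    stages <- if (settings$dof == "affine" && lev == 1) {
      list(6L, n_par)  # rigid first, then open the affine terms
    } else list(n_par)
    for (np in stages) {
      act <- seq_len(np)
      fit <- stats::optim(p[act], function(q) {
               pp <- p; pp[act] <- q; obj(pp)
             }, method = "Nelder-Mead",
             control = list(maxit = settings$maxit[lev], reltol = 1e-10,
                            parscale = c(rep(5, 3), rep(0.05, 3),
                                         rep(0.05, 6))[act]))
      p[act] <- fit$par
      final <- fit$value
      if (lev == length(settings$levels) && fit$convergence > 1) conv <- FALSE
    }
  }
  # the final-level metric at the solution must not be worse than at the
  # centre-of-mass initialization evaluated on the same level
  if (final > init_metric + 1e-12)
    stop(sprintf("register_affine: failed to improve the metric (%.6g -> %.6g)",
                 init_metric, final))
  tf <- invert_affine(make_map(p))  # resampling map inverted = moving -> fixed
  if (max(abs(tf$translation)) < settings$snap_tol &&
      max(abs(tf$matrix - diag(3))) < 1e-4)
    tf <- identity_affine()
  attr(tf, "metric") <- final
  attr(tf, "converged") <- conv
  tf
}

#' Align one subject's scans into atlas space
#'
#' Realizes the two-step normalization: each follow-up is registered to the
#' baseline scan, the baseline is registered to the atlas template, and the
#' follow-up -> baseline and baseline -> atlas transforms are composed so a
#' follow-up is never registered to the atlas directly. All volumes are then
#' resampled onto the atlas grid (trilinear); each timepoint's lesion and
#' hemorrhage masks travel with their source volume's transform
#' (nearest-neighbour).
#'
#' @param baseline `ct_volume`, the baseline scan.
#' @param followups named list of follow-up `ct_volume`s (e.g. `"24h"`,
#'   `"1week"`).
#' @param segs named list of [lesion_seg()], one per timepoint including
#'   `"baseline"`, each in its source scan's native space.
#' @param atlas An `atlas_space` from [default_atlas()].
#' @param settings A [reg_settings()].
#' @return List with `volumes` (named list incl. `baseline`), `segs` (named
#'   list), and `transforms` (named list of `affine3d`, native -> atlas).
#' @export
align_patient <- function(baseline, followups, segs, atlas,
                          settings = reg_settings()) {
  stopifnot(inherits(atlas, "atlas_space"))
  tmpl <- atlas$template
  t_b2a <- tryCatch(register_affine(baseline, tmpl, settings),
                    error = function(e) stop("align_patient [baseline->atlas]: ",
                                             conditionMessage(e)))
  transforms <- list(baseline = t_b2a)
  for (tp in names(followups)) {
    t_f2b <- tryCatch(register_affine(followups[[tp]], baseline, settings),
                      error = function(e) stop(sprintf(
                        "align_patient [%s->baseline]: %s", tp,
                        conditionMessage(e))))
    transforms[[tp]] <- compose_affine(t_f2b, t_b2a)
  }
  vols <- c(list(baseline = baseline), followups)
  out_vols <- out_segs <- list()
  for (tp in names(vols)) {
    out_vols[[tp]] <- resample_volume(vols[[tp]], transforms[[tp]], tmpl, "linear")
    if (!is.null(segs[[tp]])) {
      s <- segs[[tp]]
      out_segs[[tp]] <- lesion_seg(
        resample_volume(s$lesion_mask, transforms[[tp]], tmpl, "nearest",
                        is_mask = TRUE),
        resample_volume(s$hemorrhage_mask, transforms[[tp]], tmpl, "nearest",
                        is_mask = TRUE))
    }
  }
  list(volumes = out_vols, segs = out_segs, transforms = transforms)
}
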