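#' CT volumes and grids
#'
#' A `ct_volume` is a 3-D scalar grid in Hounsfield Units together with its
#' geometry: voxel spacing (mm) and a 4x4 voxel-to-world affine (0-based voxel
#' indices, RAS-like world axes; the midsagittal plane of the atlas sits at
#' world x = 0). Binary masks reuse the same geometry and are stored as plain
#' 0/1 arrays alongside their parent volume.
#'
#' @param data 3-D numeric array, HU (or 0/1 for masks).
#' @param spacing mm per axis, length 3, all > 0.
#' @param affine 4x4 voxel-to-world matrix; if `NULL`, a diagonal affine that
#'   centers the grid on the world origin is built from `spacing`.
#' @param subject_id,timepoint optional labels; `timepoint` is one of
#'   `"baseline"`, `"24h"`, `"1week"`.
#' @return A `ct_volume` object.
#' @export
ct_volume <- function(data, spacing, affine = NULL, subject_id = NA_character_,
                      timepoint = NA_character_) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L, all(spacing > 0))
  if (!all(is.finite(data))) stop("ct_volume: non-finite HU values")
  if (is.null(affine)) affine <- centered_affine(dim(data), spacing)
  stopifnot(all(dim(affine) == c(4, 4)))
  if (abs(det(affine[1:3, 1:3])) < 1e-12) stop("ct_volume: affine not invertible")
  structure(list(data = data, spacing = as.numeric(spacing),
                 affine = unname(affine), subject_id = subject_id,
                 timepoint = timepoint),
            class = "ct_volume")
}

# Diagonal voxel-to-world affine with the grid centre at the world origin,
# which puts the left-right midplane of a symmetric grid exactly at x = 0.
centered_affine <- function(shape, spacing) {
  origin <- -(shape - 1) * spacing / 2
  rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s / %s: %s voxels @ %s mm, HU range [%.1f, %.1f]\n",
              x$subject_id, x$timepoint, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Do two volumes share a grid?
#' @param a,b `ct_volume` objects (or lists with `data` dims and `affine`).
#' @param tol geometric tolerance, mm.
#' @return Logical.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) && max(abs(a$affine - b$affine)) <= tol
}

# World coordinates (N x 3) of every voxel centre, in array (column-major) order.
grid_world_coords <- function(vol) {
  d <- dim(vol$data)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                               k = seq_len(d[3]) - 1))
  sweep(idx %*% t(vol$affine[1:3, 1:3]), 2, vol$affine[1:3, 4], "+")
}

# World -> continuous 0-based voxel coordinates.
world_to_voxel <- function(vol, points) {
  inv <- solve(vol$affine)
  sweep(points %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], "+")
}

#' Sample a volume at arbitrary world points
#'
#' Trilinear interpolation for intensities, nearest neighbour for masks.
#' Points outside the grid return `fill`.
#'
#' @param vol A `ct_volume`.
#' @param points N x 3 world coordinates, mm.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill Value for out-of-grid points (HU -1000 suits air; 0 suits masks).
#' @return Numeric vector of length N.
#' @export
sample_volume <- function(vol, points, interpolation = c("linear", "nearest"),
                          fill = -1000) {
  interpolation <- match.arg(interpolation)
  v <- world_to_voxel(vol, points)
  d <- dim(vol$data)
  if (interpolation == "nearest") {
    i <- round(v[, 1]); j <- round(v[, 2]); k <- round(v[, 3])
    ok <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 & k >= 0 & k <= d[3] - 1
    out <- rep(fill, nrow(v))
    out[ok] <- vol$data[cbind(i[ok] + 1, j[ok] + 1, k[ok] + 1)]
    return(out)
  }
  i0 <- floor(v[, 1]); j0 <- floor(v[, 2]); k0 <- floor(v[, 3])
  fi <- v[, 1] - i0; fj <- v[, 2] - j0; fk <- v[, 3] - k0
  ok <- i0 >= 0 & i0 <= d[1] - 2 & j0 >= 0 & j0 <= d[2] - 2 & k0 >= 0 & k0 <= d[3] - 2
  # points exactly on the far faces are valid too
  hi <- i0 == d[1] - 1 & fi == 0; hj <- j0 == d[2] - 1 & fj == 0; hk <- k0 == d[3] - 1 & fk == 0
  i0[hi] <- i0[hi] - 1; fi[hi] <- 1
  j0[hj] <- j0[hj] - 1; fj[hj] <- 1
  k0[hk] <- k0[hk] - 1; fk[hk] <- 1
  ok <- ok | ((i0 >= 0 & i0 <= d[1] - 2) & (j0 >= 0 & j0 <= d[2] - 2) &
              (k0 >= 0 & k0 <= d[3] - 2))
  out <- rep(fill, nrow(v))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  fi <- fi[ok]; fj <- fj[ok]; fk <- fk[ok]
  nx <- d[1]; nxy <- d[1] * d[2]
  base <- i0 + j0 * nx + k0 * nxy + 1
  a <- vol$data
  c000 <- a[base];            c100 <- a[base + 1]
  c010 <- a[base + nx];       c110 <- a[base + nx + 1]
  c001 <- a[base + nxy];      c101 <- a[base + nxy + 1]
  c011 <- a[base + nx + nxy]; c111 <- a[base + nx + nxy + 1]
  w00 <- c000 * (1 - fi) + c100 * fi
  w10 <- c010 * (1 - fi) + c110 * fi
  w01 <- c001 * (1 - fi) + c101 * fi
  w11 <- c011 * (1 - fi) + c111 * fi
  out[ok] <- (w00 * (1 - fj) + w10 * fj) * (1 - fk) +
             (w01 * (1 - fj) + w11 * fj) * fk
  out
}

#' Resample a volume or mask onto a target grid through a transform
#'
#' `transform` maps the *input's* world space into the *target's* world space
#' (the direction [register_affine()] returns). Each target voxel is filled by
#' sampling the input at the inverse-mapped location. Masks must use nearest
#' neighbour so outputs stay binary; intensities use trilinear interpolation.
#' An exact identity transform onto an identical grid returns the input
#' unchanged (no interpolation).
#'
#' @param vol A `ct_volume` (intensity image or 0/1 mask data).
#' @param transform An `affine3d`, input world -> target world.
#' @param target A `ct_volume` (only its geometry is used).
#' @param interpolation `"linear"` (intensities) or `"nearest"` (masks).
#' @param is_mask If `TRUE`, enforce nearest-neighbour and 0/1 output.
#' @param fill Out-of-field value (default -1000 HU; 0 for masks).
#' @return A `ct_volume` on the target grid.
#' @export
resample_volume <- function(vol, transform, target,
                            interpolation = c("linear", "nearest"),
                            is_mask = FALSE, fill = if (is_mask) 0 else -1000) {
  interpolation <- match.arg(interpolation)
  if (is_mask && interpolation == "linear")
    stop("resample_volume: masks must be resampled with nearest-neighbour interpolation")
  if (is_identity_affine(transform) && same_grid(vol, target)) {
    out <- vol
    out$subject_id <- vol$subject_id
    return(out)
  }
  pts <- grid_world_coords(target)
  pts <- apply_affine(invert_affine(transform), pts)
  vals <- sample_volume(vol, pts, interpolation, fill = fill)
  out <- array(vals, dim(target$data))
  if (is_mask) out <- (out != 0) * 1
  ct_volume(out, target$spacing, target$affine, vol$subject_id, vol$timepoint)
}

# Integer-stride downsampling used by the multi-resolution registration
# schedule. Keeps voxel (0,0,0) in place and scales the affine columns.
downsample_volume <- function(vol, factor) {
  if (factor <= 1) return(vol)
  d <- dim(vol$data)
  ii <- seq(1, d[1], by = factor); jj <- seq(1, d[2], by = factor)
  kk <- seq(1, d[3], by = factor)
  aff <- vol$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * factor
  ct_volume(vol$data[ii, jj, kk, drop = FALSE], vol$spacing * factor, aff,
            vol$subject_id, vol$timepoint)
}

#' Construct a lesion segmentation
#'
#' Pairs the total-lesion mask with the hemorrhage mask on one grid. The
#' hemorrhage mask may extend beyond the lesion (hyperdensities adjacent to
#' the hypodense region are outlined too).
#'
#' @param lesion_mask,hemorrhage_mask `ct_volume`s with 0/1 data on one grid.
#' @return A `lesion_seg` object.
#' @export
lesion_seg <- function(lesion_mask, hemorrhage_mask = NULL) {
  if (is.null(hemorrhage_mask)) {
    hemorrhage_mask <- lesion_mask
    hemorrhage_mask$data <- array(0, dim(lesion_mask$data))
  }
  if (!same_grid(lesion_mask, hemorrhage_mask))
    stop("lesion_seg: lesion and hemorrhage masks are on different grids")
  for (m in list(lesion_mask, hemorrhage_mask)) {
    bad <- setdiff(unique(as.vector(m$data)), c(0, 1))
    if (length(bad))
      stop("lesion_seg: mask values outside {0,1}: ", paste(bad, collapse = ", "))
  }
  structure(list(lesion_mask = lesion_mask, hemorrhage_mask = hemorrhage_mask),
            class = "lesion_seg")
}
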