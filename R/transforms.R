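#' 3-D affine world-coordinate transforms
#'
#' An `affine3d` object maps world points (mm) of one space into world points
#' of another: `y = M x + t`, with `M` an invertible 3x3 linear part and `t` a
#' translation in mm. Transforms compose and invert exactly; they are the
#' currency passed between registration, resampling and mirroring.
#'
#' @param matrix 3x3 linear part (determinant must be non-zero).
#' @param translation length-3 translation, mm.
#' @return An object of class `affine3d`.
#' @examples
#' t1 <- affine3d(translation = c(1, 2, 3))
#' t2 <- affine3d(translation = c(4, 5, 6))
#' compose_affine(t1, t2)$translation  # (5, 7, 9)
#' @export
affine3d <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L, all(is.finite(matrix)), all(is.finite(translation)))
  if (abs(det(matrix)) < .Machine$double.eps * 100)
    stop("affine3d: linear part is singular")
  structure(list(matrix = matrix, translation = translation), class = "affine3d")
}

#' @export
print.affine3d <- function(x, ...) {
  cat("<affine3d>\n")
  print(cbind(x$matrix, x$translation))
  invisible(x)
}

#' Identity transform
#' @return The identity `affine3d`.
#' @export
identity_affine <- function() affine3d()

#' Test a transform for (near-)identity
#' @param transform An `affine3d`.
#' @param tol_mm,tol_lin Tolerances on translation (mm) and linear part.
#' @return Logical.
#' @export
is_identity_affine <- function(transform, tol_mm = 1e-8, tol_lin = 1e-10) {
  max(abs(transform$translation)) <= tol_mm &&
    max(abs(transform$matrix - diag(3))) <= tol_lin
}

#' Compose two transforms
#'
#' The result applies `first`, then `second`: `(second o first)(x)`.
#' Composition is associative and exact (closed-form matrix algebra).
#'
#' @param first,second `affine3d` objects.
#' @return The composed `affine3d`.
#' @export
compose_affine <- function(first, second) {
  stopifnot(inherits(first, "affine3d"), inherits(second, "affine3d"))
  affine3d(second$matrix %*% first$matrix,
           as.vector(second$matrix %*% first$translation) + second$translation)
}

#' Invert a transform
#' @param transform An `affine3d`.
#' @return The inverse `affine3d`.
#' @export
invert_affine <- function(transform) {
  m <- solve(transform$matrix)
  affine3d(m, -as.vector(m %*% transform$translation))
}

#' Apply a transform to world points
#' @param transform An `affine3d`.
#' @param points N x 3 matrix (or length-3 vector) of world coordinates, mm.
#' @return N x 3 matrix of mapped coordinates.
#' @export
apply_affine <- function(transform, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3L)
  sweep(points %*% t(transform$matrix), 2, transform$translation, "+")
}

#' Convert to/from a homogeneous 4x4 matrix
#' @param transform An `affine3d`.
#' @return 4x4 matrix (last row 0 0 0 1).
#' @export
affine_to_matrix <- function(transform) {
  rbind(cbind(transform$matrix, transform$translation), c(0, 0, 0, 1))
}

#' @param m 4x4 homogeneous matrix.
#' @rdname affine_to_matrix
#' @export
matrix_to_affine <- function(m) {
  stopifnot(all(dim(m) == c(4, 4)))
  affine3d(m[1:3, 1:3], m[1:3, 4])
}

# Rotation about a center: y = R (x - c) + c + t.
rotation_zyx <- function(angles) {
  cz <- cos(angles[3]); sz <- sin(angles[3])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cx <- cos(angles[1]); sx <- sin(angles[1])
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  rz %*% ry %*% rx
}

#' Build a rigid (or scaled/sheared) transform about a center point
#'
#' Parameterization used by the registration optimizer: rotations are ZYX
#' Euler angles in radians applied about `center`, followed by translation.
#' Optional per-axis log-scales and shears extend the model to full affine.
#'
#' @param translation mm, length 3.
#' @param angles radians, length 3 (rotation about x, y, z).
#' @param center world point the rotation/scaling pivots about, mm.
#' @param log_scales,shears optional length-3 affine extensions.
#' @return An `affine3d`.
#' @export
params_to_affine <- function(translation = c(0, 0, 0), angles = c(0, 0, 0),
                             center = c(0, 0, 0), log_scales = c(0, 0, 0),
                             shears = c(0, 0, 0)) {
  lin <- rotation_zyx(angles)
  if (any(log_scales != 0)) lin <- lin %*% diag(exp(log_scales))
  if (any(shears != 0)) {
    sh <- diag(3)
    sh[1, 2] <- shears[1]; sh[1, 3] <- shears[2]; sh[2, 3] <- shears[3]
    lin <- lin %*% sh
  }
  affine3d(lin, center - as.vector(lin %*% center) + translation)
}

#' Mirror transform across the midsagittal plane x = 0
#' @return The `affine3d` sending world (x, y, z) to (-x, y, z).
#' @export
mirror_affine_x <- function() affine3d(diag(c(-1, 1, 1)), c(0, 0, 0))
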