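# Rotation utilities. All rotations are 3x3 proper orthogonal matrices acting
# on laboratory-frame column vectors; rotation vectors follow the right-hand
# rule with angles in radians.

#' Rotation matrix about an axis
#'
#' Builds the proper rotation of `angle` radians about `axis` (Rodrigues
#' formula, right-hand rule).
#'
#' @param axis Numeric 3-vector; need not be normalised.
#' @param angle Rotation angle in radians.
#' @return A 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-300) stop("rotation axis has zero length")
  axis <- axis / n
  K <- matrix(c(0, axis[3L], -axis[2L],
                -axis[3L], 0, axis[1L],
                axis[2L], -axis[1L], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Rotation matrix from a rotation vector
#'
#' The rotation vector's direction is the axis and its length the angle in
#' radians; the zero vector gives the identity.
#'
#' @param v Numeric 3-vector.
#' @return A 3x3 rotation matrix.
#' @export
rotation_from_vector <- function(v) {
  ang <- sqrt(sum(v^2))
  if (ang < 1e-300) return(diag(3L))
  rotation_about_axis(v, ang)
}

#' Rotation angle and vector of a rotation matrix
#'
#' `rotation_angle()` returns the angle in radians; `rotation_vector()` the
#' full axis-times-angle vector (the matrix logarithm), whose components about
#' the laboratory x, y and z axes decompose a small misorientation.
#'
#' @param R A 3x3 rotation matrix.
#' @return Angle in radians, or a numeric 3-vector.
#' @export
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' @rdname rotation_angle
#' @export
rotation_vector <- function(R) {
  ang <- rotation_angle(R)
  if (ang < 1e-12) {
    # first-order: R ~ I + [v]_x
    return(c(R[3L, 2L] - R[2L, 3L], R[1L, 3L] - R[3L, 1L],
             R[2L, 1L] - R[1L, 2L]) / 2)
  }
  if (ang > pi - 1e-6) {
    # near-pi: axis from the symmetric part
    S <- (R + diag(3L)) / 2
    axis <- sqrt(pmax(diag(S), 0))
    # fix signs from off-diagonals using the largest component
    i <- which.max(axis)
    sgn <- c(1, 1, 1)
    j <- setdiff(1:3, i)
    sgn[j] <- sign(S[i, j] / axis[i])
    axis <- axis * sgn
    return(axis / sqrt(sum(axis^2)) * ang)
  }
  c(R[3L, 2L] - R[2L, 3L], R[1L, 3L] - R[3L, 1L], R[2L, 1L] - R[1L, 2L]) /
    (2 * sin(ang)) * ang
}

# Nearest rotation matrix (polar factor via SVD); guards against the small
# non-orthogonality introduced by finite-precision cell arithmetic.
nearest_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R
}

#' Uniformly random orientation
#'
#' Draws a rotation uniformly over all three-dimensional orientations by the
#' unit-quaternion method: four independent standard normals, normalised.
#' Uses the current RNG stream, so results are reproducible under
#' [set.seed()].
#'
#' @return A 3x3 rotation matrix.
#' @export
random_orientation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L)
}

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
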