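#' Unit cell
#'
#' Constructs a triclinic unit cell. Lengths are in Angstrom, angles in
#' degrees; the metric tensor must be positive definite.
#'
#' @param a,b,c Cell edge lengths (Angstrom), all positive.
#' @param alpha,beta,gamma Cell angles (degrees), each in (0, 180).
#' @return An object of class `unit_cell`: a named numeric vector
#'   `(a, b, c, alpha, beta, gamma)`.
#' @examples
#' unit_cell(281, 281, 165.2, 90, 90, 120)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  p <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(p))) stop("non-finite unit-cell parameter")
  if (any(p[1:3] <= 0)) stop("unit-cell lengths must be positive")
  if (any(p[4:6] <= 0 | p[4:6] >= 180)) {
    stop("unit-cell angles must lie in (0, 180) degrees")
  }
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) stop("degenerate unit cell: metric tensor not positive definite")
  structure(p, class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Unit cell: a=%.4g b=%.4g c=%.4g A  alpha=%.4g beta=%.4g gamma=%.4g deg\n",
              x[["a"]], x[["b"]], x[["c"]],
              x[["alpha"]], x[["beta"]], x[["gamma"]]))
  invisible(x)
}

#' Cell volume
#' @param cell A [unit_cell()].
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  ca <- cos(cell[["alpha"]] * pi / 180)
  cb <- cos(cell[["beta"]] * pi / 180)
  cg <- cos(cell[["gamma"]] * pi / 180)
  cell[["a"]] * cell[["b"]] * cell[["c"]] *
    sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

#' Reciprocal-basis matrix of a cell
#'
#' Returns the upper-triangular reciprocal-cell basis B in the fixed reference
#' setting with a* along laboratory x and b* in the x-y plane (Busing-Levy
#' convention). The columns of B are the reciprocal axes a*, b*, c* in
#' reciprocal Angstrom; for any orientation R, the orientation matrix is
#' A = R B and q = A h.
#'
#' @param cell A [unit_cell()].
#' @return A 3x3 upper-triangular matrix (reciprocal Angstrom).
#' @export
reciprocal_basis <- function(cell) {
  a <- cell[["a"]]; b <- cell[["b"]]; cc <- cell[["c"]]
  al <- cell[["alpha"]] * pi / 180
  be <- cell[["beta"]] * pi / 180
  ga <- cell[["gamma"]] * pi / 180
  V <- cell_volume(cell)
  as <- b * cc * sin(al) / V
  bs <- a * cc * sin(be) / V
  cs <- a * b * sin(ga) / V
  # reciprocal angles
  cgs <- (cos(al) * cos(be) - cos(ga)) / (sin(al) * sin(be))
  cbs <- (cos(al) * cos(ga) - cos(be)) / (sin(al) * sin(ga))
  sgs <- sqrt(max(0, 1 - cgs^2))
  matrix(c(as, 0, 0,
           bs * cgs, bs * sgs, 0,
           cs * cbs, -cs * sqrt(max(0, 1 - cbs^2)) * cos(al), 1 / cc),
         3L, 3L)
}

#' Recover cell parameters from an orientation (or basis) matrix
#'
#' Inverts the reciprocal metric `t(A) %*% A` to the direct metric tensor and
#' reads off lengths and angles; the result is orientation independent.
#'
#' @param A A 3x3 orientation or reciprocal-basis matrix.
#' @return A [unit_cell()].
#' @export
cell_from_matrix <- function(A) {
  Gstar <- crossprod(A)
  G <- solve(Gstar)
  len <- sqrt(diag(G))
  ang <- function(i, j) acos(G[i, j] / (len[i] * len[j])) * 180 / pi
  unit_cell(len[1L], len[2L], len[3L], ang(2L, 3L), ang(1L, 3L), ang(1L, 2L))
}
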