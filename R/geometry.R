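# Laboratory frame: right handed, incident beam travelling along -z, flat
# detector in the plane z = -distance with its x,y axes parallel to lab x,y.
# Detector coordinates are millimetres relative to the beam centre (the point
# where the direct beam intersects the plane); the beam_center field places
# that point on the physical panel, measured from the panel corner.

#' Incident beam
#'
#' @param wavelength Wavelength in Angstrom (positive).
#' @param s0_hat Unit vector of the incident beam direction; default
#'   `c(0, 0, -1)` (beam travelling along -z).
#' @return An object of class `beam` with fields `wavelength`, `s0_hat` and
#'   `s0 = s0_hat / wavelength` (the incident wavevector, reciprocal
#'   Angstrom).
#' @export
beam <- function(wavelength, s0_hat = c(0, 0, -1)) {
  if (!is.numeric(wavelength) || length(wavelength) != 1L || wavelength <= 0) {
    stop("wavelength must be a positive scalar (Angstrom)")
  }
  n <- sqrt(sum(s0_hat^2))
  if (abs(n - 1) > 1e-12) stop("s0_hat must be a unit vector")
  structure(list(wavelength = wavelength, s0_hat = as.numeric(s0_hat),
                 s0 = as.numeric(s0_hat) / wavelength),
            class = "beam")
}

#' @export
print.beam <- function(x, ...) {
  cat(sprintf("Beam: lambda = %.4g A, s0_hat = (%g, %g, %g)\n",
              x$wavelength, x$s0_hat[1L], x$s0_hat[2L], x$s0_hat[3L]))
  invisible(x)
}

#' Flat detector
#'
#' A single flat panel perpendicular to the beam at `distance` millimetres
#' from the sample.
#'
#' @param distance Sample-to-detector distance along -z (mm, positive).
#' @param pixel_size Square pixel edge (mm).
#' @param n_fast,n_slow Pixel counts along the panel x and y axes.
#' @param beam_center Position (mm) of the direct-beam intersection on the
#'   panel, measured from the panel corner; defaults to the panel centre.
#' @return An object of class `detector`.
#' @export
detector <- function(distance, pixel_size, n_fast, n_slow,
                     beam_center = c(n_fast, n_slow) * pixel_size / 2) {
  if (distance <= 0) stop("detector distance must be positive")
  if (pixel_size <= 0) stop("pixel size must be positive")
  structure(list(distance = distance, pixel_size = pixel_size,
                 n_fast = as.integer(n_fast), n_slow = as.integer(n_slow),
                 beam_center = as.numeric(beam_center)),
            class = "detector")
}

#' @export
print.detector <- function(x, ...) {
  cat(sprintf("Detector: %d x %d pixels of %.3g mm at %.4g mm, beam centre (%.4g, %.4g) mm\n",
              x$n_fast, x$n_slow, x$pixel_size, x$distance,
              x$beam_center[1L], x$beam_center[2L]))
  invisible(x)
}

#' Project diffracted rays onto the detector
#'
#' Intersects rays from the sample along the diffracted wavevectors `s1` with
#' the detector plane z = -distance. Coordinates are returned in millimetres
#' relative to the beam centre, so the direct beam maps to (0, 0).
#'
#' @param s1 Diffracted wavevector(s): a numeric 3-vector or an n x 3 matrix.
#' @param beam A [beam()] (unused by the plane intersection itself, kept for a
#'   uniform geometry signature).
#' @param det A [detector()].
#' @return A data frame with columns `x_mm`, `y_mm` and logical `hits`
#'   (`FALSE` where the ray is parallel to or directed away from the plane;
#'   coordinates are `NA` there).
#' @export
project_to_detector <- function(s1, beam, det) {
  z <- project_core(s1, det)
  data.frame(x_mm = z$x_mm, y_mm = z$y_mm, hits = z$hits)
}

project_core <- function(s1, det) {
  if (is.null(dim(s1))) s1 <- matrix(s1, 1L, 3L)
  z <- s1[, 3L]
  hits <- is.finite(z) & z < 0
  t <- ifelse(hits, -det$distance / z, NA_real_)
  list(x_mm = t * s1[, 1L], y_mm = t * s1[, 2L], hits = hits)
}

#' Back-project observed spots onto the Ewald sphere
#'
#' Converts detector centroids (mm, beam-centre relative) to scattering
#' vectors q = s1 - s0 with |s1| = 1/lambda, so every returned vector lies
#' exactly on the Ewald sphere: |q + s0| = 1/lambda.
#'
#' @param xy Numeric length-2 vector or n x 2 matrix / data frame of
#'   `(x_mm, y_mm)` positions.
#' @param beam A [beam()].
#' @param det A [detector()].
#' @return An n x 3 matrix of scattering vectors (reciprocal Angstrom).
#' @export
backproject_to_q <- function(xy, beam, det) {
  if (is.data.frame(xy)) xy <- cbind(xy$x_mm, xy$y_mm)
  if (is.null(dim(xy))) xy <- matrix(xy, 1L, 2L)
  dir <- cbind(xy[, 1L], xy[, 2L], -det$distance)
  dir <- dir / sqrt(rowSums(dir^2))
  s1 <- dir / beam$wavelength
  sweep(s1, 2L, beam$s0, "-")
}

# TRUE for beam-centre-relative positions that land on the physical panel.
on_detector <- function(xy, det) {
  if (is.data.frame(xy)) xy <- cbind(xy$x_mm, xy$y_mm)
  ax <- xy[, 1L] + det$beam_center[1L]
  ay <- xy[, 2L] + det$beam_center[2L]
  is.finite(ax) & is.finite(ay) &
    ax >= 0 & ax <= det$n_fast * det$pixel_size &
    ay >= 0 & ay <= det$n_slow * det$pixel_size
}

# Snap beam-centre-relative positions to pixel centres.
quantize_to_pixels <- function(xy, det) {
  p <- det$pixel_size
  ax <- (floor((xy[, 1L] + det$beam_center[1L]) / p) + 0.5) * p
  ay <- (floor((xy[, 2L] + det$beam_center[2L]) / p) + 0.5) * p
  cbind(ax - det$beam_center[1L], ay - det$beam_center[2L])
}
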