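# Seeded synthetic still-shot generator. A scene is the deterministic
# envelope-acceptance of the lattice under a true model: every reflection
# within the resolution range whose Ewald offset lies inside the envelope is
# projected to the detector at its reflecting position, with optional
# Gaussian centroid jitter and pixel quantisation. The truth (model,
# envelope, indices) is retained so every estimator can be scored by
# parameter recovery.

#' PSI-like still-shot conditions
#'
#' The reference simulation conditions used throughout: a hexagonal
#' photosystem-I-like crystal (a = b = 281, c = 165.2 Angstrom, gamma = 120
#' degrees), monochromatic 1.32 Angstrom radiation along -z, a flat
#' pixel-array detector with 0.11 mm pixels at 129 mm, zero mosaic spread
#' and an effective block size of 4850 Angstrom (a crystallite of 17 x 17 x
#' 30 cells), analysed over 15-3.5 Angstrom.
#'
#' @return A list with elements `cell`, `symmetry`, `beam`, `det`,
#'   `envelope` and `d_range`.
#' @export
psi_conditions <- function() {
  list(cell = unit_cell(281, 281, 165.2, 90, 90, 120),
       symmetry = "hexagonal_622",
       beam = beam(1.32),
       det = detector(129, 0.11, 1765L, 1765L),
       envelope = mosaic_envelope(0, 4850),
       d_range = c(15, 3.5))
}

#' Simulate a still-shot scene
#'
#' Generates the observed bright-spot list of one still exposure: the true
#' model's reflections within the resolution range are accepted when
#' `|delta_psi| <= envelope_halfwidth(env_true, d)`, projected onto the
#' detector at their reflecting positions, then optionally jittered with
#' Gaussian centroid noise and snapped to pixel centres. Off-detector spots
#' are dropped. Regeneration from the same seed and parameters is
#' bit-identical; the caller's RNG state is untouched.
#'
#' @param cell A [unit_cell()] (default: PSI-like).
#' @param symmetry Lattice symmetry tag.
#' @param envelope True [mosaic_envelope()].
#' @param beam A [beam()].
#' @param det A [detector()].
#' @param d_range Resolution range in Angstrom (default `c(15, 3.5)`).
#' @param orientation Optional 3x3 rotation; when NULL a uniformly random
#'   orientation is drawn from the seed.
#' @param noise_sigma_mm Gaussian centroid jitter, mm (default 0).
#' @param pixel_quantize Snap centroids to pixel centres (default FALSE).
#' @param seed Integer seed.
#' @return An object of class `still_scene`: list with `model` (true
#'   [crystal_model()]), `envelope`, `beam`, `det`, `spots` (data frame
#'   `image_id, x_mm, y_mm, intensity, h, k, l, delta_psi_rad, d_angstrom`
#'   with true indices and pre-noise offsets), `seed`, `noise_sigma_mm`,
#'   `pixel_quantize`, `d_range`.
#' @export
simulate_still <- function(cell = psi_conditions()$cell,
                           symmetry = "hexagonal_622",
                           envelope = psi_conditions()$envelope,
                           beam = psi_conditions()$beam,
                           det = psi_conditions()$det,
                           d_range = c(15, 3.5),
                           orientation = NULL,
                           noise_sigma_mm = 0,
                           pixel_quantize = FALSE,
                           seed = 1L) {
  with_seed(seed, {
    U <- if (is.null(orientation)) random_orientation() else orientation
    model <- crystal_model(cell, U, symmetry)
    refl <- enumerate_reflections(model, beam,
                                  d_min = min(d_range), d_max = max(d_range),
                                  envelope = envelope, coarse_factor = 1)
    if (nrow(refl) > 0L) {
      q <- q_from_hkl(model, as.matrix(refl[, c("h", "k", "l")]))
      r <- reflecting_position(q, beam)
      pr <- project_to_detector(sweep(r, 2L, beam$s0, "+"), beam, det)
      ok <- pr$hits & on_detector(pr, det)
      refl <- refl[ok, , drop = FALSE]
      xy <- cbind(pr$x_mm[ok], pr$y_mm[ok])
      if (noise_sigma_mm > 0 && nrow(xy) > 0L) {
        xy <- xy + matrix(stats::rnorm(2L * nrow(xy), 0, noise_sigma_mm),
                          ncol = 2L)
      }
      if (pixel_quantize && nrow(xy) > 0L) xy <- quantize_to_pixels(xy, det)
    } else {
      xy <- matrix(numeric(0), 0L, 2L)
    }
    spots <- data.frame(image_id = rep(1L, nrow(refl)),
                        x_mm = xy[, 1L], y_mm = xy[, 2L],
                        intensity = rep(NA_real_, nrow(refl)),
                        h = refl$h, k = refl$k, l = refl$l,
                        delta_psi_rad = refl$delta_psi,
                        d_angstrom = refl$d, row.names = NULL)
    scene <- structure(list(model = model, envelope = envelope, beam = beam,
                            det = det, spots = spots, seed = seed,
                            noise_sigma_mm = noise_sigma_mm,
                            pixel_quantize = pixel_quantize,
                            d_range = d_range),
                       class = "still_scene")
    if (nrow(spots) == 0L) {
      warning("envelope accepted no reflections: empty scene")
    }
    scene
  })
}

#' @export
print.still_scene <- function(x, ...) {
  cat(sprintf("Still scene: %d spots (seed %d, noise %.3g mm%s)\n",
              nrow(x$spots), x$seed, x$noise_sigma_mm,
              if (x$pixel_quantize) ", pixelated" else ""))
  print(x$model)
  print(x$envelope)
  invisible(x)
}

#' Randomly perturbed refinement start
#'
#' Draws per-axis rotations uniformly within `max_rot_deg` and relative cell
#' length errors uniformly within `max_cell_rel`, and applies them with
#' [perturb_model()]. Deterministic under the seed.
#'
#' @param model True [crystal_model()].
#' @param max_rot_deg Per-axis rotation bound in degrees (default 0.5).
#' @param max_cell_rel Relative cell-length error bound (default 0.005).
#' @param seed Integer seed.
#' @return A perturbed [crystal_model()].
#' @export
random_start <- function(model, max_rot_deg = 0.5, max_cell_rel = 0.005,
                         seed = 1L) {
  with_seed(seed, {
    dR <- stats::runif(3L, -max_rot_deg, max_rot_deg)
    er <- stats::runif(3L, -max_cell_rel, max_cell_rel)
    if (model$symmetry == "hexagonal_622") er[2L] <- er[1L]
    perturb_model(model, dR, er)
  })
}
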