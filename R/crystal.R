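#' Crystal model
#'
#' A crystal model holds a unit cell, an orientation and a lattice-symmetry
#' tag. Its reciprocal orientation matrix is `A = U %*% B`, where `B` is the
#' reciprocal basis of the cell in the fixed reference setting
#' ([reciprocal_basis()]) and `U` a proper rotation; the columns of `A` are
#' the laboratory-frame reciprocal axes a*, b*, c*, and a reflection with
#' Miller index h sits at `q = A %*% h`.
#'
#' @param cell A [unit_cell()].
#' @param orientation A 3x3 proper rotation matrix (default identity).
#' @param symmetry Lattice symmetry tag: `"triclinic"` or
#'   `"hexagonal_622"`.
#' @return An object of class `crystal_model` with fields `cell`, `U`, `B`,
#'   `A` and `symmetry`.
#' @examples
#' m <- crystal_model(unit_cell(100, 100, 100))
#' m$A                                  # diag(0.01, 0.01, 0.01)
#' @export
crystal_model <- function(cell, orientation = diag(3L),
                          symmetry = c("triclinic", "hexagonal_622")) {
  symmetry <- match.arg(symmetry)
  if (!inherits(cell, "unit_cell")) cell <- do.call(unit_cell, as.list(cell))
  U <- as.matrix(orientation)
  if (max(abs(crossprod(U) - diag(3L))) > 1e-8 || det(U) < 0) {
    stop("orientation must be a proper rotation matrix")
  }
  B <- reciprocal_basis(cell)
  structure(list(cell = cell, U = U, B = B, A = U %*% B, symmetry = symmetry),
            class = "crystal_model")
}

#' @export
print.crystal_model <- function(x, ...) {
  cat("Crystal model (", x$symmetry, ")\n", sep = "")
  print(x$cell)
  cat("Orientation (rotation vector, deg):",
      sprintf("%.4f", rotation_vector(x$U) * 180 / pi), "\n")
  invisible(x)
}

#' Reciprocal-space coordinates of reflections
#'
#' Maps Miller indices to laboratory-frame reciprocal coordinates,
#' `q = A %*% h`. The resolution of a reflection is `d = 1 / |q|`.
#'
#' @param model A [crystal_model()].
#' @param hkl Integer 3-vector or n x 3 matrix of Miller indices.
#' @return An n x 3 matrix of scattering vectors (reciprocal Angstrom).
#' @export
q_from_hkl <- function(model, hkl) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, 1L, 3L)
  t(model$A %*% t(hkl))
}

# Cartesian point-group rotations for the supported symmetry tags, expressed
# in the reference setting of reciprocal_basis(). For 622 the sixfold axis is
# along z (where the hexagonal c axis lies) and the six twofold axes lie in
# the basal plane at 30-degree spacing, starting along the direct a axis at
# -30 degrees from a* (verified integral on the hexagonal lattice in tests).
point_group_rotations <- function(symmetry) {
  switch(symmetry,
    triclinic = list(diag(3L)),
    hexagonal_622 = {
      ops <- lapply(0:5, function(k) rotation_about_axis(c(0, 0, 1), k * pi / 3))
      two <- lapply(0:5, function(k) {
        phi <- -pi / 6 + k * pi / 6
        rotation_about_axis(c(cos(phi), sin(phi), 0), pi)
      })
      c(ops, two)
    },
    stop("unknown symmetry tag: ", symmetry)
  )
}

#' Symmetry-reduced misorientation between two crystal models
#'
#' Returns the minimum, over the point-group rotations of the symmetry tag,
#' of the rotation angle relating the two model orientations, together with
#' the laboratory-axis decomposition (rotation-vector components) of that
#' minimal relating rotation. On stills only the z component moves predicted
#' spot centroids directly, so the x and y components isolate the
#' positionally silent part of the error.
#'
#' @param model,reference [crystal_model()] objects sharing the same cell up
#'   to refinement error.
#' @param symmetry Symmetry tag used for the reduction; defaults to the
#'   reference model's tag.
#' @return A list with `angle` (degrees) and `components`, the named
#'   `(R_x, R_y, R_z)` rotation-vector components in degrees.
#' @export
misorientation_angle <- function(model, reference, symmetry = reference$symmetry) {
  ops <- point_group_rotations(symmetry)
  Um <- nearest_rotation(model$U)
  Ur <- nearest_rotation(reference$U)
  best <- Inf; best_R <- diag(3L)
  for (S in ops) {
    dR <- Um %*% t(Ur %*% S)
    ang <- rotation_angle(dR)
    if (ang < best) { best <- ang; best_R <- dR }
  }
  v <- rotation_vector(best_R) * 180 / pi
  list(angle = best * 180 / pi,
       components = c(R_x = v[1L], R_y = v[2L], R_z = v[3L]))
}

#' Assign Miller indices to observed spots
#'
#' Back-projects each centroid onto the Ewald sphere and rounds the
#' fractional index `solve(A, q_obs)` to the nearest integer triple. Spots
#' whose largest fractional deviation exceeds `max_frac_dev` are left
#' unassigned (NA indices); the model must already be approximately correct
#' (misorientation below about a degree).
#'
#' @param spots Spot data frame with columns `x_mm`, `y_mm` (beam-centre
#'   relative millimetres).
#' @param model A [crystal_model()].
#' @param beam A [beam()].
#' @param det A [detector()].
#' @param max_frac_dev Assignment cutoff on the fractional-index deviation
#'   (default 0.3).
#' @return The spot data frame with `h`, `k`, `l` filled in (NA where
#'   unassigned) and an attribute `n_unassigned`.
#' @export
assign_indices <- function(spots, model, beam, det, max_frac_dev = 0.3) {
  if (nrow(spots) == 0L) {
    spots$h <- integer(0); spots$k <- integer(0); spots$l <- integer(0)
    attr(spots, "n_unassigned") <- 0L
    return(spots)
  }
  if (abs(det(model$A)) < 1e-300) stop("singular orientation matrix")
  q <- backproject_to_q(cbind(spots$x_mm, spots$y_mm), beam, det)
  hf <- t(solve(model$A, t(q)))
  h <- round(hf)
  dev <- apply(abs(hf - h), 1L, max)
  ok <- dev <= max_frac_dev
  spots$h <- ifelse(ok, h[, 1L], NA_real_)
  spots$k <- ifelse(ok, h[, 2L], NA_real_)
  spots$l <- ifelse(ok, h[, 3L], NA_real_)
  attr(spots, "n_unassigned") <- sum(!ok)
  spots
}

#' Perturb a crystal model
#'
#' Composes rotations of the stated magnitudes about the laboratory axes onto
#' the orientation and applies independent relative errors to the cell
#' lengths (cell angles are left untouched for the fixed-angle families).
#' Used to generate refinement starting points that mimic post-indexing
#' error.
#'
#' @param model A [crystal_model()].
#' @param dR_deg Rotations about lab x, y, z in degrees (length 3).
#' @param cell_rel_error Relative errors applied to (a, b, c); scalar or
#'   length 3.
#' @return A perturbed [crystal_model()].
#' @export
perturb_model <- function(model, dR_deg = c(0, 0, 0), cell_rel_error = 0) {
  r <- dR_deg * pi / 180
  R <- rotation_about_axis(c(0, 0, 1), r[3L]) %*%
    rotation_about_axis(c(0, 1, 0), r[2L]) %*%
    rotation_about_axis(c(1, 0, 0), r[1L])
  err <- rep_len(cell_rel_error, 3L)
  cl <- as.numeric(model$cell)
  cell <- unit_cell(cl[1L] * (1 + err[1L]), cl[2L] * (1 + err[2L]),
                    cl[3L] * (1 + err[3L]), cl[4L], cl[5L], cl[6L])
  crystal_model(cell, R %*% model$U, model$symmetry)
}

#' Project a cell onto a Bravais family
#'
#' Least-squares symmetrisation of the cell parameters: for
#' `"hexagonal_622"`, a and b are replaced by their mean, the angles are set
#' to 90/90/120 and the orientation is kept. Triclinic is the identity.
#'
#' @param model A [crystal_model()].
#' @param symmetry Target symmetry tag.
#' @return A [crystal_model()] in the constrained family.
#' @export
symmetrize_cell <- function(model, symmetry = c("hexagonal_622", "triclinic")) {
  symmetry <- match.arg(symmetry)
  if (symmetry == "triclinic") {
    return(crystal_model(model$cell, model$U, "triclinic"))
  }
  cl <- as.numeric(model$cell)
  cell <- unit_cell(mean(cl[1:2]), mean(cl[1:2]), cl[3L], 90, 90, 120)
  crystal_model(cell, model$U, symmetry)
}
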