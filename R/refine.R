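# Crystal-model refinement against still-shot spot centroids.
#
# The positional target is the sum of squared distances (mm^2) between
# observed centroids and the detector projections of the reflecting
# positions of the modelled reciprocal-lattice points. The hybrid target
# adds the squared Ewald-sphere offset angles, taken in units of
# radians/(2*pi) so that both terms are on comparable numerical scales.

# Per-spot calculated quantities for an assigned spot table under a model.
# Returns x/y_calc (mm), delta_psi (rad), d (A) and an ok flag (degenerate
# delta-psi configurations and non-intersecting rays are dropped from fits).
spot_calc <- function(model, spots, beam, det) {
  hkl <- cbind(spots$h, spots$k, spots$l)
  q <- q_from_hkl(model, hkl)
  dp <- dpsi_core(q, beam, light = TRUE)
  s1 <- cbind(dp$r[, 1L] + beam$s0[1L], dp$r[, 2L] + beam$s0[2L],
              dp$r[, 3L] + beam$s0[3L])
  pr <- project_core(s1, det)
  ok <- dp$ok & pr$hits
  list(x_calc = pr$x_mm, y_calc = pr$y_mm,
       delta_psi = dp$delta_psi, d = dp$d, ok = ok)
}

check_assigned <- function(spots) {
  if (nrow(spots) == 0L) stop("no spots supplied")
  if (anyNA(spots$h) || anyNA(spots$k) || anyNA(spots$l)) {
    stop("all spots must be index-assigned before computing a target")
  }
}

#' Positional least-squares target
#'
#' Sum of squared centroid residuals, in square millimetres, between the
#' observed spots and the detector projections of the model's reflecting
#' positions.
#'
#' @param model A [crystal_model()].
#' @param spots Assigned spot data frame (`x_mm`, `y_mm`, `h`, `k`, `l`).
#' @param beam A [beam()].
#' @param det A [detector()].
#' @return Scalar target value (mm^2).
#' @export
positional_target <- function(model, spots, beam, det) {
  check_assigned(spots)
  sc <- spot_calc(model, spots, beam, det)
  sum((spots$x_mm - sc$x_calc)[sc$ok]^2 + (spots$y_mm - sc$y_calc)[sc$ok]^2)
}

#' Hybrid positional + angular-offset target
#'
#' The positional target plus the sum of squared Ewald-sphere offset angles,
#' the latter in units of radians/(2*pi). The angular term constrains the
#' orientation components that leave spot centroids unmoved on a still.
#'
#' @inheritParams positional_target
#' @return Scalar target value.
#' @export
hybrid_target <- function(model, spots, beam, det) {
  check_assigned(spots)
  sc <- spot_calc(model, spots, beam, det)
  sum((spots$x_mm - sc$x_calc)[sc$ok]^2 + (spots$y_mm - sc$y_calc)[sc$ok]^2) +
    sum((sc$delta_psi[sc$ok] / (2 * pi))^2)
}

# --- parameter vector <-> model ---------------------------------------------

# Free parameters: 3 orientation updates (rad, lab axes) plus cell degrees of
# freedom under the constraint. Cell angles are carried in radians here.
param_template <- function(model, constraint) {
  cl <- as.numeric(model$cell)
  if (constraint == "triclinic") {
    c(R_x = 0, R_y = 0, R_z = 0, a = cl[1L], b = cl[2L], c = cl[3L],
      alpha = cl[4L] * pi / 180, beta = cl[5L] * pi / 180,
      gamma = cl[6L] * pi / 180)
  } else {
    c(R_x = 0, R_y = 0, R_z = 0, a = cl[1L], c = cl[3L])
  }
}

model_from_params <- function(p, U0, constraint) {
  R <- rotation_from_vector(p[1:3])
  if (constraint == "triclinic") {
    cell <- unit_cell(p[["a"]], p[["b"]], p[["c"]],
                      p[["alpha"]] * 180 / pi, p[["beta"]] * 180 / pi,
                      p[["gamma"]] * 180 / pi)
    crystal_model(cell, R %*% U0, "triclinic")
  } else {
    cell <- unit_cell(p[["a"]], p[["a"]], p[["c"]], 90, 90, 120)
    crystal_model(cell, R %*% U0, "hexagonal_622")
  }
}

# Residual vector for GN: positional x and y (mm), plus delta-psi/(2*pi) for
# the hybrid target. Flagged spots contribute zeros so the vector keeps a
# fixed length across parameter perturbations.
#
# Still-shot degeneracy structure: the calculated centroids are treated as
# functions of R_z and the cell only -- rotations about the in-plane axes
# move reciprocal-lattice points through the Ewald sphere rather than across
# the detector (their residual positional sensitivity is second order,
# ~sin(theta)), so the positional rows are evaluated with only the R_z
# component of the orientation update applied to the start orientation,
# while the angular-offset rows see the full update. This makes the
# refinement objective a single smooth function of the update parameters in
# which the angular term alone determines R_x and R_y, and the positional
# target alone leaves those angles fixed.
residual_vector <- function(p, U0, constraint, target, spots, beam, det) {
  m_full <- model_from_params(p, U0, constraint)
  p_z <- p; p_z[1:2] <- 0
  m_pos <- model_from_params(p_z, U0, constraint)
  sc <- spot_calc(m_pos, spots, beam, det)
  rx <- spots$x_mm - sc$x_calc
  ry <- spots$y_mm - sc$y_calc
  rx[!sc$ok] <- 0
  ry[!sc$ok] <- 0
  if (target == "hybrid") {
    dp <- dpsi_core(q_from_hkl(m_full, cbind(spots$h, spots$k, spots$l)), beam,
                    light = TRUE)
    rd <- dp$delta_psi / (2 * pi)
    rd[!dp$ok] <- 0
    c(rx, ry, rd)
  } else {
    c(rx, ry)
  }
}

#' Refine a crystal model against observed still-shot spots
#'
#' Damped Gauss-Newton minimisation of the positional or hybrid target over
#' the crystal orientation and the unit-cell degrees of freedom permitted by
#' the constraint: nine parameters for triclinic (three orientation updates,
#' three lengths, three angles), five for `hexagonal_622` (three orientation
#' updates, a and c; angles fixed at 90/90/120). The orientation update is a
#' lab-frame rotation vector composed onto the start orientation, which
#' avoids Euler-angle degeneracies at these small angles.
#'
#' The refinement objective encodes the still-shot degeneracy structure:
#' spot centroids are treated as functions of the beam-axis rotation and the
#' cell only, so the positional residual rows are evaluated with just the
#' R_z component of the orientation update while the angular-offset rows see
#' the full update. Rotations about the in-plane axes move reciprocal-lattice
#' points through the Ewald sphere rather than across the detector (their
#' residual centroid sensitivity is second order, ~sin(theta)), and with the
#' angular offsets weighted in radians/(2*pi) that second-order coupling
#' would otherwise dominate the in-plane angles; under the hybrid target the
#' angular term alone determines R_x and R_y, and under the positional
#' target those angles are structurally fixed. Reported residuals, target
#' values and per-spot tables are always evaluated exactly at the final
#' model.
#'
#' The Jacobian is evaluated by central finite differences and the normal
#' equations are solved through the SVD with mild damping of weak singular
#' values; steps are halved (up to `max_halvings` times) until the objective
#' does not increase, so `target_history` (the objective sequence) is
#' non-increasing.
#'
#' @param spots Assigned spot data frame (`x_mm`, `y_mm`, `h`, `k`, `l`).
#' @param start Starting [crystal_model()].
#' @param beam A [beam()].
#' @param det A [detector()].
#' @param target `"hybrid"` (positional + angular offset) or
#'   `"positional"`.
#' @param constraint `"triclinic"` or `"hexagonal_622"`; defaults to the
#'   start model's symmetry tag.
#' @param max_iter Maximum Gauss-Newton iterations (default 100).
#' @param tol Relative target-decrease convergence threshold (default
#'   1e-10); iteration also stops when the parameter step norm falls below
#'   `1e-8`.
#' @param max_halvings Step-halving budget per iteration (default 10).
#' @return An object of class `still_refinement` with elements `model`
#'   (refined [crystal_model()]), `target`, `constraint`, `value` (final
#'   target), `target_history`, `converged`, `n_iterations`, `per_spot`
#'   (data frame of observed/calculated positions, residuals in mm, signed
#'   delta-psi in radians and resolution), and `start`.
#' @seealso [run_protocol()] for the two-stage triclinic-then-constrained
#'   protocol; methods [coef.still_refinement()],
#'   [residuals.still_refinement()], [predict.still_refinement()].
#' @export
refine_model <- function(spots, start, beam, det,
                         target = c("hybrid", "positional"),
                         constraint = start$symmetry,
                         max_iter = 100L, tol = 1e-10, max_halvings = 10L) {
  target <- match.arg(target)
  check_assigned(spots)
  n_min <- if (constraint == "triclinic") 6L else 4L
  if (nrow(spots) < n_min) {
    stop("need at least ", n_min, " assigned spots for ", constraint,
         " refinement")
  }

  U0 <- start$U
  p <- param_template(start, constraint)
  np <- length(p)
  # finite-difference steps: radians for angles, Angstrom scaled to the cell
  fd <- c(1e-6, 1e-6, 1e-6,
          if (constraint == "triclinic") c(p[4:6] * 1e-6, 1e-6, 1e-6, 1e-6)
          else p[4:5] * 1e-6)

  fval <- function(p) sum(residual_vector(p, U0, constraint, target,
                                          spots, beam, det)^2)
  # The objective freezes the centroids' in-plane orientation at U0 (see
  # residual_vector), so after the inner Gauss-Newton loop settles, the
  # accumulated update is folded into U0 and the loop re-entered until the
  # base orientation itself has converged; each pass is monotone in its own
  # objective and the frozen-base bias shrinks with the remaining update.
  total_it <- 0L
  converged <- FALSE
  singular <- FALSE
  for (phase in 1:8) {
  f0 <- fval(p)
  history <- f0
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    r0 <- residual_vector(p, U0, constraint, target, spots, beam, det)
    J <- matrix(0, length(r0), np)
    for (j in seq_len(np)) {
      pp <- p; pp[j] <- pp[j] + fd[j]
      pm <- p; pm[j] <- pm[j] - fd[j]
      J[, j] <- (residual_vector(pp, U0, constraint, target, spots, beam, det) -
                 residual_vector(pm, U0, constraint, target, spots, beam, det)) /
        (2 * fd[j])
    }
    sv <- svd(J)
    keep <- sv$d > max(sv$d) * 1e-8
    if (!any(keep)) { singular <- TRUE; break }
    # mildly filtered pseudo-inverse: weak directions are damped rather than
    # followed at full length, which suppresses zigzagging along the nearly
    # degenerate cell-angle/orientation combinations
    mu <- max(sv$d) * 1e-6
    dd <- sv$d[keep] / (sv$d[keep]^2 + mu^2)
    step <- -as.numeric(sv$v[, keep, drop = FALSE] %*%
      (crossprod(sv$u[, keep, drop = FALSE], r0) * dd))

    # damped acceptance: halve until the target does not increase
    lam <- 1; accepted <- FALSE; f_best <- Inf
    for (k in 0:max_halvings) {
      p_try <- p + lam * step
      f_try <- tryCatch(fval(p_try), error = function(e) Inf)
      f_best <- min(f_best, f_try)
      if (is.finite(f_try) && f_try <= f0) { accepted <- TRUE; break }
      lam <- lam / 2
    }
    if (!accepted) {
      # damping budget exhausted: a locally flat target (no trial moves it by
      # more than ~1e-6 relative) is a stationary point at numerical
      # resolution; anything else is genuine divergence
      converged <- (f_best - f0) / max(f0, 1e-300) < 1e-6
      break
    }
    rel <- (f0 - f_try) / max(f0, 1e-300)
    p <- p_try
    f0 <- f_try
    history <- c(history, f0)
    if (rel < tol || sqrt(sum((lam * step)^2)) < 1e-8) {
      converged <- TRUE
      break
    }
  }
  total_it <- total_it + it
  if (singular) break
  # rebase: fold the accumulated orientation update into U0
  drot <- sqrt(sum(p[1:3]^2))
  U0 <- nearest_rotation(rotation_from_vector(p[1:3]) %*% U0)
  p[1:3] <- 0
  if (drot < 1e-7) break
  }
  it <- total_it

  final <- model_from_params(p, U0, constraint)
  sc <- spot_calc(final, spots, beam, det)
  value <- sum((spots$x_mm - sc$x_calc)[sc$ok]^2 +
                 (spots$y_mm - sc$y_calc)[sc$ok]^2) +
    if (target == "hybrid") sum((sc$delta_psi[sc$ok] / (2 * pi))^2) else 0
  per_spot <- data.frame(h = spots$h, k = spots$k, l = spots$l,
                         x_obs = spots$x_mm, y_obs = spots$y_mm,
                         x_calc = sc$x_calc, y_calc = sc$y_calc,
                         resid_mm = sqrt((spots$x_mm - sc$x_calc)^2 +
                                           (spots$y_mm - sc$y_calc)^2),
                         delta_psi = sc$delta_psi, d = sc$d, ok = sc$ok)
  structure(list(model = final, target = target, constraint = constraint,
                 value = value, target_history = history,
                 converged = converged, singular = singular,
                 n_iterations = it, per_spot = per_spot, start = start,
                 beam = beam, det = det),
            class = "still_refinement")
}

#' Two-stage refinement protocol
#'
#' Stage 1 refines a triclinic model (all nine parameters) against the
#' chosen target; the refined cell is then projected onto the target Bravais
#' family ([symmetrize_cell()]) and stage 2 re-refines under the symmetry
#' constraint. Choosing the hybrid target for both stages reproduces the
#' best-practice protocol; the positional target in either stage degrades
#' the orientation components that do not move spot centroids.
#'
#' @inheritParams refine_model
#' @param stage1_target,stage2_target `"hybrid"` or `"positional"`;
#'   `stage2_target = "none"` skips the second stage.
#' @param symmetry Bravais family for stage 2 (default `"hexagonal_622"`).
#' @return A `still_refinement` (the stage-2 fit, or stage 1 if skipped)
#'   with an extra element `stages` holding both stage objects.
#' @export
run_protocol <- function(spots, start, beam, det,
                         stage1_target = c("hybrid", "positional"),
                         stage2_target = c("hybrid", "positional", "none"),
                         symmetry = "hexagonal_622", ...) {
  stage1_target <- match.arg(stage1_target)
  stage2_target <- match.arg(stage2_target)
  tri <- crystal_model(start$cell, start$U, "triclinic")
  s1 <- refine_model(spots, tri, beam, det, target = stage1_target,
                     constraint = "triclinic", ...)
  if (s1$singular) stop("stage 1 refinement failed: singular normal matrix")
  if (stage2_target == "none") {
    s1$stages <- list(stage1 = s1)
    return(s1)
  }
  mid <- symmetrize_cell(s1$model, symmetry)
  s2 <- refine_model(spots, mid, beam, det, target = stage2_target,
                     constraint = symmetry, ...)
  s2$stages <- list(stage1 = s1, stage2 = s2)
  s2
}

# --- methods ----------------------------------------------------------------

#' @export
print.still_refinement <- function(x, ...) {
  cat(sprintf("Still refinement (%s target, %s constraint)\n",
              x$target, x$constraint))
  cat(sprintf("  %d spots, %d iterations, target %.6g, %s\n",
              nrow(x$per_spot), x$n_iterations, x$value,
              if (x$converged) "converged" else "NOT converged"))
  print(x$model$cell)
  invisible(x)
}

#' @export
summary.still_refinement <- function(object, ...) {
  ps <- object$per_spot[object$per_spot$ok, ]
  out <- list(target = object$target, constraint = object$constraint,
              value = object$value, converged = object$converged,
              n_iterations = object$n_iterations,
              n_spots = nrow(object$per_spot),
              rms_resid_mm = sqrt(mean(ps$resid_mm^2)),
              rms_delta_psi = sqrt(mean(ps$delta_psi^2)),
              cell = object$model$cell)
  class(out) <- "summary.still_refinement"
  out
}

#' @export
print.summary.still_refinement <- function(x, ...) {
  cat(sprintf("Still refinement: %s target, %s constraint (%s)\n", x$target,
              x$constraint, if (x$converged) "converged" else "not converged"))
  cat(sprintf("  spots %d | iterations %d | target %.6g\n",
              x$n_spots, x$n_iterations, x$value))
  cat(sprintf("  rms positional residual %.4g mm | rms delta-psi %.4g rad\n",
              x$rms_resid_mm, x$rms_delta_psi))
  print(x$cell)
  invisible(x)
}

#' Refined parameters
#' @param object A `still_refinement`.
#' @param ... Unused.
#' @return Named vector: cell parameters (Angstrom / degrees) and the
#'   orientation as a lab-frame rotation vector in degrees.
#' @export
coef.still_refinement <- function(object, ...) {
  cl <- as.numeric(object$model$cell)
  rv <- rotation_vector(object$model$U) * 180 / pi
  c(a = cl[1L], b = cl[2L], c = cl[3L], alpha = cl[4L], beta = cl[5L],
    gamma = cl[6L], R_x = rv[1L], R_y = rv[2L], R_z = rv[3L])
}

#' Per-spot residuals of a refinement
#' @param object A `still_refinement`.
#' @param type `"positional"` for centroid distances (mm) or `"delta_psi"`
#'   for signed Ewald offsets (radians).
#' @param ... Unused.
#' @export
residuals.still_refinement <- function(object,
                                       type = c("positional", "delta_psi"),
                                       ...) {
  type <- match.arg(type)
  if (type == "positional") object$per_spot$resid_mm else
    object$per_spot$delta_psi
}

#' Predict observable spots from a refined model
#'
#' Delegates to [predict_spots()] with the refined crystal model and the
#' stored geometry.
#'
#' @param object A `still_refinement`.
#' @param envelope A [mosaic_envelope()] (e.g. from [fit_mosaic()]).
#' @param d_range Resolution range in Angstrom, low to high (default
#'   `c(15, 3.5)`).
#' @param ... Unused.
#' @return A predicted spot data frame (see [predict_spots()]).
#' @export
predict.still_refinement <- function(object, envelope, d_range = c(15, 3.5),
                                     ...) {
  predict_spots(object$model, object$beam, object$det, envelope,
                d_min = min(d_range), d_max = max(d_range))
}

#' Residual plot of a refinement
#'
#' Plots signed delta-psi residuals against the diffraction angle two-theta,
#' the standard diagnostic from which the mosaic envelope is fitted.
#'
#' @param x A `still_refinement`.
#' @param ... Passed to [plot()].
#' @export
plot.still_refinement <- function(x, ...) {
  ps <- x$per_spot[x$per_spot$ok, ]
  tth <- 2 * asin(x$beam$wavelength / (2 * ps$d)) * 180 / pi
  graphics::plot(tth, ps$delta_psi, xlab = "2*theta (deg)",
                 ylab = expression(Delta * psi ~ "(rad)"),
                 main = "Ewald-sphere offsets", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
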