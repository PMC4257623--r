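# The signed minimal rotation bringing a reciprocal-lattice point onto the
# Ewald sphere. The sphere has radius 1/lambda and is centred at -s0, so a
# point q is in the exact reflecting condition when |q + s0| = 1/lambda. The
# reflecting position r is the intersection, on the same side as q, of the
# sphere |r| = |q| about the origin with the Ewald sphere; the rotation from
# q to r about an axis perpendicular to the plane through the sphere centre,
# the origin and q is the minimal one. Delta-psi is negative when q lies
# outside the Ewald sphere and positive inside.

#' Signed Ewald-sphere offset angle
#'
#' Computes, for each scattering vector, the signed minimal rotation angle
#' about the origin that brings the reciprocal-lattice point onto the Ewald
#' sphere, together with the rotation axis and the resolution. The angle is
#' evaluated from the projections of the reflecting position onto the
#' directions along and perpendicular to q (an arctangent form that keeps the
#' sign and is stable near zero).
#'
#' @param q Numeric 3-vector or n x 3 matrix of reciprocal-space positions
#'   (reciprocal Angstrom), typically from [q_from_hkl()].
#' @param beam A [beam()].
#' @return A data frame with one row per input vector: `delta_psi` (signed
#'   radians), `d` (Angstrom), `e1_x`, `e1_y`, `e1_z` (unit rotation axis)
#'   and `status` (`"ok"`, `"origin"`, `"beyond_limiting_sphere"` or
#'   `"axis_undefined"`; non-ok rows carry NA angle/axis and are excluded
#'   from fits).
#' @examples
#' b <- beam(1)
#' compute_delta_psi(c(0.8660254, 0, 0.5), b)$delta_psi  # on the sphere: 0
#' @export
compute_delta_psi <- function(q, beam) {
  z <- dpsi_core(q, beam)
  data.frame(delta_psi = z$delta_psi, d = z$d,
             e1_x = z$e1[, 1L], e1_y = z$e1[, 2L], e1_z = z$e1[, 3L],
             status = z$status, stringsAsFactors = FALSE)
}

# List-returning core shared by the fitting and prediction hot paths. The
# whole construction is two dimensional in the plane spanned by the
# direction towards the Ewald-sphere centre (chat) and the in-plane unit
# vector along q's component perpendicular to it (nhat): q = (qpar, plen)
# and the reflecting position r = (a, b) in that frame, with the signed
# angle read off by atan2 of the 2-D cross and dot products. `light = TRUE`
# skips the rotation axis and status labels.
dpsi_core <- function(q, beam, light = FALSE) {
  if (is.null(dim(q))) q <- matrix(q, 1L, 3L)
  lam <- beam$wavelength
  chat <- -beam$s0_hat                      # towards the Ewald-sphere centre
  q1 <- q[, 1L]; q2 <- q[, 2L]; q3 <- q[, 3L]
  qq <- q1^2 + q2^2 + q3^2
  qlen <- sqrt(qq)
  qpar <- q1 * chat[1L] + q2 * chat[2L] + q3 * chat[3L]
  plen <- sqrt(pmax(qq - qpar^2, 0))
  ok <- qlen >= 1e-300 & qlen < 2 / lam & plen >= 1e-12 * qlen

  a <- lam * qq / 2                          # reflecting component along chat
  b <- sqrt(pmax(qq - a^2, 0))
  ip <- 1 / ifelse(plen > 0, plen, 1)
  n1 <- (q1 - qpar * chat[1L]) * ip          # nhat columns
  n2 <- (q2 - qpar * chat[2L]) * ip
  n3 <- (q3 - qpar * chat[3L]) * ip
  r <- cbind(a * chat[1L] + n1 * b,
             a * chat[2L] + n2 * b,
             a * chat[3L] + n3 * b)          # reflecting position

  # signed angle from q to r in the (chat, nhat) frame; by construction this
  # is positive when q lies inside the Ewald sphere (a > qpar) and negative
  # outside, matching the stated sign convention
  cross2 <- b * qpar - a * plen
  dot2 <- a * qpar + b * plen
  dpsi <- atan2(cross2, dot2)
  dpsi[!ok] <- NA_real_
  d <- ifelse(qlen > 0, 1 / qlen, Inf)
  if (light) return(list(delta_psi = dpsi, d = d, ok = ok, r = r))

  status <- rep("ok", length(qq))
  status[qlen < 1e-300] <- "origin"
  status[qlen >= 2 / lam] <- "beyond_limiting_sphere"
  status[status == "ok" & plen < 1e-12 * qlen] <- "axis_undefined"
  # axis such that rotating q by dpsi about it (right-hand rule) gives r:
  # the (possibly sign-flipped) unit normal of plane(E, O, Q)
  s <- ifelse(dpsi < 0, -1, 1)
  cr <- cbind(q2 * r[, 3L] - q3 * r[, 2L],
              q3 * r[, 1L] - q1 * r[, 3L],
              q1 * r[, 2L] - q2 * r[, 1L])
  crlen <- sqrt(cr[, 1L]^2 + cr[, 2L]^2 + cr[, 3L]^2)
  onsph <- ok & crlen < 1e-14 * qq
  e1 <- cr * (s / ifelse(crlen > 0, crlen, 1))
  if (any(onsph)) {
    # exactly on-sphere: axis from the plane normal q x chat
    pn <- cbind(q2[onsph] * chat[3L] - q3[onsph] * chat[2L],
                q3[onsph] * chat[1L] - q1[onsph] * chat[3L],
                q1[onsph] * chat[2L] - q2[onsph] * chat[1L])
    e1[onsph, ] <- pn / sqrt(pn[, 1L]^2 + pn[, 2L]^2 + pn[, 3L]^2)
  }
  e1[!ok, ] <- NA_real_
  list(delta_psi = dpsi, d = d, e1 = e1, status = status, ok = ok, r = r)
}

#' Reflecting position of a reciprocal-lattice point
#'
#' Returns the image of q under the minimal delta-psi rotation: the point r
#' with `|r| = |q|` lying exactly on the Ewald sphere
#' (`|r + s0| = 1/lambda`), in the plane spanned by q and the beam.
#'
#' @inheritParams compute_delta_psi
#' @return An n x 3 matrix; rows are NA where the configuration is flagged
#'   degenerate (see [compute_delta_psi()]).
#' @export
reflecting_position <- function(q, beam) {
  z <- dpsi_core(q, beam, light = TRUE)
  r <- z$r
  r[!z$ok, ] <- NA_real_
  r
}

#' Derivatives of delta-psi with respect to model parameters
#'
#' Central finite differences of the signed delta-psi of one or more
#' reflections with respect to a selection of underlying parameters:
#' orientation angles about the laboratory axes (`"R_x"`, `"R_y"`, `"R_z"`),
#' cell parameters under the model's symmetry constraint (`"a"`, `"b"`,
#' `"c"`, `"alpha"`, `"beta"`, `"gamma"`; for `hexagonal_622` only `"a"` and
#' `"c"` are free), and the wavelength `"lambda"`.
#'
#' @param model A [crystal_model()].
#' @param hkl Integer 3-vector or n x 3 matrix of Miller indices.
#' @param beam A [beam()].
#' @param params Character vector of parameter names (default: the three
#'   orientation angles).
#' @param step Finite-difference step in natural units (radians, Angstrom),
#'   default `1e-6`.
#' @return An n x length(params) matrix of partial derivatives (radians per
#'   natural unit); NA rows for reflections flagged degenerate.
#' @export
delta_psi_gradient <- function(model, hkl, beam,
                               params = c("R_x", "R_y", "R_z"), step = 1e-6) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, 1L, 3L)
  free_cell <- if (model$symmetry == "hexagonal_622") c("a", "c") else
    c("a", "b", "c", "alpha", "beta", "gamma")
  allowed <- c("R_x", "R_y", "R_z", free_cell, "lambda")
  if (!all(params %in% allowed)) {
    stop("parameters not in the active constraint set: ",
         paste(setdiff(params, allowed), collapse = ", "))
  }
  eval_dpsi <- function(p, delta) {
    m <- model; bm <- beam
    if (p %in% c("R_x", "R_y", "R_z")) {
      axis <- diag(3L)[, match(p, c("R_x", "R_y", "R_z"))]
      m <- crystal_model(model$cell, rotation_about_axis(axis, delta) %*% model$U,
                         model$symmetry)
    } else if (p == "lambda") {
      bm <- beam(beam$wavelength + delta, beam$s0_hat)
    } else {
      cl <- as.numeric(model$cell)
      names(cl) <- c("a", "b", "c", "alpha", "beta", "gamma")
      if (p %in% c("alpha", "beta", "gamma")) {
        cl[p] <- cl[p] + delta * 180 / pi      # step given in radians
      } else {
        cl[p] <- cl[p] + delta
        if (model$symmetry == "hexagonal_622" && p == "a") cl["b"] <- cl["a"]
      }
      m <- crystal_model(do.call(unit_cell, as.list(cl)), model$U, model$symmetry)
    }
    compute_delta_psi(q_from_hkl(m, hkl), bm)$delta_psi
  }
  out <- sapply(params, function(p) {
    (eval_dpsi(p, step) - eval_dpsi(p, -step)) / (2 * step)
  })
  matrix(out, nrow(hkl), length(params), dimnames = list(NULL, params))
}
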