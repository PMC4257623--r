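# Reflection enumeration, observable-spot prediction and model/data
# agreement scoring in equal-volume resolution shells.

#' Enumerate reflections near the Ewald sphere
#'
#' Lists every Miller index whose resolution lies in `[d_min, d_max]` and
#' whose Ewald-sphere offset magnitude does not exceed a coarse bound. The
#' index search box is derived from the cell (|h| <= a/d_min and cyclically,
#' a rigorous bound since h = q . a), so no qualifying reflection is missed.
#'
#' @param model A [crystal_model()].
#' @param beam A [beam()].
#' @param d_min,d_max Resolution limits in Angstrom, `d_min < d_max`.
#' @param envelope Optional [mosaic_envelope()]; when given, the coarse
#'   bound is `coarse_factor * envelope_halfwidth(envelope, d)`.
#' @param coarse_factor Multiplier on the envelope half-width (default 5).
#' @param delta_psi_max Explicit coarse bound in radians (overrides
#'   `envelope`); default `Inf` keeps every in-range reflection.
#' @return Data frame with columns `h`, `k`, `l`, `d` and `delta_psi`.
#' @export
enumerate_reflections <- function(model, beam, d_min, d_max, envelope = NULL,
                                  coarse_factor = 5, delta_psi_max = Inf) {
  if (d_min >= d_max) stop("d_min must be smaller than d_max")
  cl <- as.numeric(model$cell)
  hmax <- ceiling(cl[1:3] / d_min)
  nh <- 2L * hmax + 1L
  H <- cbind(rep(seq.int(-hmax[1L], hmax[1L]), times = nh[2L] * nh[3L]),
             rep(rep(seq.int(-hmax[2L], hmax[2L]), each = nh[1L]),
                 times = nh[3L]),
             rep(seq.int(-hmax[3L], hmax[3L]), each = nh[1L] * nh[2L]))
  q <- H %*% t(model$A)
  inv_d <- sqrt(q[, 1L]^2 + q[, 2L]^2 + q[, 3L]^2)
  keep <- inv_d >= 1 / d_max & inv_d <= 1 / d_min
  H <- H[keep, , drop = FALSE]
  q <- q[keep, , drop = FALSE]
  inv_d <- inv_d[keep]
  bound0 <- if (!is.null(envelope)) {
    coarse_factor * envelope_halfwidth(envelope, 1 / inv_d)
  } else {
    delta_psi_max
  }
  if (any(is.finite(bound0))) {
    # cheap exact superset: the arc length |q| * |delta_psi| is at least the
    # radial distance from the Ewald sphere, so |delta_psi| >= |e| * d
    cen <- -beam$s0
    e <- abs(sqrt((q[, 1L] - cen[1L])^2 + (q[, 2L] - cen[2L])^2 +
                    (q[, 3L] - cen[3L])^2) - 1 / beam$wavelength)
    pre <- e / inv_d <= bound0
    H <- H[pre, , drop = FALSE]
    q <- q[pre, , drop = FALSE]
  }
  dp <- dpsi_core(q, beam, light = TRUE)
  bound <- if (!is.null(envelope)) {
    coarse_factor * envelope_halfwidth(envelope, dp$d)
  } else {
    delta_psi_max
  }
  keep2 <- dp$ok & abs(dp$delta_psi) <= bound
  data.frame(h = H[keep2, 1L], k = H[keep2, 2L], l = H[keep2, 3L],
             d = dp$d[keep2], delta_psi = dp$delta_psi[keep2],
             row.names = NULL)
}

#' Predict the observable spot set
#'
#' A reflection is predicted observable when its Ewald offset satisfies
#' `|delta_psi| <= envelope_halfwidth(envelope, d)`. Each accepted
#' reflection is placed at the detector projection of its reflecting
#' position (the on-sphere point about which the partial reflection is
#' centred); predictions falling off the panel are dropped and counted.
#'
#' @param model A [crystal_model()].
#' @param beam A [beam()].
#' @param det A [detector()].
#' @param envelope A [mosaic_envelope()].
#' @param d_min,d_max Resolution limits in Angstrom.
#' @return Data frame with columns `h`, `k`, `l`, `d`, `delta_psi`, `x_mm`,
#'   `y_mm` and attribute `n_off_detector`.
#' @export
predict_spots <- function(model, beam, det, envelope, d_min, d_max) {
  refl <- enumerate_reflections(model, beam, d_min, d_max,
                                envelope = envelope, coarse_factor = 1)
  if (nrow(refl) == 0L) {
    out <- cbind(refl, x_mm = numeric(0), y_mm = numeric(0))
    attr(out, "n_off_detector") <- 0L
    return(out)
  }
  q <- q_from_hkl(model, as.matrix(refl[, c("h", "k", "l")]))
  r <- reflecting_position(q, beam)
  pr <- project_to_detector(sweep(r, 2L, beam$s0, "+"), beam, det)
  ok <- pr$hits & on_detector(pr, det)
  out <- cbind(refl[ok, , drop = FALSE],
               x_mm = pr$x_mm[ok], y_mm = pr$y_mm[ok])
  rownames(out) <- NULL
  attr(out, "n_off_detector") <- sum(!ok)
  out
}

#' Equal-volume resolution shell boundaries
#'
#' Partitions `[d_min, d_max]` into `n_shells` shells of equal
#' reciprocal-space volume, i.e. equal increments of 1/d^3.
#'
#' @param d_range Resolution range (Angstrom), any order.
#' @param n_shells Number of shells.
#' @return Numeric vector of `n_shells + 1` descending d boundaries.
#' @export
resolution_shells <- function(d_range = c(15, 3.5), n_shells = 10L) {
  lo <- max(d_range); hi <- min(d_range)
  (seq(lo^-3, hi^-3, length.out = n_shells + 1L))^(-1 / 3)
}

#' Score predicted against reference reflections
#'
#' Compares two indexed reflection sets by Miller index: the
#' false-prediction fraction is the share of predicted reflections absent
#' from the reference, and the unmodeled fraction the share of reference
#' reflections absent from the prediction. Both are reported per
#' equal-volume resolution shell and overall.
#'
#' @param predicted,reference Data frames with columns `h`, `k`, `l` and `d`
#'   (or `d_angstrom`), indexed on the same lattice convention.
#' @param d_range Resolution range (Angstrom) for the shells.
#' @param n_shells Number of equal-volume shells (default 10).
#' @return An object of class `prediction_report`: a list with `shells`
#'   (per-shell data frame) and `totals` (overall counts and fractions; the
#'   false fraction is NA when nothing is predicted).
#' @export
score_prediction <- function(predicted, reference, d_range = c(15, 3.5),
                             n_shells = 10L) {
  key <- function(df) paste(df$h, df$k, df$l)
  dcol <- function(df) if (!is.null(df$d)) df$d else df$d_angstrom
  predicted$d <- dcol(predicted); reference$d <- dcol(reference)
  pk <- key(predicted); rk <- key(reference)
  bounds <- resolution_shells(d_range, n_shells)
  shell_of <- function(d) {
    pmin(pmax(findInterval(-d, -bounds, rightmost.closed = TRUE), 1L), n_shells)
  }
  ps <- shell_of(predicted$d); rs <- shell_of(reference$d)
  false_p <- !(pk %in% rk)
  unmod <- !(rk %in% pk)
  shells <- data.frame(
    d_high = bounds[-length(bounds)], d_low = bounds[-1L],
    n_predicted = tabulate(ps, n_shells),
    n_false = tabulate(ps[false_p], n_shells),
    n_reference = tabulate(rs, n_shells),
    n_unmodeled = tabulate(rs[unmod], n_shells))
  shells$false_fraction <- ifelse(shells$n_predicted > 0,
                                  shells$n_false / shells$n_predicted, NA_real_)
  shells$unmodeled_fraction <- ifelse(shells$n_reference > 0,
                                      shells$n_unmodeled / shells$n_reference,
                                      NA_real_)
  totals <- list(
    n_predicted = nrow(predicted), n_false = sum(false_p),
    n_reference = nrow(reference), n_unmodeled = sum(unmod),
    false_fraction = if (nrow(predicted) > 0)
      sum(false_p) / nrow(predicted) else NA_real_,
    unmodeled_fraction = if (nrow(reference) > 0)
      sum(unmod) / nrow(reference) else NA_real_)
  structure(list(shells = shells, totals = totals, d_range = d_range),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("Prediction score over %.4g-%.4g A (%d shells)\n",
              max(x$d_range), min(x$d_range), nrow(x$shells)))
  cat(sprintf("  predicted %d (false %.1f%%), reference %d (unmodeled %.1f%%)\n",
              x$totals$n_predicted, 100 * x$totals$false_fraction,
              x$totals$n_reference, 100 * x$totals$unmodeled_fraction))
  print(format(x$shells, digits = 3), row.names = FALSE)
  invisible(x)
}
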