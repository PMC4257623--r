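# Independent oracles used to check the package's geometry and estimators.
# These deliberately avoid the implementation paths they verify.

# Rodrigues rotation, written out directly.
o_rotate <- function(v, axis, ang) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(ang) + c(axis[2] * v[3] - axis[3] * v[2],
                   axis[3] * v[1] - axis[1] * v[3],
                   axis[1] * v[2] - axis[2] * v[1]) * sin(ang) +
    axis * sum(axis * v) * (1 - cos(ang))
}

# Rotation-scan oracle for the Ewald offset angle: scans rotations of q
# about the given axis for the sign change of |q_rot + s0| - 1/lambda
# closest to zero rotation, then polishes the root by bisection.
o_delta_psi_scan <- function(q, axis, bm) {
  miss <- function(psi) {
    sqrt(sum((o_rotate(q, axis, psi) + bm$s0)^2)) - 1 / bm$wavelength
  }
  g <- seq(-pi, pi, length.out = 4001)
  v <- vapply(g, miss, 0)
  cross <- which(v[-1L] * v[-length(v)] <= 0)
  mid <- (g[cross] + g[cross + 1L]) / 2
  i <- cross[order(abs(mid))][1L]
  stats::uniroot(miss, c(g[i], g[i + 1L]), tol = 1e-14)$root
}

# Brute-force reflection enumeration over the full index box, scalar loops.
o_enumerate <- function(A, bm, d_min, d_max, hmax) {
  out <- NULL
  for (h in -hmax:hmax) for (k in -hmax:hmax) for (l in -hmax:hmax) {
    q <- A %*% c(h, k, l)
    n <- sqrt(sum(q^2))
    if (n > 0 && 1 / n >= d_min && 1 / n <= d_max) {
      out <- rbind(out, c(h, k, l))
    }
  }
  out
}

# Grid-search minimiser of the binned straight-line objective
# sum_b (y_b - (c0 + c1 x_b))^2 over a (c0, c1) grid.
o_grid_line_fit <- function(x, y, c0_range, c1_range, n = 201) {
  c0g <- seq(c0_range[1], c0_range[2], length.out = n)
  c1g <- seq(c1_range[1], c1_range[2], length.out = n)
  best <- c(NA, NA); bv <- Inf
  for (c0 in c0g) {
    r <- vapply(c1g, function(c1) sum((y - c0 - c1 * x)^2), 0)
    i <- which.min(r)
    if (r[i] < bv) { bv <- r[i]; best <- c(c0, c1g[i]) }
  }
  best
}

# Sorted contiguous 25-per-bin reduction, written independently.
o_bin_maxima <- function(dpsi, d, size = 25L) {
  o <- order(d)
  dpsi <- abs(dpsi[o]); d <- d[o]
  nb <- length(d) %/% size
  x <- y <- numeric(nb)
  for (b in seq_len(nb)) {
    idx <- if (b < nb) ((b - 1L) * size + 1L):(b * size) else
      ((b - 1L) * size + 1L):length(d)
    x[b] <- mean(d[idx]); y[b] <- max(dpsi[idx])
  }
  list(x = x, y = y)
}
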