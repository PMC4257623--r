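test_that("envelope half-width follows eta/2 + d/D_eff", {
  expect_equal(envelope_halfwidth(
    mosaic_envelope(0.002 * 180 / pi, 5000), 5), 0.002, tolerance = 1e-12)
  env <- mosaic_envelope(0.1, 4000)
  expect_equal(envelope_halfwidth(env, 1e-9), 0.05 * pi / 180,
               tolerance = 1e-8)
  expect_equal(envelope_halfwidth(mosaic_envelope(0, 4850), 3.5), 3.5 / 4850,
               tolerance = 1e-12)
  expect_error(mosaic_envelope(-0.1, 100), "non-negative")
  expect_error(mosaic_envelope(0.1, 0), "positive")
})

test_that("binned least squares recovers an exact envelope line", {
  # 25 records per resolution, one touching the envelope exactly, so each
  # bin point (mean d, max |dpsi|) lies on the line eta/2 + d/D
  c0 <- 5e-4; c1 <- 2e-4
  d_levels <- c(9, 7, 5, 4, 3)
  rec <- do.call(rbind, lapply(d_levels, function(d) {
    w <- c0 + c1 * d
    data.frame(delta_psi_rad = c(w, seq(-0.9, 0.9, length.out = 24) * w),
               d_angstrom = rep(d, 25))
  }))
  fit <- fit_mosaic(rec, method = "ls")
  expect_equal(fit$envelope$eta / 2, c0, tolerance = 1e-12)
  expect_equal(1 / fit$envelope$d_eff, c1, tolerance = 1e-12)

  # degenerate: all offsets zero
  z <- fit_mosaic(data.frame(delta_psi_rad = numeric(60),
                             d_angstrom = runif(60, 2, 10)), method = "ls")
  expect_equal(z$envelope$eta, 0)
  expect_identical(z$envelope$d_eff, Inf)

  expect_error(fit_mosaic(rec[1:40, ], method = "ls"), "insufficient")
})

test_that("analytic least squares matches a grid-search minimiser", {
  env <- mosaic_envelope(0.06, 3000)
  rec <- simulate_envelope_records(2000, env, d_range = c(12, 2.5), seed = 81)
  fit <- fit_mosaic(rec, method = "ls")
  bins <- o_bin_maxima(rec$delta_psi_rad, rec$d_angstrom)
  grid <- o_grid_line_fit(bins$x, bins$y,
                          c0_range = c(0, 2e-3), c1_range = c(0, 1e-3),
                          n = 401)
  # agreement within one grid cell of the search
  expect_lt(abs(fit$envelope$eta / 2 - grid[1L]), 2e-3 / 400)
  expect_lt(abs(1 / fit$envelope$d_eff - grid[2L]), 1e-3 / 400)
})

test_that("maximum likelihood recovers envelope parameters within 10%", {
  env <- mosaic_envelope(0.05, 4000)
  rec <- simulate_envelope_records(3000, env, d_range = c(15, 3.5), seed = 82)
  fit <- fit_mosaic(rec, method = "ml")
  expect_true(fit$converged)
  expect_lt(abs(fit$envelope$eta - env$eta) / env$eta, 0.1)
  expect_lt(abs(fit$envelope$d_eff - env$d_eff) / env$d_eff, 0.1)

  # degenerate: all offsets zero collapses the envelope
  z <- fit_mosaic(data.frame(delta_psi_rad = numeric(100),
                             d_angstrom = runif(100, 2, 12)), method = "ml")
  expect_lt(z$envelope$eta, 1e-4)
  expect_gt(z$envelope$d_eff, 1e5)
})

test_that("the ML mosaicity does not exceed the LS mosaicity", {
  # measured offsets carry the angular scatter of centroiding error
  # (~0.03 mm at 129 mm, i.e. ~2.3e-4 rad), whose tail inflates the
  # bin-maxima line more than the likelihood optimum
  env <- mosaic_envelope(0.05, 4000)
  for (seed in 83:87) {
    rec <- simulate_envelope_records(3000, env, noise_sd_rad = 2.3e-4,
                                     seed = seed)
    eta_ml <- fit_mosaic(rec, method = "ml")$envelope$eta
    eta_ls <- fit_mosaic(rec, method = "ls")$envelope$eta
    expect_lte(eta_ml, eta_ls + 1e-12)
  }
})

test_that("the smoothed top-hat preserves probability mass within 1%", {
  # integral of the epsilon = 10 sigmoid product over the normalised offset
  # u, against the hard top-hat mass of 2
  S <- function(u, eps = 10) plogis(eps * (u + 1)) * plogis(eps * (1 - u))
  mass <- integrate(S, -Inf, Inf, rel.tol = 1e-10)$value
  expect_lt(abs(mass - 2) / 2, 0.01)
  # and it is everywhere differentiable, with height ~1 inside
  expect_gt(S(0), 0.999)
})

test_that("the ML objective has an interior, axis-unimodal maximum", {
  env <- mosaic_envelope(0.05, 4000)
  rec <- simulate_envelope_records(1200, env, seed = 88)
  ll <- function(c0, c1) stillframe:::tophat_loglik(c0, c1, rec$delta_psi_rad,
                                                    rec$d_angstrom, 10)
  c0_hat <- env$eta / 2; c1_hat <- 1 / env$d_eff
  # shrink-to-zero and grow-without-bound both lose
  expect_lt(ll(c0_hat * 0.05, c1_hat * 0.05), ll(c0_hat, c1_hat))
  expect_lt(ll(c0_hat * 20, c1_hat * 20), ll(c0_hat, c1_hat))
  # single sign change of the discrete derivative along each axis
  for (ax in 1:2) {
    g <- exp(seq(log(0.1), log(10), length.out = 60))
    v <- if (ax == 1) vapply(g, function(s) ll(c0_hat * s, c1_hat), 0)
    else vapply(g, function(s) ll(c0_hat, c1_hat * s), 0)
    expect_equal(sum(diff(sign(diff(v))) != 0), 1L)
  }
})

test_that("ML soft containment covers at least 95% of records", {
  env <- mosaic_envelope(0.05, 4000)
  rec <- simulate_envelope_records(2000, env, seed = 89)
  fit <- fit_mosaic(rec, method = "ml")
  w <- envelope_halfwidth(fit$envelope, rec$d_angstrom)
  expect_gte(mean(abs(rec$delta_psi_rad) <= 1.1 * w), 0.95)
})

test_that("the ML estimator has no larger variance than least squares", {
  env <- mosaic_envelope(0.05, 4000)
  eta_ml <- eta_ls <- numeric(50)
  for (i in 1:50) {
    rec <- simulate_envelope_records(600, env, seed = 900 + i)
    eta_ml[i] <- fit_mosaic(rec, method = "ml")$envelope$eta
    eta_ls[i] <- fit_mosaic(rec, method = "ls")$envelope$eta
  }
  expect_lte(var(eta_ml), var(eta_ls))
})

test_that("mosaic fit methods expose coefficients and envelope predictions", {
  env <- mosaic_envelope(0.05, 4000)
  rec <- simulate_envelope_records(600, env, seed = 91)
  fit <- fit_mosaic(rec, method = "ml")
  cf <- coef(fit)
  expect_equal(cf[["eta_halfwidth_deg"]], cf[["eta_fullwidth_deg"]] / 2)
  expect_equal(unname(predict(fit, d = 4)),
               envelope_halfwidth(fit$envelope, 4))
  expect_output(print(fit), "Mosaic envelope fit")
  expect_output(print(summary(fit)), "coverage")
})
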