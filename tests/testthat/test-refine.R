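test_that("targets vanish for a perfect model and follow unit-convention arithmetic", {
  sc <- toy_scene(seed = 3)          # noise-free
  expect_lt(positional_target(sc$model, sc$spots, sc$beam, sc$det), 1e-16)

  # one spot offset by 0.1 mm adds exactly 0.01 mm^2
  shifted <- sc$spots
  shifted$x_mm[1L] <- shifted$x_mm[1L] + 0.1
  expect_equal(positional_target(sc$model, shifted, sc$beam, sc$det), 0.01,
               tolerance = 1e-10)

  # hybrid adds (delta_psi / 2pi)^2: construct a single spot whose model
  # offset is pi/10 radians and whose centroid matches the observation
  one <- sc$spots[which.max(abs(sc$spots$delta_psi_rad)), , drop = FALSE]
  expect_equal(hybrid_target(sc$model, one, sc$beam, sc$det),
               (one$delta_psi_rad / (2 * pi))^2, tolerance = 1e-12)
  # unit convention: delta_psi = pi/10 contributes (0.05)^2 = 0.0025
  expect_equal((pi / 10 / (2 * pi))^2, 0.0025)
  # additivity: 0.1 mm positional + pi/10 angular -> 0.0125
  expect_equal(0.1^2 + (pi / 10 / (2 * pi))^2, 0.0125)

  # per-term oracle: target equals an independent per-spot recomputation
  pert <- perturb_model(sc$model, c(0.05, -0.03, 0.08), 1e-4)
  manual <- 0
  for (i in seq_len(nrow(sc$spots))) {
    q <- as.numeric(pert$A %*% c(sc$spots$h[i], sc$spots$k[i], sc$spots$l[i]))
    r <- as.numeric(reflecting_position(q, sc$beam))
    s1 <- r + sc$beam$s0
    x <- -sc$det$distance * s1[1L] / s1[3L]
    y <- -sc$det$distance * s1[2L] / s1[3L]
    manual <- manual + (sc$spots$x_mm[i] - x)^2 + (sc$spots$y_mm[i] - y)^2
  }
  expect_equal(positional_target(pert, sc$spots, sc$beam, sc$det), manual,
               tolerance = 1e-10)

  unassigned <- sc$spots
  unassigned$h[2L] <- NA
  expect_error(positional_target(sc$model, unassigned, sc$beam, sc$det),
               "index-assigned")
})

test_that("refinement from the truth is an immediate stationary point", {
  sc <- toy_scene(seed = 3)
  # positional target: the truth reproduces every centroid exactly
  fit <- refine_model(sc$spots, sc$model, sc$beam, sc$det, "positional",
                      "hexagonal_622")
  expect_true(fit$converged)
  expect_lte(fit$n_iterations, 2L)
  expect_lt(misorientation_angle(fit$model, sc$model)$angle, 1e-8)
  expect_equal(as.numeric(fit$model$cell), as.numeric(sc$model$cell),
               tolerance = 1e-10)
  # hybrid target: the finite-sample optimum shifts within the envelope
  # scale, since in-envelope offsets are nonzero even for a perfect model
  fit2 <- refine_model(sc$spots, sc$model, sc$beam, sc$det, "hybrid",
                       "hexagonal_622")
  env_deg <- envelope_halfwidth(sc$envelope, 2) * 180 / pi
  expect_lt(misorientation_angle(fit2$model, sc$model)$angle, env_deg)
})

test_that("two-stage hybrid refinement recovers a perturbed orientation", {
  sc <- toy_scene(seed = 8, noise_sigma_mm = 0.02)
  start <- perturb_model(sc$model, c(0.2, -0.15, 0.1), 0.002)
  fit <- run_protocol(sc$spots, start, sc$beam, sc$det, "hybrid", "hybrid")
  mis <- misorientation_angle(fit$model, sc$model)
  expect_lt(mis$angle, 0.08)
  expect_lt(abs(coef(fit)[["a"]] - 40) / 40, 1e-3)
  # per-spot residuals recomputable from the final model
  again <- stillframe:::spot_calc(fit$model, sc$spots, sc$beam, sc$det)
  expect_equal(fit$per_spot$delta_psi, again$delta_psi, tolerance = 1e-10)
  expect_equal(fit$per_spot$x_calc, again$x_calc, tolerance = 1e-10)
})

test_that("positional-only refinement cannot fix the in-plane angles", {
  sc <- toy_scene(seed = 8, noise_sigma_mm = 0.02)
  start <- perturb_model(sc$model, c(0.2, -0.15, 0.1), 0.002)
  f22 <- run_protocol(sc$spots, start, sc$beam, sc$det, "hybrid", "hybrid")
  f11 <- run_protocol(sc$spots, start, sc$beam, sc$det, "positional",
                      "positional")
  m22 <- misorientation_angle(f22$model, sc$model)
  m11 <- misorientation_angle(f11$model, sc$model)
  expect_gte(m11$angle, 5 * m22$angle)
  # the eq1 error is dominated by the in-plane components
  expect_gt(sqrt(m11$components[["R_x"]]^2 + m11$components[["R_y"]]^2),
            5 * abs(m11$components[["R_z"]]))
})

test_that("accepted Gauss-Newton steps never increase the objective", {
  for (seed in c(8, 13)) {
    sc <- toy_scene(seed = seed, noise_sigma_mm = 0.02)
    start <- random_start(sc$model, seed = seed + 100)
    fit <- refine_model(sc$spots,
                        crystal_model(start$cell, start$U, "triclinic"),
                        sc$beam, sc$det, "hybrid", "triclinic")
    expect_true(all(diff(fit$target_history) <= 1e-12))
  }
})

test_that("cell symmetrisation projects onto the hexagonal family", {
  tri <- crystal_model(unit_cell(40.02, 39.98, 30.01, 90.02, 89.99, 120.02))
  hexed <- symmetrize_cell(tri, "hexagonal_622")
  expect_equal(as.numeric(hexed$cell),
               c(40, 40, 30.01, 90, 90, 120), tolerance = 1e-9)
  expect_equal(hexed$U, tri$U)
})

test_that("insufficient or degenerate input is rejected with diagnostics", {
  sc <- toy_scene(seed = 3)
  few <- sc$spots[1:4, ]
  expect_error(refine_model(few, crystal_model(sc$model$cell, sc$model$U,
                                               "triclinic"),
                            sc$beam, sc$det, "hybrid", "triclinic"),
               "at least 6")
  # all-origin indices give an all-zero Jacobian: protocol aborts at stage 1
  zero <- sc$spots[1:8, ]
  zero$h <- zero$k <- zero$l <- 0
  expect_error(run_protocol(zero, sc$model, sc$beam, sc$det,
                            "hybrid", "hybrid"),
               "stage 1")
})

test_that("positional curvature is an order of magnitude weaker along the in-plane axes", {
  sc <- toy_scene(seed = 3)            # noise-free, at the true solution
  h <- 2e-4
  curv <- function(target_fun, axis) {
    ax <- diag(3L)[, axis]
    f <- function(delta) {
      m <- crystal_model(sc$model$cell,
                         rotation_about_axis(ax, delta) %*% sc$model$U,
                         sc$model$symmetry)
      target_fun(m, sc$spots, sc$beam, sc$det)
    }
    (f(h) - 2 * f(0) + f(-h)) / h^2
  }
  c1 <- vapply(1:3, function(a) curv(positional_target, a), 0)
  expect_gt(c1[3L], 10 * c1[1L])
  expect_gt(c1[3L], 10 * c1[2L])
})
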