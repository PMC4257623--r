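test_that("orientation matrix reproduces reference reciprocal geometries", {
  m <- crystal_model(unit_cell(100, 100, 100))
  expect_equal(m$A, diag(0.01, 3L), tolerance = 1e-12)

  psi <- crystal_model(unit_cell(281, 281, 165.2, 90, 90, 120))
  astar <- sqrt(sum(psi$A[, 1L]^2))
  bstar <- sqrt(sum(psi$A[, 2L]^2))
  expect_equal(astar, 1 / (281 * sin(2 * pi / 3)), tolerance = 1e-12)
  expect_equal(bstar, astar, tolerance = 1e-12)
  expect_equal(sqrt(sum(psi$A[, 3L]^2)), 1 / 165.2, tolerance = 1e-12)
})

test_that("cell parameters round-trip through the orientation matrix", {
  set.seed(11)
  for (i in 1:20) {
    cell <- unit_cell(runif(1, 20, 300), runif(1, 20, 300), runif(1, 20, 300),
                      runif(1, 60, 120), runif(1, 60, 120), runif(1, 60, 120))
    R <- random_orientation()
    m <- crystal_model(cell, R)
    back <- cell_from_matrix(m$A)
    expect_equal(as.numeric(back), as.numeric(cell), tolerance = 1e-8)
  }
})

test_that("degenerate cells and invalid geometry objects are rejected", {
  expect_error(unit_cell(-10, 10, 10), "positive")
  expect_error(unit_cell(10, 10, 10, 0, 90, 90), "angles")
  # angle triple violating the metric positivity condition
  expect_error(unit_cell(10, 10, 10, 150, 60, 60), "degenerate")
  expect_error(beam(0), "positive")
  expect_error(beam(1, c(1, 1, 0)), "unit vector")
  expect_error(detector(-5, 0.1, 10, 10), "positive")
  expect_error(crystal_model(unit_cell(10, 10, 10), diag(c(1, 1, -1))),
               "rotation")
})

test_that("q_from_hkl matches elementwise column combination", {
  m <- crystal_model(unit_cell(100, 100, 100))
  expect_equal(as.numeric(q_from_hkl(m, c(1, 2, 3))), c(0.01, 0.02, 0.03))
  expect_equal(1 / sqrt(sum(q_from_hkl(m, c(1, 2, 3))^2)), 26.7261,
               tolerance = 1e-4)
  expect_equal(as.numeric(q_from_hkl(m, c(0, 0, 0))), c(0, 0, 0))

  set.seed(4)
  mr <- crystal_model(unit_cell(35, 47, 61, 80, 95, 104), random_orientation())
  for (i in 1:10) {
    h <- sample(-8:8, 3, replace = TRUE)
    manual <- mr$A[, 1L] * h[1L] + mr$A[, 2L] * h[2L] + mr$A[, 3L] * h[3L]
    expect_equal(as.numeric(q_from_hkl(mr, h)), manual, tolerance = 1e-14)
  }
})

test_that("resolution scales inversely with uniform cell scaling", {
  base <- crystal_model(unit_cell(40, 50, 60, 85, 95, 100))
  scaled <- crystal_model(unit_cell(80, 100, 120, 85, 95, 100))
  h <- c(3, -2, 5)
  d1 <- 1 / sqrt(sum(q_from_hkl(base, h)^2))
  d2 <- 1 / sqrt(sum(q_from_hkl(scaled, h)^2))
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("detector projection reproduces reference rays and inverts exactly", {
  bm <- beam(1.32)
  det <- detector(129, 0.11, 1765L, 1765L)
  expect_equal(as.numeric(project_to_detector(c(0, 0, -1), bm, det)[1:2]),
               c(0, 0))
  expect_equal(as.numeric(project_to_detector(c(1, 0, -1), bm, det)[1:2]),
               c(129, 0))
  expect_false(project_to_detector(c(0.1, 0, 0.5), bm, det)$hits)

  # round trip project . backproject on random on-sphere points
  set.seed(21)
  for (i in 1:200) {
    u <- runit3()
    if (u[3L] >= -0.3) u[3L] <- -abs(u[3L]) - 0.3
    u <- u / sqrt(sum(u^2))
    s1 <- u / bm$wavelength
    q <- s1 - bm$s0
    xy <- project_to_detector(matrix(s1, 1L), bm, det)
    q2 <- backproject_to_q(c(xy$x_mm, xy$y_mm), bm, det)
    expect_lt(max(abs(q2 - q)), 1e-9)
  }
})

test_that("backprojected spots land exactly on the Ewald sphere", {
  bm <- beam(0.98)
  det <- detector(100, 0.1, 2000L, 2000L)
  set.seed(31)
  xy <- cbind(runif(1000, -80, 80), runif(1000, -80, 80))
  q <- backproject_to_q(xy, bm, det)
  on_sphere <- sqrt(rowSums(sweep(q, 2L, bm$s0, "+")^2))
  expect_lt(max(abs(on_sphere - 1 / bm$wavelength)), 1e-12)
  expect_equal(as.numeric(backproject_to_q(c(0, 0), bm, det)), c(0, 0, 0),
               tolerance = 1e-15)
})

test_that("hexagonal 622 point-group rotations map the lattice onto itself", {
  B <- reciprocal_basis(unit_cell(281, 281, 165.2, 90, 90, 120))
  for (S in stillframe:::point_group_rotations("hexagonal_622")) {
    M <- solve(B) %*% S %*% B
    expect_lt(max(abs(M - round(M))), 1e-8)
  }
  expect_length(stillframe:::point_group_rotations("hexagonal_622"), 12L)
  expect_error(stillframe:::point_group_rotations("cubic"), "unknown")
})

test_that("misorientation is symmetry-reduced and behaves as a pseudometric", {
  cell <- unit_cell(281, 281, 165.2, 90, 90, 120)
  set.seed(41)
  U <- random_orientation()
  truth <- crystal_model(cell, U, "hexagonal_622")
  expect_equal(misorientation_angle(truth, truth)$angle, 0, tolerance = 1e-9)

  # a sixfold rotation about the hexagonal c axis is a symmetry identity
  S <- rotation_about_axis(U %*% c(0, 0, 1), pi / 3)
  equiv <- crystal_model(cell, S %*% U, "hexagonal_622")
  expect_lt(misorientation_angle(equiv, truth)$angle, 1e-9)
  # ... but not under the triclinic group
  expect_gt(misorientation_angle(equiv, truth, symmetry = "triclinic")$angle,
            59)

  rot <- crystal_model(cell, rotation_about_axis(c(1, 0, 0), 0.1 * pi / 180)
                       %*% U, "hexagonal_622")
  mis <- misorientation_angle(rot, truth)
  expect_equal(mis$angle, 0.1, tolerance = 1e-9)
  expect_equal(unname(mis$components[["R_x"]]), 0.1, tolerance = 1e-9)

  # pseudometric: symmetry and triangle inequality on sampled triples
  for (i in 1:5) {
    a <- crystal_model(cell, random_orientation(), "hexagonal_622")
    b <- crystal_model(cell, random_orientation(), "hexagonal_622")
    cc <- crystal_model(cell, random_orientation(), "hexagonal_622")
    ab <- misorientation_angle(a, b)$angle
    ba <- misorientation_angle(b, a)$angle
    expect_equal(ab, ba, tolerance = 1e-9)
    expect_lte(ab, misorientation_angle(a, cc)$angle +
                 misorientation_angle(cc, b)$angle + 1e-9)
  }
})

test_that("index assignment recovers true indices and degrades when misoriented", {
  sc <- toy_scene(seed = 5)
  blank <- sc$spots
  blank$h <- blank$k <- blank$l <- NA_real_
  got <- assign_indices(blank, sc$model, sc$beam, sc$det)
  expect_identical(attr(got, "n_unassigned"), 0L)
  expect_equal(cbind(got$h, got$k, got$l),
               cbind(sc$spots$h, sc$spots$k, sc$spots$l))

  # a 5-degree misorientation must produce assignment failures
  bad <- perturb_model(sc$model, c(5, 0, 0))
  got_bad <- assign_indices(blank, bad, sc$beam, sc$det)
  expect_gt(attr(got_bad, "n_unassigned"), 0L)

  empty <- blank[0L, ]
  expect_identical(nrow(assign_indices(empty, sc$model, sc$beam, sc$det)), 0L)
})
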