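test_that("Morse energy evaluates its closed form and soft core", {
  expect_equal(morse_energy(0, U = 3, V = 3, xi = 1, gamma = 1), 0)
  expect_lt(abs(morse_energy(50, U = 2, V = 1, xi = 1, gamma = 0.5)), 1e-12)
  expect_equal(morse_energy(1, U = 2, V = 1, xi = 1, gamma = 0.5),
               2 * exp(-1) - exp(-2), tolerance = 1e-12)
  expect_error(morse_energy(-0.1, 1, 1, 1, 1), "domain")
})

test_that("Morse force matches finite differences and Newton's third law", {
  U <- 2; V <- 1; xi <- 1; ga <- 0.5
  x <- c(0.3, -0.2); y <- c(-0.4, 0.35)
  f <- morse_force(x, y, U, V, xi, ga)
  g <- fd_grad(function(p) morse_energy(sqrt(sum((p - y)^2)), U, V, xi, ga), x)
  expect_equal(f, -g, tolerance = 1e-6)
  expect_equal(morse_force(y, x, U, V, xi, ga), -f, tolerance = 1e-12)
  # r = 1 with these coefficients: repulsive with the printed magnitude
  f1 <- morse_force(c(1, 0), c(0, 0), U, V, xi, ga)
  expect_equal(sqrt(sum(f1^2)), abs(-2 * exp(-1) + 2 * exp(-2)),
               tolerance = 1e-12)
  expect_gt(f1[1], 0)               # directed to increase separation
  # zero force at the interior critical point of an asymmetric Morse
  rstar <- 2 * log(2)               # U=1, xi=2, V=1, gamma=1
  fc <- morse_force(c(rstar, 0), c(0, 0), 1, 1, 2, 1)
  expect_equal(fc, c(0, 0), tolerance = 1e-12)
})

test_that("Morse force is continuous through zero separation when U/xi = V/gamma", {
  for (r in 10^-(1:6)) {
    f <- morse_force(c(r, 0), c(0, 0), U = 12, V = 6, xi = 1.2, gamma = 0.6)
    expect_lt(sqrt(sum(f^2)), 10 * r / 0.6^2 * 12)   # O(r) decay bound
  }
  m <- vapply(10^-(1:6), function(r)
    sqrt(sum(morse_force(c(r, 0), c(0, 0), 12, 6, 1.2, 0.6)^2)), numeric(1))
  expect_true(all(diff(m) < 0))     # |force| -> 0 monotonically as r -> 0
  expect_warning(morse_force(c(0, 0), c(0, 0), 2, 1, 1, 0.9), "discontinuous")
})

test_that("linear spring force is restoring and consistent with its energy", {
  expect_equal(linear_spring_force(c(1, 0), c(0, 0), k = 5, l_eq = 1), c(0, 0))
  f <- linear_spring_force(c(1.5, 0), c(0, 0), k = 1, l_eq = 1)
  expect_equal(f, c(-0.5, 0), tolerance = 1e-12)      # pulled back together
  expect_equal(spring_energy(1.5, 1, 1), 0.125)
  x <- c(0.2, 0.7); y <- c(-0.3, -0.1)
  g <- fd_grad(function(p) spring_energy(sqrt(sum((p - y)^2)), 3, 0.8), x)
  expect_equal(linear_spring_force(x, y, 3, 0.8), -g, tolerance = 1e-6)
  expect_warning(linear_spring_force(c(0, 0), c(0, 0), 1, 1), "degenerate")
})

test_that("bending forces are gradients with zero net force and torque", {
  # straight triplet at the straight-wall equilibrium: no force
  f0 <- bending_force(c(-1, 0), c(0, 0), c(1, 0), k_bend = 2, theta_eq = pi)
  expect_equal(f0$on_x, c(0, 0)); expect_equal(f0$on_y, c(0, 0))
  # right angle penalised against straight: energy (1/2)(pi/2)^2
  expect_equal(bending_energy(c(1, 0), c(0, 0), c(0, 1), 1, pi),
               0.5 * (pi / 2)^2, tolerance = 1e-12)
  y <- c(1.1, 0.2); x <- c(0.1, -0.3); z <- c(-0.7, 0.9)
  fb <- bending_force(y, x, z, k_bend = 1.7, theta_eq = pi)
  gy <- fd_grad(function(p) bending_energy(p, x, z, 1.7, pi), y)
  gx <- fd_grad(function(p) bending_energy(y, p, z, 1.7, pi), x)
  gz <- fd_grad(function(p) bending_energy(y, x, p, 1.7, pi), z)
  expect_equal(fb$on_y, -gy, tolerance = 1e-6)
  expect_equal(fb$on_x, -gx, tolerance = 1e-6)
  expect_equal(fb$on_z, -gz, tolerance = 1e-6)
  expect_equal(fb$on_y + fb$on_x + fb$on_z, c(0, 0), tolerance = 1e-12)
  ry <- y - x; rz <- z - x                       # net torque about the vertex
  tq <- ry[1] * fb$on_y[2] - ry[2] * fb$on_y[1] +
        rz[1] * fb$on_z[2] - rz[2] * fb$on_z[1]
  expect_equal(tq, 0, tolerance = 1e-10)
  expect_error(bending_force(x, x, z, 1, pi), "zero-length")
})

test_that("assembled internal forces cancel over the whole tissue", {
  tis <- make_two_cell_tissue(gap = 0.3)
  tis <- refresh_adhesion(tis, cutoff = 0.6)
  out <- assemble_forces(tis, potential_params(), breakdown = TRUE)
  expect_equal(colSums(out$force), c(0, 0), tolerance = 1e-9)
  # the breakdown decomposes the total exactly
  tot <- out$turgor + out$pressure + out$volume_exclusion +
    out$extensibility + out$adhesion + out$bending
  expect_equal(out$force, tot, tolerance = 1e-9)
  # removing adhesion pairs removes exactly the adhesion term
  tis0 <- tis; tis0$adhesion <- matrix(integer(0), 0, 2)
  out0 <- assemble_forces(tis0, potential_params(), breakdown = TRUE)
  expect_equal(out0$force, out$force - out$adhesion, tolerance = 1e-9)
  expect_equal(out0$adhesion, matrix(0, nrow(tis$pos), 2))
})

test_that("an isolated cell relaxes towards mechanical equilibrium", {
  tis <- make_round_cell()
  p <- potential_params()
  f0 <- max(sqrt(rowSums(assemble_forces(tis, p)$force^2)))
  tis <- relax_tissue(tis, p, nsteps = 4000)
  f1 <- max(sqrt(rowSums(assemble_forces(tis, p)$force^2)))
  expect_lt(f1, 0.01 * f0)          # residual force two orders down
  expect_lt(aspect_ratio(1L, tis), 1.1)   # relaxes round
  d <- 2 * sqrt(abs(polygon_area(cell_polygon(1L, tis))) / pi)
  expect_gt(d, 5); expect_lt(d, 7.5)      # realistic cell size
})

test_that("one explicit Euler step reproduces force/damping kinematics", {
  tis <- make_round_cell()
  p <- potential_params()
  fext <- matrix(0, nrow(tis$pos), 2)
  fext[3, ] <- c(50, -20)
  out <- assemble_forces(tis, p)
  tis2 <- step(tis, p, dt = 0.4, nsteps = 1L, boundary_force = fext)
  expect_equal(tis2$pos, tis$pos + (out$force + fext) * 0.4 / p$eta_base,
               tolerance = 1e-12)
  # zero total force leaves positions unchanged
  relaxed <- relax_tissue(tis, p, nsteps = 4000)
  still <- step(relaxed, p, dt = 0.4, nsteps = 1L)
  expect_lt(max(abs(still$pos - relaxed$pos)), 1e-4)
})

test_that("pure relaxation is a gradient flow: energy never increases", {
  tis <- make_two_cell_tissue(gap = 0.3)
  tis <- refresh_adhesion(tis, potential_params()$adhesion$cutoff)
  p <- potential_params()
  tis <- step(tis, p, nsteps = 200L)      # settle the initial transient
  tis <- refresh_adhesion(tis, p$adhesion$cutoff)
  tis2 <- step(tis, p, nsteps = 100L, track_energy = TRUE)
  e <- attr(tis2, "energy")
  expect_length(e, 100)
  expect_true(all(diff(e) <= 1e-9))
})

test_that("parameter validation flags broken force continuity", {
  expect_warning(potential_params(turgor = list(U = 2, V = 1, xi = 1, gamma = 0.9)),
                 "U/xi != V/gamma")
  expect_error(potential_params(extensibility = list(k = -1, l_eq = 1)))
})
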