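test_that("elastic energy matches closed forms on simple fixtures", {
  hexp <- regular_polygon_patch(6, edge = 1)
  p0 <- mechanics_params(K = 1, A0 = 3 * sqrt(3) / 2, Lambda = 1e-12,
                         Gamma = 1e-12, beta = 1e-12)
  expect_lt(elastic_energy(hexp, p0), 1e-10)

  pG <- mechanics_params(K = 1e-12, A0 = 1, Lambda = 1e-12, Gamma = 0.1,
                         beta = 1e-12)
  expect_equal(elastic_energy(hexp, pG), 0.05 * 36, tolerance = 1e-6)

  # cube with only bending: 12 edges at theta = pi/2, cross-checked
  # against the dihedral oracle
  sh <- cube_shell()
  pb <- mechanics_params(K = 1e-12, A0 = 1, Lambda = 1e-12,
                         Gamma = 1e-12, beta = 1)
  th <- shell_geometry(sh)$dihedrals
  expect_equal(elastic_energy(sh, pb), 0.5 * sum(th^2),
               tolerance = 1e-9)
  expect_equal(0.5 * sum(th^2), 0.5 * (pi / 2)^2 * 12,
               tolerance = 1e-12)
})

test_that("elastic and active forces match the finite-difference oracle", {
  sh <- generate_sphere_shell(40, seed = 8)
  set.seed(2)
  sh$positions <- sh$positions +
    matrix(rnorm(length(sh$positions), sd = 0.03),
           nrow(sh$positions), 3)
  p <- mechanics_params()
  nem <- nematic_field(sh, psi = runif(length(sh$cells), 0, pi))
  zeta <- 0.6

  Fel <- elastic_forces(sh, p)
  Fac <- active_forces(sh, nem, zeta)
  q3 <- nematoshell:::nematic_q3(nem)
  E <- function(pos) {
    s2 <- sh
    s2$positions <- pos
    k <- nematoshell:::shell_kernel(s2, p, q3 = q3, zeta = zeta)
    k$E_elastic + k$E_active
  }
  h <- 1e-6
  set.seed(3)
  probe <- sample(nrow(sh$positions), 12)
  for (i in probe) {
    for (x in 1:3) {
      p1 <- sh$positions; p1[i, x] <- p1[i, x] + h
      p2 <- sh$positions; p2[i, x] <- p2[i, x] - h
      fd <- -(E(p1) - E(p2)) / (2 * h)
      expect_equal(Fel[i, x] + Fac[i, x], fd,
                   tolerance = 1e-5 * max(1, abs(fd)))
    }
  }
})

test_that("active stress contracts cells along the fiber axis", {
  hexp <- regular_polygon_patch(6, edge = 1)
  nem <- nematic_field(hexp, psi = 0)  # fibers along x
  F0 <- active_forces(hexp, nem, 0)
  expect_true(all(F0 == 0))

  Fx <- active_forces(hexp, nem, 0.5)
  stepped <- hexp$positions + 0.1 * Fx
  expect_lt(diff(range(stepped[, 1])), diff(range(hexp$positions[, 1])))
  expect_gt(diff(range(stepped[, 2])), diff(range(hexp$positions[, 2])))
  # net force vanishes
  expect_lt(max(abs(colSums(Fx))), 1e-12)

  # rotating the nematic by 90 degrees mirrors the deformation axes
  # (exact for a cell with fourfold symmetry)
  sq <- regular_polygon_patch(4, edge = 1)
  nsq_x <- nematic_field(sq, psi = 0)
  nsq_y <- nematic_field(sq, psi = pi / 2)
  sx <- sq$positions + 0.1 * active_forces(sq, nsq_x, 0.5)
  sy <- sq$positions + 0.1 * active_forces(sq, nsq_y, 0.5)
  expect_equal(diff(range(sy[, 2])), diff(range(sx[, 1])),
               tolerance = 1e-9)
  expect_equal(diff(range(sy[, 1])), diff(range(sx[, 2])),
               tolerance = 1e-9)
})

test_that("active stress is traceless: area change is second order in zeta", {
  hexp <- regular_polygon_patch(6, edge = 1)
  nem <- nematic_field(hexp, psi = 0)
  dA <- function(z) {
    F <- active_forces(hexp, nem, z)
    moved <- hexp
    moved$positions <- hexp$positions + F  # one overdamped step, dt = 1
    abs(build_cell_geometry(moved, 1)$area -
          build_cell_geometry(hexp, 1)$area)
  }
  r <- dA(0.2) / dA(0.1)
  expect_gt(r, 3)
  expect_lt(r, 5)
})

test_that("volume projection zeroes the constrained component", {
  sh <- generate_sphere_shell(80, seed = 3)
  k <- nematoshell:::shell_kernel(sh, mechanics_params(), forces = TRUE)
  G <- k$volgrad
  set.seed(4)
  Fr <- matrix(rnorm(length(G)), nrow(G), 3)
  pr <- volume_constrained_forces(sh, Fr, G)
  expect_lt(abs(sum(pr$forces * G)), 1e-10 * sum(abs(Fr)))

  # forces already orthogonal to G pass through unchanged
  pr2 <- volume_constrained_forces(sh, pr$forces, G)
  expect_equal(pr2$mu, 0, tolerance = 1e-12)
  expect_equal(pr2$forces, pr$forces, tolerance = 1e-12)

  # uniform inward radial forces are mostly a pure-volume mode
  ctr <- colMeans(sh$positions)
  rad <- sweep(sh$positions, 2, ctr)
  Fin <- -rad / sqrt(rowSums(rad^2))
  pr3 <- volume_constrained_forces(sh, Fin, G)
  expect_lt(pr3$mu, 0)
  expect_lt(sqrt(sum(pr3$forces^2)), 0.5 * sqrt(sum(Fin^2)))
})

test_that("relaxation is an energy descent with conserved volume", {
  sh <- generate_sphere_shell(100, seed = 6)
  st <- shell_state(sh, mechanics_params())
  set.seed(9)
  st$shell$positions <- st$shell$positions +
    matrix(rnorm(length(sh$positions), sd = 0.02),
           nrow(sh$positions), 3)
  E <- numeric(80)
  for (i in seq_along(E)) {
    st <- step_dynamics(st, 1, zeta = 0, t1 = FALSE)
    k <- nematoshell:::shell_kernel(st$shell, st$params)
    E[i] <- k$E_elastic
    expect_lt(abs(k$volume - st$V0) / st$V0, 1e-6)
  }
  expect_true(all(diff(E) <= 1e-9))
})

test_that("halving the time step barely changes the relaxed state", {
  sh <- generate_sphere_shell(60, seed = 7)
  p <- mechanics_params()
  set.seed(10)
  pert <- matrix(rnorm(length(sh$positions), sd = 0.01),
                 nrow(sh$positions), 3)
  run <- function(dt) {
    st <- shell_state(sh, p)
    st$shell$positions <- st$shell$positions + pert
    n <- round(30 / dt)
    st <- step_dynamics(st, n, zeta = 0, dt = dt, t1 = FALSE)
    st$shell$positions
  }
  d <- max(abs(run(p$dt) - run(p$dt / 2)))
  expect_lt(d, 1e-3)
})

test_that("the reference parameters have a negative 2D Poisson ratio", {
  p <- mechanics_params()
  nu <- measure_poisson_ratio(p)
  expect_lt(nu, 0)
  expect_error(measure_poisson_ratio(p, eps_xx = 0), "nonzero")
  nu2 <- measure_poisson_ratio(p, eps_xx = 5e-3)
  expect_lt(abs(nu - nu2) / abs(nu), 0.05)
})

test_that("step sizes above the stability bound are rejected", {
  expect_error(mechanics_params(dt = 1), "stability bound")
  sh <- cube_shell()
  st <- shell_state(sh, mechanics_params())
  expect_error(step_dynamics(st, 1, dt = 1), "stability bound")
})
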