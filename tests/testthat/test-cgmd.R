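test_that("pair-bond forces match the closed form and its equilibrium", {
  sys <- particle_system(x = c(0, 0.011), y = c(0, 0),
                         phase = PHASES[["SOLID"]], body = 0L)
  topo <- bond_topology(data.frame(i = 1L, j = 2L, kb = 10, r0 = 0.01,
                                   rmax = NA))
  f <- bond_forces(sys, topo)
  # |F| = 2 k_b |r - r0| = 2 * 10 * 1e-3, restoring and antisymmetric
  expect_equal(f$fx[1], 2e-2, tolerance = 1e-12)
  expect_equal(f$fx[2], -2e-2, tolerance = 1e-12)
  expect_equal(f$length, 0.011)
  # equilibrium
  sys$x[2] <- 0.01
  f0 <- bond_forces(sys, topo)
  expect_equal(max(abs(c(f0$fx, f0$fy))), 0)
  # coincident particles are a hard error
  sys$x[2] <- 0
  expect_error(bond_forces(sys, topo), "coincident")
})

test_that("bond and angle forces match finite differences of U", {
  set.seed(5)
  for (rep in 1:25) {
    x <- runif(3); y <- runif(3)
    kb <- runif(1, 1, 20); r0 <- runif(1, 0.1, 0.5)
    ka <- runif(1, 0.1, 5); th0 <- runif(1, 0.5, 2.5)
    sys <- particle_system(x = x, y = y, phase = PHASES[["SOLID"]],
                           body = 0L)
    topo <- bond_topology(
      bonds = data.frame(i = 1L, j = 2L, kb = kb, r0 = r0, rmax = NA),
      angles = data.frame(i = 1L, j = 2L, k = 3L, ka = ka, theta0 = th0))
    fb <- bond_forces(sys, topo)
    fa <- angle_forces(sys, topo)
    Ub <- function(x, y) kb * (sqrt((x[1] - x[2])^2 + (y[1] - y[2])^2) - r0)^2
    Ua <- function(x, y) U_angle(x, y, 1, 2, 3, ka, th0)
    fdb <- fd_forces_2d(Ub, x, y, 1e-7)
    fda <- fd_forces_2d(Ua, x, y, 1e-7)
    expect_equal(fb$fx, fdb$fx, tolerance = 1e-6)
    expect_equal(fb$fy, fdb$fy, tolerance = 1e-6)
    expect_equal(fa$fx, fda$fx, tolerance = 1e-6)
    expect_equal(fa$fy, fda$fy, tolerance = 1e-6)
    # translational and rotational invariance of the triplet
    expect_lt(abs(sum(fa$fx)) + abs(sum(fa$fy)), 1e-12 * max(abs(fa$fx), 1))
    torque <- sum(x * fa$fy - y * fa$fx)
    expect_lt(abs(torque), 1e-10 * max(abs(fa$fx), 1))
  }
})

test_that("angle forces vanish at the rest angle and reject zero arms", {
  th0 <- 2  # radians
  sys <- particle_system(x = c(cos(th0), 0, 1), y = c(sin(th0), 0, 0),
                         phase = PHASES[["SOLID"]], body = 0L)
  topo <- bond_topology(angles = data.frame(i = 1L, j = 2L, k = 3L,
                                            ka = 3, theta0 = th0))
  f <- angle_forces(sys, topo)
  expect_lt(max(abs(c(f$fx, f$fy))), 1e-12)
  sys$x[1] <- 0; sys$y[1] <- 0
  expect_error(angle_forces(sys, topo), "zero-length arm")
})

test_that("dihedral forces match finite differences in the 3D harness", {
  set.seed(6)
  for (rep in 1:10) {
    pos <- matrix(runif(12), 4, 3)
    kd <- runif(1, 0.5, 3); phi0 <- runif(1, -2, 2)
    topo <- bond_topology(dihedrals = data.frame(
      i = 1L, j = 2L, k = 3L, l = 4L, kd = kd, phi0 = phi0))
    out <- dihedral_forces(pos, topo)
    fd <- fd_forces_3d(function(p) U_dihedral(p, kd, phi0), pos, 1e-7)
    expect_equal(out$f, fd, tolerance = 1e-6)
    expect_lt(max(abs(colSums(out$f))), 1e-10 * max(abs(out$f), 1))
  }
  # at the rest dihedral the force is zero
  pos <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -0.3, 0.5))
  topo <- bond_topology(dihedrals = data.frame(i = 1L, j = 2L, k = 3L,
                                               l = 4L, kd = 2, phi0 = 0))
  phi <- dihedral_forces(pos, topo)$phi
  topo$dihedrals$phi0 <- phi
  expect_lt(max(abs(dihedral_forces(pos, topo)$f)), 1e-12)
})

test_that("rigid-body motion of a topology produces no CGMD force", {
  mem <- build_membrane(12, kb = 10, r0 = 0.01, ka = 2, theta0 = NULL)
  rot <- 0.7
  x <- mem$x * cos(rot) - mem$y * sin(rot) + 3.2
  y <- mem$x * sin(rot) + mem$y * cos(rot) - 1.1
  sys <- particle_system(x = x, y = y, phase = PHASES[["SOLID"]],
                         body = 0L)
  fb <- bond_forces(sys, mem$topology)
  fa <- angle_forces(sys, mem$topology)
  expect_lt(max(abs(c(fb$fx, fb$fy))), 1e-10)
  expect_lt(max(abs(c(fa$fx, fa$fy))), 1e-10)
})

test_that("breakage removes over-stretched bonds and their hinges", {
  mem <- build_membrane(48, kb = 10, r0 = 3.3e-6, rmax = 3.6e-6,
                        ka = 1e-18, theta0 = 172.5)
  sys <- particle_system(x = mem$x, y = mem$y, phase = PHASES[["SOLID"]],
                         body = 0L)
  # all bonds at rest: nothing happens
  br <- break_bonds(sys, mem$topology, step = 1L)
  expect_equal(nrow(br$topology$bonds), 48L)
  expect_equal(nrow(br$events), 0L)
  # stretch one bond past 1.01 rmax by displacing bead 1 radially
  ctr <- c(mean(mem$x), mean(mem$y))
  dir <- c(sys$x[1] - ctr[1], sys$y[1] - ctr[2])
  dir <- dir / sqrt(sum(dir^2))
  sys$x[1] <- sys$x[1] + dir[1] * 2e-6
  sys$y[1] <- sys$y[1] + dir[2] * 2e-6
  br2 <- break_bonds(sys, mem$topology, step = 2L)
  # the two bonds incident to bead 1 exceed rmax: ring opens into a chain
  expect_lt(nrow(br2$topology$bonds), 48L)
  expect_gte(nrow(br2$topology$bonds), 46L)
  expect_gt(nrow(br2$events), 0L)
  # angle bonds referencing a broken pair go with it
  gone <- 48L - nrow(br2$topology$bonds)
  expect_lte(nrow(br2$topology$angles), 48L - gone)
  # breakage is irreversible: re-running on the relaxed ring adds nothing
  br3 <- break_bonds(sys, br2$topology, step = 3L)
  expect_equal(nrow(br3$topology$bonds), nrow(br2$topology$bonds))
})

test_that("membrane and braced-lattice builders produce the right topology", {
  mem <- build_membrane(48, kb = 10, r0 = 3.3e-6, ka = 1e-18,
                        theta0 = 172.5)
  expect_equal(length(mem$x), 48L)
  expect_equal(nrow(mem$topology$bonds), 48L)
  expect_equal(nrow(mem$topology$angles), 48L)
  m3 <- build_membrane(3, kb = 1, r0 = 1, ka = 1)
  expect_equal(nrow(m3$topology$bonds), 3L)
  expect_equal(nrow(m3$topology$angles), 3L)
  # the 48-gon interior angle equals the printed membrane rest angle
  expect_equal(pi - 2 * pi / 48, 172.5 * pi / 180)

  blk <- build_braced_lattice(7, 7, 2.3e-3, kb = 10, ka = 1e-4,
                              theta0 = 90)
  expect_equal(length(blk$x), 49L)
  expect_equal(nrow(blk$topology$bonds), 2 * 7 * 6)
  b2 <- build_braced_lattice(2, 2, 0.01, kb = 1, ka = 1)
  expect_equal(nrow(b2$topology$bonds), 4L)
  expect_equal(nrow(b2$topology$angles), 1L)
  # rigid translation of the small block is force-free
  sys <- particle_system(x = b2$x + 0.3, y = b2$y - 0.2,
                         phase = PHASES[["SOLID"]], body = 0L)
  f <- bond_forces(sys, b2$topology)
  expect_lt(max(abs(c(f$fx, f$fy))), 1e-12)
  # 1% isotropic stretch pulls every particle back towards the centre
  ctr <- c(mean(b2$x), mean(b2$y))
  sys2 <- particle_system(x = ctr[1] + (b2$x - ctr[1]) * 1.01,
                          y = ctr[2] + (b2$y - ctr[2]) * 1.01,
                          phase = PHASES[["SOLID"]], body = 0L)
  f2 <- bond_forces(sys2, b2$topology)
  inward <- (sys2$x - ctr[1]) * f2$fx + (sys2$y - ctr[2]) * f2$fy
  expect_true(all(inward < 0))
})

test_that("a membrane ring at its rest geometry is force-free", {
  mem <- build_membrane(24, kb = 10, r0 = 0.01, ka = 2, theta0 = NULL)
  sys <- particle_system(x = mem$x, y = mem$y, phase = PHASES[["SOLID"]],
                         body = 0L)
  fb <- bond_forces(sys, mem$topology)
  fa <- angle_forces(sys, mem$topology)
  expect_lt(max(abs(c(fb$fx, fb$fy, fa$fx, fa$fy))), 1e-10)
})

test_that("the bonded-pair oscillation period matches the closed form", {
  m <- 1e-3; kb <- 10; r0 <- 0.01
  Tper <- 2 * pi * sqrt((m / 2) / (2 * kb))
  dt <- Tper / 1000
  sys <- particle_system(x = c(0, r0 * 1.05), y = c(0, 0), mass = m,
                         phase = PHASES[["SOLID"]], body = 0L)
  topo <- bond_topology(data.frame(i = 1L, j = 2L, kb = kb, r0 = r0,
                                   rmax = NA))
  cfg <- scenario_config("osc", boundary_spec(c(-1, 1), c(-1, 1)),
                         dt = dt, n_steps = 0, cutoff = 0.05,
                         physics = list(breakage = FALSE))
  ini <- init_state(sys, topo, cfg)
  st <- ini$state
  sep <- numeric(3000)
  for (k in 1:3000) {
    st <- integrate_step(st, ini$cfg, k)
    sep[k] <- diff(st$system$x)
  }
  z <- which(diff(sign(sep - r0)) > 0)
  period <- (z[length(z)] - z[1]) / (length(z) - 1) * dt
  expect_equal(period, Tper, tolerance = 0.01)
})
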