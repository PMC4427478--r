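test_that("normal contact force follows the spring-dashpot form", {
  law <- contact_law(1e5, gn = 0)
  expect_equal(dem_normal_force(0, 0, 1, law), 0)
  expect_equal(dem_normal_force(1e-4, 0, 1, law), 10)
  # dashpot opposes approach and never produces adhesion at separation
  law2 <- contact_law(1e5, gn = 10)
  expect_gt(dem_normal_force(1e-4, 0.5, 1, law2), 10)   # approaching
  expect_equal(dem_normal_force(1e-6, -100, 1, law2), 0) # separating, clamped
})

test_that("tangential force sticks below the Coulomb limit and slides above", {
  law <- contact_law(1e5, kt = 1e3, gt = 0, mus = 0.5, mud = 0.5)
  out0 <- dem_tangential_force(0, 0, 10, 1, law)
  expect_equal(out0$ft, 0)
  # candidate exactly at mu_s f_n stays on the static branch
  xi_edge <- 0.5 * 10 / 1e3
  out_edge <- dem_tangential_force(xi_edge, 0, 10, 1, law)
  expect_equal(out_edge$ft, -5)
  expect_equal(out_edge$xi, xi_edge)
  # above the limit the force drops to mu_d f_n and xi is rescaled
  out_slip <- dem_tangential_force(2 * xi_edge, 0, 10, 1, law)
  expect_equal(abs(out_slip$ft), 0.5 * 10)
  expect_equal(out_slip$xi, -out_slip$ft / 1e3)
})

test_that("a growing tangential pull sticks, then slides at the dynamic level", {
  law <- contact_law(1e5, kt = 1e3, mus = 0.5, mud = 0.4)
  fn <- 10
  xi <- 0
  history <- c()
  for (pull in seq_len(30)) {
    xi <- xi + 2e-4  # imposed tangential creep
    out <- dem_tangential_force(xi, 0, fn, 1, law)
    xi <- out$xi
    history <- c(history, abs(out$ft))
    expect_lte(abs(out$ft), law$mus * fn + 1e-12)
  }
  # the spring ratchets up to the static limit, slips to the dynamic
  # level, and keeps cycling between the two
  expect_equal(max(history), law$mus * fn, tolerance = 0.05)
  expect_true(any(abs(history - law$mud * fn) < 1e-9))
  after_slip <- history[seq(which.max(history), length(history))]
  expect_true(all(after_slip >= law$mud * fn - 1e-9))
})

test_that("binary-collision restitution matches the damped-oscillator form", {
  kn <- 1e5; m <- 1
  for (gn in c(0, 5, 20, 60)) {
    meff <- m / 2
    wd <- sqrt(kn / meff - gn^2 / 4)
    e_theory <- exp(-gn * pi / (2 * wd))
    tc <- pi / wd
    fx <- fixture_generator("two_body_collision", speed = 1, gap = 1e-3,
                            radius = 0.05, mass = m)
    cfg <- scenario_config("col", fx$domain, dt = tc / 400, n_steps = 0,
                           cutoff = 0.2,
                           contact = contact_law(kn, gn),
                           physics = list(breakage = FALSE))
    st <- run_steps(fx$system, fx$topology, cfg, 1200)
    e_sim <- st$system$vx[2] - st$system$vx[1]
    expect_equal(e_sim, e_theory, tolerance = 0.01)
    # momentum conserved through the collision
    expect_lt(abs(sum(st$system$mass * st$system$vx)), 1e-12)
  }
})

test_that("the contact ledger tracks exactly the overlapping pairs", {
  fx <- fixture_generator("two_body_collision", speed = 1, gap = 1e-3,
                          radius = 0.05, mass = 1)
  cfg <- scenario_config("col", fx$domain, dt = 1e-5, n_steps = 0,
                         cutoff = 0.2, contact = contact_law(1e5, 5),
                         physics = list(breakage = FALSE))
  ini <- init_state(fx$system, fx$topology, cfg)
  st <- ini$state
  for (k in 1:1100) {  # past the full contact duration pi/omega_d
    st <- integrate_step(st, ini$cfg, k)
    s <- st$system
    overlap <- (s$radius[1] + s$radius[2]) -
      sqrt((s$x[1] - s$x[2])^2 + (s$y[1] - s$y[2])^2)
    expect_equal(length(st$ledger$key), as.integer(overlap > 0))
  }
  # after fly-apart the ledger is empty again
  expect_equal(length(st$ledger$key), 0L)
})

test_that("truncated LJ force matches its derivative and cutoff", {
  eps <- 1e-12; sigma <- 5e-6
  expect_equal(lj_force(sigma * 1.2, eps, sigma, rc = sigma), 0)
  expect_equal(lj_force(sigma, eps, sigma, rc = 2.5 * sigma),
               24 * eps / sigma)
  # finite-difference check at r = 0.9 sigma
  U <- function(r) 4 * eps * ((sigma / r)^12 - (sigma / r)^6)
  r <- 0.9 * sigma
  fd <- -(U(r + 1e-13) - U(r - 1e-13)) / 2e-13
  expect_equal(lj_force(r, eps, sigma, rc = 2.5 * sigma), fd,
               tolerance = 1e-4)
  expect_gt(lj_force(r, eps, sigma, rc = 2.5 * sigma), 0)
  # beyond the potential minimum the branch is attractive
  expect_lt(lj_force(1.5 * sigma, eps, sigma, rc = 2.5 * sigma), 0)
})

test_that("no-slip coupling vanishes when fluid and solid move together", {
  sys <- particle_system(x = c(0, 1e-3), y = c(0, 0), vx = 0.1, vy = 0,
                         mass = 1e-6, density = 1000,
                         phase = c(PHASES[["FLUID"]], PHASES[["SOLID"]]),
                         body = c(-1L, 0L), radius = 5e-4)
  dom <- boundary_spec(c(-1, 1), c(-1, 1))
  nl <- build_neighbor_list(sys, 3e-3, dom)
  spec <- kernel_spec(1.3e-3)
  law <- fluid_law(1000, 1, 0.1, "morris")
  f <- apply_no_slip(sys, nl, spec, law)
  expect_equal(max(abs(c(f$fx, f$fy))), 0)
  # with relative motion the coupling damps it, equal and opposite
  sys$vx[2] <- 0
  f2 <- apply_no_slip(sys, nl, spec, law)
  expect_lt(f2$fx[1], 0)
  expect_equal(f2$fx[1], -f2$fx[2])
})

test_that("an advected rigid block relaxes to the fluid velocity", {
  # small periodic fluid box moving uniformly, one bonded 2x2 block at rest
  fx <- fixture_generator("uniform_lattice", n = 8, dx = 1e-3)
  sys <- fx$system
  sys$vx <- rep(2e-3, sys$n)
  blk <- build_braced_lattice(2, 2, 1e-3, kb = 10, ka = 1e-6,
                              origin = c(3.1e-3, 3.6e-3))
  keep <- rep(TRUE, sys$n)
  for (k in seq_along(blk$x))
    keep <- keep & ((sys$x - blk$x[k])^2 + (sys$y - blk$y[k])^2 > (0.9e-3)^2)
  sys <- subset_system(sys, keep)
  n0 <- sys$n
  solid <- particle_system(x = blk$x, y = blk$y, mass = 1e-3,
                           density = 1000, phase = PHASES[["SOLID"]],
                           body = 0L, radius = 5e-4)
  sys <- bind_systems(sys, solid)
  topo <- merge_topologies(blk$topology, offsets = n0)
  h <- 1.3e-3
  cfg <- scenario_config("adv", fx$domain, h = h, dt = 2e-5, n_steps = 0,
                         fluid = fluid_law(1000, 0.05, 0.1, "morris"),
                         coupling = coupling_law(1e-12, 1e-3),
                         cutoff = 2 * h, physics = list(breakage = FALSE))
  st <- run_steps(sys, topo, cfg, 1500)
  vs <- st$system$vx[st$system$phase == PHASES[["SOLID"]]]
  expect_true(all(abs(vs - 2e-3) / 2e-3 < 0.15))
})
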