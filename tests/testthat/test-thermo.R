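casting_law <- function(k_T = 0) {
  thermal_law(kappa = 1, cv_solid = 2, cv_liquid = 1, T_star = 25,
              e_sol = 50, e_liq = 100, k_T = k_T, T_air = 0,
              bond_radius = 2.5e-2, bond_kb = 1e5, bond_r0 = 2.5e-2)
}

test_that("the caloric EOS maps energy to temperature branch by branch", {
  law <- casting_law()
  out <- energy_to_temperature(c(40, 75, 120), law)
  expect_equal(out$temperature, c(20, 25, 45))
  expect_equal(out$fraction, c(0, 0.5, 1))
  # continuity and monotonicity across the full range
  e <- seq(-10, 200, by = 0.5)
  Tv <- energy_to_temperature(e, law)$temperature
  expect_true(all(diff(Tv) >= 0))
  expect_lt(max(abs(diff(Tv))), 1)  # no jumps at the branch points
  # collapsed plateau (no latent heat) stays continuous and monotone
  law0 <- thermal_law(kappa = 1, cv_solid = 2, cv_liquid = 1, T_star = 25,
                      e_sol = 50, e_liq = 50)
  Tv0 <- energy_to_temperature(e, law0)$temperature
  expect_true(all(diff(Tv0) >= 0))
  expect_equal(energy_to_temperature(50, law0)$temperature, 25)
})

test_that("the caloric EOS is exactly invertible off the plateau", {
  law <- casting_law()
  invert <- function(Tv) ifelse(Tv < law$T_star, Tv * law$cv_solid,
                                (Tv - law$T_star) * law$cv_liquid +
                                  law$e_liq)
  e <- c(seq(0, 49.9, by = 0.7), seq(100.1, 300, by = 0.7))
  Tv <- energy_to_temperature(e, law)$temperature
  expect_equal(invert(Tv), e, tolerance = 1e-12)
})

test_that("heat conduction is zero at uniform temperature and conservative", {
  fx <- fixture_generator("uniform_lattice", n = 8, dx = 2.5e-2)
  sys <- fx$system
  sys$kappa <- rep(1, sys$n)
  sys$energy <- rep(50, sys$n)
  sys$temperature <- rep(50, sys$n)
  h <- 1.3 * 2.5e-2
  spec <- kernel_spec(h)
  nl <- build_neighbor_list(sys, 2 * h, fx$domain)
  expect_equal(heat_conduction_rhs(sys, nl, spec), rep(0, sys$n))
  # random temperatures: pairwise antisymmetry conserves total m*e
  set.seed(3)
  sys$temperature <- runif(sys$n, 0, 100)
  dedt <- heat_conduction_rhs(sys, nl, spec)
  expect_lt(abs(sum(sys$mass * dedt)), 1e-12 * sum(abs(sys$mass * dedt)))
  # heat flows from hot to cold: hottest particle cools
  expect_lt(dedt[which.max(sys$temperature)], 0)
})

test_that("closed conduction conserves total thermal energy over many steps", {
  fx <- fixture_generator("uniform_lattice", n = 8, dx = 2.5e-2)
  sys <- fx$system
  sys$kappa <- rep(1, sys$n)
  set.seed(4)
  sys$energy <- runif(sys$n, 10, 200)
  law <- thermal_law(kappa = 1, cv_solid = 1, cv_liquid = 1, T_star = 0,
                     e_sol = 0, e_liq = 0)
  sys$temperature <- energy_to_temperature(sys$energy, law)$temperature
  h <- 1.3 * 2.5e-2
  cfg <- scenario_config("cond", fx$domain, h = h, dt = 5e-3, n_steps = 0,
                         thermal = law, cutoff = 2 * h,
                         physics = list(momentum = FALSE,
                                        solidification = FALSE,
                                        breakage = FALSE))
  E0 <- sum(sys$mass * sys$energy)
  st <- run_steps(sys, bond_topology(), cfg, 2000)
  E1 <- sum(st$system$mass * st$system$energy)
  expect_equal(E1, E0, tolerance = 1e-12)
  # temperatures homogenize towards the energy-weighted mean
  expect_lt(diff(range(st$system$temperature)),
            diff(range(energy_to_temperature(sys$energy, law)$temperature)))
})

test_that("surface cooling follows Newton's law on free-surface particles", {
  # isolated particle, coordination 0: T(t) = T0 exp(-k_T t)
  law <- thermal_law(kappa = 1, cv_solid = 1, cv_liquid = 1, T_star = 0,
                     e_sol = 0, e_liq = 0, k_T = 0.02, T_air = 0)
  sys <- particle_system(x = 0, y = 0, energy = 100, temperature = 100,
                         kappa = 1)
  cfg <- scenario_config("cool", boundary_spec(c(-1, 1), c(-1, 1)),
                         h = 0.1, dt = 0.025, n_steps = 0, thermal = law,
                         cutoff = 0.2,
                         physics = list(momentum = FALSE,
                                        solidification = FALSE,
                                        breakage = FALSE))
  st <- run_steps(sys, bond_topology(), cfg, 2000)  # t = 50 s
  expect_equal(st$system$temperature[1], 100 * exp(-1), tolerance = 1e-3)
  # interior lattice particles (high coordination) are untouched;
  # h = 1.6 dx reaches first and second lattice shells (coordination 8)
  fx <- fixture_generator("uniform_lattice", n = 8, dx = 2.5e-2)
  sys2 <- fx$system
  sys2$temperature <- rep(100, sys2$n)
  sys2$energy <- rep(100, sys2$n)
  h <- 1.6 * 2.5e-2
  nl <- build_neighbor_list(sys2, 2 * h, fx$domain)
  out <- surface_cooling(sys2, nl, law, kernel_spec(h))
  expect_equal(max(abs(out$dedt)), 0)  # periodic lattice has no surface
  expect_false(any(out$surface))
  # particle already at the ambient temperature stops cooling
  sys$temperature[1] <- 0; sys$energy[1] <- 0
  nl1 <- build_neighbor_list(sys, 0.2, cfg$domain)
  out1 <- surface_cooling(sys, nl1, law, kernel_spec(0.1))
  expect_equal(out1$dedt, 0)
})

test_that("latent-plateau surface particles keep draining energy", {
  law <- casting_law(k_T = 0.02)
  sys <- particle_system(x = 0, y = 0, energy = 75,
                         temperature = 25, kappa = 1)
  nl <- build_neighbor_list(sys, 0.2, boundary_spec(c(-1, 1), c(-1, 1)))
  out <- surface_cooling(sys, nl, law, kernel_spec(0.1))
  # the rate the law imposes just above the plateau: cv_liquid k_T (T* - T_air)
  expect_equal(out$dedt[1], -1 * 0.02 * 25)
})

test_that("solidification bonds new solids to solid neighbors in radius", {
  law <- casting_law()
  dx <- 2.5e-2
  sys <- particle_system(x = c(0, dx, 2 * dx), y = c(0, 0, 0),
                         energy = c(60, 60, 60), temperature = 25,
                         kappa = 1, radius = dx / 2)
  dom <- boundary_spec(c(-1, 1), c(-1, 1))
  nl <- build_neighbor_list(sys, 2 * dx, dom)
  topo <- bond_topology()
  # nothing below the solidus: no change
  out <- solidify(sys, nl, topo, law)
  expect_equal(length(out$new_solid), 0L)
  expect_equal(nrow(out$topology$bonds), 0L)
  # particle 1 crosses first: becomes solid, no solid neighbor yet
  sys$energy[1] <- 40
  out1 <- solidify(sys, nl, topo, law)
  expect_equal(out1$new_solid, 1L)
  expect_equal(nrow(out1$topology$bonds), 0L)
  expect_equal(out1$system$phase[1], PHASES[["SOLID"]])
  # particle 2 crosses on the next step: exactly one bond (1,2) forms;
  # particle 3 is within radius of 2 but still liquid
  sys2 <- out1$system; sys2$energy[2] <- 40
  out2 <- solidify(sys2, nl, out1$topology, law)
  expect_equal(out2$new_solid, 2L)
  expect_equal(nrow(out2$topology$bonds), 1L)
  expect_setequal(c(out2$topology$bonds$i, out2$topology$bonds$j), c(1L, 2L))
  # a same-step cohort bonds internally too (order independence)
  sys3 <- particle_system(x = c(0, dx), y = c(0, 0), energy = 40,
                          temperature = 20, kappa = 1, radius = dx / 2)
  nl3 <- build_neighbor_list(sys3, 2 * dx, dom)
  out3 <- solidify(sys3, nl3, bond_topology(), law)
  expect_equal(nrow(out3$topology$bonds), 1L)
  check_phase_consistency(out3$system, out3$topology)
})

test_that("melting relabels the particle and destroys exactly its bonds", {
  law <- casting_law()
  dx <- 2.5e-2
  blk <- build_braced_lattice(3, 3, dx, kb = 1e5, ka = 0)
  sys <- particle_system(x = blk$x, y = blk$y, energy = 40,
                         temperature = 20, phase = PHASES[["SOLID"]],
                         body = 0:8, kappa = 1, radius = dx / 2)
  topo <- blk$topology
  # all below the liquidus: unchanged
  out0 <- melt(sys, topo, law)
  expect_equal(length(out0$melted), 0L)
  # re-melt the centre particle (index 5): its four bonds disappear
  sys$energy[5] <- 120
  out1 <- melt(sys, topo, law)
  expect_equal(out1$melted, 5L)
  expect_equal(out1$system$phase[5], PHASES[["FLUID"]])
  expect_equal(nrow(out1$topology$bonds), nrow(topo$bonds) - 4L)
  expect_true(all(out1$system$phase[-5] == PHASES[["SOLID"]]))
  check_phase_consistency(out1$system, out1$topology)
  # full melt: no bonds remain, everything fluid
  sys$energy <- rep(120, sys$n)
  out2 <- melt(sys, topo, law)
  expect_equal(nrow(out2$topology$bonds), 0L)
  expect_true(all(out2$system$phase == PHASES[["FLUID"]]))
})

test_that("blended pair forces interpolate between pure SPH and pure DEM", {
  law <- thermal_law(kappa = 1, cv_solid = 1, cv_liquid = 1, T_star = 500,
                     e_sol = 500, e_liq = 500, blend_T_range = c(500, 1000))
  dx <- 2.5e-2
  mk <- function(Tpair, phase = PHASES[["FLUID"]]) {
    e <- Tpair  # cv = 1
    sys <- particle_system(x = c(0, 0.8 * dx), y = c(0, 0), mass = 1.25,
                           density = 2100, energy = e, temperature = Tpair,
                           phase = phase,
                           body = if (phase == PHASES[["SOLID"]])
                             c(0L, 1L) else -1L,
                           radius = dx / 2, kappa = 1)
    sys$pressure <- tait_pressure(sys$density, fl)
    sys
  }
  fl <- fluid_law(2000, 12, 1.0, "morris")
  cl <- contact_law(1e6, 0, 0, 0, 0)
  dom <- boundary_spec(c(-1, 1), c(-1, 1))
  cfg <- scenario_config("blend", dom, h = 4e-2, dt = 1e-4, n_steps = 0,
                         fluid = fl, contact = cl, thermal = law,
                         physics = list(blend = TRUE, breakage = FALSE),
                         cutoff = 0.1)
  force_on_1 <- function(Tpair, phase) {
    sys <- mk(Tpair, phase)
    nl <- build_neighbor_list(sys, 0.1, dom)
    dispatch_pair_forces(sys, nl, bond_topology(), contact_ledger(),
                         cfg)$fx[1]
  }
  # lambda = 1: identical to the pure SPH pair force
  sys_hot <- mk(1200)
  nl <- build_neighbor_list(sys_hot, 0.1, dom)
  f_sph <- sph_momentum_forces(sys_hot, nl, kernel_spec(4e-2), fl)$fx[1]
  expect_equal(force_on_1(1200, PHASES[["FLUID"]]), f_sph, tolerance = 1e-12)
  # lambda = 0: identical to the pure DEM contact force
  sys_cold <- mk(300, PHASES[["SOLID"]])
  f_dem <- dem_contact_forces(sys_cold,
                              build_neighbor_list(sys_cold, 0.1, dom),
                              contact_ledger(), cl, 1e-4)$fx[1]
  expect_equal(force_on_1(300, PHASES[["SOLID"]]), f_dem, tolerance = 1e-12)
  # lambda = 1/2: the arithmetic mean of the two families
  f_mid <- force_on_1(750, PHASES[["TRANSITION"]])
  sys_mid <- mk(750, PHASES[["TRANSITION"]])
  nl_mid <- build_neighbor_list(sys_mid, 0.1, dom)
  f_sph_mid <- sph_momentum_forces(sys_mid, nl_mid, kernel_spec(4e-2),
                                   fl)$fx[1]
  f_dem_mid <- dem_contact_forces(sys_mid, nl_mid, contact_ledger(), cl,
                                  1e-4)$fx[1]
  expect_equal(f_mid, 0.5 * f_sph_mid + 0.5 * f_dem_mid, tolerance = 1e-12)
})
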