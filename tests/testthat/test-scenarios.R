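test_that("the cell-in-channel builder matches the published census", {
  scn <- build_scenario("cell_channel")
  s <- scn$system
  # 48-bead membrane, 61 cytoplasm particles, 2048-site fluid lattice
  expect_equal(sum(s$species == "cell"), 48L)
  expect_equal(sum(s$species == "cytoplasm"), 61L)
  expect_equal(scn$config$extra$n_fluid_lattice, 2048L)
  expect_equal(nrow(scn$topology$bonds), 48L)
  expect_equal(nrow(scn$topology$angles), 48L)
  # membrane parameters as configured
  expect_equal(unique(scn$topology$bonds$kb), 10)
  expect_equal(unique(scn$topology$bonds$r0), 3.3e-6)
  expect_equal(unique(scn$topology$angles$theta0), 172.5 * pi / 180)
  # cytoplasm is SPH fluid; membrane is bead-spring solid
  expect_true(all(s$phase[s$species == "cytoplasm"] == PHASES[["FLUID"]]))
  expect_true(all(s$phase[s$species == "cell"] == PHASES[["SOLID"]]))
})

test_that("every cube in Poiseuille flow has 49 elemental particles", {
  scn <- build_scenario("cubes_poiseuille", overrides = list(n_cubes = 3))
  s <- scn$system
  cubes <- table(s$body[s$species == "cube"])
  expect_equal(length(cubes), 3L)
  expect_true(all(cubes == 49L))
  # brace angles at right angles
  expect_equal(unique(scn$topology$angles$theta0), pi / 2)
})

test_that("sorter species differ only in their angular stiffness", {
  scn <- build_scenario("plinko", overrides = list(
    y0 = 0.3e-3, x0 = 0.3e-3, n_flex = 4, n_rigid = 4), seed = 2)
  s <- scn$system
  expect_equal(sum(s$species == "flexible") / 16, 4)
  expect_equal(sum(s$species == "rigid") / 16, 4)
  a <- scn$topology$angles
  ka_by_bead <- tapply(a$ka, a$j, unique)
  flex_beads <- which(s$species == "flexible")
  rigid_beads <- which(s$species == "rigid")
  expect_true(all(unlist(ka_by_bead[as.character(flex_beads)]) == 1e-16))
  expect_true(all(unlist(ka_by_bead[as.character(rigid_beads)]) == 1e-15))
  # everything else identical
  b <- scn$topology$bonds
  expect_equal(unique(b$kb), 1e-2)
  expect_equal(unique(b$r0), 3.9e-6)
  expect_equal(length(unique(s$mass[s$phase == PHASES[["SOLID"]]])), 1L)
})

test_that("every shipped scenario builds and validates", {
  for (nm in list_scenarios()) {
    scn <- build_scenario(nm, seed = 1)
    expect_s3_class(scn, "scenario")
    expect_gt(scn$system$n, 0)
  }
  expect_error(build_scenario("volcano"), "unknown scenario")
  expect_error(build_scenario("plinko", overrides = list(nope = 1)),
               "unknown override")
})

test_that("runs are deterministic given the config and seed", {
  run_once <- function() {
    scn <- build_scenario("plinko", overrides = list(
      y0 = 0.25e-3, x0 = 0.25e-3, n_flex = 3, n_rigid = 3,
      n_steps = 300), seed = 7)
    r <- run_scenario(scn, observe_every = 300)
    c(r$system$x, r$system$y, r$system$vx, r$system$vy)
  }
  expect_identical(run_once(), run_once())
  # different seeds place the cells differently
  scn_a <- build_scenario("plinko", overrides = list(
    y0 = 0.25e-3, x0 = 0.25e-3, n_flex = 3, n_rigid = 3), seed = 1)
  scn_b <- build_scenario("plinko", overrides = list(
    y0 = 0.25e-3, x0 = 0.25e-3, n_flex = 3, n_rigid = 3), seed = 2)
  expect_false(identical(scn_a$system$x, scn_b$system$x))
})

test_that("frames round-trip through CSV and carry conformant headers", {
  fx <- fixture_generator("random_gas", n = 20, seed = 3)
  sys <- fx$system
  sys$temperature <- runif(20, 0, 100)
  td <- tempfile()
  dir.create(td)
  p <- write_frame(sys, fx$topology, file.path(td, "f"), "csv", seed = 3)
  back <- read_frame(p)
  expect_equal(back$x, sys$x)           # full precision
  expect_equal(back$temperature, sys$temperature)
  expect_equal(nrow(back), 20L)
  expect_match(readLines(p, n = 1), "seed=3")
  # extended XYZ: count line, properties line, one row per particle
  px <- write_frame(sys, fx$topology, file.path(td, "f2"), "xyz", seed = 3)
  lx <- readLines(px)
  expect_equal(as.integer(lx[1]), 20L)
  expect_match(lx[2], "Properties=")
  expect_equal(length(lx), 22L)
  # legacy VTK header conformance
  pv <- write_frame(sys, fx$topology, file.path(td, "f3"), "vtk", seed = 3)
  lv <- readLines(pv)
  expect_equal(lv[1], "# vtk DataFile Version 3.0")
  expect_equal(lv[3], "ASCII")
  expect_equal(lv[4], "DATASET POLYDATA")
  expect_match(lv[5], "POINTS 20 double")
  # an empty system still writes a valid zero-particle file
  empty <- subset_system(sys, integer(0))
  pe <- write_frame(empty, bond_topology(), file.path(td, "f4"), "csv")
  expect_equal(nrow(read_frame(pe)), 0L)
  unlink(td, recursive = TRUE)
})

test_that("fixture generators are deterministic and as specified", {
  two <- fixture_generator("two_body_collision", speed = 2)
  expect_equal(two$system$n, 2L)
  expect_equal(two$system$vx[1] - two$system$vx[2], 2)
  ring <- fixture_generator("bonded_ring", n = 48, r0 = 3.3e-6, kb = 10,
                            ka = 1e-18)
  mem <- build_membrane(48, kb = 10, r0 = 3.3e-6, ka = 1e-18)
  expect_equal(ring$system$x, mem$x)
  expect_equal(ring$topology$bonds, mem$topology$bonds)
  g1 <- fixture_generator("random_gas", n = 50, seed = 12)
  g2 <- fixture_generator("random_gas", n = 50, seed = 12)
  expect_identical(g1$system$x, g2$system$x)
})

test_that("the dispatcher rejects systems with unknown phases", {
  fx <- fixture_generator("random_gas", n = 10, seed = 1)
  sys <- fx$system
  sys$phase[3] <- 9L
  nl <- build_neighbor_list(sys, 0.3, fx$domain)
  cfg <- scenario_config("bad", fx$domain, h = 0.1, dt = 1e-3,
                         n_steps = 0, cutoff = 0.3)
  expect_error(dispatch_pair_forces(sys, nl, bond_topology(),
                                    contact_ledger(), cfg),
               "unknown phase")
})
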