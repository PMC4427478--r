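#' Deterministic test fixtures
#'
#' Small seeded systems each exercising one physics family; used
#' throughout the test suite and handy for quick experiments.
#'
#' * `uniform_lattice`: an `n x n` square lattice of fluid particles at
#'   spacing `dx` in a periodic box.
#' * `random_gas`: `n` particles at uniform random positions in the unit
#'   box (neighbor-search and property tests).
#' * `two_body_collision`: two solid particles approaching head-on with
#'   the requested closing speed.
#' * `bonded_ring`: a closed membrane of `n` beads (delegates to
#'   [build_membrane]).
#' * `hot_slab`: a fluid slab at `T_hot` between cold isothermal walls
#'   (transient-conduction tests).
#' * `dry_soil_strip`: a strip of dry soil particles under a water
#'   reservoir column (half-space diffusion tests).
#'
#' @param kind Fixture name, see above.
#' @param n Size parameter (particles per side, beads, ...).
#' @param seed Random seed (`random_gas` placement).
#' @param ... Kind-specific overrides, see the implementations.
#' @return List with `system`, `topology`, `domain` and kind-specific
#'   extras.
#' @export
fixture_generator <- function(kind = c("uniform_lattice", "random_gas",
                                       "two_body_collision", "bonded_ring",
                                       "hot_slab", "dry_soil_strip"),
                              n = 10, seed = 1, ...) {
  kind <- match.arg(kind)
  args <- list(...)
  get_arg <- function(nm, default) args[[nm]] %||% default
  empty <- bond_topology()
  switch(kind,
    uniform_lattice = {
      dx <- get_arg("dx", 1e-3)
      rho0 <- get_arg("rho0", 1000)
      g <- expand.grid(ix = seq_len(n), iy = seq_len(n))
      sys <- particle_system(x = (g$ix - 0.5) * dx, y = (g$iy - 0.5) * dx,
                             mass = rho0 * dx^2, density = rho0)
      dom <- boundary_spec(c(0, n * dx), c(0, n * dx), c(TRUE, TRUE))
      list(system = sys, topology = empty, domain = dom, dx = dx)
    },
    random_gas = {
      set.seed(seed)
      sys <- particle_system(x = runif(n), y = runif(n), mass = 1,
                             density = 1000)
      dom <- boundary_spec(c(0, 1), c(0, 1),
                           get_arg("periodic", c(TRUE, TRUE)))
      list(system = sys, topology = empty, domain = dom)
    },
    two_body_collision = {
      v <- get_arg("speed", 1)
      gap <- get_arg("gap", 1e-3)
      radius <- get_arg("radius", 0.05)
      m <- get_arg("mass", 1)
      sys <- particle_system(x = c(-radius - gap / 2, radius + gap / 2),
                             y = c(0, 0), vx = c(v / 2, -v / 2), vy = 0,
                             mass = m, density = 1000, phase = PH_SOLID,
                             body = c(0L, 1L), radius = radius)
      dom <- boundary_spec(c(-1, 1), c(-1, 1), c(FALSE, FALSE))
      list(system = sys, topology = empty, domain = dom)
    },
    bonded_ring = {
      r0 <- get_arg("r0", 3.3e-6)
      mem <- build_membrane(n, kb = get_arg("kb", 10), r0 = r0,
                            rmax = get_arg("rmax", NA),
                            ka = get_arg("ka", 1e-18),
                            theta0 = get_arg("theta0", NULL))
      sys <- particle_system(x = mem$x, y = mem$y,
                             mass = get_arg("mass", 2.5e-8),
                             density = 1000, phase = PH_SOLID, body = 0L,
                             radius = r0 / 2)
      L <- 4 * max(abs(c(mem$x, mem$y)))
      dom <- boundary_spec(c(-L, L), c(-L, L), c(FALSE, FALSE))
      list(system = sys, topology = mem$topology, domain = dom)
    },
    hot_slab = {
      dx <- get_arg("dx", 2.5e-2)
      rho0 <- get_arg("rho0", 1000)
      T_hot <- get_arg("T_hot", 100)
      cv <- get_arg("cv", 1)
      kappa <- get_arg("kappa", 1)
      kappa_wall <- get_arg("kappa_wall", kappa)
      ny <- get_arg("ny", 6)
      wl <- get_arg("wall_layers", 3)
      ix <- seq_len(n + 2 * wl) - wl   # 1..n interior, walls outside
      g <- expand.grid(ix = ix, iy = seq_len(ny))
      wall <- g$ix < 1 | g$ix > n
      sys <- particle_system(
        x = g$ix * dx, y = (g$iy - 1) * dx, mass = rho0 * dx^2,
        density = rho0,
        energy = ifelse(wall, 0, cv * T_hot),
        temperature = ifelse(wall, 0, T_hot),
        phase = ifelse(wall, PH_WALL, PH_FLUID),
        body = ifelse(wall, ifelse(g$ix < 1, 0L, 1L), -1L),
        kappa = ifelse(wall, kappa_wall, kappa),
        fixed_temperature = wall)
      dom <- boundary_spec(c((1 - wl) * dx - dx / 2, (n + wl) * dx + dx / 2),
                           c(-dx / 2, (ny - 0.5) * dx), c(FALSE, TRUE))
      list(system = sys, topology = empty, domain = dom, dx = dx,
           L = (n + 1) * dx)
    },
    dry_soil_strip = {
      dx <- get_arg("dx", 2.5e-2)
      rho0 <- get_arg("rho0", 1000)
      D <- get_arg("D", 1e-4)
      ny <- get_arg("ny", 6)
      n_res <- get_arg("n_reservoir", 8)
      ix <- seq_len(n + n_res)
      g <- expand.grid(ix = ix, iy = seq_len(ny))
      res <- g$ix <= n_res   # reservoir column at x <= 0
      m <- rho0 * dx^2
      sys <- particle_system(
        x = (g$ix - n_res) * dx - dx / 2, y = (g$iy - 1) * dx, mass = m,
        density = rho0,
        water = ifelse(res, m, 0),
        concentration = ifelse(res, 1, 0),
        diffusivity = D, reservoir = res)
      dom <- boundary_spec(c(-n_res * dx, n * dx),
                           c(-dx / 2, (ny - 0.5) * dx), c(FALSE, TRUE))
      list(system = sys, topology = empty, domain = dom, dx = dx)
    })
}
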