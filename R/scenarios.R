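#' Build one of the shipped scenarios
#'
#' Programmatic builders for the example applications: deformable cells in
#' channel, obstacle, aspiration, shear and piercing geometries; cubic
#' dispersed particles in Poiseuille flow (neutrally buoyant, floating, or
#' heavy and brittle); casting with slow or ultrafast solidification;
#' cleaning of a protein soil deposit under a moving wall; lava flow on an
#' inclined plane with SPH/DEM blending; and the pin-array ("Plinko")
#' cell sorter in the quiescent-fluid drag mode. Geometry, material laws
#' and run control default to the published parameter sets; `overrides`
#' replaces any builder parameter by name (reduced particle counts and
#' step counts for desk-scale tests).
#'
#' @param name Scenario name, one of `"cell_channel"`, `"cell_obstacle"`,
#'   `"cell_aspiration"`, `"cell_shear"`, `"cell_piercing"`,
#'   `"cubes_poiseuille"`, `"casting_slow"`, `"casting_fast"`,
#'   `"cleaning"`, `"lava_incline"`, `"plinko"`.
#' @param overrides Named list of builder-parameter overrides.
#' @param seed Random seed (used only where a builder randomizes, e.g.
#'   initial cell placement in the sorter); recorded in the config.
#' @return A list of class `scenario`: `config` ([scenario_config]),
#'   `system` ([particle_system]), `topology` ([bond_topology]).
#' @export
build_scenario <- function(name, overrides = list(), seed = 1L) {
  builders <- list(
    cell_channel = build_cell_channel,
    cell_obstacle = function(o, s) build_cell_channel(o, s, geometry = "obstacle"),
    cell_aspiration = function(o, s) build_cell_channel(o, s, geometry = "aspiration"),
    cell_shear = function(o, s) build_cell_channel(o, s, geometry = "shear"),
    cell_piercing = function(o, s) build_cell_channel(o, s, geometry = "piercing"),
    cubes_poiseuille = build_cubes_poiseuille,
    casting_slow = function(o, s) build_casting(o, s, fast = FALSE),
    casting_fast = function(o, s) build_casting(o, s, fast = TRUE),
    cleaning = build_cleaning,
    lava_incline = build_lava_incline,
    plinko = build_plinko)
  if (!name %in% names(builders))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(builders), collapse = ", "))
  scn <- builders[[name]](overrides, as.integer(seed))
  scn$config$name <- name
  scn$config$seed <- as.integer(seed)
  validate_system(scn$system)
  class(scn) <- "scenario"
  scn
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> '", x$config$name, "'\n", sep = "")
  print(x$system)
  print(x$topology)
  invisible(x)
}

#' List the shipped scenarios
#' @return Character vector of scenario names.
#' @export
list_scenarios <- function() {
  c("cell_channel", "cell_obstacle", "cell_aspiration", "cell_shear",
    "cell_piercing", "cubes_poiseuille", "casting_slow", "casting_fast",
    "cleaning", "lava_incline", "plinko")
}

merge_params <- function(defaults, overrides) {
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown override(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, overrides)
}

#' Subset a particle system
#'
#' @param sys A [particle_system].
#' @param keep Logical or integer index of particles to keep.
#' @return The subsetted [particle_system].
#' @export
subset_system <- function(sys, keep) {
  fields <- setdiff(names(sys), "n")
  out <- lapply(sys[fields], `[`, keep)
  out$n <- length(out$x)
  class(out) <- "particle_system"
  out
}

# Drop fluid particles that sit within `clearance` of any obstacle point
# (solid bodies and furniture are placed by carving the fluid lattice, not
# by stacking on top of it).
carve_fluid <- function(fluid, ox, oy, clearance) {
  if (!length(ox)) return(fluid)
  keep <- rep(TRUE, fluid$n)
  for (k in seq_along(ox)) {
    keep <- keep & ((fluid$x - ox[k])^2 + (fluid$y - oy[k])^2 >
                      clearance^2)
  }
  subset_system(fluid, keep)
}

# Hydrostatic Tait-consistent density profile under a vertical body force:
# rho(y) = rho0 (1 + 7 g (H - y) / c0^2)^(1/7), with H the free-surface
# height. Removes most of the start-up acoustic transient.
hydrostatic_density <- function(y, H, gmag, law) {
  arg <- pmax(0, 1 + 7 * gmag * (H - y) / law$c0^2)
  law$rho0 * arg^(1 / 7)
}

apply_hydrostatic <- function(sys, H, gmag, law, which = NULL) {
  if (gmag <= 0) return(sys)
  if (is.null(which)) which <- rep(TRUE, sys$n)
  sys$density[which] <- hydrostatic_density(sys$y[which], H, gmag, law)
  sys$pressure[which] <- tait_pressure(sys$density[which], law)
  sys
}

# Channel chassis: fluid lattice between frozen-particle walls, periodic
# or walled in x. Fluid rows at (k - 1/2) dx; the innermost wall rows sit
# at -dx/2 and L + dx/2, which is where the no-slip plane of the
# dummy-particle treatment lies.
channel_parts <- function(nx, ny, dx, rho0, wall_layers = 3,
                          v_top = 0, v_bottom = 0, periodic_x = TRUE,
                          fill = 1, kappa = 0, kappa_wall = kappa,
                          energy = 0, temperature = 0, energy_wall = 0,
                          temperature_wall = 0, fixed_wall_T = FALSE,
                          D = 0) {
  m <- rho0 * dx^2
  wl <- wall_layers
  ny_f <- round(ny * fill)
  fy <- as.vector(outer(rep(1, nx), (seq_len(ny_f) - 0.5) * dx))
  fxp <- as.vector(outer((seq_len(nx) - 0.5) * dx, rep(1, ny_f)))
  fluid <- particle_system(x = fxp, y = fy, mass = m, density = rho0,
                           energy = energy, temperature = temperature,
                           kappa = kappa, diffusivity = D,
                           reservoir = D > 0,
                           concentration = as.numeric(D > 0),
                           water = (D > 0) * m / rho0)
  wy_b <- as.vector(outer(rep(1, nx), -(seq_len(wl) - 0.5) * dx))
  wy_t <- as.vector(outer(rep(1, nx), (ny + seq_len(wl) - 0.5) * dx))
  wx <- as.vector(outer((seq_len(nx) - 0.5) * dx, rep(1, wl)))
  mk_wall <- function(wx, wy, v, body)
    particle_system(x = wx, y = wy, vx = v, mass = m, density = rho0,
                    phase = PH_WALL, body = body, radius = dx / 2,
                    kappa = kappa_wall, energy = energy_wall,
                    temperature = temperature_wall,
                    fixed_temperature = fixed_wall_T)
  parts <- list(fluid = fluid,
                wall_bottom = mk_wall(wx, wy_b, v_bottom, 0L),
                wall_top = mk_wall(wx, wy_t, v_top, 1L))
  dom <- boundary_spec(c(0, nx * dx),
                       c(-wl * dx, (ny + wl) * dx),
                       c(periodic_x, FALSE))
  list(parts = parts, domain = dom, m = m, L = (ny + 1) * dx)
}

# Hexagonal disc of points: rings k = 0..n_rings at radius k*a, 6k points
# per ring (1 + sum 6k points total)
hex_disc <- function(n_rings, a, center = c(0, 0)) {
  x <- center[1]; y <- center[2]
  for (k in seq_len(n_rings)) {
    th <- 2 * pi * (seq_len(6 * k) - 1) / (6 * k) + pi / (6 * k)
    x <- c(x, center[1] + k * a * cos(th))
    y <- c(y, center[2] + k * a * sin(th))
  }
  list(x = x, y = y)
}

build_cell_channel <- function(overrides, seed, geometry = "channel") {
  p <- merge_params(list(
    nx = 64, ny = 32, dx = 5e-6, rho0 = 1000, mu = 0.1, h = 1.18e-5,
    c0 = 0.1, wall_layers = 3, fg = 1, dt = 1e-7, n_steps = 1e7,
    n_beads = 48, r0 = 3.3e-6, rmax = NA, kb = 10, ka = 1e-18,
    theta0 = 172.5, n_cyto_rings = 4, lj_eps = 1e-12, lj_sigma = NULL,
    include_cell = TRUE, wall_speed = 2e-3, gap = 3e-5,
    output_every = 1000), overrides)
  if (is.null(p$lj_sigma)) p$lj_sigma <- p$dx
  periodic_x <- !(geometry %in% c("aspiration", "piercing"))
  if (geometry == "shear") {
    v_top <- p$wall_speed; fg <- c(0, 0); p$rmax <- 3.6e-6
  } else {
    v_top <- 0
    fg <- c(if (geometry == "aspiration") 10 else p$fg, 0)
    if (geometry == "piercing") { fg <- c(10, 0); p$rmax <- 3.6e-6 }
  }
  ch <- channel_parts(p$nx, p$ny, p$dx, p$rho0, p$wall_layers,
                      v_top = v_top, periodic_x = periodic_x)
  parts <- ch$parts
  topo_list <- list(bond_topology())
  offs <- 0L
  # geometry furniture: extra frozen-particle bodies (fluid is carved out
  # around them rather than stacked underneath)
  extra <- cell_channel_furniture(geometry, p, ch)
  if (!is.null(extra)) {
    parts$furniture <- extra
    parts$fluid <- carve_fluid(parts$fluid, extra$x, extra$y, 0.75 * p$dx)
  }
  if (!periodic_x) {
    # closed ends: wall columns at both x extremes
    wl <- p$wall_layers
    ys <- seq(-wl + 0.5, p$ny + wl - 0.5) * p$dx
    exL <- as.vector(outer(-(seq_len(wl) - 0.5) * p$dx, rep(1, length(ys))))
    exR <- as.vector(outer((p$nx + seq_len(wl) - 0.5) * p$dx,
                           rep(1, length(ys))))
    eyy <- as.vector(outer(rep(1, wl), ys))
    parts$ends <- particle_system(
      x = c(exL, exR), y = c(eyy, eyy), mass = ch$m, density = p$rho0,
      phase = PH_WALL, body = 5L, radius = p$dx / 2)
    ch$domain <- boundary_spec(c(-wl * p$dx, (p$nx + wl) * p$dx),
                               ch$domain$ylim, c(FALSE, FALSE))
  }
  if (p$include_cell) {
    mem <- build_membrane(p$n_beads, kb = p$kb, r0 = p$r0, rmax = p$rmax,
                          ka = p$ka, theta0 = p$theta0)
    R_cell <- p$r0 / (2 * sin(pi / p$n_beads))
    ctr <- c(p$nx * p$dx * 0.25, p$ny * p$dx / 2)
    if (geometry == "shear") ctr[2] <- p$ny * p$dx * 0.6
    # carve a cavity matching the cell's equilibrium footprint. The
    # printed census over-packs the interior slightly (the cell sits
    # mildly pressurized), so its footprint is a little smaller than its
    # raw particle count would suggest.
    n_cell <- p$n_beads + 1 + sum(6 * seq_len(p$n_cyto_rings))
    parts$fluid <- carve_fluid(parts$fluid, ctr[1], ctr[2],
                               sqrt(n_cell / pi) * p$dx)
    beads <- particle_system(
      x = mem$x + ctr[1], y = mem$y + ctr[2], mass = ch$m,
      density = p$rho0, phase = PH_SOLID, body = 10L, radius = p$r0 / 2,
      species = "cell")
    cy <- hex_disc(p$n_cyto_rings, (R_cell - 0.7 * p$dx) / p$n_cyto_rings,
                   ctr)
    cyto <- particle_system(x = cy$x, y = cy$y, mass = ch$m,
                            density = p$rho0, species = "cytoplasm")
    n_before <- sum(vapply(parts, function(s) s$n, numeric(1)))
    parts$beads <- beads
    parts$cyto <- cyto
    topo_list <- c(topo_list, list(mem$topology))
    offs <- c(0L, n_before)
  }
  sys <- do.call(bind_systems, unname(parts))
  topo <- do.call(merge_topologies, c(topo_list, list(offsets = offs)))
  cfg <- scenario_config(
    "cell_channel", ch$domain, h = p$h, dt = p$dt, n_steps = p$n_steps,
    gravity = fg,
    fluid = fluid_law(p$rho0, p$c0, p$mu, "morris", reinit_every = 40L),
    coupling = coupling_law(p$lj_eps, p$lj_sigma, rc = p$lj_sigma),
    physics = list(breakage = !is.na(p$rmax)),
    output_every = p$output_every,
    extra = list(geometry = geometry,
                 n_fluid_lattice = as.integer(p$nx * round(p$ny))))
  list(config = cfg, system = sys, topology = topo)
}

# Obstacle / funnel / spike bodies for the cell geometries
cell_channel_furniture <- function(geometry, p, ch) {
  dx <- p$dx; m <- ch$m
  grid_block <- function(xs, ys) {
    g <- expand.grid(x = xs, y = ys)
    particle_system(x = g$x, y = g$y, mass = m, density = p$rho0,
                    phase = PH_WALL, body = 4L, radius = dx / 2)
  }
  W <- p$ny * dx
  if (geometry == "obstacle") {
    xm <- p$nx * dx * 0.6
    xs <- xm + (0:2) * dx
    gap <- p$gap
    ys_b <- seq(0.5 * dx, (W - gap) / 2, by = dx)
    ys_t <- seq(W - 0.5 * dx, (W + gap) / 2, by = -dx)
    return(grid_block(xs, c(ys_b, ys_t)))
  }
  if (geometry == "aspiration") {
    # converging funnel towards the outlet: wall columns whose opening
    # narrows linearly from the full width down to the gap
    x0 <- p$nx * dx * 0.7
    n_cols <- 8
    pts_x <- c(); pts_y <- c()
    for (k in seq_len(n_cols)) {
      xk <- x0 + (k - 1) * dx
      open_half <- (W / 2 - p$gap / 2) * (1 - k / n_cols) + p$gap / 2
      ys_b <- seq(0.5 * dx, W / 2 - open_half, by = dx)
      if (!length(ys_b)) next
      pts_x <- c(pts_x, rep(xk, 2 * length(ys_b)))
      pts_y <- c(pts_y, ys_b, W - ys_b)
    }
    g <- data.frame(x = pts_x, y = pts_y)
    return(particle_system(x = g$x, y = g$y, mass = m, density = p$rho0,
                           phase = PH_WALL, body = 4L, radius = dx / 2))
  }
  if (geometry == "piercing") {
    # a sharp wedge pointing upstream at the channel end
    xt <- p$nx * dx * 0.85
    nyw <- 6
    pts_x <- c(); pts_y <- c()
    for (k in 0:nyw) {
      xs <- xt + k * dx
      half <- k * dx / 2 + dx / 4
      yy <- seq(W / 2 - half, W / 2 + half, by = dx / 2)
      pts_x <- c(pts_x, rep(xs, length(yy)))
      pts_y <- c(pts_y, yy)
    }
    g <- data.frame(x = pts_x, y = pts_y)
    return(particle_system(x = g$x, y = g$y, mass = m, density = p$rho0,
                           phase = PH_WALL, body = 4L, radius = dx / 2))
  }
  NULL
}

build_cubes_poiseuille <- function(overrides, seed) {
  p <- merge_params(list(
    variant = "neutral", nx = 40, ny = 24, dx = 2.39e-3, rho0 = 1000,
    mu = 0.1, h = 5.6e-3, c0 = 8, wall_layers = 3, fg = 0.1, dt = 0.5e-4,
    n_steps = 1e7, n_cubes = 4, cube_n = 7, r0 = 2.3e-3, kb = 10,
    ka = 1e-4, theta0 = 90, kn = 1e5, gn = 0.3, kt = 1e3, gt = 0.2,
    mus = 0.5, lj_eps = 1e-4, output_every = 1000), overrides)
  variant <- match.arg(p$variant, c("neutral", "buoyant", "heavy"))
  rho_cube <- switch(variant, neutral = 1000, buoyant = 990, heavy = 1500)
  gy <- if (variant == "neutral") 0 else -9.81
  fill <- if (variant == "buoyant") 0.7 else 1
  strain <- if (variant == "heavy") 1e-3 else NA  # rmax/r0 - 1
  ch <- channel_parts(p$nx, p$ny, p$dx, p$rho0, p$wall_layers, fill = fill)
  parts <- ch$parts
  topo_list <- list(bond_topology())
  side <- (p$cube_n - 1) * p$r0
  ny_f <- round(p$ny * fill)
  blocks <- list()
  for (kc in seq_len(p$n_cubes)) {
    cx <- (kc - 0.5) / p$n_cubes * p$nx * p$dx - side / 2
    cyy <- (0.25 + 0.5 * (kc %% 2)) * ny_f * p$dx - side / 2
    blk <- build_braced_lattice(p$cube_n, p$cube_n, p$r0, kb = p$kb,
                                rmax = if (is.na(strain)) NA
                                       else p$r0 * (1 + strain),
                                ka = p$ka, theta0 = p$theta0,
                                origin = c(cx, cyy))
    parts$fluid <- carve_fluid(parts$fluid, blk$x, blk$y, 1.05 * p$dx)
    blocks[[kc]] <- blk
  }
  if (gy != 0) {
    law0 <- fluid_law(p$rho0, p$c0, p$mu, "morris")
    H <- ny_f * p$dx
    for (nm in c("fluid", "wall_bottom"))
      parts[[nm]] <- apply_hydrostatic(parts[[nm]], H, -gy, law0)
  }
  offs <- 0L
  n_before <- sum(vapply(parts, function(s) s$n, numeric(1)))
  for (kc in seq_len(p$n_cubes)) {
    blk <- blocks[[kc]]
    parts[[paste0("cube", kc)]] <- particle_system(
      x = blk$x, y = blk$y, mass = rho_cube * p$r0^2, density = rho_cube,
      phase = PH_SOLID, body = 10L + kc, radius = p$r0 / 2,
      species = "cube")
    topo_list <- c(topo_list, list(blk$topology))
    offs <- c(offs, n_before)
    n_before <- n_before + length(blk$x)
  }
  sys <- do.call(bind_systems, unname(parts))
  topo <- do.call(merge_topologies, c(topo_list, list(offsets = offs)))
  cfg <- scenario_config(
    "cubes_poiseuille", ch$domain, h = p$h, dt = p$dt,
    n_steps = p$n_steps, gravity = c(p$fg, gy),
    fluid = fluid_law(p$rho0, p$c0, p$mu, "monaghan", h = p$h),
    contact = contact_law(p$kn, p$gn, p$kt, p$gt, p$mus),
    coupling = coupling_law(p$lj_eps, p$dx, rc = p$dx),
    physics = list(breakage = !is.na(strain)),
    output_every = p$output_every,
    extra = list(variant = variant))
  list(config = cfg, system = sys, topology = topo)
}

build_casting <- function(overrides, seed, fast = FALSE) {
  p <- merge_params(list(
    dx = 2.5e-2, mould_w = 20, mould_h = 12, wall_layers = 3,
    pour_w = 8, pour_h = 25, drop = 0.05, pour = TRUE, quiescent = FALSE,
    rho0 = 992, mu = 1.0, h = 4e-2, c0 = 10, dt = 5e-4, n_steps = 1e5,
    kappa = 1, kappa_wall = 100, cv_solid = 2, cv_liquid = 1, T_star = 25,
    T_init = 100, k_T = if (fast) 0.5 else 0.02, T_air = 0,
    bond_kb = 1e5, bond_rmax = if (fast) 4e-2 else NA,
    kn = 1e4, gn = 0.3, kt = 1e3, gt = 0.2, mus = 0.5,
    gravity_y = -9.81, output_every = 200), overrides)
  if (p$quiescent) p$pour <- FALSE
  e_sol <- p$cv_solid * p$T_star                  # 50 J/kg
  e_liq <- if (fast) e_sol else 100
  e_init <- e_liq + p$cv_liquid * (p$T_init - p$T_star)
  dx <- p$dx; m <- p$rho0 * dx^2
  wl <- p$wall_layers
  # U-shaped mould: floor plus two side walls
  xs_in <- (seq_len(p$mould_w) - 0.5) * dx
  floor_x <- rep(c(-(seq_len(wl) - 0.5) * dx, xs_in,
                   p$mould_w * dx + (seq_len(wl) - 0.5) * dx), wl)
  nfx <- p$mould_w + 2 * wl
  floor_y <- rep(-(seq_len(wl) - 0.5) * dx, each = nfx)
  side_y <- (seq_len(p$mould_h) - 0.5) * dx
  sideL_x <- rep(-(seq_len(wl) - 0.5) * dx, each = p$mould_h)
  sideR_x <- rep(p$mould_w * dx + (seq_len(wl) - 0.5) * dx,
                 each = p$mould_h)
  wall <- particle_system(
    x = c(floor_x, sideL_x, sideR_x),
    y = c(floor_y, rep(side_y, 2 * wl)),
    mass = m, density = p$rho0, phase = PH_WALL, body = 0L,
    radius = dx / 2, kappa = p$kappa_wall, energy = 0, temperature = 0,
    fixed_temperature = TRUE)
  if (p$pour) {
    px <- (p$mould_w / 2 - p$pour_w / 2) * dx +
      (seq_len(p$pour_w) - 0.5) * dx
    py <- p$mould_h * dx + p$drop + (seq_len(p$pour_h) - 0.5) * dx
  } else {
    px <- xs_in
    py <- (seq_len(p$pour_h) - 0.5) * dx
  }
  g <- expand.grid(x = px, y = py)
  melt_blk <- particle_system(
    x = g$x, y = g$y, mass = m, density = p$rho0, energy = e_init,
    temperature = p$T_init, kappa = p$kappa, radius = dx / 2)
  sys <- bind_systems(wall, melt_blk)
  dom_h <- if (p$pour) p$mould_h * dx + p$drop + (p$pour_h + 2) * dx
           else (p$mould_h + 2) * dx
  dom <- boundary_spec(c(-(wl + 1) * dx, (p$mould_w + wl + 1) * dx),
                       c(-wl * dx, dom_h), c(FALSE, FALSE))
  thermal <- thermal_law(
    kappa = p$kappa, cv_solid = p$cv_solid, cv_liquid = p$cv_liquid,
    T_star = p$T_star, e_sol = e_sol, e_liq = e_liq, k_T = p$k_T,
    T_air = p$T_air, bond_radius = dx, bond_kb = p$bond_kb,
    bond_r0 = dx, bond_rmax = p$bond_rmax)
  cfg <- scenario_config(
    "casting", dom, h = p$h, dt = p$dt, n_steps = p$n_steps,
    gravity = c(0, if (p$pour) p$gravity_y else 0),
    fluid = fluid_law(p$rho0, p$c0, p$mu, "morris"),
    contact = contact_law(p$kn, p$gn, p$kt, p$gt, p$mus),
    coupling = coupling_law(1e-4, dx, rc = dx),
    thermal = thermal,
    physics = list(breakage = !is.na(p$bond_rmax),
                   momentum = !p$quiescent),
    output_every = p$output_every)
  list(config = cfg, system = sys, topology = bond_topology())
}

build_cleaning <- function(overrides, seed) {
  p <- merge_params(list(
    nx = 24, ny = 12, dx = 4.8e-5, rho0 = 1000, mu = 1e-3, h = 1.1e-4,
    c0 = 0.01, wall_layers = 3, v_wall = 2e-4, moving_wall = TRUE,
    dt = 1e-6, n_steps = 5e7, soil_cols = 8, soil_rows = 2,
    soil_diam = 4.7e-5, soil_rho = 1800, D = 1e-9, c_rel = 0.5,
    eps_pair = 7e-11, eps_surface = 5e-10, adh_sigma = 5e-5,
    lj_eps = 1e-12, removal_height = 1.5e-4, removal_distance = NULL,
    output_every = 1000),
    overrides)
  ch <- channel_parts(p$nx, p$ny, p$dx, p$rho0, p$wall_layers,
                      v_top = if (p$moving_wall) p$v_wall else 0,
                      D = p$D)
  r_s <- p$soil_diam / 2
  m_s <- p$soil_rho * pi * r_s^2
  # the deposit is assembled at the adhesion-potential minimum
  # (2^(1/6) sigma), the mechanical equilibrium of the van der Waals
  # wells; packing at touching diameters would start deep inside the
  # repulsive core and rattle the deposit apart
  a_eq <- 2^(1 / 6) * p$adh_sigma
  x0 <- (p$nx * p$dx - p$soil_cols * a_eq) / 2
  y0 <- a_eq - p$dx / 2   # equilibrium height above the wall row
  sx <- sy <- c()
  for (row in seq_len(p$soil_rows)) {
    off <- if (row %% 2 == 0) a_eq / 2 else 0
    sx <- c(sx, x0 + off + (seq_len(p$soil_cols) - 0.5) * a_eq)
    sy <- c(sy, rep(y0 + (row - 1) * a_eq * sqrt(3) / 2, p$soil_cols))
  }
  soil <- particle_system(
    x = sx, y = sy, mass = m_s, density = p$soil_rho, phase = PH_SOLID,
    body = 100L + seq_along(sx), radius = r_s, diffusivity = p$D,
    species = "soil")
  # clear the full coupling range sigma so no fluid starts inside the
  # repulsive Lennard-Jones core of a soil particle
  fluid <- carve_fluid(ch$parts$fluid, sx, sy,
                       max(r_s + 0.5 * p$dx, p$adh_sigma))
  sys <- bind_systems(fluid, ch$parts$wall_bottom, ch$parts$wall_top,
                      soil)
  cfg <- scenario_config(
    "cleaning", ch$domain, h = p$h, dt = p$dt, n_steps = p$n_steps,
    fluid = fluid_law(p$rho0, p$c0, p$mu, "morris"),
    coupling = coupling_law(p$lj_eps, p$adh_sigma, rc = p$adh_sigma),
    diffusion = diffusion_law(p$D, c_rel = p$c_rel,
                              eps_pair = p$eps_pair,
                              eps_surface = p$eps_surface,
                              sigma = p$adh_sigma,
                              swell_gain = 1 / p$rho0),
    physics = list(breakage = FALSE),
    removal = list(surface_y = 0, height = p$removal_height,
                   distance = p$removal_distance %||% 3 * p$soil_diam),
    output_every = p$output_every)
  list(config = cfg, system = sys, topology = bond_topology())
}

build_lava_incline <- function(overrides, seed) {
  p <- merge_params(list(
    nx = 60, nx_lava = NULL, ny_lava = 6, dx = 2.5e-2, rho0 = 2000,
    mu = 1.0, h = 4e-2, c0 = 15, wall_layers = 3, incline_deg = 30,
    g = 9.81, dt = 1e-4, n_steps = 1e7, kappa = 1, cv = 1, T_star = 500,
    T_init = 1000, k_T = 0.02, T_air = 0, bond_kb = 1e5,
    bond_rmax = 4e-2, kn = 1e6, gn = 0.3, kt = 1e4, gt = 0.1, mus = 0.5,
    output_every = 1000), overrides)
  dx <- p$dx; m <- p$rho0 * dx^2
  wl <- p$wall_layers
  # default: a full-width film on the periodic incline (no collapsing
  # front); a finite tongue is available by overriding nx_lava
  if (is.null(p$nx_lava)) p$nx_lava <- p$nx
  # incline realized in the rotated frame: floor along y = 0, gravity tilted
  gvec <- p$g * c(sin(p$incline_deg * pi / 180),
                  -cos(p$incline_deg * pi / 180))
  wx <- as.vector(outer((seq_len(p$nx) - 0.5) * dx, rep(1, wl)))
  wy <- as.vector(outer(rep(1, p$nx), -(seq_len(wl) - 0.5) * dx))
  floor_w <- particle_system(x = wx, y = wy, mass = m, density = p$rho0,
                             phase = PH_WALL, body = 0L, radius = dx / 2,
                             kappa = 0, fixed_temperature = TRUE)
  e_init <- p$cv * p$T_init
  g <- expand.grid(x = (seq_len(p$nx_lava) - 0.5) * dx,
                   y = (seq_len(p$ny_lava) - 0.5) * dx)
  lava <- particle_system(x = g$x, y = g$y, mass = m, density = p$rho0,
                          energy = e_init, temperature = p$T_init,
                          kappa = p$kappa, radius = dx / 2)
  law0 <- fluid_law(p$rho0, p$c0, p$mu, "morris")
  lava <- apply_hydrostatic(lava, p$ny_lava * dx, -gvec[2], law0)
  floor_w <- apply_hydrostatic(floor_w, p$ny_lava * dx, -gvec[2], law0)
  dom <- boundary_spec(c(0, p$nx * dx),
                       c(-wl * dx, (p$ny_lava + 20) * dx), c(TRUE, FALSE))
  e_star <- p$cv * p$T_star
  thermal <- thermal_law(
    kappa = p$kappa, cv_solid = p$cv, cv_liquid = p$cv, T_star = p$T_star,
    e_sol = e_star, e_liq = e_star, k_T = p$k_T, T_air = p$T_air,
    bond_radius = dx, bond_kb = p$bond_kb, bond_r0 = dx,
    bond_rmax = p$bond_rmax,
    blend_T_range = c(p$T_star, p$T_init))
  cfg <- scenario_config(
    "lava_incline", dom, h = p$h, dt = p$dt, n_steps = p$n_steps,
    gravity = gvec,
    fluid = fluid_law(p$rho0, p$c0, p$mu, "morris"),
    contact = contact_law(p$kn, p$gn, p$kt, p$gt, p$mus),
    thermal = thermal,
    physics = list(blend = TRUE),
    output_every = p$output_every)
  list(config = cfg, system = bind_systems(floor_w, lava),
       topology = bond_topology())
}

build_plinko <- function(overrides, seed) {
  p <- merge_params(list(
    x0 = 0.45e-3, y0 = 1.5e-3, pitch = 30e-6, pin_diam = 10e-6,
    pins_top = 0.7, pins_bottom = 0.1, n_flex = 10, n_rigid = 10,
    n_beads = 16, r0 = 3.9e-6, kb = 1e-2, theta0 = 157.5,
    ka_rigid = 1e-15, ka_flex = 1e-16, bead_mass = 2e-11, rho = 1000,
    kn = 10, gn = 0.3, kt = 10, gt = 0.3, mus = 0.5, drag_mu = 1e-3,
    f = 100, dt = 1e-7, n_steps = 5e5, wall_dx = 5e-6,
    output_every = 1000), overrides)
  set.seed(seed)
  r_pin <- p$pin_diam / 2
  R_cell <- p$r0 / (2 * sin(pi / p$n_beads))
  gap <- 2.4 * R_cell
  # staggered (triangular) pin array
  rowy <- seq(p$pins_top * p$y0, p$pins_bottom * p$y0,
              by = -p$pitch * sin(pi / 3))
  px <- c(); py <- c()
  for (ri in seq_along(rowy)) {
    offx <- if (ri %% 2 == 0) p$pitch / 2 else 0
    xs <- seq(offx + p$pitch / 2, p$x0 - 1e-9, by = p$pitch)
    px <- c(px, xs); py <- c(py, rep(rowy[ri], length(xs)))
  }
  pins <- particle_system(x = px, y = py, mass = 1, density = 1000,
                          phase = PH_WALL, body = 2L, radius = r_pin,
                          species = "pin")
  wy <- seq(p$wall_dx / 2, p$y0 + 3 * gap, by = p$wall_dx)
  walls <- particle_system(
    x = c(rep(-p$wall_dx / 2, length(wy)), rep(p$x0 + p$wall_dx / 2,
                                               length(wy)),
          seq(p$wall_dx / 2, p$x0, by = p$wall_dx)),
    y = c(wy, wy, rep(-p$wall_dx / 2, length(seq(p$wall_dx / 2, p$x0,
                                                 by = p$wall_dx)))),
    mass = 1, density = 1000, phase = PH_WALL, body = 3L,
    radius = p$wall_dx / 2, species = "wall")
  # cells randomly allocated in the upper region, non-overlapping grid
  n_cells <- p$n_flex + p$n_rigid
  gx <- seq(gap, p$x0 - gap, by = gap)
  gy <- seq(p$y0 + 2 * gap, p$pins_top * p$y0 + 2 * gap, by = -gap)
  slots <- expand.grid(x = gx, y = gy)
  if (nrow(slots) < n_cells) stop("upper region too small for the cells")
  slots <- slots[sample(nrow(slots), n_cells), ]
  kind <- sample(rep(c("flexible", "rigid"),
                     c(p$n_flex, p$n_rigid)))
  parts <- list(pins = pins, walls = walls)
  topo_list <- list(bond_topology())
  offs <- 0L
  n_before <- pins$n + walls$n
  for (kc in seq_len(n_cells)) {
    ka <- if (kind[kc] == "flexible") p$ka_flex else p$ka_rigid
    mem <- build_membrane(p$n_beads, kb = p$kb, r0 = p$r0, ka = ka,
                          theta0 = p$theta0)
    jit <- runif(2, -2e-6, 2e-6)
    parts[[paste0("cell", kc)]] <- particle_system(
      x = mem$x + slots$x[kc] + jit[1], y = mem$y + slots$y[kc] + jit[2],
      mass = p$bead_mass, density = p$rho, phase = PH_SOLID,
      body = 10L + kc, radius = p$r0 / 2, species = kind[kc])
    topo_list <- c(topo_list, list(mem$topology))
    offs <- c(offs, n_before)
    n_before <- n_before + p$n_beads
  }
  sys <- do.call(bind_systems, unname(parts))
  topo <- do.call(merge_topologies, c(topo_list, list(offsets = offs)))
  dom <- boundary_spec(c(-2 * p$wall_dx, p$x0 + 2 * p$wall_dx),
                       c(-2 * p$wall_dx, p$y0 + 4 * gap),
                       c(FALSE, FALSE))
  cfg <- scenario_config(
    "plinko", dom, h = NULL, dt = p$dt, n_steps = p$n_steps,
    gravity = c(0, -p$f),
    contact = contact_law(p$kn, p$gn, p$kt, p$gt, p$mus),
    drag_mu = p$drag_mu,
    physics = list(momentum = FALSE, breakage = FALSE),
    cutoff = 2 * max(r_pin, p$wall_dx, p$r0),
    output_every = p$output_every)
  list(config = cfg, system = sys, topology = topo)
}
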