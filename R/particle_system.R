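#' Create a particle system
#'
#' The flat per-particle state shared by every force family: positions and
#' velocities, mass, SPH density and pressure, specific internal energy and
#' temperature, water mass and concentration, phase and body labels, and a
#' contact/drag radius. All vectors are recycled to the length of `x`.
#'
#' @param x,y Positions (m).
#' @param vx,vy Velocities (m/s). For `WALL` particles these are the
#'   prescribed wall velocities.
#' @param mass Particle mass (kg), must be positive.
#' @param density SPH density (kg/m^3), must be positive.
#' @param pressure Pressure (Pa).
#' @param energy Specific internal energy (J/kg).
#' @param temperature Temperature (deg C).
#' @param water Water mass carried by the particle (kg).
#' @param concentration Water mass fraction proxy, in `[0, 1]`.
#' @param phase Integer phase code, see [PHASES].
#' @param body Integer body id: `-1` for fluid, a shared non-negative id for
#'   the elemental particles of one dispersed body or wall.
#' @param radius Contact/drag radius (m).
#' @param kappa Thermal conductivity (J s^-1 m^-1 K^-1).
#' @param diffusivity Water diffusion coefficient (m^2/s).
#' @param species Optional species label used by observables (e.g. to track
#'   the centre of mass of flexible vs rigid cells).
#' @param reservoir Logical; `TRUE` for particles that act as a fixed
#'   concentration reservoir (bulk water in the cleaning scenario).
#' @param fixed_temperature Logical; `TRUE` for isothermal particles
#'   (cold mould walls) whose energy is never updated.
#' @return An object of class `particle_system`: a list of aligned vectors
#'   plus force accumulators `fx`, `fy` and the particle count `n`.
#' @export
particle_system <- function(x, y, vx = 0, vy = 0, mass = 1, density = 1000,
                            pressure = 0, energy = 0, temperature = 0,
                            water = 0, concentration = 0,
                            phase = PH_FLUID, body = -1L, radius = 0,
                            kappa = 0, diffusivity = 0, species = "bulk",
                            reservoir = FALSE, fixed_temperature = FALSE) {
  n <- length(x)
  stopifnot(length(y) == n)
  r <- function(v) rep_len(v, n)
  sys <- list(
    x = as.numeric(x), y = as.numeric(y),
    vx = r(as.numeric(vx)), vy = r(as.numeric(vy)),
    mass = r(as.numeric(mass)), density = r(as.numeric(density)),
    pressure = r(as.numeric(pressure)), energy = r(as.numeric(energy)),
    temperature = r(as.numeric(temperature)), water = r(as.numeric(water)),
    concentration = r(as.numeric(concentration)),
    phase = r(as.integer(phase)), body = r(as.integer(body)),
    radius = r(as.numeric(radius)), kappa = r(as.numeric(kappa)),
    diffusivity = r(as.numeric(diffusivity)),
    species = r(as.character(species)),
    reservoir = r(as.logical(reservoir)),
    fixed_temperature = r(as.logical(fixed_temperature)),
    dry_mass = r(as.numeric(mass)), dry_radius = r(as.numeric(radius)),
    removed = r(FALSE),
    fx = numeric(n), fy = numeric(n), n = n
  )
  class(sys) <- "particle_system"
  validate_system(sys)
  sys
}

#' Validate a particle system's invariants
#'
#' Checks positive masses, positive densities for SPH-participating
#' particles, known phase codes, non-negative body ids for solid and wall
#' particles, and finiteness of all state.
#'
#' @param sys A [particle_system].
#' @return `sys`, invisibly. Errors with a diagnostic naming the first
#'   offending particle otherwise.
#' @export
validate_system <- function(sys) {
  if (any(bad <- !is.finite(sys$x) | !is.finite(sys$y)))
    stop("non-finite position for particle ", which(bad)[1])
  if (any(bad <- sys$mass <= 0))
    stop("non-positive mass for particle ", which(bad)[1])
  sphlike <- sys$phase %in% c(PH_FLUID, PH_TRANSITION, PH_WALL)
  if (any(bad <- sphlike & sys$density <= 0))
    stop("non-positive density for SPH particle ", which(bad)[1])
  if (any(bad <- !(sys$phase %in% PHASES)))
    stop("unknown phase code for particle ", which(bad)[1])
  if (any(bad <- sys$phase %in% c(PH_SOLID, PH_WALL) & sys$body < 0L))
    stop("negative body id for solid/wall particle ", which(bad)[1])
  invisible(sys)
}

#' Concatenate particle systems
#'
#' Combines particle blocks (fluid lattice, membranes, walls ...) into one
#' system, preserving all per-particle fields.
#'
#' @param ... [particle_system] objects.
#' @return A single [particle_system].
#' @export
bind_systems <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  stopifnot(length(parts) > 0)
  fields <- setdiff(names(parts[[1]]), "n")
  out <- lapply(fields, function(f) do.call(c, lapply(parts, `[[`, f)))
  names(out) <- fields
  out$n <- length(out$x)
  class(out) <- "particle_system"
  out
}

#' @export
print.particle_system <- function(x, ...) {
  cnt <- table(factor(x$phase, levels = PHASES, labels = names(PHASES)))
  cat("<particle_system> ", x$n, " particles (",
      paste(sprintf("%s: %d", names(cnt), cnt), collapse = ", "), ")\n",
      sep = "")
  cat(sprintf("  x range [%.3g, %.3g] m, y range [%.3g, %.3g] m\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' Total linear momentum of a system
#' @param sys A [particle_system].
#' @return Numeric vector `c(px, py)` (kg m/s).
#' @export
total_momentum <- function(sys) {
  c(sum(sys$mass * sys$vx), sum(sys$mass * sys$vy))
}

#' Total kinetic energy of a system
#' @param sys A [particle_system].
#' @return Scalar (J).
#' @export
kinetic_energy <- function(sys) {
  0.5 * sum(sys$mass * (sys$vx^2 + sys$vy^2))
}
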