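#' Solute-diffusion and surface law
#'
#' Water diffusion through the SPH formalism, soil swelling, and
#' concentration-dependent adhesion. Bulk-water particles act as a fixed
#' concentration reservoir (`c = 1`); soil particles absorb water, swell
#' in proportion to the absorbed mass, and lose adhesion linearly with
#' concentration until, at the release threshold, only repulsive contact
#' remains and the flow washes them away.
#'
#' @param D Water diffusion coefficient inside the soil (m^2/s).
#' @param c_rel Release threshold concentration, in `(0, 1]`.
#' @param eps_pair Soil-soil adhesion well depth at zero water (J).
#' @param eps_surface Soil-surface adhesion well depth at zero water (J).
#' @param sigma Adhesion LJ zero-crossing distance (m).
#' @param rc Adhesion cutoff (m); the conventional `2.5 sigma` by default
#'   so the attractive well acts.
#' @param swell_gain Area gained per unit absorbed water mass (m^2/kg);
#'   the inverse of the water density by default (absorbed water adds its
#'   own volume).
#' @return An object of class `diffusion_law`.
#' @export
diffusion_law <- function(D, c_rel = 0.5, eps_pair = 0, eps_surface = 0,
                          sigma = 1, rc = 2.5 * sigma,
                          swell_gain = 1 / 1000) {
  stopifnot(D >= 0, c_rel > 0, c_rel <= 1, swell_gain >= 0)
  structure(list(D = D, c_rel = c_rel, eps_pair = eps_pair,
                 eps_surface = eps_surface, sigma = sigma, rc = rc,
                 swell_gain = swell_gain),
            class = "diffusion_law")
}

#' SPH water-diffusion rate
#'
#' `dw_i/dt = sum_j m_i m_j / (rho_i rho_j) (D_i + D_j) (c_j - c_i)
#' |dW|/r`: water flows down the concentration gradient, and the total
#' water mass is conserved pairwise. Reservoir particles have their rate
#' zeroed (fixed concentration, the injected mass is logged by the run
#' loop); pairs in which either side has zero diffusivity do not exchange.
#'
#' @param sys A [particle_system] (uses the per-particle `diffusivity`).
#' @param nl A [neighbor_list].
#' @param spec A [kernel_spec].
#' @return `dw/dt` (kg/s) per particle.
#' @export
mass_diffusion_rhs <- function(sys, nl, spec) {
  dw <- cpp_pair_laplacian(nl$i, nl$j, nl$r, sys$mass, sys$density,
                           sys$diffusivity, sys$concentration, spec$h,
                           sys$n)
  dw[sys$reservoir | sys$phase == PH_WALL] <- 0
  dw
}

#' Apply swelling to soil particles
#'
#' Each soil particle's area (2D volume) grows by `swell_gain` per unit
#' absorbed water: `A = A_dry + gain * w`, the radius follows from the
#' area, the mass is the dry mass plus the water mass, and the density is
#' recomputed from mass over area.
#'
#' @param sys A [particle_system].
#' @param law A [diffusion_law].
#' @param which_particles Logical mask of swelling particles; defaults to
#'   non-reservoir particles with positive diffusivity (the soil).
#' @return The updated [particle_system].
#' @export
apply_swelling <- function(sys, law, which_particles = NULL) {
  if (is.null(which_particles))
    which_particles <- sys$diffusivity > 0 & !sys$reservoir &
      sys$phase != PH_WALL
  s <- which_particles
  if (!any(s)) return(sys)
  area <- pi * sys$dry_radius[s]^2 + law$swell_gain * sys$water[s]
  sys$radius[s] <- sqrt(area / pi)
  sys$mass[s] <- sys$dry_mass[s] + sys$water[s]
  sys$density[s] <- sys$mass[s] / area
  sys
}

#' Concentration-scaled adhesion strength
#'
#' `eps_eff = eps * max(0, 1 - c_pair / c_rel)` with `c_pair` the mean
#' concentration of the pair: full adhesion when dry, linear decay with
#' water content, and no adhesive well at or beyond the release threshold.
#'
#' @param ci,cj Concentrations of the two pair members; vectorized.
#' @param eps Zero-water well depth (J).
#' @param law A [diffusion_law].
#' @return Effective well depths (J).
#' @export
scale_adhesion <- function(ci, cj, eps, law) {
  cbar <- 0.5 * (ci + cj)
  eps * pmax(0, 1 - cbar / law$c_rel)
}

#' Stokes drag in a quiescent fluid
#'
#' `F_i = -6 pi mu r_i v_i` on every mobile particle: the drag mode used
#' when the surrounding water is stagnant and no SPH component is carried
#' (the pin-array cell sorter). Opposes motion, zero at rest, and
#' recovers ballistic motion at `mu = 0`.
#'
#' @param sys A [particle_system].
#' @param mu Dynamic viscosity of the ambient fluid (kg m^-1 s^-1).
#' @return List with `fx`, `fy` (N).
#' @export
stokes_drag <- function(sys, mu) {
  mob <- sys$phase != PH_WALL
  coef <- -6 * pi * mu * sys$radius * mob
  list(fx = coef * sys$vx, fy = coef * sys$vy)
}
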