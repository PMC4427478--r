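#' Thermal and phase-change law
#'
#' Caloric equation of state with latent heat, Newton surface cooling, and
#' the bond-formation rule applied on solidification. The caloric EOS is
#' piecewise linear in specific internal energy `e` (reference energy and
#' temperature both zero): `T = e / cv_solid` below the solidus `e_sol`,
#' `T = T_star` on the latent plateau `[e_sol, e_liq]`, and
#' `T = (e - e_liq) / cv_liquid + T_star` above the liquidus. Setting
#' `e_sol = e_liq` collapses the plateau (no latent heat).
#'
#' @param kappa Thermal conductivity of the bulk material
#'   (J s^-1 m^-1 K^-1).
#' @param cv_solid,cv_liquid Heat capacities (J kg^-1 K^-1).
#' @param T_star Transition temperature (deg C).
#' @param e_sol,e_liq Solidus/liquidus specific internal energies (J/kg),
#'   `e_sol <= e_liq`. Continuity at the solidus requires
#'   `e_sol = cv_solid * T_star`.
#' @param k_T Newton cooling rate towards the ambient (1/s).
#' @param T_air Ambient temperature (deg C).
#' @param coord_threshold Particles with coordination number (cutoff `h`)
#'   below this are treated as free-surface particles and cooled.
#' @param bond_radius Neighbor-search radius for bond formation on
#'   solidification (m).
#' @param bond_kb,bond_r0,bond_rmax Parameters of the harmonic bonds formed
#'   on solidification (`rmax = NA` for unbreakable).
#' @param blend_T_range Optional `c(T_low, T_high)`: when set, the
#'   SPH/DEM blending fraction ramps linearly with temperature over this
#'   window (the sub-scale-solids rheology) instead of following the
#'   latent-plateau liquid fraction.
#' @return An object of class `thermal_law`.
#' @export
thermal_law <- function(kappa, cv_solid, cv_liquid, T_star, e_sol, e_liq,
                        k_T = 0, T_air = 0, coord_threshold = 5.5,
                        bond_radius = 0, bond_kb = 0, bond_r0 = 0,
                        bond_rmax = NA, blend_T_range = NULL) {
  stopifnot(kappa >= 0, cv_solid > 0, cv_liquid > 0, e_sol <= e_liq)
  if (abs(e_sol - cv_solid * T_star) > 1e-9 * max(1, abs(e_sol)))
    warning("caloric EOS discontinuous at the solidus: e_sol != cv_solid * T_star")
  structure(list(kappa = kappa, cv_solid = cv_solid, cv_liquid = cv_liquid,
                 T_star = T_star, e_sol = e_sol, e_liq = e_liq,
                 k_T = k_T, T_air = T_air,
                 coord_threshold = coord_threshold,
                 bond_radius = bond_radius, bond_kb = bond_kb,
                 bond_r0 = bond_r0, bond_rmax = bond_rmax,
                 blend_T_range = blend_T_range),
            class = "thermal_law")
}

#' SPH heat-conduction rate
#'
#' `de_i/dt = (1/m_i) sum_j m_i m_j / (rho_i rho_j) (kappa_i + kappa_j)
#' (T_j - T_i) |dW|/r`: heat flows from hot to cold and the total thermal
#' energy `sum m_i e_i` is conserved pairwise in a closed system. Pairs in
#' which either particle has zero conductivity do not exchange heat.
#'
#' @param sys A [particle_system] (uses the per-particle `kappa` field, so
#'   walls may conduct differently from the bulk).
#' @param nl A [neighbor_list].
#' @param spec A [kernel_spec].
#' @return `de/dt` (J kg^-1 s^-1) per particle.
#' @export
heat_conduction_rhs <- function(sys, nl, spec) {
  Q <- cpp_pair_laplacian(nl$i, nl$j, nl$r, sys$mass, sys$density,
                          sys$kappa, sys$temperature, spec$h, sys$n)
  Q / sys$mass
}

#' Caloric equation of state: energy to temperature and liquid fraction
#'
#' Continuous and monotone non-decreasing in `e`; exactly invertible off
#' the latent plateau. The liquid fraction is
#' `(e - e_sol) / (e_liq - e_sol)` clamped to `[0, 1]` (a step at the
#' transition energy when the plateau is collapsed).
#'
#' @param e Specific internal energies (J/kg); vectorized.
#' @param law A [thermal_law].
#' @return List with `temperature` (deg C) and `fraction` (liquid
#'   fraction in `[0, 1]`).
#' @export
energy_to_temperature <- function(e, law) {
  Tv <- ifelse(e < law$e_sol, e / law$cv_solid,
        ifelse(e > law$e_liq, (e - law$e_liq) / law$cv_liquid + law$T_star,
               law$T_star))
  if (law$e_liq > law$e_sol) {
    frac <- pmin(1, pmax(0, (e - law$e_sol) / (law$e_liq - law$e_sol)))
  } else {
    frac <- as.numeric(e >= law$e_liq)
  }
  list(temperature = Tv, fraction = frac)
}

#' Newton surface cooling
#'
#' Free-surface particles (coordination number below the threshold,
#' computed with the smoothing length as cutoff) exchange heat with a
#' virtual isothermal medium: `dT/dt = -k_T (T - T_air)`, converted to an
#' energy rate through the local caloric-EOS branch slope. On the latent
#' plateau, where the temperature rate carries no information, energy
#' drains at the rate the law would impose just above the plateau
#' (`cv_liquid * k_T * (T_star - T_air)`), keeping the flux continuous
#' across the liquidus so solidification proceeds.
#'
#' @param sys A [particle_system].
#' @param nl A [neighbor_list].
#' @param law A [thermal_law].
#' @param spec A [kernel_spec] (its `h` is the coordination cutoff).
#' @return List with `dedt` (J kg^-1 s^-1, nonzero only for surface
#'   particles) and the logical `surface` mask.
#' @export
surface_cooling <- function(sys, nl, law, spec) {
  coord <- cpp_coordination(nl$i, nl$j, nl$r, spec$h, sys$n)
  surface <- coord < law$coord_threshold & sys$phase != PH_WALL
  dedt <- numeric(sys$n)
  if (any(surface)) {
    e <- sys$energy[surface]
    Tv <- sys$temperature[surface]
    slope <- ifelse(e < law$e_sol, law$cv_solid,
             ifelse(e > law$e_liq, law$cv_liquid, NA_real_))
    dTdt <- -law$k_T * (Tv - law$T_air)
    dedt_s <- slope * dTdt
    plateau <- is.na(slope)
    dedt_s[plateau] <- -law$cv_liquid * law$k_T * (law$T_star - law$T_air)
    dedt[surface] <- dedt_s
  }
  list(dedt = dedt, surface = surface)
}

#' Solidification pass
#'
#' Particles whose energy has dropped below the solidus are relabelled
#' `SOLID`, given a fresh body id, and bonded (harmonic, with the law's
#' stiffness and rest length) to every already-solid particle within the
#' bond-search radius. A particle that solidified earlier cannot actively
#' create new bonds but can be included in bonds formed by newly
#' solidifying particles; pairs solidifying in the same step are bonded to
#' each other as well, which removes any dependence on processing order.
#'
#' @param sys A [particle_system].
#' @param nl A [neighbor_list] (its pairs are the bond-search candidates).
#' @param topo A [bond_topology].
#' @param law A [thermal_law].
#' @return List with the updated `system`, `topology` and an integer
#'   vector `new_solid` of the particles that solidified.
#' @export
solidify <- function(sys, nl, topo, law) {
  candidate <- sys$phase %in% c(PH_FLUID, PH_TRANSITION) &
    sys$energy < law$e_sol
  new_idx <- which(candidate)
  if (!length(new_idx))
    return(list(system = sys, topology = topo, new_solid = integer()))
  sys$phase[new_idx] <- PH_SOLID
  next_id <- max(c(0L, sys$body + 1L))
  sys$body[new_idx] <- next_id + seq_along(new_idx) - 1L
  is_new <- logical(sys$n); is_new[new_idx] <- TRUE
  solid <- sys$phase == PH_SOLID
  # candidate pairs within the bond-search radius where at least one side
  # is newly solid and the other is solid (old or new)
  sel <- nl$r <= law$bond_radius &
    ((is_new[nl$i] & solid[nl$j]) | (is_new[nl$j] & solid[nl$i]))
  if (any(sel)) {
    bi <- nl$i[sel]; bj <- nl$j[sel]
    key <- pair_key(bi, bj)
    fresh <- !(key %in% pair_key(topo$bonds$i, topo$bonds$j)) &
      !duplicated(key)
    if (any(fresh)) {
      nb <- data.frame(i = bi[fresh], j = bj[fresh], kb = law$bond_kb,
                       r0 = law$bond_r0, rmax = law$bond_rmax)
      topo$bonds <- rbind(topo$bonds, nb)
    }
  }
  list(system = sys, topology = topo, new_solid = new_idx)
}

#' Melting pass
#'
#' Solid particles whose energy has risen above the liquidus are
#' relabelled `FLUID`, rejoin the SPH family, and every bond referencing
#' them is destroyed.
#'
#' @param sys A [particle_system].
#' @param topo A [bond_topology].
#' @param law A [thermal_law].
#' @return List with the updated `system`, `topology` and the integer
#'   vector `melted`.
#' @export
melt <- function(sys, topo, law) {
  melted <- which(sys$phase == PH_SOLID & sys$energy > law$e_liq)
  if (!length(melted))
    return(list(system = sys, topology = topo, melted = integer()))
  sys$phase[melted] <- PH_FLUID
  sys$body[melted] <- -1L
  b <- topo$bonds
  if (nrow(b)) {
    drop <- b$i %in% melted | b$j %in% melted
    topo$bonds <- b[!drop, , drop = FALSE]
  }
  a <- topo$angles
  if (nrow(a)) {
    drop <- a$i %in% melted | a$j %in% melted | a$k %in% melted
    topo$angles <- a[!drop, , drop = FALSE]
  }
  d <- topo$dihedrals
  if (nrow(d)) {
    drop <- d$i %in% melted | d$j %in% melted | d$k %in% melted |
      d$l %in% melted
    topo$dihedrals <- d[!drop, , drop = FALSE]
  }
  list(system = sys, topology = topo, melted = melted)
}

#' SPH/DEM blending fraction
#'
#' The per-particle liquid fraction `lambda` used to mix force families
#' for partially solidified material: pure SPH at `lambda = 1`, pure DEM
#' at `lambda = 0`, and `lambda_pair F_SPH + (1 - lambda_pair) F_DEM` in
#' between, with `lambda_pair` the mean of the two particles' fractions.
#' With a `blend_T_range` set in the law, `lambda` ramps linearly with
#' temperature over that window; otherwise it is the latent-plateau liquid
#' fraction from [energy_to_temperature].
#'
#' @param sys A [particle_system].
#' @param law A [thermal_law].
#' @return Numeric vector `lambda` in `[0, 1]`.
#' @export
blend_fraction <- function(sys, law) {
  if (!is.null(law$blend_T_range)) {
    lo <- law$blend_T_range[1]; hi <- law$blend_T_range[2]
    lam <- pmin(1, pmax(0, (sys$temperature - lo) / (hi - lo)))
  } else {
    lam <- energy_to_temperature(sys$energy, law)$fraction
  }
  lam[sys$phase == PH_SOLID] <- 0
  lam
}

#' Check phase-label/topology consistency
#'
#' No `FLUID` particle may appear in any bond; asserted after every
#' solidify/melt pass.
#'
#' @param sys A [particle_system].
#' @param topo A [bond_topology].
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
check_phase_consistency <- function(sys, topo) {
  members <- unique(c(topo$bonds$i, topo$bonds$j, topo$angles$i,
                      topo$angles$j, topo$angles$k))
  if (length(members) && any(sys$phase[members] == PH_FLUID))
    stop("fluid particle participates in a bond")
  invisible(TRUE)
}
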