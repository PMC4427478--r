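#' Scenario configuration
#'
#' Full declarative description of a run: domain and boundaries, material
#' laws, external forcing, physics toggles and run control. Builders for
#' the shipped scenarios assemble these; [run_scenario] executes them.
#'
#' @param name Scenario name.
#' @param domain A [boundary_spec].
#' @param h Smoothing length (m); may be `NULL` for drag-only runs.
#' @param dt Time step (s), positive.
#' @param n_steps Number of steps.
#' @param gravity Body-force acceleration vector `c(gx, gy)` (m/s^2),
#'   applied to every non-wall particle.
#' @param fluid A [fluid_law] or `NULL`.
#' @param contact A [contact_law] or `NULL`.
#' @param coupling A [coupling_law] (fluid-solid no-penetration) or `NULL`.
#' @param thermal A [thermal_law] or `NULL`.
#' @param diffusion A [diffusion_law] or `NULL`.
#' @param drag_mu Ambient viscosity for Stokes drag (quiescent-fluid
#'   mode), or `NULL`.
#' @param physics Named list of toggles: `momentum`, `thermal`,
#'   `mass_transfer`, `blend`, `breakage`, `solidification`.
#' @param seed Random seed recorded in every output header; builders use
#'   it for any randomized placement.
#' @param output_every Observable cadence (steps).
#' @param cutoff Neighbor-search cutoff (m); one global cutoff covering
#'   kernel support, contact diameters and bond-search radius, derived
#'   automatically when `NULL`.
#' @param removal Cleaning-scenario removal rule:
#'   `list(surface_y =, height =)`, or `NULL`.
#' @param extra Free-form list for builder bookkeeping.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(name, domain, h = NULL, dt, n_steps,
                            gravity = c(0, 0), fluid = NULL, contact = NULL,
                            coupling = NULL, thermal = NULL,
                            diffusion = NULL, drag_mu = NULL,
                            physics = list(), seed = 1L,
                            output_every = 100L, cutoff = NULL,
                            removal = NULL, extra = list()) {
  stopifnot(dt > 0, n_steps >= 0)
  defaults <- list(momentum = !is.null(fluid), thermal = !is.null(thermal),
                   mass_transfer = !is.null(diffusion), blend = FALSE,
                   breakage = TRUE, solidification = !is.null(thermal))
  physics <- utils::modifyList(defaults, physics)
  cfg <- structure(
    list(name = name, domain = domain, h = h, dt = dt, n_steps = n_steps,
         gravity = gravity, fluid = fluid, contact = contact,
         coupling = coupling, thermal = thermal, diffusion = diffusion,
         drag_mu = drag_mu, physics = physics, seed = as.integer(seed),
         output_every = as.integer(output_every), cutoff = cutoff,
         removal = removal, extra = extra),
    class = "scenario_config")
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  on <- names(Filter(isTRUE, x$physics))
  cat("<scenario_config> '", x$name, "': dt = ", format(x$dt),
      " s, ", x$n_steps, " steps, physics: ",
      paste(on, collapse = ", "), ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Global neighbor cutoff: max of kernel support, contact diameter, coupling
# and adhesion cutoffs, and the solidification bond-search radius.
derive_cutoff <- function(cfg, sys) {
  cands <- c(if (!is.null(cfg$h)) 2 * cfg$h,
             if (any(sys$radius > 0)) 2 * max(sys$radius),
             if (!is.null(cfg$coupling)) cfg$coupling$rc,
             if (!is.null(cfg$diffusion)) cfg$diffusion$rc,
             if (!is.null(cfg$thermal)) cfg$thermal$bond_radius)
  if (!length(cands)) stop("cannot derive a neighbor cutoff")
  max(cands)
}

#' Route every neighbor pair to its force families
#'
#' The interaction-type dispatch: fluid-fluid pairs get SPH pressure and
#' viscous forces plus the continuity sum (Type 1); solid-solid pairs of
#' one body are handled by the bond topology (Type 2) and receive nothing
#' here; solid-solid pairs of different bodies get DEM contact forces
#' (Type 3); solid-fluid pairs get the Lennard-Jones no-penetration force
#' plus the ghost-value no-slip viscous coupling (Type 4). Wall particles
#' act as SPH dummy particles towards the fluid and as DEM bodies towards
#' solids. With blending enabled, partially solidified pairs receive
#' `lambda F_SPH + (1 - lambda) F_DEM` with `lambda` the pair-mean liquid
#' fraction. Heat conduction and water diffusion run over every pair
#' whose two members both carry the corresponding transport coefficient.
#'
#' @param sys A [particle_system].
#' @param nl A [neighbor_list] at the global cutoff.
#' @param topo A [bond_topology] (bonded pairs are excluded from DEM).
#' @param ledger A [contact_ledger].
#' @param cfg A [scenario_config].
#' @return List with force accumulators `fx`, `fy`, rates `drho`, `dedt`,
#'   `dwdt`, the updated `ledger`, and `n_capped` over-penetration events.
#' @export
dispatch_pair_forces <- function(sys, nl, topo, ledger, cfg) {
  n <- sys$n
  fx <- numeric(n); fy <- numeric(n)
  drho <- numeric(n); dedt <- numeric(n); dwdt <- numeric(n)
  n_capped <- 0L
  ph <- sys$phase
  if (any(!(ph %in% PHASES))) stop("unknown phase in system")
  spec <- if (!is.null(cfg$h)) kernel_spec(cfg$h)
  fl <- ph == PH_FLUID | ph == PH_TRANSITION
  so <- ph == PH_SOLID
  wa <- ph == PH_WALL
  fi <- fl[nl$i]; fj <- fl[nl$j]
  si <- so[nl$i]; sj <- so[nl$j]
  wi <- wa[nl$i]; wj <- wa[nl$j]
  bonded_keys <- if (nrow(topo$bonds))
    pair_key(topo$bonds$i, topo$bonds$j) else numeric(0)

  blend <- isTRUE(cfg$physics$blend) && !is.null(cfg$thermal)
  lam <- NULL
  if (blend) {
    lam <- blend_fraction(sys, cfg$thermal)
    lam_i <- ifelse(wa[nl$i], lam[nl$j], lam[nl$i])
    lam_j <- ifelse(wa[nl$j], lam[nl$i], lam[nl$j])
    lam_pair <- 0.5 * (lam_i + lam_j)
  }

  if (isTRUE(cfg$physics$momentum) && !is.null(cfg$fluid)) {
    if (blend) {
      sel <- !(wi & wj) & lam_pair > 0
      scale <- lam_pair[sel]
    } else {
      sel <- (fi & fj) | (fi & wj) | (wi & fj)
      scale <- 1
    }
    if (any(sel)) {
      sub <- nl_subset(nl, sel)
      f <- sph_momentum_forces(sys, sub, spec, cfg$fluid, scale = scale)
      fx <- fx + f$fx; fy <- fy + f$fy
      drho <- drho + continuity_rhs(sys, sub, spec, scale = scale)
    }
    # Type 4: fluid-solid interface (hard dispatch only; under blending
    # all non-wall particles belong to the one melting species)
    if (!blend) {
      sel_fs <- (fi & sj) | (si & fj)
      if (any(sel_fs)) {
        sub <- nl_subset(nl, sel_fs)
        if (!is.null(cfg$coupling)) {
          lj <- lj_pair_forces(sys, sub, cfg$coupling$eps,
                               cfg$coupling$sigma, cfg$coupling$rc,
                               fmax = lj_cap(cfg, sys, cfg$coupling$sigma))
          fx <- fx + lj$fx; fy <- fy + lj$fy
          n_capped <- n_capped + lj$n_capped
        }
        ns <- apply_no_slip(sys, sub, spec, cfg$fluid)
        fx <- fx + ns$fx; fy <- fy + ns$fy
      }
    }
  }

  # DEM contacts: inter-body solid pairs (and solid-wall), never bonded
  # pairs; under blending any pair that is not fully liquid.
  if (!is.null(cfg$contact)) {
    if (blend) {
      sel <- !(wi & wj) & lam_pair < 1
      scale <- 1 - lam_pair[sel]
    } else {
      sel <- ((si & sj) & sys$body[nl$i] != sys$body[nl$j]) |
        (si & wj) | (wi & sj)
      scale <- 1
    }
    if (any(sel) && length(bonded_keys)) {
      keys <- pair_key(nl$i, nl$j)
      sel <- sel & !(keys %in% bonded_keys)
      if (blend) scale <- (1 - lam_pair)[sel]
    }
    if (any(sel)) {
      sub <- nl_subset(nl, sel)
      dem <- dem_contact_forces(sys, sub, ledger, cfg$contact, cfg$dt,
                                scale = scale)
      fx <- fx + dem$fx; fy <- fy + dem$fy
      ledger <- dem$ledger
    } else {
      ledger <- contact_ledger()
    }
  }

  # Concentration-scaled van der Waals adhesion (soil-soil, soil-surface)
  if (!is.null(cfg$diffusion) &&
      (cfg$diffusion$eps_pair > 0 || cfg$diffusion$eps_surface > 0)) {
    dl <- cfg$diffusion
    soil <- so & sys$diffusivity > 0 & !sys$reservoir
    ss <- soil[nl$i] & soil[nl$j]
    sw <- (soil[nl$i] & wj) | (wi & soil[nl$j])
    for (case in list(list(sel = ss, eps0 = dl$eps_pair),
                      list(sel = sw, eps0 = dl$eps_surface))) {
      if (any(case$sel) && case$eps0 > 0) {
        sub <- nl_subset(nl, case$sel)
        eps_eff <- scale_adhesion(sys$concentration[sub$i],
                                  sys$concentration[sub$j],
                                  case$eps0, dl)
        lj <- lj_pair_forces(sys, sub, eps_eff, dl$sigma, dl$rc,
                             fmax = lj_cap(cfg, sys, cfg$coupling$sigma))
        fx <- fx + lj$fx; fy <- fy + lj$fy
        n_capped <- n_capped + lj$n_capped
      }
    }
  }

  if (isTRUE(cfg$physics$thermal) && !is.null(cfg$thermal)) {
    sel <- sys$kappa[nl$i] > 0 & sys$kappa[nl$j] > 0
    if (any(sel)) {
      dedt <- heat_conduction_rhs(sys, nl_subset(nl, sel), spec)
    }
    if (cfg$thermal$k_T > 0) {
      cool <- surface_cooling(sys, nl, cfg$thermal, spec)
      dedt <- dedt + cool$dedt
    }
    dedt[sys$fixed_temperature] <- 0
  }

  if (isTRUE(cfg$physics$mass_transfer) && !is.null(cfg$diffusion)) {
    sel <- sys$diffusivity[nl$i] > 0 & sys$diffusivity[nl$j] > 0
    if (any(sel)) dwdt <- mass_diffusion_rhs(sys, nl_subset(nl, sel), spec)
  }

  list(fx = fx, fy = fy, drho = drho, dedt = dedt, dwdt = dwdt,
       ledger = ledger, n_capped = n_capped)
}

# Over-penetration force cap for truncated LJ: limits the velocity kick of
# one step to a fraction of sigma per step, so a deeply penetrated pair
# (signalling a too-large dt) stays finite instead of exploding.
lj_cap <- function(cfg, sys, sigma) {
  0.05 * min(sys$mass) * sigma / cfg$dt^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply an external volumetric body force
#'
#' `force += m * f_g` for every non-wall particle: the gravity-like
#' driving force of the channel-flow scenarios.
#'
#' @param sys A [particle_system].
#' @param body_force Acceleration vector `c(gx, gy)` (m/s^2).
#' @return List with `fx`, `fy` increments (N).
#' @export
apply_external_forces <- function(sys, body_force) {
  mob <- sys$phase != PH_WALL
  list(fx = sys$mass * body_force[1] * mob,
       fy = sys$mass * body_force[2] * mob)
}

# Full force/rate evaluation for the current state.
evaluate_forces <- function(sys, topo, ledger, cfg) {
  nl <- build_neighbor_list(sys, cfg$cutoff, cfg$domain)
  out <- dispatch_pair_forces(sys, nl, topo, ledger, cfg)
  if (nrow(topo$bonds)) {
    bf <- bond_forces(sys, topo)
    out$fx <- out$fx + bf$fx; out$fy <- out$fy + bf$fy
  }
  if (nrow(topo$angles)) {
    af <- angle_forces(sys, topo)
    out$fx <- out$fx + af$fx; out$fy <- out$fy + af$fy
  }
  if (any(cfg$gravity != 0)) {
    g <- apply_external_forces(sys, cfg$gravity)
    out$fx <- out$fx + g$fx; out$fy <- out$fy + g$fy
  }
  if (!is.null(cfg$drag_mu) && cfg$drag_mu > 0) {
    d <- stokes_drag(sys, cfg$drag_mu)
    out$fx <- out$fx + d$fx; out$fy <- out$fy + d$fy
  }
  out$nl <- nl
  out
}
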