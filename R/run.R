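#' Advance the simulation by one velocity-Verlet step
#'
#' Symplectic second-order kick-drift-kick update of positions and
#' velocities, with one force evaluation per step. Wall particles advance
#' position only, by their prescribed wall velocity. Scalar fields
#' (density, specific energy, water mass) advance with the same single
#' rate evaluation; pressure, temperature and concentration are
#' re-derived from their closures after the update. The post-step pass
#' runs the phase-change state machine (melt, then solidify), bond
#' breakage, swelling, and the cleaning removal rule, in the flowchart
#' order force evaluation -> integration -> topology updates.
#'
#' @param state List with `system`, `topology`, `ledger` and `eval` (the
#'   force/rate evaluation for the current state, from the previous step
#'   or an initial [dispatch_pair_forces] pass).
#' @param cfg A [scenario_config] (with a resolved `cutoff`).
#' @param step Step number, used in diagnostics and event logs.
#' @return The updated state, carrying the evaluation at the new
#'   positions, plus accumulated `events`.
#' @export
integrate_step <- function(state, cfg, step = 1L) {
  sys <- state$system
  topo <- state$topology
  ev <- state$eval
  dt <- cfg$dt
  mob <- sys$phase != PH_WALL
  inv_m <- 1 / sys$mass

  # kick
  sys$vx <- sys$vx + 0.5 * dt * ev$fx * inv_m * mob
  sys$vy <- sys$vy + 0.5 * dt * ev$fy * inv_m * mob
  # drift (walls move with their prescribed velocity)
  sys$x <- sys$x + dt * sys$vx
  sys$y <- sys$y + dt * sys$vy
  sys <- wrap_positions(sys, cfg$domain)

  # scalar fields
  sph_carried <- sys$phase %in% c(PH_FLUID, PH_TRANSITION, PH_WALL)
  if (!is.null(cfg$fluid)) {
    sys$density <- sys$density + dt * ev$drho * sph_carried
    sys$pressure[sph_carried] <-
      tait_pressure(sys$density[sph_carried], cfg$fluid)
  }
  if (isTRUE(cfg$physics$thermal)) {
    sys$energy <- sys$energy + dt * ev$dedt
    et <- energy_to_temperature(sys$energy, cfg$thermal)
    upd <- !sys$fixed_temperature
    sys$temperature[upd] <- et$temperature[upd]
  }
  if (isTRUE(cfg$physics$mass_transfer)) {
    sys$water <- sys$water + dt * ev$dwdt
    upd <- !sys$reservoir & sys$phase != PH_WALL
    sys$concentration[upd] <- pmin(1, pmax(0,
      sys$water[upd] * sys$density[upd] / sys$mass[upd]))
    if (cfg$diffusion$swell_gain > 0)
      sys <- apply_swelling(sys, cfg$diffusion)
  }

  # second force evaluation and kick
  ev2 <- evaluate_forces(sys, topo, state$ledger, cfg)
  sys$vx <- sys$vx + 0.5 * dt * ev2$fx * inv_m * mob
  sys$vy <- sys$vy + 0.5 * dt * ev2$fy * inv_m * mob

  # periodic Shepard reinitialization of the density field
  if (!is.null(cfg$fluid) && cfg$fluid$reinit_every > 0L &&
      step %% cfg$fluid$reinit_every == 0L) {
    spec <- kernel_spec(cfg$h)
    rho_s <- shepard_density(sys, ev2$nl, spec)
    carried <- sys$phase %in% c(PH_FLUID, PH_TRANSITION, PH_WALL)
    sys$density[carried] <- rho_s[carried]
    sys$pressure[carried] <- tait_pressure(rho_s[carried], cfg$fluid)
  }

  events <- state$events
  # phase-change state machine
  if (isTRUE(cfg$physics$thermal) && isTRUE(cfg$physics$solidification)) {
    m <- melt(sys, topo, cfg$thermal)
    sys <- m$system; topo <- m$topology
    s <- solidify(sys, ev2$nl, topo, cfg$thermal)
    sys <- s$system; topo <- s$topology
    if (length(s$new_solid)) {
      events$first_solid_step[s$new_solid] <-
        ifelse(is.na(events$first_solid_step[s$new_solid]), step,
               events$first_solid_step[s$new_solid])
    }
    # relabel still-liquid particles on/off the latent plateau
    free <- sys$phase %in% c(PH_FLUID, PH_TRANSITION)
    lam <- energy_to_temperature(sys$energy, cfg$thermal)$fraction
    sys$phase[free & lam < 1] <- PH_TRANSITION
    sys$phase[free & lam >= 1] <- PH_FLUID
  }

  if (isTRUE(cfg$physics$breakage) && nrow(topo$bonds)) {
    br <- break_bonds(sys, topo, step)
    topo <- br$topology
    if (nrow(br$events))
      events$bond_breaks <- rbind(events$bond_breaks, br$events)
  }

  # irreversible removal of washed-away soil: a particle counts as removed
  # once it clears the deposit either vertically (hysteresis height above
  # the surface) or laterally (carried beyond a few diameters from its
  # initial position by the flow)
  if (!is.null(cfg$removal)) {
    soil <- sys$diffusivity > 0 & !sys$reservoir & sys$phase == PH_SOLID
    lifted <- sys$y > cfg$removal$surface_y + cfg$removal$height
    shifted <- FALSE
    if (!is.null(cfg$removal$distance)) {
      dx0 <- sys$x - events$x0
      if (cfg$domain$periodic[1]) {
        L <- diff(cfg$domain$xlim)
        dx0 <- dx0 - L * round(dx0 / L)
      }
      shifted <- abs(dx0) > cfg$removal$distance
    }
    gone <- soil & !sys$removed & (lifted | shifted)
    if (any(gone)) {
      sys$removed[gone] <- TRUE
      events$removals <- rbind(events$removals,
        data.frame(step = step, id = which(gone),
                   concentration = sys$concentration[gone]))
    }
  }

  if (any(!is.finite(sys$vx) | !is.finite(sys$vy) |
          !is.finite(sys$x) | !is.finite(sys$y))) {
    bad <- which(!is.finite(sys$vx) | !is.finite(sys$vy) |
                 !is.finite(sys$x) | !is.finite(sys$y))[1]
    stop("blow-up at step ", step, ": non-finite state for particle ", bad)
  }

  list(system = sys, topology = topo, ledger = ev2$ledger, eval = ev2,
       events = events)
}

#' Initialize an integration state
#'
#' Resolves the neighbor cutoff, performs the initial force/rate
#' evaluation, and packs the state consumed by [integrate_step] — the
#' low-level entry point for stepping a system outside [run_scenario].
#'
#' @param sys A [particle_system].
#' @param topo A [bond_topology].
#' @param cfg A [scenario_config].
#' @return List with the resolved `cfg` and the `state` for
#'   [integrate_step].
#' @export
init_state <- function(sys, topo, cfg) {
  validate_system(sys)
  if (is.null(cfg$cutoff)) cfg$cutoff <- derive_cutoff(cfg, sys)
  ev <- evaluate_forces(sys, topo, contact_ledger(), cfg)
  events <- new_event_log(sys$n)
  events$x0 <- sys$x
  list(cfg = cfg,
       state = list(system = sys, topology = topo, ledger = ev$ledger,
                    eval = ev, events = events))
}

new_event_log <- function(n) {
  list(bond_breaks = data.frame(step = integer(), i = integer(),
                                j = integer(), length = numeric()),
       removals = data.frame(step = integer(), id = integer(),
                             concentration = numeric()),
       first_solid_step = rep(NA_integer_, n),
       x0 = numeric(n))
}

#' Run a scenario
#'
#' Executes a built scenario for its configured number of steps,
#' recording the observable series at the configured cadence and,
#' optionally, writing trajectory frames. Deterministic given the
#' configuration and seed: two runs produce identical trajectories.
#'
#' @param scn A scenario bundle from [build_scenario]: list with
#'   `config`, `system`, `topology`.
#' @param n_steps Override for the configured step count.
#' @param observe_every Override for the observable cadence.
#' @param out_dir If non-`NULL`, trajectory frames and event logs are
#'   written there.
#' @param frame_every Frame-writing cadence (steps), when `out_dir` is
#'   set.
#' @param format Frame format, see [write_frame].
#' @param observer Optional `function(sys, topo, step)` returning a named
#'   numeric vector appended to each observable record (scenario-specific
#'   probes).
#' @param stop_when Optional `function(sys, topo, step)` checked at the
#'   observable cadence; the run ends early when it returns `TRUE` (e.g.
#'   "stop at first wall contact").
#' @return List of class `scenario_result` with the final `system`,
#'   `topology`, `ledger`, the `observables` data.frame, the `events`
#'   log, and the `config`.
#' @export
run_scenario <- function(scn, n_steps = NULL, observe_every = NULL,
                         out_dir = NULL, frame_every = NULL,
                         format = "csv", observer = NULL,
                         stop_when = NULL) {
  cfg <- scn$config
  if (!is.null(n_steps)) cfg$n_steps <- n_steps
  if (!is.null(observe_every)) cfg$output_every <- as.integer(observe_every)
  sys <- scn$system
  topo <- scn$topology
  ini <- init_state(sys, topo, cfg)
  cfg <- ini$cfg
  state <- ini$state
  obs <- vector("list", cfg$n_steps %/% cfg$output_every + 1L)
  obs_k <- 0L
  record <- function(step) {
    s <- state$system
    rec <- c(step = step, time = step * cfg$dt,
             px = sum(s$mass * s$vx), py = sum(s$mass * s$vy),
             kinetic = kinetic_energy(s),
             thermal = sum(s$mass * s$energy),
             water = sum(s$water),
             n_bonds = nrow(state$topology$bonds),
             n_solid = sum(s$phase == PH_SOLID),
             n_attached = sum(s$diffusivity > 0 & !s$reservoir &
                                s$phase != PH_WALL & !s$removed))
    if (!is.null(cfg$fluid)) {
      fl <- s$phase %in% c(PH_FLUID, PH_TRANSITION)
      # the flow-compressibility contract excludes the enclosed
      # cytoplasm, which the published cell census leaves deliberately
      # over-packed (a statically pressurized interior)
      bulk <- fl & s$species != "cytoplasm"
      rec <- c(rec,
        rho_dev = if (any(bulk))
          max(abs(s$density[bulk] - cfg$fluid$rho0)) / cfg$fluid$rho0
          else 0,
        rho_dev_all = if (any(fl))
          max(abs(s$density[fl] - cfg$fluid$rho0)) / cfg$fluid$rho0
          else 0)
    }
    for (sp in unique(s$species)) {
      sel <- s$species == sp & s$phase != PH_WALL
      if (any(sel))
        rec[paste0("yc_", sp)] <- sum(s$mass[sel] * s$y[sel]) /
          sum(s$mass[sel])
    }
    if (!is.null(observer)) rec <- c(rec, observer(s, state$topology, step))
    rec
  }
  obs_k <- obs_k + 1L; obs[[obs_k]] <- record(0L)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (step in seq_len(cfg$n_steps)) {
    state <- integrate_step(state, cfg, step)
    if (step %% cfg$output_every == 0L) {
      obs_k <- obs_k + 1L; obs[[obs_k]] <- record(step)
      if (!is.null(stop_when) &&
          isTRUE(stop_when(state$system, state$topology, step))) break
    }
    if (!is.null(out_dir) && !is.null(frame_every) &&
        step %% frame_every == 0L) {
      write_frame(state$system, state$topology,
                  file.path(out_dir, sprintf("frame_%06d", step)),
                  format = format, seed = cfg$seed)
      # contact-event log: the live ledger (pair, age, tangential history)
      led <- state$ledger
      if (length(led$key)) {
        write.csv(data.frame(step = step,
                             i = as.integer(led$key %/% 2^26),
                             j = as.integer(led$key %% 2^26),
                             age = led$age, xix = led$xix,
                             xiy = led$xiy),
                  file.path(out_dir, sprintf("contacts_%06d.csv", step)),
                  row.names = FALSE)
      }
    }
  }
  obs <- as.data.frame(do.call(rbind, obs[seq_len(obs_k)]))
  if (!is.null(out_dir)) {
    write.csv(obs, file.path(out_dir, "observables.csv"),
              row.names = FALSE)
    write.csv(state$events$bond_breaks,
              file.path(out_dir, "bond_breaks.csv"), row.names = FALSE)
    write.csv(state$events$removals,
              file.path(out_dir, "removals.csv"), row.names = FALSE)
  }
  structure(list(system = state$system, topology = state$topology,
                 ledger = state$ledger, observables = obs,
                 events = state$events, config = cfg),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> '", x$config$name, "': ",
      max(x$observables$step), " steps, ", x$system$n, " particles, ",
      nrow(x$topology$bonds), " bonds\n", sep = "")
  invisible(x)
}
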