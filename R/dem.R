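#' DEM contact law
#'
#' Linear spring-dashpot contact parameters. The normal force is
#' `f_n = k_n delta + m_eff gamma_n v_n` (with `v_n` the approach rate and
#' `m_eff = m_i m_j / (m_i + m_j)`), clamped to be non-adhesive; the
#' tangential force follows the history spring `-k_t xi - m_eff gamma_t v_t`
#' truncated to the Coulomb cone `|f_t| <= mu_s f_n`, sliding at
#' `mu_d f_n` beyond it.
#'
#' @param kn,kt Normal/tangential stiffness (J/m^2), positive.
#' @param gn,gt Normal/tangential damping rates (1/s), non-negative.
#' @param mus Static friction coefficient.
#' @param mud Dynamic friction coefficient; defaults to `mus`, and must
#'   not exceed it.
#' @return An object of class `contact_law`.
#' @export
contact_law <- function(kn, gn = 0, kt = 0, gt = 0, mus = 0, mud = mus) {
  stopifnot(kn > 0, kt >= 0, gn >= 0, gt >= 0, mus >= 0,
            mud >= 0, mud <= mus)
  structure(list(kn = kn, gn = gn, kt = kt, gt = gt, mus = mus, mud = mud),
            class = "contact_law")
}

#' Lennard-Jones solid-liquid coupling law
#'
#' No-penetration coupling between fluid and solid-surface particles via
#' the repulsive branch of `U = 4 eps ((sigma/r)^12 - (sigma/r)^6)`,
#' truncated at `rc <= 2^(1/6) sigma`.
#'
#' @param eps Well depth (J).
#' @param sigma Zero-crossing distance (m).
#' @param rc Cutoff (m); defaults to `sigma` (repulsion only).
#' @return An object of class `coupling_law`.
#' @export
coupling_law <- function(eps, sigma, rc = sigma) {
  stopifnot(eps >= 0, sigma > 0, rc > 0, rc <= 2^(1 / 6) * sigma + 1e-15)
  structure(list(eps = eps, sigma = sigma, rc = rc),
            class = "coupling_law")
}

#' Empty DEM contact ledger
#'
#' Per-pair contact history: accumulated tangential displacement and
#' contact age. An entry exists iff the pair currently overlaps; the
#' displacement is reset to zero when a contact begins and re-projected
#' onto the current tangent each step.
#'
#' @return A data.frame of class `contact_ledger` with columns `key`
#'   (canonical unordered-pair key), `xix`, `xiy` (m) and `age` (steps).
#' @export
contact_ledger <- function() {
  structure(data.frame(key = numeric(), xix = numeric(), xiy = numeric(),
                       age = integer()),
            class = c("contact_ledger", "data.frame"))
}

#' DEM normal force (scalar form)
#'
#' @param delta Overlap (m), non-negative.
#' @param vn Normal approach rate (m/s), positive when approaching.
#' @param meff Effective mass (kg).
#' @param law A [contact_law].
#' @return Normal force magnitude (N), clamped at zero so the dashpot
#'   never produces adhesion.
#' @export
dem_normal_force <- function(delta, vn, meff, law) {
  stopifnot(all(delta >= 0))
  pmax(0, law$kn * delta + meff * law$gn * vn)
}

#' DEM tangential force with Coulomb switch (scalar form)
#'
#' Candidate `f_t = -k_t xi - m_eff gamma_t v_t`; kept on the static
#' branch while `|f_t| <= mu_s f_n`, otherwise slides at `mu_d f_n`
#' opposing the slip with the history displacement rescaled to the
#' sliding value.
#'
#' @param xi Accumulated tangential displacement (m, signed).
#' @param vt Tangential relative velocity (m/s).
#' @param fn Current normal force (N).
#' @param meff Effective mass (kg).
#' @param law A [contact_law].
#' @return List with `ft` (N) and the updated `xi`.
#' @export
dem_tangential_force <- function(xi, vt, fn, meff, law) {
  ft <- -law$kt * xi - meff * law$gt * vt
  slide <- abs(ft) > law$mus * fn
  if (any(slide)) {
    s <- sign(ft[slide])
    ft[slide] <- s * law$mud * fn[slide]
    if (law$kt > 0)
      xi[slide] <- -(ft[slide] + meff * law$gt * vt[slide]) / law$kt
  }
  list(ft = ft, xi = xi)
}

#' Batch DEM contact forces over a pair set, with ledger bookkeeping
#'
#' Detects the overlapping subset of the supplied inter-body pairs
#' (overlap `delta = r_i + r_j - r > 0` from the particle radii), carries
#' tangential history across steps in the ledger, and accumulates
#' spring-dashpot normal plus Coulomb tangential forces.
#'
#' @param sys A [particle_system].
#' @param nl A [neighbor_list] restricted to DEM-eligible pairs.
#' @param ledger A [contact_ledger] from the previous step.
#' @param law A [contact_law].
#' @param dt Time step (s), used to integrate the tangential displacement.
#' @param scale Optional per-pair blending weight.
#' @return List with `fx`, `fy`, the updated `ledger`, and per-contact
#'   diagnostics `fn`, `ft`, `i`, `j`.
#' @export
dem_contact_forces <- function(sys, nl, ledger, law, dt, scale = 1) {
  delta <- sys$radius[nl$i] + sys$radius[nl$j] - nl$r
  on <- delta > 0
  if (!any(on)) {
    return(list(fx = numeric(sys$n), fy = numeric(sys$n),
                ledger = contact_ledger(),
                fn = numeric(0), ft = numeric(0),
                i = integer(0), j = integer(0)))
  }
  sub <- nl_subset(nl, on)
  delta <- delta[on]
  if (length(scale) > 1) scale <- scale[on]
  key <- pair_key(sub$i, sub$j)
  prev <- match(key, ledger$key)
  xix <- ifelse(is.na(prev), 0, ledger$xix[prev])
  xiy <- ifelse(is.na(prev), 0, ledger$xiy[prev])
  age <- ifelse(is.na(prev), 0L, ledger$age[prev]) + 1L
  out <- cpp_dem_forces(sub$i, sub$j, delta, sub$ux, sub$uy,
                        sys$mass, sys$vx, sys$vy,
                        law$kn, law$gn, law$kt, law$gt, law$mus, law$mud,
                        xix, xiy, dt, as.numeric(scale), sys$n)
  new_ledger <- structure(
    list(key = key, xix = out$xix, xiy = out$xiy, age = age),
    class = c("contact_ledger", "data.frame"),
    row.names = c(NA_integer_, -length(key)))
  list(fx = out$fx, fy = out$fy, ledger = new_ledger,
       fn = out$fn, ft = out$ft, i = sub$i, j = sub$j)
}

#' Lennard-Jones pair force magnitude
#'
#' `-dU/dr` for `U = 4 eps ((sigma/r)^12 - (sigma/r)^6)`, zero at and
#' beyond the cutoff; positive values are repulsive. At `sigma` the
#' potential is zero and the force is `24 eps / sigma`, repulsive.
#'
#' @param r Pair distances (m), positive.
#' @param eps Well depth (J); recycled over pairs.
#' @param sigma Zero-crossing distance (m).
#' @param rc Cutoff (m).
#' @return Force magnitudes (N), signed (negative = attractive).
#' @export
lj_force <- function(r, eps, sigma, rc) {
  stopifnot(all(r > 0))
  sr6 <- (sigma / r)^6
  f <- 24 * eps / r * (2 * sr6^2 - sr6)
  f[r >= rc] <- 0
  f
}

#' Accumulate Lennard-Jones forces over a pair set
#'
#' Used both for the repulsive no-penetration coupling (cut at the
#' potential minimum or at `sigma`) and, with a `2.5 sigma` cutoff and a
#' per-pair concentration-scaled well depth, for van der Waals adhesion.
#' The magnitude is capped to keep over-penetrating pairs finite; a capped
#' pair signals a too-large time step and is counted in the diagnostics.
#'
#' @param sys A [particle_system].
#' @param nl A [neighbor_list] restricted to the eligible pairs.
#' @param eps Well depth (J), scalar or per-pair.
#' @param sigma,rc As in [coupling_law].
#' @param fmax Force cap (N).
#' @return List with `fx`, `fy` and `n_capped`.
#' @export
lj_pair_forces <- function(sys, nl, eps, sigma, rc, fmax = Inf) {
  cpp_lj_forces(nl$i, nl$j, nl$r, nl$ux, nl$uy, as.numeric(eps),
                sigma, rc, fmax, sys$n)
}

#' Ghost-value no-slip coupling
#'
#' Fluid particles near a solid surface experience the Morris viscous pair
#' term computed against the solid particles carrying the solid's local
#' velocity (the dummy-particle realization of zero relative slip). Zero
#' when fluid and solid move together.
#'
#' @param sys A [particle_system].
#' @param nl A [neighbor_list] restricted to fluid-solid pairs.
#' @param spec A [kernel_spec].
#' @param law A [fluid_law] providing the viscosity.
#' @param scale Optional per-pair weight.
#' @return List with `fx`, `fy`.
#' @export
apply_no_slip <- function(sys, nl, spec, law, scale = 1) {
  sph_momentum_forces(sys, nl, spec, law, scale = scale,
                      viscous_only = TRUE)
}
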