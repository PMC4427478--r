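#' Smoothing kernel specification
#'
#' The cubic-spline kernel with support radius `2h`, the default choice in
#' the weakly-compressible SPH literature. In 2D the normalization constant
#' is `10 / (7 pi h^2)`, so that the kernel integrates to one over the
#' plane. The abstraction keeps the kernel family swappable.
#'
#' @param h Smoothing length (m), positive.
#' @param family Kernel family; only `"cubic"` is shipped.
#' @return An object of class `kernel_spec` with fields `h`, `support`
#'   (`= 2h`) and `family`.
#' @export
kernel_spec <- function(h, family = "cubic") {
  stopifnot(h > 0, family == "cubic")
  structure(list(h = h, support = 2 * h, family = family,
                 w0 = 10 / (7 * pi * h^2)),
            class = "kernel_spec")
}

#' Kernel value W(r, h)
#'
#' @param r Distances (m), non-negative; vectorized.
#' @param spec A [kernel_spec].
#' @return Kernel weights (1/m^2 in 2D); zero at and beyond the support.
#' @export
kernel_value <- function(r, spec) {
  stopifnot(all(r >= 0))
  cpp_kernel_w(as.numeric(r), spec$h)
}

#' Radial kernel derivative dW/dr
#'
#' Negative for `0 < r < 2h`; the gradient of `W` with respect to `r_i` is
#' `dW/dr` times the unit vector from `j` to `i`, which is antisymmetric
#' under exchange of the pair.
#'
#' @inheritParams kernel_value
#' @return dW/dr (1/m^3 in 2D).
#' @export
kernel_grad <- function(r, spec) {
  cpp_kernel_dw(as.numeric(r), spec$h)
}

#' Weakly-compressible fluid law
#'
#' Material constants for the SPH fluid: Tait equation-of-state parameters
#' and the viscosity formulation. `"morris"` applies the physical-viscosity
#' pair term appropriate at low Reynolds number; `"monaghan"` applies the
#' artificial-viscosity form appropriate at `Re > 1`, with the alpha
#' parameter mapped from the dynamic viscosity through the standard 2D
#' relation `alpha = 8 nu / (h c0)` unless given explicitly.
#'
#' @param rho0 Rest density (kg/m^3).
#' @param c0 Sound speed at rest density (m/s).
#' @param mu Dynamic viscosity (kg m^-1 s^-1).
#' @param viscosity `"morris"` or `"monaghan"`.
#' @param alpha Monaghan artificial-viscosity parameter; derived from `mu`
#'   when `NULL`.
#' @param h Smoothing length used for the alpha mapping.
#' @param reinit_every Reinitialize the continuity-evolved density with
#'   the Shepard-filtered summation every this many steps (0 = off, the
#'   default). Used by scenarios with long-lived fluid-solid interfaces,
#'   where the continuity field otherwise drifts slowly.
#' @return An object of class `fluid_law`.
#' @export
fluid_law <- function(rho0, c0, mu, viscosity = c("morris", "monaghan"),
                      alpha = NULL, h = NULL, reinit_every = 0L) {
  viscosity <- match.arg(viscosity)
  stopifnot(rho0 > 0, c0 > 0, mu > 0)
  if (viscosity == "monaghan" && is.null(alpha)) {
    stopifnot(!is.null(h))
    alpha <- 8 * (mu / rho0) / (h * c0)
  }
  structure(list(rho0 = rho0, c0 = c0, mu = mu, viscosity = viscosity,
                 alpha = alpha, reinit_every = as.integer(reinit_every)),
            class = "fluid_law")
}

#' Tait equation of state
#'
#' `P = (c0^2 rho0 / 7) * ((rho/rho0)^7 - 1)`: the stiff water-like closure
#' that keeps density variations small at low Mach number. `P(rho0) = 0`,
#' strictly increasing in `rho`; tension (negative pressure) is permitted.
#'
#' @param rho Densities (kg/m^3), positive; vectorized.
#' @param law A [fluid_law].
#' @return Pressures (Pa).
#' @export
tait_pressure <- function(rho, law) {
  stopifnot(all(rho > 0))
  (law$c0^2 * law$rho0 / 7) * ((rho / law$rho0)^7 - 1)
}

#' SPH continuity-equation density rate
#'
#' `drho_i/dt = sum_j m_j (v_i - v_j) . grad_i W_ij` over the supplied
#' pairs. Zero exactly when all particles share one velocity; positive
#' under compression.
#'
#' @param sys A [particle_system].
#' @param nl A [neighbor_list] (or a pair subset of one).
#' @param spec A [kernel_spec].
#' @param scale Optional per-pair weight (SPH/DEM blending).
#' @return Numeric vector of `drho/dt` (kg m^-3 s^-1) for every particle.
#' @export
continuity_rhs <- function(sys, nl, spec, scale = 1) {
  cpp_continuity(nl$i, nl$j, nl$r, nl$ux, nl$uy, sys$mass,
                 sys$vx, sys$vy, spec$h, as.numeric(scale), sys$n)
}

#' SPH momentum forces (pressure + viscosity)
#'
#' Adds, for every supplied pair, the symmetrized pressure force
#' `-m_i m_j (P_i/rho_i^2 + P_j/rho_j^2 + Pi_ij) grad_i W_ij` with `Pi_ij`
#' the Monaghan artificial-viscosity term or the Morris physical-viscosity
#' pair term, per the law's formulation. Pair forces are antisymmetric, so
#' momentum conservation is structural.
#'
#' @inheritParams continuity_rhs
#' @param law A [fluid_law].
#' @param viscous_only If `TRUE`, apply only the Morris viscous term
#'   (the ghost-value no-slip coupling against solid surfaces).
#' @return List with force accumulators `fx`, `fy` (N) for every particle.
#' @export
sph_momentum_forces <- function(sys, nl, spec, law, scale = 1,
                                viscous_only = FALSE) {
  vt <- if (viscous_only) 3L
        else if (law$viscosity == "monaghan") 1L else 2L
  mu <- rep_len(law$mu, sys$n)
  cpp_sph_forces(nl$i, nl$j, nl$r, nl$ux, nl$uy, sys$mass, sys$density,
                 sys$pressure, sys$vx, sys$vy, spec$h, vt,
                 if (is.null(law$alpha)) 0 else law$alpha, law$c0,
                 mu, as.numeric(scale), sys$n)
}

#' Summation-density reinitialization
#'
#' `rho_i = sum_j m_j W_ij` including the self term; an optional
#' reinitialization of the continuity-evolved density field.
#'
#' @inheritParams continuity_rhs
#' @return Densities (kg/m^3).
#' @export
summation_density <- function(sys, nl, spec) {
  cpp_summation_density(nl$i, nl$j, nl$r, sys$mass, spec$h, sys$n)
}

#' Shepard-filtered summation density
#'
#' `rho_i = sum_j m_j W_ij / sum_j (m_j / rho_j) W_ij` (self terms
#' included): the kernel-deficiency-corrected density estimate used to
#' periodically reinitialize the continuity-evolved field near long-lived
#' fluid-solid interfaces, where the pairwise continuity sum otherwise
#' accumulates a slow bias.
#'
#' @inheritParams continuity_rhs
#' @return Densities (kg/m^3).
#' @export
shepard_density <- function(sys, nl, spec) {
  cpp_shepard_density(nl$i, nl$j, nl$r, sys$mass, sys$density, spec$h,
                      sys$n)
}
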