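---
title: "A hybrid SPH / bead-spring / DEM particle model for solid-liquid flows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid SPH / bead-spring / DEM particle model for solid-liquid flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphdem)
```

## The model

`sphdem` simulates two-dimensional dispersed solid-liquid flows by letting
three classical particle methods act on one common set of computational
particles. Every particle obeys Newton's second law,

$$ m_i \frac{d\mathbf v_i}{dt} = \sum_{j \ne i} \mathbf F_{ij} + \mathbf F_E, $$

and the physics lives entirely in the pair force $\mathbf F_{ij}$, which is
dispatched by the phase and body labels of the pair:

* **Fluid–fluid** pairs carry weakly compressible SPH: the symmetrized
  pressure force
  $-m_i m_j (P_i/\rho_i^2 + P_j/\rho_j^2 + \Pi_{ij})\nabla_i W_{ij}$
  with the cubic-spline kernel $W$ (support $2h$), density evolved by the
  SPH continuity equation
  $d\rho_i/dt = \sum_j m_j \mathbf v_{ij}\cdot\nabla_i W_{ij}$, and the
  Tait closure $P = (c_0^2\rho_0/7)\,[(\rho/\rho_0)^7 - 1]$. The viscous
  term $\Pi_{ij}$ is either Monaghan's artificial viscosity (inertial
  regimes) or Morris's physical-viscosity pair term (creeping flows); each
  scenario configuration states which one it uses.
* **Solid–solid pairs inside one body** are governed by coarse-grained
  bead-spring mechanics: harmonic pair bonds $U = k_b (r - r_0)^2$, angle
  bonds $U = k_a(\theta - \theta_0)^2$, and (in a 3D harness only, since
  the dihedral degenerates in the plane) dihedral bonds
  $U = k_d(\varphi - \varphi_0)^2$. A pair bond whose length exceeds its
  $r_{\max}$ breaks irreversibly, taking any hinge that references it.
* **Solid–solid pairs across bodies** collide through linear
  spring-dashpot DEM contacts, $f_n = k_n\delta + m_{\rm eff}\gamma_n v_n$
  (clamped non-adhesive), with a tangential history spring
  $f_t = -k_t\xi - m_{\rm eff}\gamma_t v_t$ truncated to the Coulomb cone
  $|f_t| \le \mu_s f_n$ and sliding at $\mu_d f_n$ beyond it.
* **Fluid–solid** pairs receive the interface conditions as forces: a
  truncated, purely repulsive Lennard-Jones force for no-penetration, and
  a ghost-value viscous coupling for no-slip (the solid particle enters
  the Morris viscous sum carrying the solid's local velocity).

Walls are layers of frozen particles at least one kernel support thick.
Towards the fluid they act as SPH dummy particles (their density and
pressure evolve, their velocity is the prescribed wall velocity, which is
what enforces no-slip); towards dispersed solids they act as DEM bodies.

Heat and solute transport ride on the same kernel sums. Conduction uses
the SPH second-derivative pair form
$m_i\,de_i/dt = \sum_j \frac{m_i m_j}{\rho_i\rho_j}(\kappa_i+\kappa_j)
(T_j - T_i)\,W'(r)/r$, which is pairwise antisymmetric (exact energy
conservation in closed systems) and, on a uniform lattice, converges to
$\rho\,c_v\,\partial T/\partial t = \kappa\nabla^2 T$. Water diffusion is
the same operator with $(D_i + D_j)$ and concentrations, conserving total
water mass; bulk water acts as a fixed reservoir at $c \equiv 1$. The
caloric equation of state is piecewise linear with a latent plateau:
$T = e/c_v^S$ below the solidus $e_{sol}$, $T = T^*$ on
$[e_{sol}, e_{liq}]$, and $T = (e - e_{liq})/c_v^L + T^*$ above; setting
$e_{sol} = e_{liq}$ switches the latent heat off. Free-surface particles
(coordination number below 5.5, counted within $h$) cool against a
virtual ambient by Newton's law $dT/dt = -k_T (T - T_{air})$.

Solidification and melting are a state machine: a particle crossing
$e < e_{sol}$ is relabelled solid and bonds to every already-solid
particle within the bond-search radius (it cannot actively bond later,
but can be bonded *to*; pairs solidifying in the same step bond to each
other, which removes any processing-order dependence). A solid particle
crossing $e > e_{liq}$ remelts, losing all its bonds. For rheology with
sub-scale solids the two force families can instead be *blended*:
$\mathbf F = \lambda\,\mathbf F_{\rm SPH} + (1-\lambda)\,\mathbf F_{\rm DEM}$
with $\lambda$ the pair-mean liquid fraction (lava flows use a linear
temperature ramp between solidus and fully-liquid temperature).

The quiescent-fluid mode replaces the SPH fluid entirely by Stokes drag
$\mathbf F_i = -6\pi\mu r_i \mathbf v_i$ on every bead — used by the
pin-array cell sorter, where the ambient water is stagnant.

## Numerical choices

* **Integrator.** Velocity-Verlet (kick-drift-kick): symplectic, second
  order, one force evaluation per step, standard for all three parent
  methods. Scalar fields (density, energy, water) advance with the same
  single rate evaluation. The bonded-oscillator energy drift over $10^5$
  steps at $dt = T/1000$ is bounded and non-secular (tested).
* **Neighbor search.** One global cell-binned list per step, at a cutoff
  equal to the largest of: kernel support $2h$, largest contact diameter,
  coupling/adhesion cutoffs, and the solidification bond-search radius.
  Each pair is stored once and all forces are applied equal-and-opposite
  from that single record, so momentum conservation is structural.
* **No-slip plane.** With dummy-particle walls, zero velocity is enforced
  where the wall particles sit; the effective channel width is therefore
  the distance between the two innermost wall rows, $(n_y + 1)\,\Delta L$
  for $n_y$ fluid rows. The same convention holds for fixed-temperature
  walls (Dirichlet plane on the innermost wall row) and for the
  fixed-concentration reservoir. Verified against Poiseuille, Couette,
  transient-conduction and half-space-diffusion closed forms.
* **Sound speed.** Chosen per scenario from the weak-compressibility
  rule $c_0 \ge 10\,v_{\max}$, extended where viscous or gravitational
  pressure scales dominate (e.g. $c_0 \ge 10\sqrt{gH}$ under gravity; the
  low-Reynolds channels use Morris's criterion
  $c^2 \ge \nu V/(0.01 L)$). Each configuration records its $c_0$.
  Bodies of fluid under gravity are initialized with the Tait-consistent
  hydrostatic density profile, which removes most of the start-up
  acoustic transient. Note the contract "density within 1% of rest"
  includes the *equilibrium* hydrostatic stratification
  $\approx gH/c_0^2$, which the $10\times$ rule keeps just inside 1%.
* **Density reinitialization.** Around long-lived fluid-solid interfaces
  the pairwise continuity sum accumulates a slow bias (a percent over a
  few thousand steps at the shipped resolutions). Scenarios with
  suspended bodies therefore reinitialize the density with the
  Shepard-filtered summation
  $\rho_i = \sum_j m_j W_{ij} / \sum_j (m_j/\rho_j) W_{ij}$ every 40
  steps (`reinit_every` in the fluid law; off by default), which is
  self-normalizing at walls and free surfaces and pins the field to the
  actual particle packing.
* **Degenerate inputs.** The truncated LJ force is capped at a finite
  magnitude (a capped pair signals an over-penetration, i.e. a too-large
  time step, and is counted). Angle forces guard the collinear limit;
  coincident bonded particles and zero-length angle arms are hard errors.
  Negative Tait pressure (tension) is allowed — the shipped scenarios are
  confined or gravity-dominated and no tensile-instability treatment is
  applied.
* **Solidified bodies.** Fig-style body bookkeeping assigns each freshly
  solidified particle its own body id; DEM acts between solid pairs that
  are in different bodies *and not directly bonded*, so a bonded
  solidified cluster is internally elastic while fragments collide.

## Parameters that matter

| Parameter | Units | Typical default | Role |
|---|---|---|---|
| `h` | m | $1.2{-}1.6\,\Delta L$ | kernel support, sets resolution |
| `c0` | m/s | $10\,v_{\max}$ | pressure stiffness / Mach number |
| `mu` | kg/(m s) | water-like | physical viscosity (Morris) |
| `k_b, r_0, r_max` | J/m², m, m | per scenario | bond stiffness, rest length, breakage |
| `k_a, theta_0` | J, rad | per scenario | bending stiffness and rest angle |
| `k_n, gamma_n, k_t, gamma_t, mu_s` | — | per scenario | DEM contact law |
| `eps, sigma, r_c` | J, m, m | $\sigma = \Delta L$, $r_c = \sigma$ | no-penetration coupling |
| `e_sol, e_liq, T*, c_v` | J/kg, °C | per material | caloric EOS with latent plateau |
| `k_T, T_air` | 1/s, °C | 0.02–0.5, 0 | Newton surface cooling |
| `D, c_rel` | m²/s, — | $10^{-9}$, 0.5 | water diffusion, adhesion release |

Angle rest angles printed in degrees by the sources (172.5°, 90°, 157.5°)
are accepted in degrees by the topology builders and stored in radians.
The 48-bead membrane's 172.5° is exactly the interior angle of a regular
48-gon, so the ring is force-free at rest.

## The shipped scenarios and their desk-scale variants

`build_scenario()` assembles eleven configurations: a deformable cell in
a periodic channel (2048-site fluid lattice, 48-bead membrane, 61-bead
cytoplasm), the same cell against an obstacle, an aspiration funnel, a
shear-driven tearing flow and a piercing spike; neutrally buoyant,
floating, and heavy brittle cubes (7×7 bead blocks) in Poiseuille flow;
casting with slow and ultrafast solidification; cleaning of a swelling
protein soil under a moving wall; lava flowing down a 30° incline with
SPH/DEM blending; and a pin-array sorter separating cells by rigidity in
the Stokes-drag mode. All printed material parameters appear verbatim in
the builder defaults and are greppable by name.

Full-scale runs use up to $10^7$ steps; the test suite and the
acceptance script run *reduced variants* that cut particle counts and
step counts by roughly two orders of magnitude while preserving the
dimensionless groups the phenomenology depends on. Where that required a
choice, the reasoning is:

* **Fluid in the cell scenarios is carved, not stacked**: lattice sites
  inside a body or wall-furniture footprint are removed so the initial
  density field is uniform; the cell cavity holds the same number of
  lattice sites as the cell inserts, so local mass balance is preserved.
* **Quiescent casting** (`quiescent = TRUE`) disables momentum and the
  pour so the solidification-ordering observable (first-solidification
  time vs distance from the mould wall) is driven purely by conduction;
  bonds are softened to `bond_kb = 10` there because the printed
  $k_b = 10^5$ J/m² demands a time step far below what pure conduction
  needs, and bond stiffness does not enter the ordering observable.
* **The desk pour** drops the melt from 2.25 m under a reduced
  $0.5\ \mathrm{m/s^2}$ body force, giving a ~3.5 s flight: long enough
  for $k_T = 0.5\ \mathrm{s^{-1}}$ surface cooling to freeze a crust
  mid-air and short enough that $k_T = 0.02$ freezes nothing — the
  contrast under test. Runs stop at first wall contact; the slamming
  phase afterwards is a deliberate acoustic transient outside the
  weak-compressibility contract and outside the tested window.
* **Cleaning** assembles the deposit at the adhesion-potential minimum
  ($2^{1/6}\sigma$ spacing): packing grains at touching diameters would
  start them deep inside the repulsive core of the published adhesion
  well ($\sigma = 5\times10^{-5}$ m exceeds the grain diameter) and the
  stored elastic energy would rattle the deposit apart. The desk variant
  compresses time two ways: the soil diffusivity is raised to
  $10^{-8}\ \mathrm{m^2/s}$ and the wall speed to
  $5\times10^{-3}$ m/s, keeping the adhesion-to-shear force margin ~6×
  so dry soil stays attached until water weakens it. The release rule is
  per particle — a grain is washed away only after *its own* water
  concentration reaches the release level — and "washed away" is
  operationalized as an irreversible flag set when a grain leaves the
  deposit footprint (laterally by more than three diameters, or lifted
  above the deposit), which makes the attached count monotone
  non-increasing by construction. In 2D without gravity the observed
  erosion mode is lateral entrainment along the wall rather than
  suspension.
* **The pin-array sorter** omits two quantities in its source
  description: the pin diameter and the bead mass. Discrimination by
  rigidity requires (i) gaps narrower than the cell diameter — 14 µm
  pins at 30 µm pitch give a 16 µm gap against a 19.9 µm cell — and
  (ii) a driving force per bead comparable to the rigid membrane's
  bending resistance, which fixes the bead mass near
  $8\times10^{-13}$ kg ($\Lambda_{\rm rigid} = 16\,m f r_0 / k_a \approx 5$,
  so rigid cells squeeze reluctantly and flexible cells, ten times
  softer, easily). The dynamics are strongly overdamped, so the ambient
  viscosity only sets the time scale; the desk variant reduces it to
  $1.1\times10^{-4}$ kg/(m s) to compress the run. Initial cell placement
  is the one seeded random element; the separation observable
  ($y_C^{\rm rigid} - y_C^{\rm flexible}$) is averaged over seeds and is
  positive on average but not in every single seed at this small cell
  count.

## What the tests do and do not show

The synthetic systems exercise one physics family each against an
independent oracle: finite differences of the potentials for every
bead-spring force; closed forms for the harmonic period, spring-dashpot
restitution, Newton cooling and Stokes terminal velocity; Fourier-series
and error-function solutions for transient conduction and half-space
diffusion; and the Poiseuille/Couette profiles for the viscous coupling.
Conservation of momentum, thermal energy and water mass is checked to
round-off over $10^4$ steps. Passing these shows the discrete operators
are implemented correctly and converge at the shipped resolutions; it
does not validate the model against laboratory data, and the reduced
phenomenology runs show the right *orderings* (which cells sort faster,
where solidification starts, when soil releases) rather than
quantitative rates.

Known limitations: 2D only; no surface tension, no density-diffusion or
tensile-instability corrections; temperature-independent viscosity and
heat capacity; viscous-dissipation heating neglected; the restitution
closed form ignores the non-adhesive clamp, which is why the verified
damping sweep stays in the lightly-to-moderately damped range
($e \gtrsim 0.8$); violent free-surface impacts (the pour slamming into
the mould) produce acoustic density spikes beyond the weakly
compressible regime and are not part of any verified window.

## A worked example

```{r example, eval = FALSE}
scn <- build_scenario("cell_channel",
                      overrides = list(nx = 32, ny = 20, n_steps = 2000))
res <- run_scenario(scn, observe_every = 500)
tail(res$observables[, c("step", "kinetic", "rho_dev", "n_bonds")], 3)
```

The observable series reports, per cadence tick, the total momentum and
kinetic energy, total thermal energy and water mass, bond and solid
counts, the worst relative density deviation, and the per-species centre
of mass (`yc_<species>`) — the separation observable of the sorter.
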