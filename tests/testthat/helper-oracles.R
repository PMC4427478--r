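# Shared oracles and stepping helpers for the test suite.

# O(N^2) all-pairs neighbor search with minimum image: the brute-force
# oracle for the cell-binned search.
brute_pair_keys <- function(sys, cutoff, dom) {
  n <- sys$n
  Lx <- diff(dom$xlim); Ly <- diff(dom$ylim)
  keys <- c()
  for (i in seq_len(n - 1)) {
    dx <- sys$x[i] - sys$x[(i + 1):n]
    dy <- sys$y[i] - sys$y[(i + 1):n]
    if (dom$periodic[1]) dx <- dx - Lx * round(dx / Lx)
    if (dom$periodic[2]) dy <- dy - Ly * round(dy / Ly)
    j <- which(dx^2 + dy^2 <= cutoff^2) + i
    keys <- c(keys, i * 1e6 + j)
  }
  keys
}

# Advance a raw system/topology/config bundle n steps; returns final state.
run_steps <- function(sys, topo, cfg, n) {
  ini <- init_state(sys, topo, cfg)
  st <- ini$state
  for (k in seq_len(n)) st <- integrate_step(st, ini$cfg, k)
  st
}

# Central finite differences of a scalar potential over 2D coordinates.
fd_forces_2d <- function(U, x, y, eps) {
  n <- length(x)
  fx <- fy <- numeric(n)
  for (i in seq_len(n)) {
    xp <- x; xm <- x; xp[i] <- x[i] + eps; xm[i] <- x[i] - eps
    fx[i] <- -(U(xp, y) - U(xm, y)) / (2 * eps)
    yp <- y; ym <- y; yp[i] <- y[i] + eps; ym[i] <- y[i] - eps
    fy[i] <- -(U(x, yp) - U(x, ym)) / (2 * eps)
  }
  list(fx = fx, fy = fy)
}

# Same for 3D coordinate matrices (dihedral harness).
fd_forces_3d <- function(U, pos, eps) {
  f <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) for (d in 1:3) {
    pp <- pos; pm <- pos
    pp[i, d] <- pos[i, d] + eps
    pm[i, d] <- pos[i, d] - eps
    f[i, d] <- -(U(pp) - U(pm)) / (2 * eps)
  }
  f
}

U_angle <- function(x, y, i, j, k, ka, th0) {
  ux <- x[i] - x[j]; uy <- y[i] - y[j]
  wx <- x[k] - x[j]; wy <- y[k] - y[j]
  ct <- (ux * wx + uy * wy) / sqrt((ux^2 + uy^2) * (wx^2 + wy^2))
  ka * (acos(pmin(1, pmax(-1, ct))) - th0)^2
}

U_dihedral <- function(pos, kd, phi0) {
  b1 <- pos[2, ] - pos[1, ]; b2 <- pos[3, ] - pos[2, ]
  b3 <- pos[4, ] - pos[3, ]
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  phi <- atan2(sum(cr(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
  d <- phi - phi0
  d <- d - 2 * pi * round(d / (2 * pi))
  kd * d^2
}

# A small fluid channel between frozen walls: the fixture for the
# Poiseuille/Couette continuum tests. The no-slip planes sit on the
# innermost wall rows, so the analytic channel width is (ny + 1) dx.
make_test_channel <- function(nx = 20, ny = 20, dx = 5e-6, rho0 = 1000,
                              mu = 0.1, wall_layers = 3, fg = 0,
                              v_top = 0, c0 = 0.05, dt = 5e-8) {
  h <- 1.3 * dx
  ys <- c(-(wall_layers:1) + 0.5, (1:ny) - 0.5,
          ny + (1:wall_layers) - 0.5) * dx
  role <- c(rep(2L, wall_layers), rep(0L, ny), rep(3L, wall_layers))
  g <- expand.grid(ix = 1:nx, k = seq_along(ys))
  wall <- role[g$k] != 0L
  sys <- particle_system(
    x = (g$ix - 0.5) * dx, y = ys[g$k],
    vx = ifelse(role[g$k] == 3L, v_top, 0),
    mass = rho0 * dx^2, density = rho0,
    phase = ifelse(wall, PHASES[["WALL"]], PHASES[["FLUID"]]),
    body = ifelse(wall, ifelse(role[g$k] == 2L, 0L, 1L), -1L))
  dom <- boundary_spec(c(0, nx * dx), c(-wall_layers * dx,
                                        (ny + wall_layers) * dx),
                       c(TRUE, FALSE))
  cfg <- scenario_config("test_channel", dom, h = h, dt = dt, n_steps = 0,
                         gravity = c(fg, 0),
                         fluid = fluid_law(rho0, c0, mu, "morris"),
                         physics = list(breakage = FALSE), cutoff = 2 * h)
  list(sys = sys, cfg = cfg, dx = dx, ny = ny,
       L = (ny + 1) * dx)  # analytic width, wall-row to wall-row
}

# Row-averaged x-velocity profile of the fluid phase.
channel_profile <- function(sys, dx) {
  fl <- sys$phase == PHASES[["FLUID"]]
  rows <- round(sys$y[fl] / dx - 0.5)
  list(y = tapply(sys$y[fl], rows, mean), v = tapply(sys$vx[fl], rows, mean))
}

l2_rel_error <- function(sim, ref) sqrt(sum((sim - ref)^2) / sum(ref^2))
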