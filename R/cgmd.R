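#' Bond topology for bead-spring solids
#'
#' The coarse-grained connectivity of the solid phase: harmonic pair bonds
#' `U = k_b (r - r0)^2`, angle bonds `U = k_a (theta - theta0)^2`, and
#' dihedral bonds `U = k_d (phi - phi0)^2`. Pair bonds may carry a breakage
#' length `rmax` (`NA` for unbreakable bonds). All indices reference
#' particles of one [particle_system].
#'
#' @param bonds data.frame with columns `i, j, kb, r0, rmax`.
#' @param angles data.frame with columns `i, j, k, ka, theta0` (vertex `j`,
#'   `theta0` in radians).
#' @param dihedrals data.frame with columns `i, j, k, l, kd, phi0`
#'   (radians). Dihedrals degenerate in the plane; they are supported for
#'   completeness and exercised in a 3D test harness, but unused by the 2D
#'   scenarios.
#' @return An object of class `bond_topology`.
#' @export
bond_topology <- function(bonds = NULL, angles = NULL, dihedrals = NULL) {
  empty_b <- data.frame(i = integer(), j = integer(), kb = numeric(),
                        r0 = numeric(), rmax = numeric())
  empty_a <- data.frame(i = integer(), j = integer(), k = integer(),
                        ka = numeric(), theta0 = numeric())
  empty_d <- data.frame(i = integer(), j = integer(), k = integer(),
                        l = integer(), kd = numeric(), phi0 = numeric())
  topo <- list(bonds = if (is.null(bonds)) empty_b else bonds,
               angles = if (is.null(angles)) empty_a else angles,
               dihedrals = if (is.null(dihedrals)) empty_d else dihedrals)
  if (nrow(topo$bonds)) {
    stopifnot(all(topo$bonds$i != topo$bonds$j),
              all(is.na(topo$bonds$rmax) | topo$bonds$rmax >= topo$bonds$r0))
    key <- pair_key(topo$bonds$i, topo$bonds$j)
    if (anyDuplicated(key)) stop("duplicate pair bonds")
  }
  class(topo) <- "bond_topology"
  topo
}

#' @export
print.bond_topology <- function(x, ...) {
  cat("<bond_topology> ", nrow(x$bonds), " pair bonds, ",
      nrow(x$angles), " angle bonds, ", nrow(x$dihedrals),
      " dihedral bonds\n", sep = "")
  invisible(x)
}

# Canonical unordered-pair key (i, j are 1-based particle indices)
pair_key <- function(i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  lo * 2^26 + hi  # exact in doubles for n < 2^26
}

#' Merge bond topologies, offsetting particle indices
#'
#' @param ... `bond_topology` objects.
#' @param offsets Integer index offset for each topology (the number of
#'   particles preceding that block in the combined system).
#' @return A single [bond_topology].
#' @export
merge_topologies <- function(..., offsets = NULL) {
  tps <- list(...)
  if (is.null(offsets)) offsets <- rep(0L, length(tps))
  stopifnot(length(offsets) == length(tps))
  shift <- function(df, off, cols) {
    if (nrow(df)) df[cols] <- df[cols] + off
    df
  }
  b <- do.call(rbind, Map(function(t, o) shift(t$bonds, o, c("i", "j")),
                          tps, offsets))
  a <- do.call(rbind, Map(function(t, o) shift(t$angles, o, c("i", "j", "k")),
                          tps, offsets))
  d <- do.call(rbind, Map(function(t, o)
    shift(t$dihedrals, o, c("i", "j", "k", "l")), tps, offsets))
  bond_topology(b, a, d)
}

#' Harmonic pair-bond forces
#'
#' `U = k_b (r - r0)^2`: restoring force of magnitude `2 k_b |r - r0|`
#' along the bond axis, equal and opposite on the pair.
#'
#' @param sys A [particle_system].
#' @param topo A [bond_topology].
#' @return List with accumulators `fx`, `fy` (N) and the current `length`
#'   of every bond (m).
#' @export
bond_forces <- function(sys, topo) {
  b <- topo$bonds
  if (!nrow(b)) return(list(fx = numeric(sys$n), fy = numeric(sys$n),
                            length = numeric(0)))
  cpp_bond_forces(b$i, b$j, b$kb, b$r0, sys$x, sys$y, sys$n)
}

#' Harmonic angle-bond forces
#'
#' `U = k_a (theta - theta0)^2` with the vertex at the middle particle.
#' The three forces are the exact negative gradient of `U`, so the net
#' force and net torque of each triplet vanish.
#'
#' @inheritParams bond_forces
#' @return List with accumulators `fx`, `fy` (N) and the current `theta`
#'   of every angle bond (radians).
#' @export
angle_forces <- function(sys, topo) {
  a <- topo$angles
  if (!nrow(a)) return(list(fx = numeric(sys$n), fy = numeric(sys$n),
                            theta = numeric(0)))
  cpp_angle_forces(a$i, a$j, a$k, a$ka, a$theta0, sys$x, sys$y, sys$n)
}

#' Harmonic dihedral forces (3D)
#'
#' `U = k_d (phi - phi0)^2` with `phi` the angle between the planes of
#' particles (1,2,3) and (2,3,4). The dihedral is undefined in the plane,
#' so this operates on explicit 3D coordinates; it is validated against
#' finite differences in a 3D harness and unused by the 2D scenarios.
#'
#' @param pos Numeric matrix `n x 3` of 3D positions.
#' @param topo A [bond_topology] with a `dihedrals` table.
#' @return List with an `n x 3` force matrix `f` and the current `phi` per
#'   dihedral (radians).
#' @export
dihedral_forces <- function(pos, topo) {
  d <- topo$dihedrals
  f <- matrix(0, nrow(pos), 3)
  phi_all <- numeric(nrow(d))
  if (!nrow(d)) return(list(f = f, phi = phi_all))
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  for (m in seq_len(nrow(d))) {
    i1 <- d$i[m]; i2 <- d$j[m]; i3 <- d$k[m]; i4 <- d$l[m]
    b1 <- pos[i2, ] - pos[i1, ]
    b2 <- pos[i3, ] - pos[i2, ]
    b3 <- pos[i4, ] - pos[i3, ]
    n1 <- cross(b1, b2); n2 <- cross(b2, b3)
    l1 <- sum(n1^2); l2 <- sum(n2^2); lb2 <- sqrt(sum(b2^2))
    if (l1 < 1e-300 || l2 < 1e-300 || lb2 < 1e-300)
      stop("degenerate plane definition in dihedral ", m)
    phi <- atan2(sum(cross(n1, n2) * b2) / lb2, sum(n1 * n2))
    phi_all[m] <- phi
    dphi <- phi - d$phi0[m]
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi)) # smallest signed diff
    dU <- 2 * d$kd[m] * dphi
    g1 <- -lb2 / l1 * n1
    g4 <- lb2 / l2 * n2
    c12 <- sum(b1 * b2) / lb2^2
    c32 <- sum(b3 * b2) / lb2^2
    g2 <- -(1 + c12) * g1 + c32 * g4
    g3 <- c12 * g1 - (1 + c32) * g4
    f[i1, ] <- f[i1, ] - dU * g1
    f[i2, ] <- f[i2, ] - dU * g2
    f[i3, ] <- f[i3, ] - dU * g3
    f[i4, ] <- f[i4, ] - dU * g4
  }
  list(f = f, phi = phi_all)
}

#' Remove over-stretched bonds
#'
#' Deletes every pair bond whose current length exceeds its `rmax`,
#' together with any angle or dihedral bond that references the broken
#' pair (a hinge with a missing arm is undefined). Breakage is
#' irreversible; re-bonding happens only through solidification.
#'
#' @inheritParams bond_forces
#' @param step Step number recorded in the event log.
#' @return List with the updated `topology` and an `events` data.frame
#'   (`step`, `i`, `j`, `length`).
#' @export
break_bonds <- function(sys, topo, step = NA_integer_) {
  b <- topo$bonds
  ev <- data.frame(step = integer(), i = integer(), j = integer(),
                   length = numeric())
  if (!nrow(b)) return(list(topology = topo, events = ev))
  len <- sqrt((sys$x[b$i] - sys$x[b$j])^2 + (sys$y[b$i] - sys$y[b$j])^2)
  broken <- !is.na(b$rmax) & len > b$rmax
  if (!any(broken)) return(list(topology = topo, events = ev))
  ev <- data.frame(step = step, i = b$i[broken], j = b$j[broken],
                   length = len[broken])
  bkey <- pair_key(b$i[broken], b$j[broken])
  topo$bonds <- b[!broken, , drop = FALSE]
  a <- topo$angles
  if (nrow(a)) {
    drop_a <- pair_key(a$j, a$i) %in% bkey | pair_key(a$j, a$k) %in% bkey
    topo$angles <- a[!drop_a, , drop = FALSE]
  }
  d <- topo$dihedrals
  if (nrow(d)) {
    drop_d <- pair_key(d$i, d$j) %in% bkey | pair_key(d$j, d$k) %in% bkey |
      pair_key(d$k, d$l) %in% bkey
    topo$dihedrals <- d[!drop_d, , drop = FALSE]
  }
  list(topology = topo, events = ev)
}

#' Build a closed membrane ring
#'
#' A ring of `n_beads` beads with consecutive pair bonds and
#' consecutive-triplet angle bonds: the single-layer membrane model with
#' elastic and bending modulus but no shear or torsional stiffness.
#' With `theta0` equal to the regular-polygon interior angle the ring is
#' force-free at rest.
#'
#' @param n_beads Number of beads, at least 3.
#' @param radius Ring radius (m). If `NULL`, derived from `r0` so that the
#'   chord between consecutive beads equals `r0`.
#' @param kb,r0,rmax Pair-bond stiffness (J/m^2), rest length (m) and
#'   breakage length (m, `NA` = unbreakable).
#' @param ka Angle stiffness (J).
#' @param theta0 Rest angle; interpreted in degrees if `degrees = TRUE`.
#'   If `NULL`, the regular-polygon interior angle `pi - 2 pi / n` is used.
#' @param degrees Interpret `theta0` in degrees?
#' @param center Ring centre (m).
#' @return List with numeric vectors `x`, `y` (bead positions, consecutive
#'   around the ring) and the local-index `topology`.
#' @export
build_membrane <- function(n_beads, radius = NULL, kb, r0, rmax = NA,
                           ka, theta0 = NULL, degrees = TRUE,
                           center = c(0, 0)) {
  stopifnot(n_beads >= 3)
  if (is.null(radius)) radius <- r0 / (2 * sin(pi / n_beads))
  if (is.null(theta0)) th0 <- pi - 2 * pi / n_beads
  else th0 <- if (degrees) theta0 * pi / 180 else theta0
  ang <- 2 * pi * (seq_len(n_beads) - 1) / n_beads
  x <- center[1] + radius * cos(ang)
  y <- center[2] + radius * sin(ang)
  nxt <- c(seq_len(n_beads)[-1], 1L)
  prv <- c(n_beads, seq_len(n_beads)[-n_beads])
  bonds <- data.frame(i = seq_len(n_beads), j = nxt, kb = kb, r0 = r0,
                      rmax = rmax)
  angles <- data.frame(i = prv, j = seq_len(n_beads), k = nxt, ka = ka,
                       theta0 = th0)
  list(x = x, y = y, topology = bond_topology(bonds, angles))
}

#' Build a braced rectangular lattice
#'
#' A rectangular block of beads with nearest-neighbor pair bonds and
#' right-angle angle bonds bracing shear: the model for brittle cubes and
#' for solidified bodies. The lattice is force-free at its rest spacing.
#'
#' @param nx,ny Beads per side, at least 2.
#' @param spacing Lattice spacing (m); also the pair-bond rest length
#'   unless `r0` is given.
#' @param kb,r0,rmax Pair-bond parameters as in [build_membrane].
#' @param ka Angle stiffness (J).
#' @param theta0 Brace rest angle, degrees by default (90 for a square
#'   lattice).
#' @param degrees Interpret `theta0` in degrees?
#' @param origin Lower-left bead position (m).
#' @return List with `x`, `y` (row-major, `nx` fastest) and the
#'   local-index `topology`.
#' @export
build_braced_lattice <- function(nx, ny, spacing, kb, r0 = spacing,
                                 rmax = NA, ka, theta0 = 90,
                                 degrees = TRUE, origin = c(0, 0)) {
  stopifnot(nx >= 2, ny >= 2)
  th0 <- if (degrees) theta0 * pi / 180 else theta0
  idx <- function(ix, iy) (iy - 1L) * nx + ix
  gx <- rep(seq_len(nx), ny); gy <- rep(seq_len(ny), each = nx)
  x <- origin[1] + (gx - 1) * spacing
  y <- origin[2] + (gy - 1) * spacing
  right <- gx < nx
  up <- gy < ny
  bonds <- rbind(
    data.frame(i = idx(gx, gy)[right], j = idx(gx + 1L, gy)[right],
               kb = kb, r0 = r0, rmax = rmax),
    data.frame(i = idx(gx, gy)[up], j = idx(gx, gy + 1L)[up],
               kb = kb, r0 = r0, rmax = rmax))
  corner <- right & up
  angles <- data.frame(i = idx(gx + 1L, gy)[corner],
                       j = idx(gx, gy)[corner],
                       k = idx(gx, gy + 1L)[corner],
                       ka = ka, theta0 = th0)
  list(x = x, y = y, topology = bond_topology(bonds, angles))
}
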