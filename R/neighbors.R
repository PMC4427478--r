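#' Boundary specification
#'
#' Per-axis boundary conditions for the rectangular simulation domain.
#' Periodic axes use the minimum-image convention in the neighbor search and
#' wrap positions after each step; wall boundaries are realized as layers of
#' frozen `WALL` particles built by the scenario builders (thick enough that
#' fluid kernels never see vacuum through a wall).
#'
#' @param xlim,ylim Domain bounds (m), length-2 numeric.
#' @param periodic Logical length-2: is the x (resp. y) axis periodic?
#' @return An object of class `boundary_spec`.
#' @export
boundary_spec <- function(xlim, ylim, periodic = c(FALSE, FALSE)) {
  stopifnot(length(xlim) == 2, length(ylim) == 2, length(periodic) == 2,
            xlim[2] > xlim[1], ylim[2] > ylim[1])
  structure(list(xlim = as.numeric(xlim), ylim = as.numeric(ylim),
                 periodic = as.logical(periodic)),
            class = "boundary_spec")
}

#' Build the neighbor pair list
#'
#' Cell-binned search for all particle pairs within `cutoff`, with the
#' minimum-image convention on periodic axes. Each pair is stored once with
#' `i < j` together with its distance and the unit separation vector
#' pointing from `j` to `i`; forces are applied equal-and-opposite from this
#' single record, which makes momentum conservation structural.
#'
#' @param sys A [particle_system].
#' @param cutoff Search radius (m), positive.
#' @param domain A [boundary_spec].
#' @return A list of class `neighbor_list` with integer vectors `i`, `j`,
#'   numerics `r`, `ux`, `uy`, and the `cutoff` used.
#' @export
build_neighbor_list <- function(sys, cutoff, domain) {
  nl <- cpp_neighbor_list(sys$x, sys$y, cutoff,
                          domain$xlim[1], domain$xlim[2],
                          domain$ylim[1], domain$ylim[2],
                          domain$periodic[1], domain$periodic[2])
  nl$cutoff <- cutoff
  class(nl) <- "neighbor_list"
  nl
}

#' @export
print.neighbor_list <- function(x, ...) {
  cat("<neighbor_list> ", length(x$i), " pairs within ",
      format(x$cutoff), " m\n", sep = "")
  invisible(x)
}

# Subset a neighbor list by a logical/integer pair index
nl_subset <- function(nl, idx) {
  out <- list(i = nl$i[idx], j = nl$j[idx], r = nl$r[idx],
              ux = nl$ux[idx], uy = nl$uy[idx], cutoff = nl$cutoff)
  class(out) <- "neighbor_list"
  out
}

# Wrap positions back into the domain on periodic axes
wrap_positions <- function(sys, domain) {
  if (domain$periodic[1]) {
    L <- diff(domain$xlim)
    sys$x <- domain$xlim[1] + (sys$x - domain$xlim[1]) %% L
  }
  if (domain$periodic[2]) {
    L <- diff(domain$ylim)
    sys$y <- domain$ylim[1] + (sys$y - domain$ylim[1]) %% L
  }
  sys
}
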