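#' Write a trajectory frame
#'
#' Writes the per-particle state (position, velocity, phase, body id,
#' temperature, concentration and the rest of the carried fields) in one
#' of three plain-text formats, with a self-describing header carrying
#' units and the scenario seed, plus a bond-table sidecar so that
#' breakage history is reconstructible.
#'
#' @param sys A [particle_system].
#' @param topo A [bond_topology]; written to `<path>.bonds.tsv`.
#' @param path Output path without extension.
#' @param format `"csv"`, `"xyz"` (extended XYZ) or `"vtk"` (legacy VTK
#'   polydata).
#' @param seed Seed recorded in the header.
#' @return The main file path, invisibly.
#' @export
write_frame <- function(sys, topo, path, format = c("csv", "xyz", "vtk"),
                        seed = NA) {
  format <- match.arg(format)
  df <- as.data.frame(sys[c("x", "y", "vx", "vy", "mass", "density",
                            "pressure", "energy", "temperature", "water",
                            "concentration", "phase", "body", "radius")])
  main <- paste0(path, ".", format)
  if (format == "csv") {
    con <- file(main, "w")
    writeLines(sprintf("# sphdem frame; n=%d; seed=%s; units=SI (m, s, kg, Pa, J/kg, degC)",
                       sys$n, seed), con)
    writeLines(paste(names(df), collapse = ","), con)
    if (sys$n > 0L) {
      num <- vapply(df, function(col) sprintf("%.17g", col),
                    character(nrow(df)))
      if (sys$n == 1L) num <- matrix(num, nrow = 1)
      writeLines(apply(num, 1, paste, collapse = ","), con)
    }
    close(con)
  } else if (format == "xyz") {
    con <- file(main, "w")
    writeLines(as.character(sys$n), con)
    writeLines(paste0(
      'Properties=species:S:1:pos:R:2:velo:R:2:mass:R:1:temperature:R:1:concentration:R:1:body:I:1 seed=',
      seed, ' units=SI'), con)
    sp <- names(PHASES)[match(sys$phase, PHASES)]
    writeLines(sprintf("%s %.17g %.17g %.17g %.17g %.17g %.17g %.17g %d",
                       sp, sys$x, sys$y, sys$vx, sys$vy, sys$mass,
                       sys$temperature, sys$concentration, sys$body), con)
    close(con)
  } else {
    con <- file(main, "w")
    writeLines(c("# vtk DataFile Version 3.0",
                 sprintf("sphdem frame seed=%s", seed),
                 "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d double", sys$n)), con)
    writeLines(sprintf("%.17g %.17g 0", sys$x, sys$y), con)
    writeLines(c(sprintf("POINT_DATA %d", sys$n),
                 "SCALARS temperature double 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.17g", sys$temperature), con)
    writeLines(c("SCALARS phase int 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%d", sys$phase), con)
    writeLines("VECTORS velocity double", con)
    writeLines(sprintf("%.17g %.17g 0", sys$vx, sys$vy), con)
    close(con)
  }
  if (!is.null(topo)) {
    bt <- paste0(path, ".bonds.tsv")
    con <- file(bt, "w")
    writeLines("# type\tindices...\tparameters...", con)
    b <- topo$bonds
    if (nrow(b))
      writeLines(sprintf("bond\t%d\t%d\t%.17g\t%.17g\t%.17g",
                         b$i, b$j, b$kb, b$r0, b$rmax), con)
    a <- topo$angles
    if (nrow(a))
      writeLines(sprintf("angle\t%d\t%d\t%d\t%.17g\t%.17g",
                         a$i, a$j, a$k, a$ka, a$theta0), con)
    close(con)
  }
  invisible(main)
}

#' Read back a CSV frame
#'
#' Round-trips the per-particle table written by [write_frame] with
#' `format = "csv"` at full precision.
#'
#' @param path Path to the `.csv` frame file.
#' @return A data.frame of per-particle fields.
#' @export
read_frame <- function(path) {
  read.csv(path, comment.char = "#")
}
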