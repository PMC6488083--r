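# Rigid rotation and translation scans of the second monomer's dipole
# around the native dimer geometry.
#
# The question answered here: is the native relative orientation of the
# first two elements of an assembly the energy minimum? The second dipole
# vector is rotated in 10-degree steps about three orthogonal axes built
# from the pair geometry (pure grid scan, no continuous optimization), and
# three alternative translational arrangements (side-by-side, top-down,
# staggered) are generated and re-scanned. Scans operate on the dipole
# abstraction (moment + application point); atoms never enter the energy
# laws. Steric clash is not modeled: unfavorable angles are reported, never
# excluded.

#' Local rotation frame of a dipole pair
#'
#' The x-axis is the unit inter-dipole distance vector; the y-axis is the
#' perpendicular to the plane of the x-axis and the second dipole's moment
#' (`unit(x cross m2)`); the z-axis completes the right-handed triad
#' (`x cross y`). When the moment is parallel to the distance vector the
#' frame is degenerate and an arbitrary perpendicular is chosen for y, with
#' a warning.
#'
#' @param d1,d2 `"pseudo_dipole"` objects with distinct application points.
#' @param warn_degenerate warn when the fallback perpendicular is used
#'   (disable where the degeneracy is expected by construction).
#' @return object of class `"local_frame"`: `origin` (d2's application
#'   point), `x_axis`, `y_axis`, `z_axis`.
#' @export
local_frame <- function(d1, d2, warn_degenerate = TRUE) {
  g <- pair_geometry(d1, d2)
  x <- g$u_r
  v <- d2$moment
  y0 <- cross3(x, v)
  if (vnorm(y0) <= 1e-9 * max(vnorm(v), 1)) {
    if (warn_degenerate)
      warning("dipole moment parallel to the pair axis: degenerate frame, ",
              "using an arbitrary perpendicular for the y-axis")
    e <- diag(3)[, which.min(abs(x))]
    y0 <- cross3(x, e)
  }
  y <- unitvec(y0)
  z <- cross3(x, y)
  structure(list(origin = d2$application_point,
                 x_axis = x, y_axis = y, z_axis = z),
            class = "local_frame")
}

#' @export
print.local_frame <- function(x, ...) {
  cat("<local_frame>\n")
  for (ax in c("x_axis", "y_axis", "z_axis"))
    cat(sprintf("  %s: (%.4f, %.4f, %.4f)\n", sub("_axis", "", ax),
                x[[ax]][1L], x[[ax]][2L], x[[ax]][3L]))
  invisible(x)
}

scan_result <- function(kind, axis, angles, energies, tie = FALSE) {
  m <- find_min_index(energies, angles)
  structure(list(kind = kind, axis = axis, angles_deg = angles,
                 energies = energies, native_energy = energies[1L],
                 min_angle_deg = angles[m$idx],
                 min_angle_signed = signed_angle(angles[m$idx]),
                 min_energy = energies[m$idx], tie = m$tie),
            class = "scan_result")
}

signed_angle <- function(a) ((a + 180) %% 360) - 180

# argmin with ties broken toward the angle closest to 0 degrees; the tie
# band scales with the energy range so it is invariant to any positive
# rescaling of the whole scan (moment magnitudes, distance unit)
find_min_index <- function(energies, angles, rel_tol = 1e-9) {
  mn <- min(energies)
  tol <- rel_tol * diff(range(energies))
  cand <- which(energies <= mn + tol)
  idx <- cand[which.min(abs(signed_angle(angles[cand])))]
  list(idx = idx, tie = length(cand) > 1L)
}

#' Grid angle of the scan minimum
#'
#' Global minimum over the angle grid; ties (e.g. a constant scan) are
#' broken toward the angle closest to 0 degrees and flagged.
#'
#' @param s a `"scan_result"`.
#' @return list: `angle_deg`, `angle_signed` (alias in (-180, 180]),
#'   `energy`, `tie`.
#' @export
find_min_angle <- function(s) {
  stopifnot(inherits(s, "scan_result"), length(s$energies) > 0L)
  list(angle_deg = s$min_angle_deg, angle_signed = s$min_angle_signed,
       energy = s$min_energy, tie = s$tie)
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "<scan %s, axis %s> native %.4g a.u.; min %.4g a.u. at %d deg (%d deg)%s\n",
    x$kind, x$axis, x$native_energy, x$min_energy, x$min_angle_deg,
    x$min_angle_signed, if (x$tie) " [tie]" else ""))
  invisible(x)
}

#' @export
plot.scan_result <- function(x, ...) {
  graphics::plot(x$angles_deg, x$energies, type = "b", pch = 16,
                 xlab = "rotation angle (deg)",
                 ylab = sprintf("%s (a.u.)",
                                if (x$kind == "hydrophobic") "enH" else "enD"),
                 main = sprintf("%s rotation scan, %s-axis", x$kind, x$axis),
                 ...)
  graphics::abline(v = x$min_angle_deg, lty = 2)
  invisible(x)
}

#' Rotation scan of the second dipole about the three frame axes
#'
#' Rotates only the second dipole's moment vector (the geometry, the
#' monomer coordinates, and the other kind's dipole are untouched) through
#' a full turn in `step_deg` steps about each axis of [local_frame()], and
#' evaluates the pair energy at each grid angle. Angle 0 is the native
#' orientation.
#'
#' @param d1,d2 `"pseudo_dipole"` objects of the same kind.
#' @param step_deg grid step in degrees (default 10).
#' @param distance_unit,r0 hydrophobic distance convention, see
#'   [energy_hydrophobic()].
#' @param warn_degenerate see [local_frame()].
#' @return named list of three `"scan_result"` (`x`, `y`, `z`).
#' @export
rotation_scan <- function(d1, d2, step_deg = 10,
                          distance_unit = "scaled", r0 = 10,
                          warn_degenerate = TRUE) {
  if (d1$kind != d2$kind) stop("cannot mix dipole kinds in a scan")
  if (!d1$defined || !d2$defined)
    stop("rotation scan requires two defined dipoles")
  fr <- local_frame(d1, d2, warn_degenerate = warn_degenerate)
  g <- pair_geometry(d1, d2)
  rs <- if (d1$kind == "hydrophobic")
    scale_distance(g$r_mag, distance_unit, r0) else g$r_mag
  kern <- if (d1$kind == "hydrophobic") en_h_kernel else en_d_kernel
  angles <- seq(0, 360 - step_deg, by = step_deg)
  out <- lapply(c(x = "x_axis", y = "y_axis", z = "z_axis"), function(ax) {
    en <- vapply(angles, function(a)
      kern(d1$moment, rotate_vector(d2$moment, fr[[ax]], a), g$u_r, rs),
      numeric(1))
    scan_result(d1$kind, sub("_axis", "", ax), angles, en)
  })
  names(out) <- c("x", "y", "z")
  out
}

#' Alternative translational arrangements of a dimer
#'
#' Generates the three schematic arrangements against which the native
#' dimer is compared, on the dipole abstraction: the second dipole's moment
#' is set parallel to the first's (keeping its own magnitude) and its
#' application point is placed at the native center distance `|r|` along
#' (1) a direction perpendicular to the first moment (`side_by_side`,
#' membrane-like), (2) the first moment's direction (`top_down`), or
#' (3) the normalized sum of both (`staggered`). The native separation is
#' preserved because larger separations only decay both energies. Each
#' arrangement is then re-scanned with [rotation_scan()].
#'
#' @param d1,d2 `"pseudo_dipole"` objects of one kind.
#' @param step_deg rotation grid step for the per-arrangement scans.
#' @param distance_unit,r0 hydrophobic distance convention.
#' @return named list (`side_by_side`, `top_down`, `staggered`); each
#'   element holds `d2` (the repositioned dipole), `energy0` (the
#'   arrangement's unrotated `"energy_value"`), and `scans` (three
#'   `"scan_result"`).
#' @export
translation_arrangements <- function(d1, d2, step_deg = 10,
                                     distance_unit = "scaled", r0 = 10) {
  if (d1$kind != d2$kind) stop("cannot mix dipole kinds")
  if (!d1$defined || !d2$defined || vnorm(d1$moment) == 0)
    stop("translation arrangements require two defined dipoles")
  g <- pair_geometry(d1, d2)
  um <- unitvec(d1$moment)
  # perpendicular displacement: component of the native r perpendicular to
  # the first moment, or an arbitrary perpendicular when r is parallel to it
  perp <- g$r_vec - sum(g$r_vec * um) * um
  if (vnorm(perp) <= 1e-9 * g$r_mag) {
    e <- diag(3)[, which.min(abs(um))]
    perp <- cross3(um, e)
  }
  u_perp <- unitvec(perp)
  # along-moment displacement keeps the native sense when there is one
  s <- sum(g$r_vec * um)
  u_par <- if (s < 0) -um else um
  dirs <- list(side_by_side = u_perp, top_down = u_par,
               staggered = unitvec(u_perp + u_par))
  lapply(dirs, function(u) {
    m2 <- vnorm(d2$moment) * um
    nd2 <- new_pseudo_dipole(d2$kind, m2,
                             d1$application_point + g$r_mag * u,
                             monomer_id = d2$monomer_id)
    list(d2 = nd2,
         energy0 = pair_energy(d1, nd2, distance_unit = distance_unit,
                               r0 = r0),
         # the top-down arrangement is frame-degenerate by construction
         scans = rotation_scan(d1, nd2, step_deg, distance_unit, r0,
                               warn_degenerate = FALSE))
  })
}
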