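# Dipole-dipole interaction pseudo-energies, consecutive-pair statistics,
# cumulative growth curves, and driver classification.
#
# Two interaction laws, both in arbitrary units (a.u.), negative =
# attractive:
#   electrostatic:  enD = -[3(u.D1)(u.D2) - D1.D2] / r^3      (4*pi*eps0 = 1)
#   hydrophobic:    enH = +[3(u.H1)(u.H2) - H1.H2] / (k e^r)  (k = 1)
# The sign flip encodes the inverted affinities of hydrophobic "charges":
# like-sign hydrophobic charges attract, so aligned H vectors attract while
# aligned D vectors repel. The two energies are never magnitude-comparable.

#' Geometry of a dipole pair
#'
#' @param d1,d2 `"pseudo_dipole"` objects; the distance vector runs from
#'   `d1`'s application point to `d2`'s.
#' @param r_vec alternatively, give the distance vector directly.
#' @return object of class `"pair_geometry"`: `r_vec`, `r_mag`, `u_r`.
#' @export
pair_geometry <- function(d1 = NULL, d2 = NULL, r_vec = NULL) {
  if (is.null(r_vec)) {
    stopifnot(inherits(d1, "pseudo_dipole"), inherits(d2, "pseudo_dipole"))
    r_vec <- d2$application_point - d1$application_point
  }
  r_vec <- check_vec3(r_vec, "r_vec")
  r_mag <- vnorm(r_vec)
  if (r_mag == 0) stop("singular geometry: coincident dipole positions")
  structure(list(r_vec = r_vec, r_mag = r_mag, u_r = r_vec / r_mag),
            class = "pair_geometry")
}

#' @export
print.pair_geometry <- function(x, ...) {
  cat(sprintf("<pair_geometry> |r| = %.3f A, u_r = (%.3f, %.3f, %.3f)\n",
              x$r_mag, x$u_r[1L], x$u_r[2L], x$u_r[3L]))
  invisible(x)
}

# reversed geometry (-r), used by symmetry checks
rev_geometry <- function(g) pair_geometry(r_vec = -g$r_vec)

# numeric kernels (moments m1, m2; unit vector u; scalar distance already
# in the unit entering the law)
en_d_kernel <- function(m1, m2, u, r)
  -(3 * sum(u * m1) * sum(u * m2) - sum(m1 * m2)) / r^3

en_h_kernel <- function(m1, m2, u, r)
  +(3 * sum(u * m1) * sum(u * m2) - sum(m1 * m2)) / exp(r)

# distance entering the exponential of the hydrophobic law
scale_distance <- function(r_ang, distance_unit, r0) {
  switch(distance_unit,
         angstrom = r_ang,
         nanometer = r_ang / 10,
         scaled = r_ang / r0,
         stop("unknown distance_unit: ", distance_unit))
}

energy_value <- function(kind, value, defined = TRUE)
  structure(list(kind = kind, value = value, defined = defined),
            class = "energy_value")

#' @export
print.energy_value <- function(x, ...) {
  cat(sprintf("<energy %s> %s a.u.%s\n", x$kind,
              formatC(x$value, digits = 6),
              if (x$defined) "" else " (undefined dipole: zero contribution)"))
  invisible(x)
}

#' Electrostatic dipole-dipole interaction energy
#'
#' Evaluates `enD = -[3(u.D1)(u.D2) - D1.D2] / r^3` with the Coulomb
#' prefactor set to 1 (arbitrary units). Negative values are attractive.
#' An undefined dipole on either side yields value 0 with
#' `defined = FALSE`.
#'
#' @param d1,d2 electrostatic `"pseudo_dipole"` objects.
#' @param g `"pair_geometry"`; defaults to the native geometry of the pair.
#' @return an `"energy_value"`.
#' @export
energy_electrostatic <- function(d1, d2, g = pair_geometry(d1, d2)) {
  if (d1$kind != "electrostatic" || d2$kind != "electrostatic")
    stop("energy_electrostatic requires two electrostatic dipoles")
  if (!d1$defined || !d2$defined)
    return(energy_value("electrostatic", 0, FALSE))
  energy_value("electrostatic",
               en_d_kernel(d1$moment, d2$moment, g$u_r, g$r_mag))
}

#' Hydrophobic dipole-dipole interaction energy
#'
#' Evaluates `enH = +[3(u.H1)(u.H2) - H1.H2] / (k e^r)` with `k = 1`
#' (arbitrary units). The plus sign inverts the electrostatic affinities:
#' aligned hydrophobic moments attract. The distance entering the
#' exponential is `r` expressed in the configured unit: `"scaled"`
#' (default) uses `r / r0` with `r0` in Angstrom, `"angstrom"` uses `r`
#' as-is, `"nanometer"` uses `r / 10`.
#'
#' @param d1,d2 hydrophobic `"pseudo_dipole"` objects.
#' @param g `"pair_geometry"`; defaults to the native geometry of the pair.
#' @param distance_unit `"scaled"`, `"angstrom"` or `"nanometer"`.
#' @param r0 length scale (Angstrom) for `distance_unit = "scaled"`.
#' @return an `"energy_value"`.
#' @export
energy_hydrophobic <- function(d1, d2, g = pair_geometry(d1, d2),
                               distance_unit = c("scaled", "angstrom",
                                                 "nanometer"), r0 = 10) {
  distance_unit <- match.arg(distance_unit)
  if (d1$kind != "hydrophobic" || d2$kind != "hydrophobic")
    stop("energy_hydrophobic requires two hydrophobic dipoles")
  if (!d1$defined || !d2$defined)
    return(energy_value("hydrophobic", 0, FALSE))
  energy_value("hydrophobic",
               en_h_kernel(d1$moment, d2$moment, g$u_r,
                           scale_distance(g$r_mag, distance_unit, r0)))
}

#' Pairwise energy for either kind
#'
#' Dispatches on the (shared) kind of the two dipoles; mixing kinds is an
#' error, never a silent computation.
#'
#' @inheritParams energy_hydrophobic
#' @return an `"energy_value"`.
#' @export
pair_energy <- function(d1, d2, g = pair_geometry(d1, d2),
                        distance_unit = "scaled", r0 = 10) {
  if (d1$kind != d2$kind)
    stop("cannot mix dipole kinds: ", d1$kind, " vs ", d2$kind)
  if (d1$kind == "electrostatic") energy_electrostatic(d1, d2, g)
  else energy_hydrophobic(d1, d2, g, distance_unit, r0)
}

# pairwise energy as a plain number (0 when undefined), plus defined flag
pair_energy_num <- function(d1, d2, control) {
  if (!d1$defined || !d2$defined) return(c(value = 0, defined = 0))
  g <- pair_geometry(d1, d2)
  e <- if (d1$kind == "electrostatic")
    en_d_kernel(d1$moment, d2$moment, g$u_r, g$r_mag)
  else
    en_h_kernel(d1$moment, d2$moment, g$u_r,
                scale_distance(g$r_mag, control$distance_unit, control$r0))
  c(value = e, defined = 1)
}

#' Mean and SD of the consecutive-pair interaction energy
#'
#' Computes the pairwise energy over ordinal-consecutive monomer pairs
#' (1-2, 2-3, ...) and returns the mean and sample (n-1) standard
#' deviation. Pairs involving an undefined dipole are excluded from the
#' statistics; with fewer than one usable pair the result is flagged
#' indeterminate.
#'
#' @param x an `"assembly"`, or a list of `"pseudo_dipole"` objects of one
#'   kind in assembly order.
#' @param kind `"electrostatic"` or `"hydrophobic"` (ignored when `x` is
#'   already a dipole list).
#' @param n_pairs optional: use only the first `n_pairs` consecutive pairs.
#' @param control see [energetics_control()].
#' @return list of class `"pair_stats"`: `mean`, `sd`, `n`, `kind`,
#'   `defined`.
#' @export
consecutive_pair_stats <- function(x, kind = c("hydrophobic",
                                               "electrostatic"),
                                   n_pairs = NULL,
                                   control = energetics_control()) {
  dip <- dipole_list(x, kind, control)
  kind <- dip[[1L]]$kind
  np <- length(dip) - 1L
  if (!is.null(n_pairs)) np <- min(np, n_pairs)
  if (np < 1L)
    return(structure(list(mean = NA_real_, sd = NA_real_, n = 0L,
                          kind = kind, defined = FALSE),
                     class = "pair_stats"))
  vals <- vapply(seq_len(np), function(i)
    pair_energy_num(dip[[i]], dip[[i + 1L]], control), numeric(2))
  use <- vals["defined", ] == 1
  e <- vals["value", use]
  structure(list(mean = if (length(e)) mean(e) else NA_real_,
                 sd = if (length(e) > 1L) stats::sd(e) else
                   if (length(e) == 1L) 0 else NA_real_,
                 n = length(e), kind = kind, defined = length(e) >= 1L),
            class = "pair_stats")
}

#' @export
print.pair_stats <- function(x, ...) {
  if (x$defined)
    cat(sprintf("<pair_stats %s> mean = %.4g +/- %.2g a.u. over %d pairs\n",
                x$kind, x$mean, x$sd, x$n))
  else
    cat(sprintf("<pair_stats %s> indeterminate (no defined pairs)\n", x$kind))
  invisible(x)
}

# accept an assembly or a ready-made dipole list
dipole_list <- function(x, kind, control) {
  if (inherits(x, "assembly"))
    return(assembly_dipoles(x, match.arg(kind, c("hydrophobic",
                                                 "electrostatic")), control))
  stopifnot(is.list(x), length(x) >= 2L,
            all(vapply(x, inherits, logical(1), "pseudo_dipole")))
  kinds <- unique(vapply(x, `[[`, character(1), "kind"))
  if (length(kinds) != 1L) stop("mixed dipole kinds in list")
  x
}

#' Cumulative assembly-energy growth curve
#'
#' The energy stored by the first `N` assembled elements is the sum of the
#' pairwise energy over all pairs among them; adding element `N` adds the
#' `N-1` new pair terms. `mode = "sequential"` grows the assembly in
#' ordinal order from element 1; `mode = "around_center"` grows it from a
#' chosen inner element outward, adding remaining monomers in order of
#' increasing application-point distance from the center element's.
#' Undefined dipoles contribute zero.
#'
#' @inheritParams consecutive_pair_stats
#' @param mode `"sequential"` or `"around_center"`.
#' @param center_ordinal ordinal of the center element for
#'   `"around_center"`.
#' @return object of class `"growth_curve"`: data.frame `points`
#'   (`N`, `energy`), plus `kind`, `mode`, `center_ordinal`, `order`
#'   (ordinals in inclusion order).
#' @export
growth_curve <- function(x, kind = c("hydrophobic", "electrostatic"),
                         mode = c("sequential", "around_center"),
                         center_ordinal = NULL,
                         control = energetics_control()) {
  mode <- match.arg(mode)
  dip <- dipole_list(x, kind, control)
  kind <- dip[[1L]]$kind
  n <- length(dip)
  if (n < 2L) stop("growth curve requires at least 2 monomers")
  ord <- seq_len(n)
  if (mode == "around_center") {
    if (is.null(center_ordinal) || center_ordinal < 1L || center_ordinal > n)
      stop("around_center mode requires a valid center_ordinal")
    ap <- t(vapply(dip, `[[`, numeric(3), "application_point"))
    d2c <- sqrt(rowSums((ap - matrix(ap[center_ordinal, ], n, 3L,
                                     byrow = TRUE))^2))
    d2c[center_ordinal] <- -Inf   # center first
    ord <- order(d2c)
  }
  energy <- numeric(n - 1L)
  acc <- 0
  for (k in 2L:n) {
    new <- dip[[ord[k]]]
    acc <- acc + sum(vapply(seq_len(k - 1L), function(i)
      pair_energy_num(dip[[ord[i]]], new, control)["value"], numeric(1)))
    energy[k - 1L] <- acc
  }
  structure(list(points = data.frame(N = 2L:n, energy = energy),
                 kind = kind, mode = mode,
                 center_ordinal = if (mode == "around_center")
                   as.integer(center_ordinal) else NA_integer_,
                 order = ord),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve %s, %s%s> N = 2..%d, E(N_max) = %.4g a.u.\n",
              x$kind, x$mode,
              if (!is.na(x$center_ordinal))
                paste0(" around ", x$center_ordinal) else "",
              max(x$points$N), x$points$energy[nrow(x$points)]))
  invisible(x)
}

#' @export
plot.growth_curve <- function(x, ...) {
  graphics::plot(x$points$N, x$points$energy, type = "b", pch = 16,
                 xlab = "N (assembled elements)",
                 ylab = sprintf("cumulative %s energy (a.u.)",
                                if (x$kind == "hydrophobic") "enH" else "enD"),
                 main = sprintf("%s growth (%s)", x$kind, x$mode), ...)
  invisible(x)
}

#' Classify the driving interaction of an assembly
#'
#' The sign pattern of the mean consecutive-pair energies decides the
#' label: both means negative (attractive) gives `dual_attractive`; only
#' `enH < 0` gives `hydrophobic_driven`; only `enD < 0` gives
#' `electrostatic_driven`; both non-negative gives `dual_repulsive`; an
#' indeterminate component gives `indeterminate`. Magnitudes are never
#' compared across kinds: both energies are in their own arbitrary units.
#'
#' @param stats_H,stats_D `"pair_stats"` for the hydrophobic and
#'   electrostatic energies over the same pair set.
#' @return object of class `"driver_classification"`.
#' @export
classify_driver <- function(stats_H, stats_D) {
  stopifnot(inherits(stats_H, "pair_stats"), inherits(stats_D, "pair_stats"),
            stats_H$kind == "hydrophobic", stats_D$kind == "electrostatic")
  label <- if (!stats_H$defined || !stats_D$defined) "indeterminate"
  else if (stats_H$mean < 0 && stats_D$mean < 0) "dual_attractive"
  else if (stats_H$mean < 0) "hydrophobic_driven"
  else if (stats_D$mean < 0) "electrostatic_driven"
  else "dual_repulsive"
  structure(list(mean_enH = stats_H$mean, sd_enH = stats_H$sd,
                 mean_enD = stats_D$mean, sd_enD = stats_D$sd,
                 n_pairs = max(stats_H$n, stats_D$n), label = label),
            class = "driver_classification")
}

#' @export
print.driver_classification <- function(x, ...) {
  cat(sprintf("<driver_classification> %s\n", x$label))
  cat(sprintf("  <enH> = %s +/- %s a.u.   <enD> = %s +/- %s a.u.   (n = %d pairs)\n",
              formatC(x$mean_enH, digits = 4), formatC(x$sd_enH, digits = 2),
              formatC(x$mean_enD, digits = 4), formatC(x$sd_enD, digits = 2),
              x$n_pairs))
  invisible(x)
}

#' Per-pair energy table
#'
#' Long table of consecutive-pair (default) or all-pairs energies of both
#' kinds, suitable for CSV export.
#'
#' @param assembly an `"assembly"`.
#' @param pairs `"consecutive"` or `"all"`.
#' @param control see [energetics_control()].
#' @return data.frame: `ordinal_i`, `ordinal_j`, `monomer_i`, `monomer_j`,
#'   `r`, `enH`, `enD`, `enH_defined`, `enD_defined`.
#' @export
pair_energy_table <- function(assembly, pairs = c("consecutive", "all"),
                              control = energetics_control()) {
  pairs <- match.arg(pairs)
  dh <- assembly_dipoles(assembly, "hydrophobic", control)
  dd <- assembly_dipoles(assembly, "electrostatic", control)
  n <- length(assembly)
  ij <- if (pairs == "consecutive")
    cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  else t(utils::combn(n, 2L))
  rows <- lapply(seq_len(nrow(ij)), function(k) {
    i <- ij[k, 1L]; j <- ij[k, 2L]
    eh <- pair_energy_num(dh[[i]], dh[[j]], control)
    ed <- pair_energy_num(dd[[i]], dd[[j]], control)
    r <- if (dh[[i]]$defined && dh[[j]]$defined)
      vnorm(dh[[j]]$application_point - dh[[i]]$application_point)
    else if (dd[[i]]$defined && dd[[j]]$defined)
      vnorm(dd[[j]]$application_point - dd[[i]]$application_point)
    else NA_real_
    data.frame(ordinal_i = i, ordinal_j = j,
               monomer_i = assembly[[i]]$monomer_id,
               monomer_j = assembly[[j]]$monomer_id,
               r = r, enH = eh["value"], enD = ed["value"],
               enH_defined = eh["defined"] == 1,
               enD_defined = ed["defined"] == 1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
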