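# Top-level interface: one call taking an assembly and a set of modelling
# conventions, returning a classed result with the per-monomer dipoles,
# the consecutive-pair energies of both kinds, and the driver
# classification.

#' Modelling conventions for the dipole energetics
#'
#' Collects every convention the coarse-grained model leaves open, with
#' the package defaults.
#'
#' @param site_mode_electrostatic residue-site convention for electrostatic
#'   charges (default `"charged_group_centroid"`: the charge sits on its
#'   physical carrier atoms).
#' @param site_mode_hydrophobic residue-site convention for hydrophobic
#'   charges (default `"sidechain_centroid"`).
#' @param include_his count His as +1 (default `FALSE`; His is mostly
#'   neutral at physiological pH).
#' @param include_termini add +1/-1 terminal charges at the backbone N/C
#'   termini (default `FALSE`: side-chain-only accounting).
#' @param scale hydrophobicity scale, default [eisenberg_scale()].
#' @param distance_unit unit of the distance entering the exponential of
#'   the hydrophobic law: `"scaled"` (r / r0, default), `"angstrom"`,
#'   `"nanometer"`.
#' @param r0 length scale in Angstrom for `distance_unit = "scaled"`
#'   (default 10, the order of the inter-monomer spacing).
#' @param application_point where a dipole "sits" for the inter-dipole
#'   distance vector: `"midpoint"` of the two charge centroids (default),
#'   the monomer `"geometric_center"`, or the positive centroid
#'   `"c_plus"`.
#' @param n_pairs number of consecutive pairs entering the summary
#'   statistics (`NULL` = all).
#' @param scan_step rotation-scan grid step in degrees.
#' @param soft_separation_range centroid-separation range (Angstrom)
#'   outside which a warning is raised; `NULL` disables the check.
#' @return list of class `"energetics_control"`.
#' @export
energetics_control <- function(site_mode_electrostatic = "charged_group_centroid",
                               site_mode_hydrophobic = "sidechain_centroid",
                               include_his = FALSE,
                               include_termini = FALSE,
                               scale = eisenberg_scale(),
                               distance_unit = c("scaled", "angstrom",
                                                 "nanometer"),
                               r0 = 10,
                               application_point = c("midpoint",
                                                     "geometric_center",
                                                     "c_plus"),
                               n_pairs = NULL,
                               scan_step = 10,
                               soft_separation_range = c(1, 10)) {
  structure(list(
    site_mode_electrostatic = match.arg(site_mode_electrostatic,
                                        c("charged_group_centroid", "calpha",
                                          "sidechain_centroid")),
    site_mode_hydrophobic = match.arg(site_mode_hydrophobic,
                                      c("sidechain_centroid", "calpha",
                                        "charged_group_centroid")),
    include_his = isTRUE(include_his),
    include_termini = isTRUE(include_termini),
    scale = scale,
    distance_unit = match.arg(distance_unit),
    r0 = r0,
    application_point = match.arg(application_point),
    n_pairs = n_pairs,
    scan_step = scan_step,
    soft_separation_range = soft_separation_range),
    class = "energetics_control")
}

# short text fingerprint of the effective conventions, embedded in outputs
control_fingerprint <- function(control) {
  paste(
    sprintf("site_e=%s", control$site_mode_electrostatic),
    sprintf("site_h=%s", control$site_mode_hydrophobic),
    sprintf("his=%s", control$include_his),
    sprintf("termini=%s", control$include_termini),
    sprintf("scale=%s", attr(control$scale, "scale_name")),
    sprintf("dist=%s", control$distance_unit),
    sprintf("r0=%g", control$r0),
    sprintf("ap=%s", control$application_point),
    sep = ";")
}

#' Dipole energetics of a protein assembly
#'
#' The main entry point: computes the electrostatic and hydrophobic pseudo
#' dipole of every monomer, the pairwise energies of consecutive monomer
#' pairs, their mean and SD for both kinds, and the driving-interaction
#' classification.
#'
#' @param assembly an `"assembly"` from [load_assembly()] or a synthetic
#'   generator.
#' @param control modelling conventions, see [energetics_control()].
#' @param n_pairs shortcut overriding `control$n_pairs`.
#' @return object of class `"assembly_energetics"` with elements
#'   `dipoles_H`, `dipoles_D` (per-monomer dipole lists), `pairs` (the
#'   consecutive-pair energy table), `stats_H`, `stats_D`,
#'   `classification`, `control`, `call`.
#' @examples
#' asm <- reference_assembly("hydrophobic_driven", n_monomers = 8)
#' fit <- assembly_energetics(asm)
#' fit
#' coef(fit)
#' @export
assembly_energetics <- function(assembly, control = energetics_control(),
                                n_pairs = control$n_pairs) {
  stopifnot(inherits(assembly, "assembly"))
  dh <- assembly_dipoles(assembly, "hydrophobic", control)
  dd <- assembly_dipoles(assembly, "electrostatic", control)
  stats_H <- consecutive_pair_stats(dh, n_pairs = n_pairs, control = control)
  stats_D <- consecutive_pair_stats(dd, n_pairs = n_pairs, control = control)
  structure(list(
    dipoles_H = dh, dipoles_D = dd,
    pairs = pair_energy_table(assembly, "consecutive", control),
    stats_H = stats_H, stats_D = stats_D,
    classification = classify_driver(stats_H, stats_D),
    n_monomers = length(assembly),
    source = attr(assembly, "source"),
    control = control, call = match.call()),
    class = "assembly_energetics")
}

#' @export
print.assembly_energetics <- function(x, ...) {
  cat("Dipole energetics of a protein assembly\n")
  if (!is.na(x$source)) cat("  source:", x$source, "\n")
  cat(sprintf("  %d monomers, %d consecutive pairs\n", x$n_monomers,
              nrow(x$pairs)))
  cl <- x$classification
  fmt <- function(m, s, n) {
    if (!is.finite(m)) "n/a (undefined dipoles)"
    else sprintf("%.4g +/- %.3g a.u. (n = %d)", m, s, n)
  }
  cat("  <enH> =", fmt(cl$mean_enH, cl$sd_enH, x$stats_H$n), "\n")
  cat("  <enD> =", fmt(cl$mean_enD, cl$sd_enD, x$stats_D$n), "\n")
  cat("  driver:", cl$label, "\n")
  invisible(x)
}

#' @export
summary.assembly_energetics <- function(object, ...) {
  structure(list(fit = object), class = "summary.assembly_energetics")
}

#' @export
print.summary.assembly_energetics <- function(x, ...) {
  print(x$fit)
  cat("\nPer-monomer dipoles:\n")
  print(dipole_table(x$fit), digits = 4)
  cat("\nConsecutive-pair energies (a.u.):\n")
  print(utils::head(x$fit$pairs, 15L), digits = 4)
  if (nrow(x$fit$pairs) > 15L)
    cat("  ...", nrow(x$fit$pairs) - 15L, "more pairs\n")
  cat("\nConventions:", control_fingerprint(x$fit$control), "\n")
  invisible(x)
}

#' @export
coef.assembly_energetics <- function(object, ...) {
  cl <- object$classification
  c(mean_enH = cl$mean_enH, sd_enH = cl$sd_enH,
    mean_enD = cl$mean_enD, sd_enD = cl$sd_enD)
}

#' @export
plot.assembly_energetics <- function(x, kind = c("hydrophobic",
                                                 "electrostatic"), ...) {
  kind <- match.arg(kind)
  e <- if (kind == "hydrophobic") x$pairs$enH else x$pairs$enD
  graphics::plot(x$pairs$ordinal_i, e, type = "h", lwd = 3,
                 xlab = "pair (i, i+1)",
                 ylab = sprintf("%s (a.u.)",
                                if (kind == "hydrophobic") "enH" else "enD"),
                 main = sprintf("consecutive-pair %s energies", kind), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Per-monomer dipole table of a fitted energetics object
#'
#' @param fit an `"assembly_energetics"` object.
#' @return data.frame: one row per monomer and kind with the moment
#'   components, total positive charge, centroid separation, application
#'   point and defined flag.
#' @export
dipole_table <- function(fit) {
  stopifnot(inherits(fit, "assembly_energetics"))
  row1 <- function(d, ordinal) data.frame(
    ordinal = ordinal, monomer_id = d$monomer_id, kind = d$kind,
    Px = d$moment[1L], Py = d$moment[2L], Pz = d$moment[3L],
    P = vnorm(d$moment), q_plus = d$q_plus, separation = d$separation,
    apx = d$application_point[1L], apy = d$application_point[2L],
    apz = d$application_point[3L], defined = d$defined,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, c(
    lapply(seq_along(fit$dipoles_H), function(i) row1(fit$dipoles_H[[i]], i)),
    lapply(seq_along(fit$dipoles_D), function(i) row1(fit$dipoles_D[[i]], i))))
  rownames(out) <- NULL
  out
}
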