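# Pseudo dipole moments of a monomer's charge distribution.
#
# Proteins rarely carry zero net (electrostatic or hydrophobic) charge, so
# the exact dipole moment sum(q_i * r_i) is origin-dependent and unusable.
# The pseudo dipole moment P = Q+ * (c+ - c-) -- total positive charge times
# the separation of the positive and negative charge centroids -- is
# translation-invariant by construction and coincides with the exact dipole
# for neutral charge sets.

#' Positive/negative charge centroids of a charge set
#'
#' @param cs a `"charge_set"`.
#' @return list with `q_plus` (sum of positive charges), `q_minus` (sum of
#'   magnitudes of negative charges), `c_plus`, `c_minus`
#'   (charge-magnitude-weighted mean positions; `NA` vector when the
#'   corresponding subset is empty).
#' @export
charge_centroids <- function(cs) {
  stopifnot(inherits(cs, "charge_set"))
  pos <- cs$q > 0; neg <- cs$q < 0
  q_plus <- sum(cs$q[pos]); q_minus <- sum(-cs$q[neg])
  c_plus <- if (any(pos))
    colSums(cs$xyz[pos, , drop = FALSE] * cs$q[pos]) / q_plus
  else rep(NA_real_, 3L)
  c_minus <- if (any(neg))
    colSums(cs$xyz[neg, , drop = FALSE] * (-cs$q[neg])) / q_minus
  else rep(NA_real_, 3L)
  list(q_plus = q_plus, q_minus = q_minus, c_plus = c_plus, c_minus = c_minus)
}

#' Construct a pseudo dipole directly from a moment vector
#'
#' Low-level constructor for tests and geometry scans where only the moment
#' and its application point matter.
#'
#' @param kind `"electrostatic"` or `"hydrophobic"`.
#' @param moment numeric 3-vector (charge x Angstrom).
#' @param application_point numeric 3-vector (Angstrom).
#' @param defined logical.
#' @param monomer_id label.
#' @return an object of class `"pseudo_dipole"`.
#' @export
new_pseudo_dipole <- function(kind, moment, application_point,
                              defined = TRUE, monomer_id = NA_character_) {
  structure(list(kind = match.arg(kind, c("electrostatic", "hydrophobic")),
                 q_plus = NA_real_, q_minus = NA_real_,
                 c_plus = rep(NA_real_, 3L), c_minus = rep(NA_real_, 3L),
                 moment = check_vec3(moment, "moment"),
                 application_point = check_vec3(application_point,
                                                "application_point"),
                 separation = NA_real_,
                 defined = isTRUE(defined), monomer_id = monomer_id),
            class = "pseudo_dipole")
}

#' Pseudo dipole moment of a charge set
#'
#' Computes P = Q+ * (c+ - c-). When either charge subset is empty the
#' dipole is undefined (`defined = FALSE`, zero moment) and contributes
#' zero energy downstream. For typical protein monomers the centroid
#' separation |c+ - c-| falls between 1 and 10 Angstrom; values outside
#' that range raise a warning (soft check), never an error.
#'
#' @param cs a `"charge_set"`.
#' @param application_point `"midpoint"` (of the two centroids; default),
#'   `"geometric_center"` (requires `center`), or `"c_plus"`. This is the
#'   point the inter-dipole distance vector joins.
#' @param center 3-vector used when `application_point = "geometric_center"`.
#' @param soft_range numeric length-2; centroid-separation range outside
#'   which a warning is emitted (set to `NULL` to disable).
#' @return an object of class `"pseudo_dipole"`.
#' @export
pseudo_dipole <- function(cs,
                          application_point = c("midpoint",
                                                "geometric_center", "c_plus"),
                          center = NULL, soft_range = NULL) {
  stopifnot(inherits(cs, "charge_set"))
  application_point <- match.arg(application_point)
  cen <- charge_centroids(cs)
  defined <- cen$q_plus > 0 && cen$q_minus > 0
  moment <- if (defined) cen$q_plus * (cen$c_plus - cen$c_minus) else c(0, 0, 0)
  sep <- if (defined) vnorm(cen$c_plus - cen$c_minus) else NA_real_
  if (defined && !is.null(soft_range) &&
      (sep < soft_range[1L] || sep > soft_range[2L]))
    warning(sprintf(
      "%s centroid separation %.2f A outside the typical %g-%g A range (%s)",
      cs$kind, sep, soft_range[1L], soft_range[2L], cs$monomer_id))
  ap <- switch(application_point,
    midpoint = if (defined) (cen$c_plus + cen$c_minus) / 2
               else rep(NA_real_, 3L),
    geometric_center = check_vec3(center, "center"),
    c_plus = cen$c_plus)
  structure(list(kind = cs$kind, q_plus = cen$q_plus, q_minus = cen$q_minus,
                 c_plus = cen$c_plus, c_minus = cen$c_minus,
                 moment = moment, application_point = ap,
                 separation = sep, defined = defined,
                 monomer_id = cs$monomer_id),
            class = "pseudo_dipole")
}

#' @export
print.pseudo_dipole <- function(x, ...) {
  if (x$defined)
    cat(sprintf(
      "<pseudo_dipole %s> %s: |P| = %.3f, P = (%.3f, %.3f, %.3f), |c+ - c-| = %.2f A\n",
      x$kind, x$monomer_id, vnorm(x$moment), x$moment[1L], x$moment[2L],
      x$moment[3L], x$separation))
  else
    cat(sprintf("<pseudo_dipole %s> %s: undefined (empty charge subset)\n",
                x$kind, x$monomer_id))
  invisible(x)
}

#' Dipole moment under alternative conventions
#'
#' Sensitivity-analysis helper: the moment recomputed as Q- * (c+ - c-)
#' (`"q_minus"`), or as the exact dipole sum(q_i * r_i) (`"exact"`,
#' origin-dependent unless the set is neutral), alongside the default
#' Q+ * (c+ - c-) (`"q_plus"`). All agree for neutral sets; conventions
#' must never be mixed within one analysis.
#'
#' @param cs a `"charge_set"`.
#' @param convention `"q_plus"`, `"q_minus"` or `"exact"`.
#' @return numeric 3-vector, with attribute `defined`.
#' @export
alternative_moment <- function(cs, convention = c("q_plus", "q_minus",
                                                  "exact")) {
  convention <- match.arg(convention)
  cen <- charge_centroids(cs)
  if (convention == "exact") {
    m <- if (length(cs$q)) colSums(cs$xyz * cs$q) else c(0, 0, 0)
    attr(m, "defined") <- TRUE
    return(m)
  }
  defined <- cen$q_plus > 0 && cen$q_minus > 0
  qfac <- if (convention == "q_plus") cen$q_plus else cen$q_minus
  m <- if (defined) qfac * (cen$c_plus - cen$c_minus) else c(0, 0, 0)
  attr(m, "defined") <- defined
  m
}

#' Both pseudo dipoles of one monomer
#'
#' Convenience wrapper: derives residue sites under the configured
#' conventions, assigns charges, and returns the electrostatic and/or
#' hydrophobic pseudo dipole. Toy monomers built by [toy_monomer()] carry
#' explicit charge sets which are used directly.
#'
#' @param monomer a `"monomer"` (or `"toy_monomer"`).
#' @param kind `"electrostatic"` or `"hydrophobic"`.
#' @param control conventions, see [energetics_control()].
#' @return a `"pseudo_dipole"`.
#' @export
monomer_dipole <- function(monomer, kind = c("electrostatic", "hydrophobic"),
                           control = energetics_control()) {
  kind <- match.arg(kind)
  cs <- monomer_charge_set(monomer, kind, control)
  pseudo_dipole(cs, application_point = control$application_point,
                center = monomer$geometric_center,
                soft_range = control$soft_separation_range)
}

# charge set of a monomer under the configured conventions
monomer_charge_set <- function(monomer, kind, control = energetics_control()) {
  if (!is.null(monomer$charge_sets)) {        # toy monomer: explicit charges
    cs <- monomer$charge_sets[[kind]]
    if (is.null(cs)) cs <- charge_set(kind, numeric(0),
                                      matrix(numeric(0), ncol = 3L),
                                      monomer$monomer_id)
    return(cs)
  }
  if (kind == "electrostatic") {
    sites <- residue_sites(monomer, control$site_mode_electrostatic)
    term <- if (control$include_termini) terminal_positions(monomer)
    electrostatic_charges(sites, include_his = control$include_his,
                          termini = term, monomer_id = monomer$monomer_id)
  } else {
    sites <- residue_sites(monomer, control$site_mode_hydrophobic)
    hydrophobic_charges(sites, scale = control$scale,
                        monomer_id = monomer$monomer_id)
  }
}

#' Dipoles of every monomer in an assembly
#'
#' @param assembly an `"assembly"`.
#' @param kind `"electrostatic"` or `"hydrophobic"`.
#' @param control see [energetics_control()].
#' @return list of `"pseudo_dipole"`, one per monomer in assembly order.
#' @export
assembly_dipoles <- function(assembly, kind, control = energetics_control()) {
  lapply(assembly, monomer_dipole, kind = kind, control = control)
}

#' Export dipole vectors as a ChimeraX BILD script
#'
#' Draws each defined dipole as an arrow of length `scale * |P|` starting
#' at its application point (hydrophobic green, electrostatic yellow).
#'
#' @param dipoles list of `"pseudo_dipole"` (mixed kinds allowed).
#' @param path output file.
#' @param scale arrow length multiplier.
#' @return invisibly, the path.
#' @export
write_dipole_bild <- function(dipoles, path, scale = 1) {
  lines <- character(0)
  for (d in dipoles) {
    if (!d$defined) next
    col <- if (d$kind == "hydrophobic") "0 0.8 0" else "0.9 0.8 0"
    tip <- d$application_point + scale * d$moment
    lines <- c(lines,
               paste(".color", col),
               sprintf(".arrow %.3f %.3f %.3f %.3f %.3f %.3f 0.3 0.6",
                       d$application_point[1L], d$application_point[2L],
                       d$application_point[3L], tip[1L], tip[2L], tip[3L]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export dipole vectors as a PyMOL CGO script
#'
#' @inheritParams write_dipole_bild
#' @return invisibly, the path.
#' @export
write_dipole_pml <- function(dipoles, path, scale = 1) {
  lines <- c("from pymol.cgo import CYLINDER, CONE", "from pymol import cmd")
  i <- 0L
  for (d in dipoles) {
    if (!d$defined) next
    i <- i + 1L
    col <- if (d$kind == "hydrophobic") c(0, 0.8, 0) else c(0.9, 0.8, 0)
    a <- d$application_point
    b <- a + 0.8 * scale * d$moment
    tip <- a + scale * d$moment
    obj <- sprintf("dipole_%s_%d", substr(d$kind, 1L, 1L), i)
    lines <- c(lines, sprintf(
      paste0("cmd.load_cgo([CYLINDER, %.3f,%.3f,%.3f, %.3f,%.3f,%.3f, 0.3,",
             " %.2f,%.2f,%.2f, %.2f,%.2f,%.2f,",
             " CONE, %.3f,%.3f,%.3f, %.3f,%.3f,%.3f, 0.6, 0.0,",
             " %.2f,%.2f,%.2f, %.2f,%.2f,%.2f, 1.0, 1.0], '%s')"),
      a[1L], a[2L], a[3L], b[1L], b[2L], b[3L],
      col[1L], col[2L], col[3L], col[1L], col[2L], col[3L],
      b[1L], b[2L], b[3L], tip[1L], tip[2L], tip[3L],
      col[1L], col[2L], col[3L], col[1L], col[2L], col[3L], obj))
  }
  writeLines(lines, path)
  invisible(path)
}
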