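# Synthetic fixtures: toy monomers with explicit point charges, helical
# assemblies with known screw symmetry, and a minimal PDB writer, so the
# whole pipeline is testable offline with closed-form expectations.

#' Build a toy monomer from explicit point charges
#'
#' A toy monomer carries explicit electrostatic and/or hydrophobic charge
#' sets that bypass the residue tables; downstream dipole and energy code
#' treats it like any other monomer. One pseudo-CA site is recorded per
#' charge position so the monomer can also be written to PDB.
#'
#' @param electrostatic,hydrophobic `NULL`, or `list(q = numeric, xyz =
#'   n-by-3 matrix)` of signed charges (Angstrom positions).
#' @param label monomer id.
#' @param ordinal assembly position.
#' @return object of class `c("toy_monomer", "monomer")`.
#' @export
toy_monomer <- function(electrostatic = NULL, hydrophobic = NULL,
                        label = "toy", ordinal = 1L) {
  if (is.null(electrostatic) && is.null(hydrophobic))
    stop("a toy monomer needs at least one charge")
  mk <- function(kind, spec) {
    if (is.null(spec)) return(NULL)
    charge_set(kind, spec$q, spec$xyz, monomer_id = label)
  }
  cs <- list(electrostatic = mk("electrostatic", electrostatic),
             hydrophobic = mk("hydrophobic", hydrophobic))
  xyz <- rbind(if (!is.null(cs$electrostatic)) cs$electrostatic$xyz,
               if (!is.null(cs$hydrophobic)) cs$hydrophobic$xyz)
  if (is.null(xyz) || nrow(xyz) == 0L) stop("a toy monomer needs at least one charge")
  atoms <- data.frame(chain = "A", resno = seq_len(nrow(xyz)), ins = "",
                      resid = "GLY", elety = "CA",
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                      stringsAsFactors = FALSE)
  m <- new_monomer(label, ordinal, atoms)
  m$charge_sets <- Filter(Negate(is.null), cs)
  class(m) <- c("toy_monomer", "monomer")
  m
}

#' Random toy charge set (seeded)
#'
#' Uniform positions in a cube of half-width `box` and uniform charges in
#' `[-qmax, qmax]` (excluding zero); optionally balanced to exact
#' neutrality by appending one compensating charge. Pure function of its
#' arguments: the seed is applied locally and the RNG state restored.
#'
#' @param n number of charges.
#' @param kind charge kind.
#' @param seed integer seed.
#' @param box half-width of the position cube (Angstrom).
#' @param qmax maximum charge magnitude.
#' @param neutral logical; force the set to sum to zero.
#' @return a `"charge_set"`.
#' @export
random_charge_set <- function(n, kind = "hydrophobic", seed = 1L, box = 10,
                              qmax = 2, neutral = FALSE) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  q <- stats::runif(n, -qmax, qmax)
  q[q == 0] <- qmax / 2
  xyz <- matrix(stats::runif(3L * n, -box, box), ncol = 3L)
  if (neutral) {
    q <- c(q, -sum(q))
    xyz <- rbind(xyz, stats::runif(3L, -box, box))
  }
  charge_set(kind, q, xyz, monomer_id = sprintf("rand%d", seed))
}

.Random.seed_save <- function()
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# rigid transform of a toy monomer: positions -> R p + t
transform_toy <- function(m, R, t, ordinal = m$ordinal,
                          label = m$monomer_id) {
  tx <- function(xyz) t(R %*% t(xyz)) + matrix(t, nrow(xyz), 3L, byrow = TRUE)
  cs_e <- m$charge_sets$electrostatic
  cs_h <- m$charge_sets$hydrophobic
  toy_monomer(
    electrostatic = if (!is.null(cs_e)) list(q = cs_e$q, xyz = tx(cs_e$xyz)),
    hydrophobic = if (!is.null(cs_h)) list(q = cs_h$q, xyz = tx(cs_h$xyz)),
    label = label, ordinal = ordinal)
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
}

#' Helical assembly of copies of a template toy monomer
#'
#' Emulates the geometry class of helicoidal protein assemblies (amyloid
#' and capsid spirals): element `k` (k = 0, 1, ...) is the template,
#' offset radially by `radius` along +x, rotated about the z (helix) axis
#' by `k * twist_per_monomer` and raised by `k * rise_per_monomer`. Charges
#' transform equivariantly, so every consecutive pair is related by the
#' same screw motion and all consecutive-pair distances are equal.
#'
#' @param template a `"toy_monomer"` (its coordinates are read as local,
#'   centered on the helix circle at angle 0).
#' @param n_monomers number of elements (>= 2).
#' @param radius helix radius in Angstrom (> 0).
#' @param rise_per_monomer axial rise per element, Angstrom.
#' @param twist_per_monomer rotation about the helix axis per element,
#'   degrees.
#' @return an `"assembly"`.
#' @export
helical_assembly <- function(template, n_monomers, radius = 20,
                             rise_per_monomer = 2, twist_per_monomer = 22.5) {
  stopifnot(inherits(template, "toy_monomer"), n_monomers >= 2L, radius > 0)
  base <- transform_toy(template, diag(3), c(radius, 0, 0))
  mons <- lapply(seq_len(n_monomers), function(k) {
    transform_toy(base, rot_z((k - 1L) * twist_per_monomer),
                  c(0, 0, (k - 1L) * rise_per_monomer),
                  ordinal = k, label = sprintf("M%02d", k))
  })
  as_assembly(mons, source = sprintf(
    "synthetic helix (n=%d, radius=%g, rise=%g, twist=%g)",
    n_monomers, radius, rise_per_monomer, twist_per_monomer))
}

# residue whose Eisenberg index matches q (NULL if none)
eisenberg_residue_for <- function(q, tol = 1e-9) {
  sc <- eisenberg_scale()
  i <- which(abs(sc - q) < tol)
  if (length(i)) names(sc)[i[1L]] else NULL
}

#' Write a toy assembly as a minimal PDB file
#'
#' One pseudo C-alpha record per charge site, one chain per monomer.
#' Residue names are chosen so the real residue tables regenerate the
#' intended charges on reload: electrostatic +1/-1 become Lys/Asp;
#' hydrophobic charges must equal an Eisenberg index and become that
#' residue. Monomers mixing both charge kinds cannot be represented
#' faithfully and are rejected.
#'
#' @param assembly an `"assembly"` of `"toy_monomer"` objects.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_toy_pdb <- function(assembly, path) {
  chains <- c(LETTERS, letters, as.character(0:9))
  if (length(assembly) > length(chains))
    stop("too many monomers for single-character chain ids")
  lines <- character(0)
  serial <- 0L
  for (k in seq_along(assembly)) {
    m <- assembly[[k]]
    stopifnot(inherits(m, "toy_monomer"))
    kinds <- names(m$charge_sets)
    if (length(kinds) != 1L)
      stop("write_toy_pdb supports single-kind toy monomers only")
    cs <- m$charge_sets[[1L]]
    for (i in seq_along(cs$q)) {
      resid <- if (kinds == "electrostatic") {
        if (abs(cs$q[i] - 1) < 1e-9) "LYS"
        else if (abs(cs$q[i] + 1) < 1e-9) "ASP"
        else stop("electrostatic toy charges must be +1 or -1 for PDB export")
      } else {
        r <- eisenberg_residue_for(cs$q[i])
        if (is.null(r))
          stop("hydrophobic toy charge ", cs$q[i],
               " does not match any Eisenberg index")
        r
      }
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, resid, chains[k], i,
        cs$xyz[i, 1L], cs$xyz[i, 2L], cs$xyz[i, 3L]))
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Reference synthetic assemblies with known driving interactions
#'
#' Three helical assemblies built so the driver classification ground
#' truth is known by construction: consecutive hydrophobic moments are
#' near-parallel side-by-side (attractive under the sign-flipped
#' hydrophobic law) while electric dipoles are likewise parallel
#' (repulsive), and vice versa; the dual-attractive case counter-aligns
#' the electric dipoles by alternating their sense along the helix. The
#' dipole templates use a centroid separation of 4 Angstrom, inside the
#' 1-10 Angstrom range typical of protein monomers.
#'
#' @param label `"hydrophobic_driven"`, `"electrostatic_driven"` or
#'   `"dual_attractive"`.
#' @param n_monomers number of elements.
#' @return an `"assembly"` with attribute `truth` (the expected label).
#' @export
reference_assembly <- function(label = c("hydrophobic_driven",
                                         "electrostatic_driven",
                                         "dual_attractive"),
                               n_monomers = 12L) {
  label <- match.arg(label)
  two <- function(sep = 4) list(q = c(1, -1),
                                xyz = rbind(c(0, 0, sep / 2),
                                            c(0, 0, -sep / 2)))
  flip <- function(s) list(q = -s$q, xyz = s$xyz)
  tpl <- switch(label,
    # moments along +z (helix axis), consecutive pairs displaced nearly
    # perpendicular to the moments: attractive for H, repulsive for D
    hydrophobic_driven = toy_monomer(hydrophobic = two(),
                                     electrostatic = two(), label = "T"),
    electrostatic_driven = toy_monomer(hydrophobic = two(),
                                       electrostatic = two(), label = "T"),
    dual_attractive = toy_monomer(hydrophobic = two(),
                                  electrostatic = two(), label = "T"))
  asm <- if (label == "dual_attractive") {
    # alternate the sense of the electric dipole so neighbors counter-align
    mons <- lapply(seq_len(n_monomers), function(k) {
      t0 <- toy_monomer(hydrophobic = two(),
                        electrostatic = if (k %% 2L) two() else flip(two()),
                        label = sprintf("M%02d", k), ordinal = k)
      transform_toy(transform_toy(t0, diag(3), c(20, 0, 0)),
                    rot_z((k - 1L) * 22.5), c(0, 0, (k - 1L) * 2),
                    ordinal = k, label = sprintf("M%02d", k))
    })
    as_assembly(mons, source = "synthetic dual-attractive helix")
  } else if (label == "electrostatic_driven") {
    # stack along the moment axis: head-to-tail D attracts, H repels
    mons <- lapply(seq_len(n_monomers), function(k)
      transform_toy(tpl, diag(3), c(0, 0, (k - 1L) * 12),
                    ordinal = k, label = sprintf("M%02d", k)))
    as_assembly(mons, source = "synthetic electrostatic stack")
  } else {
    helical_assembly(tpl, n_monomers)
  }
  attr(asm, "truth") <- label
  asm
}
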