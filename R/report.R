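# Machine-readable reporting: CSV/JSON writers behind the command-line
# surface (inst/cli/dipole-assembly.R). Plots are decorative; CSV and JSON
# are the contract. Every output embeds the effective-convention
# fingerprint and package version so runs are reproducible byte-for-byte.

pkg_version <- function()
  as.character(utils::packageVersion("asmdipole"))

write_csv_with_header <- function(df, path, control) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# asmdipole %s; %s", pkg_version(),
                     control_fingerprint(control)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Per-monomer dipole vectors report
#'
#' Computes both dipoles for every monomer and (optionally) writes a CSV
#' table plus ChimeraX/PyMOL arrow scripts into `out_dir`.
#'
#' @param assembly an `"assembly"`.
#' @param control see [energetics_control()].
#' @param out_dir output directory (`NULL` = no files written).
#' @return the dipole table (invisibly when writing).
#' @export
run_vectors <- function(assembly, control = energetics_control(),
                        out_dir = NULL) {
  fit <- assembly_energetics(assembly, control)
  tab <- dipole_table(fit)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_csv_with_header(tab, file.path(out_dir, "dipoles.csv"), control)
    write_dipole_bild(c(fit$dipoles_H, fit$dipoles_D),
                      file.path(out_dir, "dipoles.bild"))
    write_dipole_pml(c(fit$dipoles_H, fit$dipoles_D),
                     file.path(out_dir, "dipoles.pml"))
    return(invisible(tab))
  }
  tab
}

#' Driver-classification report
#'
#' @inheritParams run_vectors
#' @param n_pairs consecutive pairs entering the statistics (`NULL` = all).
#' @return the `"assembly_energetics"` fit (invisibly when writing); the
#'   JSON summary holds means, SDs, n, label, conventions and version.
#' @export
run_classify <- function(assembly, control = energetics_control(),
                         n_pairs = control$n_pairs, out_dir = NULL) {
  fit <- assembly_energetics(assembly, control, n_pairs = n_pairs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cl <- fit$classification
    jsonlite::write_json(
      list(label = cl$label,
           mean_enH = cl$mean_enH, sd_enH = cl$sd_enH, n_H = fit$stats_H$n,
           mean_enD = cl$mean_enD, sd_enD = cl$sd_enD, n_D = fit$stats_D$n,
           n_monomers = fit$n_monomers, source = fit$source,
           settings = control_fingerprint(control),
           version = pkg_version()),
      file.path(out_dir, "classification.json"),
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    write_csv_with_header(fit$pairs, file.path(out_dir, "pair_energies.csv"),
                          control)
    return(invisible(fit))
  }
  fit
}

#' Growth-curve report
#'
#' @inheritParams run_vectors
#' @param kind energy kind.
#' @param mode growth mode(s), any of `"sequential"`, `"around_center"`.
#' @param center_ordinal center element for `"around_center"`.
#' @return named list of `"growth_curve"` objects.
#' @export
run_growth <- function(assembly, kind = c("hydrophobic", "electrostatic"),
                       mode = "sequential", center_ordinal = NULL,
                       control = energetics_control(), out_dir = NULL) {
  kind <- match.arg(kind)
  curves <- lapply(mode, function(m)
    growth_curve(assembly, kind, mode = m, center_ordinal = center_ordinal,
                 control = control))
  names(curves) <- mode
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    long <- do.call(rbind, lapply(names(curves), function(m)
      cbind(mode = m, kind = kind, curves[[m]]$points)))
    write_csv_with_header(long, file.path(out_dir,
                                          sprintf("growth_%s.csv", kind)),
                          control)
    return(invisible(curves))
  }
  curves
}

#' Rotation/translation scan report
#'
#' Scans the dipole of monomer `j` against monomer `i` (native rotations
#' about the three frame axes, plus the three translational arrangements,
#' each re-scanned), for the requested kind.
#'
#' @inheritParams run_growth
#' @param i,j ordinals of the reference and scanned monomers (default the
#'   first dimer).
#' @param translations logical; include the translational arrangements.
#' @return list with `rotation` (three `"scan_result"`), optionally
#'   `translation` (per-arrangement results), and `minima` (summary
#'   data.frame).
#' @export
run_scan <- function(assembly, kind = c("hydrophobic", "electrostatic"),
                     i = 1L, j = 2L, translations = TRUE,
                     control = energetics_control(), out_dir = NULL) {
  kind <- match.arg(kind)
  dip <- assembly_dipoles(assembly, kind, control)
  rot <- rotation_scan(dip[[i]], dip[[j]], step_deg = control$scan_step,
                       distance_unit = control$distance_unit, r0 = control$r0)
  out <- list(rotation = rot)
  if (translations)
    out$translation <- translation_arrangements(
      dip[[i]], dip[[j]], step_deg = control$scan_step,
      distance_unit = control$distance_unit, r0 = control$r0)
  minima <- do.call(rbind, lapply(names(rot), function(ax) {
    m <- find_min_angle(rot[[ax]])
    data.frame(arrangement = "native", axis = ax, kind = kind,
               native_energy = rot[[ax]]$native_energy,
               min_angle_deg = m$angle_deg, min_angle_signed = m$angle_signed,
               min_energy = m$energy, tie = m$tie)
  }))
  if (translations) {
    for (arr in names(out$translation)) {
      for (ax in names(out$translation[[arr]]$scans)) {
        s <- out$translation[[arr]]$scans[[ax]]
        m <- find_min_angle(s)
        minima <- rbind(minima, data.frame(
          arrangement = arr, axis = ax, kind = kind,
          native_energy = s$native_energy, min_angle_deg = m$angle_deg,
          min_angle_signed = m$angle_signed, min_energy = m$energy,
          tie = m$tie))
      }
    }
  }
  out$minima <- minima
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    long <- do.call(rbind, c(
      lapply(names(rot), function(ax)
        data.frame(arrangement = "native", axis = ax, kind = kind,
                   angle_deg = rot[[ax]]$angles_deg,
                   energy = rot[[ax]]$energies)),
      if (translations) unlist(lapply(names(out$translation), function(arr)
        lapply(names(out$translation[[arr]]$scans), function(ax) {
          s <- out$translation[[arr]]$scans[[ax]]
          data.frame(arrangement = arr, axis = ax, kind = kind,
                     angle_deg = s$angles_deg, energy = s$energies)
        })), recursive = FALSE)))
    write_csv_with_header(long, file.path(out_dir,
                                          sprintf("scan_%s.csv", kind)),
                          control)
    jsonlite::write_json(
      list(minima = minima, settings = control_fingerprint(control),
           version = pkg_version()),
      file.path(out_dir, sprintf("scan_minima_%s.json", kind)),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
    return(invisible(out))
  }
  out
}

#' Read a run configuration file
#'
#' Plain `key = value` (or `key: value`) text file mapping onto
#' [energetics_control()] arguments plus the input-selection keys `input`,
#' `format`, `model_index`, `groups` (chain groups as `A+B,C+D`) and
#' `accession`. Lines starting with `#` are ignored.
#'
#' @param path config file.
#' @return list with elements `input`, `format`, `model_index`, `groups`,
#'   `accession` and `control` (an `"energetics_control"`).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*[:=]\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("unparsable config line(s): ",
                     paste(lines[bad], collapse = " | "))
  vals <- stats::setNames(vapply(kv, `[`, character(1), 3L),
                          vapply(kv, `[`, character(1), 2L))
  num <- function(k, d) if (k %in% names(vals)) as.numeric(vals[[k]]) else d
  chr <- function(k, d) if (k %in% names(vals)) vals[[k]] else d
  lgl <- function(k, d) if (k %in% names(vals))
    tolower(vals[[k]]) %in% c("true", "yes", "1") else d
  ctrl <- energetics_control(
    site_mode_electrostatic = chr("site_mode_electrostatic",
                                  "charged_group_centroid"),
    site_mode_hydrophobic = chr("site_mode_hydrophobic",
                                "sidechain_centroid"),
    include_his = lgl("include_his", FALSE),
    include_termini = lgl("include_termini", FALSE),
    scale = if ("scale_file" %in% names(vals))
      read_hydrophobicity_scale(vals[["scale_file"]]) else eisenberg_scale(),
    distance_unit = chr("distance_unit", "scaled"),
    r0 = num("r0", 10),
    application_point = chr("application_point", "midpoint"),
    n_pairs = if ("n_pairs" %in% names(vals)) as.integer(vals[["n_pairs"]]),
    scan_step = num("scan_step", 10))
  groups <- if ("groups" %in% names(vals))
    lapply(strsplit(vals[["groups"]], ",")[[1L]],
           function(g) strsplit(trimws(g), "\\+")[[1L]])
  list(input = chr("input", NULL), format = chr("format", "auto"),
       model_index = as.integer(num("model_index", 1)),
       groups = groups, accession = chr("accession", NULL), control = ctrl)
}
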