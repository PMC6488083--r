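# Reading multimeric structures and exposing ordered monomer lists.
#
# A "monomer" is one element of the growing assembly: by default one polymer
# chain of the deposited (biological) assembly, or a user-defined group of
# chains (e.g. a pentamer, or a tubulin heterodimer). Atoms are kept as a
# plain data.frame so per-residue representative sites can be recomputed
# under different conventions.

#' Construct a monomer object
#'
#' Normally produced by [load_assembly()]; exposed so synthetic generators
#' can build monomers directly.
#'
#' @param monomer_id text label (chain id or joined chain ids).
#' @param ordinal integer position (>= 1) in assembly order.
#' @param atoms data.frame with columns `chain`, `resno`, `ins`, `resid`,
#'   `elety`, `x`, `y`, `z` (coordinates in Angstrom).
#' @return an object of class `"monomer"`.
#' @export
new_monomer <- function(monomer_id, ordinal, atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L,
            all(c("chain", "resno", "ins", "resid", "elety", "x", "y", "z")
                %in% names(atoms)))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates in monomer ", monomer_id)
  structure(
    list(monomer_id = as.character(monomer_id),
         ordinal = as.integer(ordinal),
         atoms = atoms,
         geometric_center = colMeans(atoms[, c("x", "y", "z")])),
    class = "monomer")
}

#' @export
print.monomer <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "resno", "ins")]))
  cat(sprintf("<monomer %s> ordinal %d: %d residues, %d atoms\n",
              x$monomer_id, x$ordinal, nres, nrow(x$atoms)))
  invisible(x)
}

#' Bundle monomers into an ordered assembly
#'
#' @param monomers list of `"monomer"` objects; ordinals are (re)assigned
#'   consecutively from 1 in list order.
#' @param source optional text describing the origin (file path, accession).
#' @return an object of class `"assembly"` (a list of monomers).
#' @export
as_assembly <- function(monomers, source = NA_character_) {
  if (length(monomers) == 0L) stop("empty assembly")
  stopifnot(all(vapply(monomers, inherits, logical(1), "monomer")))
  for (i in seq_along(monomers)) monomers[[i]]$ordinal <- i
  structure(monomers, class = "assembly", source = source)
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly> %d monomers: %s\n", length(x),
              paste(vapply(x, `[[`, character(1), "monomer_id"),
                    collapse = " ")))
  invisible(x)
}

#' @export
`[.assembly` <- function(x, i) {
  as_assembly(unclass(x)[i], source = attr(x, "source"))
}

# decompress a .gz structure file to a temp file, return usable path
maybe_gunzip <- function(path) {
  if (!grepl("\\.gz$", path, ignore.case = TRUE)) return(path)
  out <- tempfile(fileext = sub("\\.gz$", "", basename(path), ignore.case = TRUE))
  con <- gzfile(path, "rb"); on.exit(close(con))
  writeBin(readBin(con, "raw", n = 5e8), out)
  out
}

# altLoc filter: per (chain, resno, ins, elety) keep highest occupancy,
# ties broken by alphabetical altLoc label
filter_altloc <- function(at) {
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(at)
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$ins, at$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  at <- at[ord, , drop = FALSE]
  at[!duplicated(paste(at$chain, at$resno, at$ins, at$elety, sep = "\r")), ,
     drop = FALSE]
}

#' Load a multimeric structure as an ordered list of monomers
#'
#' Reads a PDB or mmCIF file (optionally gzip-compressed), keeps standard
#' protein residues only (hetero atoms, waters and hydrogens are excluded;
#' for alternate locations the highest-occupancy conformer is kept), and
#' returns the assembly elements in deposition order.
#'
#' @param path path to a PDB or mmCIF file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param model_index model to use for multi-model (NMR) files; default 1.
#' @param groups optional monomer grouping: a list of character vectors of
#'   chain ids, each vector becoming one monomer (e.g.
#'   `list(c("A","B"), c("C","D"))`). Default: one monomer per chain.
#' @param chain_order optional character vector of chain ids (or group
#'   labels) giving an explicit assembly order overriding deposition order.
#' @return an `"assembly"`: ordered list of `"monomer"` objects.
#' @seealso [residue_sites()], [fetch_structure()]
#' @export
load_assembly <- function(path, format = c("auto", "pdb", "cif"),
                          model_index = 1L, groups = NULL,
                          chain_order = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  fpath <- maybe_gunzip(path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", fpath, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(fpath, multi = TRUE)
    else bio3d::read.pdb(fpath, multi = TRUE),
    error = function(e) stop("could not parse '", path, "' as ", format,
                             ": ", conditionMessage(e)))
  at <- pdb$atom
  # multi-model: take coordinates of the requested model
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model_index < 1L || model_index > nmod)
    stop("model_index ", model_index, " out of range (file has ", nmod,
         " model(s))")
  if (model_index > 1L) {
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
    at$x <- xyz[, 1L]; at$y <- xyz[, 2L]; at$z <- xyz[, 3L]
  }
  at <- at[at$type == "ATOM", , drop = FALSE]
  dropped <- setdiff(unique(at$resid), AA3)
  if (length(dropped))
    message("dropping non-standard residues: ", paste(dropped, collapse = ", "))
  at <- at[at$resid %in% AA3, , drop = FALSE]
  # hydrogens out (element symbol if present, else atom-name heuristic)
  if ("elesy" %in% names(at) && !all(is.na(at$elesy))) {
    at <- at[is.na(at$elesy) | at$elesy != "H", , drop = FALSE]
  } else {
    at <- at[!grepl("^[0-9]*H", at$elety), , drop = FALSE]
  }
  if (!"insert" %in% names(at)) at$insert <- ""
  at$ins <- ifelse(is.na(at$insert), "", at$insert)
  at <- filter_altloc(at)
  if (nrow(at) == 0L) stop("empty assembly: no standard protein atoms selected")

  chains <- unique(at$chain)             # deposition order
  if (is.null(groups)) groups <- as.list(chains)
  labels <- vapply(groups, paste, character(1), collapse = "+")
  if (!is.null(chain_order)) {
    idx <- match(chain_order, labels)
    if (any(is.na(idx)))
      stop("chain_order entries not found: ",
           paste(chain_order[is.na(idx)], collapse = ", "))
    groups <- groups[idx]; labels <- labels[idx]
  }
  monomers <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    sub <- at[at$chain %in% groups[[i]], , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("empty assembly: no atoms for chain group ", labels[i])
    monomers[[i]] <- new_monomer(
      labels[i], i,
      sub[, c("chain", "resno", "ins", "resid", "elety", "x", "y", "z")])
  }
  as_assembly(monomers, source = path)
}

#' Fetch a structure from the PDB by accession
#'
#' Downloads `<accession>.cif.gz` from the RCSB file server into a local
#' cache directory (skipped when already cached). Requires network access;
#' all analysis functions work equally on local files.
#'
#' @param accession 4-character PDB id.
#' @param dir cache directory (created if needed).
#' @param timeout seconds before the download attempt is abandoned.
#' @return path to the cached file (invisibly usable with [load_assembly()]).
#' @export
fetch_structure <- function(accession, dir = file.path(tempdir(), "pdb_cache"),
                            timeout = 60) {
  stopifnot(grepl("^[0-9][A-Za-z0-9]{3}$", accession))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(dir, paste0(toupper(accession), ".cif.gz"))
  if (file.exists(dest)) return(dest)
  url <- paste0("https://files.rcsb.org/download/", toupper(accession),
                ".cif.gz")
  old <- options(timeout = timeout); on.exit(options(old))
  status <- tryCatch(utils::download.file(url, dest, quiet = TRUE,
                                          mode = "wb"),
                     error = function(e) -1L, warning = function(w) -1L)
  if (!identical(status, 0L) || !file.exists(dest) || file.size(dest) == 0L) {
    unlink(dest)
    stop("could not fetch ", accession, " from the PDB (network unavailable?)")
  }
  dest
}

# charged-group atom names per residue (side-chain charge carriers)
CHARGED_GROUP_ATOMS <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"),
  LYS = "NZ",
  ARG = c("NH1", "NH2", "NE"),
  HIS = c("ND1", "NE2"))

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Per-residue representative coordinates of a monomer
#'
#' Reduces a monomer to one point per standard residue under one of three
#' conventions: the C-alpha position, the centroid of the side-chain heavy
#' atoms (C-alpha for Gly), or the centroid of the charged-group atoms
#' (Asp OD1/OD2, Glu OE1/OE2, Lys NZ, Arg NH1/NH2/NE, His ND1/NE2; other
#' residues fall back to the side-chain centroid). Residues lacking the
#' atoms a mode requires fall back toward C-alpha with a warning; residues
#' with no usable atoms at all are skipped with a warning.
#'
#' @param monomer a `"monomer"` object.
#' @param site_mode `"calpha"`, `"sidechain_centroid"` or
#'   `"charged_group_centroid"`.
#' @return data.frame with one row per residue: `chain`, `resno`, `ins`,
#'   `resid`, `x`, `y`, `z`, `site_mode`.
#' @export
residue_sites <- function(monomer,
                          site_mode = c("calpha", "sidechain_centroid",
                                        "charged_group_centroid")) {
  site_mode <- match.arg(site_mode)
  at <- monomer$atoms
  key <- paste(at$chain, at$resno, at$ins, sep = "\r")
  idx <- split(seq_len(nrow(at)), factor(key, levels = unique(key)))
  out <- vector("list", length(idx))
  fellback <- character(0); skipped <- character(0)
  for (k in seq_along(idx)) {
    sub <- at[idx[[k]], , drop = FALSE]
    resid <- sub$resid[1L]
    rlab <- paste0(resid, sub$resno[1L], sub$ins[1L])
    sel <- integer(0)
    if (site_mode == "charged_group_centroid" &&
        !is.null(CHARGED_GROUP_ATOMS[[resid]])) {
      sel <- which(sub$elety %in% CHARGED_GROUP_ATOMS[[resid]])
      if (length(sel) == 0L) fellback <- c(fellback, rlab)
    }
    if (length(sel) == 0L && site_mode != "calpha" && resid != "GLY") {
      sel <- which(!sub$elety %in% BACKBONE_ATOMS)
      if (length(sel) == 0L && site_mode == "sidechain_centroid")
        fellback <- c(fellback, rlab)
    }
    if (length(sel) == 0L) sel <- which(sub$elety == "CA")
    if (length(sel) == 0L) { skipped <- c(skipped, rlab); next }
    pos <- colMeans(sub[sel, c("x", "y", "z"), drop = FALSE])
    out[[k]] <- data.frame(chain = sub$chain[1L], resno = sub$resno[1L],
                           ins = sub$ins[1L], resid = resid,
                           x = pos[1L], y = pos[2L], z = pos[3L],
                           site_mode = site_mode,
                           stringsAsFactors = FALSE)
  }
  if (length(fellback))
    warning("missing side-chain/charged-group atoms, used fallback site for: ",
            paste(utils::head(fellback, 10L), collapse = ", "),
            if (length(fellback) > 10L) " ...")
  if (length(skipped))
    warning("skipped residues with no usable atoms: ",
            paste(skipped, collapse = ", "))
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0L)
    stop("no usable residues in monomer ", monomer$monomer_id)
  rownames(res) <- NULL
  res
}

# N-terminal N and C-terminal C (carboxyl carbon) positions, or NULL
terminal_positions <- function(monomer) {
  at <- monomer$atoms
  key <- paste(at$chain, at$resno, at$ins, sep = "\r")
  first <- at[key == key[1L], , drop = FALSE]
  last <- at[key == key[length(key)], , drop = FALSE]
  np <- first[first$elety == "N", c("x", "y", "z")]
  cp <- last[last$elety == "C", c("x", "y", "z")]
  if (nrow(np) == 0L || nrow(cp) == 0L) return(NULL)
  list(n_pos = as.numeric(np[1L, ]), c_pos = as.numeric(cp[1L, ]))
}
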