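# Assignment of electrostatic charges and hydrophobic "charges"
# (hydrophobicity indices treated formally as signed point charges) to
# per-residue sites.

#' The Eisenberg normalized consensus hydrophobicity scale
#'
#' Dimensionless per-residue hydrophobicity indices (Eisenberg, Schwarz,
#' Komaromy & Wall, J Mol Biol 179:125-142, 1984). Positive values mark
#' hydrophobic residues, negative values hydrophilic ones; this sign
#' convention is what makes the indices usable as signed "hydrophobic
#' charges".
#'
#' @return named numeric vector over the 20 standard residues (3-letter
#'   codes), with attribute `scale_name`.
#' @export
eisenberg_scale <- function() {
  v <- c(ALA =  0.62, ARG = -2.53, ASN = -0.78, ASP = -0.90, CYS =  0.29,
         GLN = -0.85, GLU = -0.74, GLY =  0.48, HIS = -0.40, ILE =  1.38,
         LEU =  1.06, LYS = -1.50, MET =  0.64, PHE =  1.19, PRO =  0.12,
         SER = -0.18, THR = -0.05, TRP =  0.81, TYR =  0.26, VAL =  1.08)
  attr(v, "scale_name") <- "eisenberg_consensus"
  v
}

#' Read an alternative hydrophobicity scale from a text table
#'
#' Two whitespace- or comma-separated columns: 3-letter residue code and
#' numeric index. Must cover all 20 standard residues and contain both
#' positive and negative values.
#'
#' @param path file path.
#' @param name label stored as the scale name.
#' @return named numeric vector as in [eisenberg_scale()].
#' @export
read_hydrophobicity_scale <- function(path, name = basename(path)) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("resid", "value"),
                           stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(tab) == 1L && grepl(",", tab$resid[1L]))
    tab <- utils::read.csv(path, header = FALSE,
                           col.names = c("resid", "value"))
  v <- stats::setNames(as.numeric(tab$value), toupper(tab$resid))
  missing <- setdiff(AA3, names(v))
  if (length(missing))
    stop("scale is missing residues: ", paste(missing, collapse = ", "))
  v <- v[AA3]
  if (!any(v > 0) || !any(v < 0))
    stop("a hydrophobicity scale must contain both positive and negative values")
  attr(v, "scale_name") <- name
  v
}

#' Construct a charge set
#'
#' A set of signed point charges (electrostatic, in elementary-charge
#' units, or hydrophobic, in hydrophobicity-index units) with 3D positions,
#' belonging to one monomer. Zero charges are dropped.
#'
#' @param kind `"electrostatic"` or `"hydrophobic"`.
#' @param q numeric vector of signed charges.
#' @param xyz numeric matrix, one row per charge, columns x,y,z (Angstrom).
#' @param monomer_id text label.
#' @return an object of class `"charge_set"`.
#' @export
charge_set <- function(kind = c("electrostatic", "hydrophobic"), q, xyz,
                       monomer_id = NA_character_) {
  kind <- match.arg(kind)
  q <- as.numeric(q)
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  if (length(q) != nrow(xyz))
    stop("q and xyz disagree in length")
  if (length(q) && any(!is.finite(q) | !is.finite(rowSums(xyz))))
    stop("non-finite charge or position")
  keep <- q != 0
  structure(list(kind = kind, q = q[keep],
                 xyz = xyz[keep, , drop = FALSE],
                 monomer_id = monomer_id),
            class = "charge_set")
}

#' @export
print.charge_set <- function(x, ...) {
  cat(sprintf("<charge_set %s> %s: %d charges (%d+, %d-), total %+.3f\n",
              x$kind, x$monomer_id, length(x$q), sum(x$q > 0), sum(x$q < 0),
              sum(x$q)))
  invisible(x)
}

#' Electrostatic charges of a monomer's residue sites
#'
#' Asp and Glu carry -1, Lys and Arg +1, each at its residue site. His
#' (+1) is excluded by default given its near-neutral pKa; terminal charges
#' (+1 at the N-terminal amine nitrogen, -1 at the C-terminal carboxyl
#' carbon) are excluded by default and added when their atom positions are
#' supplied.
#'
#' @param sites data.frame from [residue_sites()].
#' @param include_his logical; count His as +1.
#' @param termini `NULL`, or `list(n_pos=, c_pos=)` of 3-vectors (as from
#'   the internal terminal-atom lookup) to add the two terminal charges.
#' @param monomer_id label forwarded to the charge set.
#' @return a `"charge_set"` of kind `"electrostatic"` (possibly empty).
#' @export
electrostatic_charges <- function(sites, include_his = FALSE, termini = NULL,
                                  monomer_id = NA_character_) {
  pos_res <- c("LYS", "ARG", if (include_his) "HIS")
  neg_res <- c("ASP", "GLU")
  sel <- sites$resid %in% c(pos_res, neg_res)
  q <- ifelse(sites$resid[sel] %in% pos_res, 1, -1)
  xyz <- as.matrix(sites[sel, c("x", "y", "z"), drop = FALSE])
  if (!is.null(termini)) {
    q <- c(q, 1, -1)
    xyz <- rbind(xyz, termini$n_pos, termini$c_pos)
  }
  charge_set("electrostatic", q, xyz, monomer_id)
}

#' Hydrophobic charges of a monomer's residue sites
#'
#' One signed charge per residue, equal to the residue's hydrophobicity
#' index, at the residue site. Residues with index exactly 0 are excluded.
#'
#' @param sites data.frame from [residue_sites()].
#' @param scale named numeric vector as from [eisenberg_scale()] (default).
#' @param monomer_id label forwarded to the charge set.
#' @return a `"charge_set"` of kind `"hydrophobic"`.
#' @export
hydrophobic_charges <- function(sites, scale = eisenberg_scale(),
                                monomer_id = NA_character_) {
  missing <- setdiff(unique(sites$resid), names(scale))
  if (length(missing))
    stop("residue(s) absent from hydrophobicity scale: ",
         paste(missing, collapse = ", "))
  q <- as.numeric(scale[sites$resid])
  charge_set("hydrophobic", q, as.matrix(sites[, c("x", "y", "z")]),
             monomer_id)
}
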