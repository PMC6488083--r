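# internal vector helpers ----------------------------------------------------

vnorm <- function(v) sqrt(sum(v * v))

unitvec <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

check_vec3 <- function(v, what = "vector") {
  if (!is.numeric(v) || length(v) != 3L || any(!is.finite(v)))
    stop(what, " must be a finite numeric 3-vector")
  as.numeric(v)
}

#' Rotate a 3-vector about an axis
#'
#' Right-handed rotation of `v` about the unit vector `axis` (Rodrigues
#' formula). The rotation is applied to the vector itself; norms are
#' preserved.
#'
#' @param v numeric 3-vector.
#' @param axis unit-norm numeric 3-vector (checked to 1e-6).
#' @param angle_deg rotation angle in degrees (right-handed about `axis`).
#' @return the rotated 3-vector.
#' @examples
#' rotate_vector(c(1, 0, 0), c(0, 0, 1), 90)  # ~ (0, 1, 0)
#' @export
rotate_vector <- function(v, axis, angle_deg) {
  v <- check_vec3(v, "v")
  axis <- check_vec3(axis, "axis")
  if (abs(vnorm(axis) - 1) > 1e-6) stop("axis must be unit-norm")
  th <- angle_deg * pi / 180
  v * cos(th) + cross3(axis, v) * sin(th) + axis * sum(axis * v) * (1 - cos(th))
}

# standard 20 amino acids, 3-letter codes
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
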