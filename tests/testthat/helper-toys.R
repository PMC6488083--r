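# shared fixtures and independent oracles

# a unit dipole of either kind with an explicit moment and position
ud <- function(moment, at = c(0, 0, 0), kind = "hydrophobic")
  new_pseudo_dipole(kind, moment, at)

geom_r <- function(r_vec) pair_geometry(r_vec = r_vec)

# independent closed-form oracles, written directly from the interaction laws
oracle_enD <- function(m1, m2, r_vec) {
  r <- sqrt(sum(r_vec^2)); u <- r_vec / r
  -(3 * sum(u * m1) * sum(u * m2) - sum(m1 * m2)) / r^3
}
oracle_enH <- function(m1, m2, r_vec, rexp = sqrt(sum(r_vec^2))) {
  r <- sqrt(sum(r_vec^2)); u <- r_vec / r
  +(3 * sum(u * m1) * sum(u * m2) - sum(m1 * m2)) / exp(rexp)
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# all-pairs energy by brute-force double loop over a dipole list
brute_all_pairs <- function(dipoles, kind, distance_unit = "scaled", r0 = 10) {
  n <- length(dipoles); tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    di <- dipoles[[i]]; dj <- dipoles[[j]]
    if (!di$defined || !dj$defined) next
    rv <- dj$application_point - di$application_point
    tot <- tot + if (kind == "hydrophobic") {
      r <- sqrt(sum(rv^2))
      rs <- switch(distance_unit, angstrom = r, nanometer = r / 10,
                   scaled = r / r0)
      oracle_enH(di$moment, dj$moment, rv, rs)
    } else oracle_enD(di$moment, dj$moment, rv)
  }
  tot
}

# random toy assembly: n monomers, each a random two-sign charge cloud of
# both kinds, scattered in space (some distances large, energies small but
# exact arithmetic is what is being checked)
random_toy_assembly <- function(n, seed) {
  set.seed(seed)
  mons <- lapply(seq_len(n), function(k) {
    center <- stats::runif(3, -40, 40)
    mk <- function() {
      m <- stats::rnorm(3)
      m <- m / sqrt(sum(m^2)) * stats::runif(1, 2, 8)
      list(q = c(1, -1), xyz = rbind(center + m / 2, center - m / 2))
    }
    toy_monomer(hydrophobic = mk(), electrostatic = mk(),
                label = sprintf("R%02d", k), ordinal = k)
  })
  as_assembly(mons, source = sprintf("random toy assembly seed %d", seed))
}

# residue-site data.frame for hand-built peptides
site_df <- function(resids, xyz = NULL) {
  n <- length(resids)
  if (is.null(xyz)) xyz <- cbind(3.8 * seq_len(n), 0, 0)
  data.frame(chain = "A", resno = seq_len(n), ins = "", resid = resids,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             site_mode = "calpha", stringsAsFactors = FALSE)
}

cross3_test <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

vnorm_test <- function(v) sqrt(sum(v * v))
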