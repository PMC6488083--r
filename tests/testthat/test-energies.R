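# interaction laws, pair statistics, growth curves, classification

test_that("the electrostatic law matches its closed forms", {
  z <- c(0, 0, 1); x <- c(1, 0, 0)
  g1 <- geom_r(x)                          # |r| = 1 along x
  # parallel unit moments perpendicular to r: repulsive +1
  e <- energy_electrostatic(ud(z, kind = "electrostatic"),
                            ud(z, c(1, 0, 0), kind = "electrostatic"), g1)
  expect_equal(e$value, 1, tolerance = 1e-9)
  # collinear head-to-tail: attractive -2
  e <- energy_electrostatic(ud(x, kind = "electrostatic"),
                            ud(x, c(1, 0, 0), kind = "electrostatic"), g1)
  expect_equal(e$value, -2, tolerance = 1e-9)
  # antiparallel perpendicular at r = 2: attractive -1/8
  e <- energy_electrostatic(ud(z, kind = "electrostatic"),
                            ud(-z, c(2, 0, 0), kind = "electrostatic"),
                            geom_r(c(2, 0, 0)))
  expect_equal(e$value, -1 / 8, tolerance = 1e-9)
})

test_that("the hydrophobic law matches its closed forms (sign-flipped, e^-r)", {
  z <- c(0, 0, 1); x <- c(1, 0, 0)
  g1 <- geom_r(x)
  # aligned moments perpendicular to r attract: -1/e
  e <- energy_hydrophobic(ud(z), ud(z, x), g1, distance_unit = "angstrom")
  expect_equal(e$value, -1 / exp(1), tolerance = 1e-9)
  # antiparallel perpendicular: repulsive +1/e
  e <- energy_hydrophobic(ud(z), ud(-z, x), g1, distance_unit = "angstrom")
  expect_equal(e$value, +1 / exp(1), tolerance = 1e-9)
  # collinear: repulsive +2/e
  e <- energy_hydrophobic(ud(x), ud(x, x), g1, distance_unit = "angstrom")
  expect_equal(e$value, +2 / exp(1), tolerance = 1e-9)
})

test_that("energies obey exchange symmetry and the distance laws", {
  set.seed(23)
  for (rep in 1:10) {
    m1 <- rnorm(3); m2 <- rnorm(3); rv <- runif(3, 1, 10)
    d1 <- ud(m1, c(0, 0, 0), "electrostatic")
    d2 <- ud(m2, rv, "electrostatic")
    g <- pair_geometry(d1, d2)
    expect_equal(energy_electrostatic(d1, d2, g)$value,
                 energy_electrostatic(d2, d1, rev_geometry(g))$value,
                 tolerance = 1e-12)
    h1 <- ud(m1); h2 <- ud(m2, rv)
    expect_equal(energy_hydrophobic(h1, h2, g)$value,
                 energy_hydrophobic(h2, h1, rev_geometry(g))$value,
                 tolerance = 1e-12)
  }
  # log-slope of |enD| vs log r is -3; of log|enH| vs r is -1 (angstrom)
  rr <- seq(2, 12, by = 0.5)
  z <- c(0, 0, 1)
  eD <- vapply(rr, function(r)
    energy_electrostatic(ud(z, kind = "electrostatic"),
                         ud(z, c(r, 0, 0), kind = "electrostatic"),
                         geom_r(c(r, 0, 0)))$value, numeric(1))
  expect_equal(unname(coef(lm(log(abs(eD)) ~ log(rr)))[2]), -3,
               tolerance = 1e-9)
  eH <- vapply(rr, function(r)
    energy_hydrophobic(ud(z), ud(z, c(r, 0, 0)), geom_r(c(r, 0, 0)),
                       distance_unit = "angstrom")$value, numeric(1))
  expect_equal(unname(coef(lm(log(abs(eH)) ~ rr))[2]), -1, tolerance = 1e-9)
})

test_that("undefined dipoles give zero flagged energies; misuse errors", {
  und <- new_pseudo_dipole("hydrophobic", c(0, 0, 0), c(0, 0, 0),
                           defined = FALSE)
  ok <- ud(c(0, 0, 1), c(5, 0, 0))
  e <- energy_hydrophobic(und, ok, geom_r(c(5, 0, 0)))
  expect_false(e$defined)
  expect_equal(e$value, 0)

  expect_error(pair_energy(ok, ud(c(1, 0, 0), c(3, 0, 0), "electrostatic")),
               "mix")
  expect_error(energy_electrostatic(ok, ok, geom_r(c(1, 0, 0))),
               "electrostatic")
  expect_error(pair_geometry(r_vec = c(0, 0, 0)), "singular")
})

test_that("rigid motion of a whole assembly leaves pair energies unchanged", {
  asm <- random_toy_assembly(6, seed = 5)
  ctrl <- energetics_control()
  t0 <- pair_energy_table(asm, "all", ctrl)
  set.seed(99)
  R <- random_rotation(); tr <- runif(3, -30, 30)
  moved <- as_assembly(lapply(asm, asmdipole:::transform_toy, R = R, t = tr))
  t1 <- pair_energy_table(moved, "all", ctrl)
  expect_equal(t1$enH, t0$enH, tolerance = 1e-9)
  expect_equal(t1$enD, t0$enD, tolerance = 1e-9)
  expect_equal(t1$r, t0$r, tolerance = 1e-9)
})

test_that("consecutive-pair statistics match hand-computed energies", {
  # identical, equally spaced monomers: zero SD, mean = single-pair energy
  tpl <- toy_monomer(hydrophobic = list(q = c(1, -1),
                                        xyz = rbind(c(0, 0, 2), c(0, 0, -2))))
  asm <- helical_assembly(tpl, 5, radius = 18, rise_per_monomer = 0,
                          twist_per_monomer = 25)
  st <- consecutive_pair_stats(asm, "hydrophobic")
  expect_equal(st$n, 4L)
  expect_equal(st$sd, 0, tolerance = 1e-9)
  d <- assembly_dipoles(asm, "hydrophobic")
  e12 <- pair_energy(d[[1]], d[[2]])$value
  expect_equal(st$mean, e12, tolerance = 1e-12)

  # 3-monomer toy against direct evaluation of the laws
  m1 <- ud(c(0, 0, 3), c(0, 0, 0))
  m2 <- ud(c(0, 1, 2.5), c(8, 0, 0))
  m3 <- ud(c(1, 0, 3), c(15, 2, 0))
  e12 <- oracle_enH(m1$moment, m2$moment,
                    m2$application_point - m1$application_point, rexp = 0.8)
  e23 <- oracle_enH(m2$moment, m3$moment,
                    m3$application_point - m2$application_point,
                    rexp = sqrt(49 + 4) / 10)
  st2 <- consecutive_pair_stats(list(m1, m2, m3))
  expect_equal(st2$mean, (e12 + e23) / 2, tolerance = 1e-12)
  expect_equal(st2$sd, sd(c(e12, e23)), tolerance = 1e-12)

  # truncation to the first n_pairs
  st3 <- consecutive_pair_stats(list(m1, m2, m3), n_pairs = 1)
  expect_equal(st3$mean, e12, tolerance = 1e-12)
  expect_equal(st3$n, 1L)

  # fewer than two defined dipoles: indeterminate
  und <- new_pseudo_dipole("hydrophobic", c(0, 0, 0), c(0, 0, 0), FALSE)
  st4 <- consecutive_pair_stats(list(m1, und))
  expect_false(st4$defined)
  expect_true(is.na(st4$mean))
})

test_that("growth curves equal a brute-force all-pairs sum and are additive", {
  ctrl <- energetics_control()
  for (seed in c(2, 9)) {
    asm <- random_toy_assembly(20, seed = seed)
    for (kind in c("hydrophobic", "electrostatic")) {
      dip <- assembly_dipoles(asm, kind, ctrl)
      gc <- growth_curve(asm, kind)
      for (N in c(2, 5, 13, 20))
        expect_equal(gc$points$energy[gc$points$N == N],
                     brute_all_pairs(dip[seq_len(N)], kind),
                     tolerance = 1e-9)
      # additivity: E(N) - E(N-1) is the sum of the N-1 new pair terms
      dE <- diff(gc$points$energy)
      for (N in 3:8) {
        new_terms <- sum(vapply(seq_len(N - 1), function(i)
          brute_all_pairs(dip[c(i, N)], kind), numeric(1)))
        expect_equal(dE[N - 2], new_terms, tolerance = 1e-9)
      }
      # around-center mode: same all-pairs oracle on the distance-ranked set
      gc2 <- growth_curve(asm, kind, mode = "around_center",
                          center_ordinal = 7)
      ord <- gc2$order
      expect_equal(ord[1], 7)
      for (N in c(2, 10, 20))
        expect_equal(gc2$points$energy[gc2$points$N == N],
                     brute_all_pairs(dip[ord[seq_len(N)]], kind),
                     tolerance = 1e-9)
    }
  }
  expect_error(growth_curve(random_toy_assembly(4, 1), "hydrophobic",
                            mode = "around_center"), "center_ordinal")
})

test_that("the driver label follows the sign pattern of the mean energies", {
  mk <- function(kind, mean) structure(
    list(mean = mean, sd = abs(mean) / 10, n = 10L, kind = kind,
         defined = !is.na(mean)), class = "pair_stats")
  expect_equal(classify_driver(mk("hydrophobic", -2.34),
                               mk("electrostatic", 2.01))$label,
               "hydrophobic_driven")
  expect_equal(classify_driver(mk("hydrophobic", 0.225),
                               mk("electrostatic", -31.79))$label,
               "electrostatic_driven")
  expect_equal(classify_driver(mk("hydrophobic", -0.1),
                               mk("electrostatic", -1.5))$label,
               "dual_attractive")
  expect_equal(classify_driver(mk("hydrophobic", 0.3),
                               mk("electrostatic", 0.2))$label,
               "dual_repulsive")
  expect_equal(classify_driver(mk("hydrophobic", NA),
                               mk("electrostatic", -1))$label,
               "indeterminate")
})
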