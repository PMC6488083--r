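# rotation frames, grid scans, translational arrangements

test_that("the local frame is the documented right-handed triad", {
  d1 <- ud(c(0, 1, 0), c(0, 0, 0))
  d2 <- ud(c(0, 1, 0), c(5, 0, 0))
  fr <- local_frame(d1, d2)
  expect_equal(fr$x_axis, c(1, 0, 0))
  expect_equal(fr$y_axis, c(0, 0, 1))   # unit(x cross m2)
  expect_equal(fr$z_axis, c(0, -1, 0))  # x cross y completes the triad
  # orthonormal and right-handed for arbitrary pairs
  set.seed(31)
  for (rep in 1:10) {
    a <- ud(rnorm(3), runif(3, -5, 5))
    b <- ud(rnorm(3), runif(3, 6, 12))
    f <- local_frame(a, b)
    M <- rbind(f$x_axis, f$y_axis, f$z_axis)
    expect_equal(M %*% t(M), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(det(M), 1, tolerance = 1e-9)
    expect_equal(cross3_test(f$x_axis, f$y_axis), f$z_axis, tolerance = 1e-9)
  }
  # degenerate case: moment parallel to the pair axis
  expect_warning(local_frame(ud(c(0, 0, 1)), ud(c(2, 0, 0), c(4, 0, 0))),
                 "degenerate")
})

test_that("the whole frame rotates with the input (equivariance)", {
  set.seed(13)
  d1 <- ud(rnorm(3), c(0, 0, 0)); d2 <- ud(rnorm(3), c(7, 1, -2))
  f0 <- local_frame(d1, d2)
  R <- random_rotation(); tr <- runif(3, -10, 10)
  rot <- function(d) new_pseudo_dipole(d$kind, as.numeric(R %*% d$moment),
                                       as.numeric(R %*% d$application_point + tr))
  f1 <- local_frame(rot(d1), rot(d2))
  for (ax in c("x_axis", "y_axis", "z_axis"))
    expect_equal(f1[[ax]], as.numeric(R %*% f0[[ax]]), tolerance = 1e-9)
})

test_that("rotate_vector is a right-handed, norm-preserving rotation", {
  expect_equal(rotate_vector(c(1, 0, 0), c(0, 0, 1), 90), c(0, 1, 0),
               tolerance = 1e-12)
  set.seed(4)
  v <- rnorm(3); ax <- c(0, 1, 0)
  expect_equal(rotate_vector(v, ax, 360), v, tolerance = 1e-9)
  # nine 10-degree steps compose to one quarter turn
  w <- v
  for (i in 1:9) w <- rotate_vector(w, ax, 10)
  expect_equal(w, rotate_vector(v, ax, 90), tolerance = 1e-9)
  expect_equal(sqrt(sum(w^2)), sqrt(sum(v^2)), tolerance = 1e-12)
})

test_that("scan minima match brute-force argmin and analytic optima", {
  # collinear setup: enH(theta) = +2 cos(theta) / e^r about the y-axis,
  # minimum at 180 deg; enD(theta) = -2 cos(theta) / r^3, minimum at 0
  d1h <- ud(c(1, 0, 0)); d2h <- ud(c(1, 0, 0), c(4, 0, 0))
  sc <- suppressWarnings(rotation_scan(d1h, d2h))  # degenerate frame is fine
  expect_equal(sc$y$min_angle_deg, 180)
  expect_equal(sc$y$energies[1], 2 / exp(0.4), tolerance = 1e-9)
  d1e <- ud(c(1, 0, 0), kind = "electrostatic")
  d2e <- ud(c(1, 0, 0), c(4, 0, 0), kind = "electrostatic")
  sce <- suppressWarnings(rotation_scan(d1e, d2e))
  expect_equal(sce$y$min_angle_deg, 0)

  # random orientations: grid minimum equals a direct argmin over the grid
  set.seed(17)
  for (rep in 1:5) {
    d1 <- ud(rnorm(3), c(0, 0, 0)); d2 <- ud(rnorm(3), runif(3, 5, 9))
    sc <- rotation_scan(d1, d2)
    for (ax in c("x", "y", "z")) {
      s <- sc[[ax]]
      expect_equal(s$min_energy, min(s$energies), tolerance = 1e-12)
      expect_equal(s$min_angle_deg,
                   s$angles_deg[which.min(s$energies)])
      expect_equal(s$energies[1], s$native_energy)
      expect_equal(s$angles_deg, seq(0, 350, by = 10))
    }
  }
})

test_that("rotating a moment about its own axis leaves the energy constant", {
  # moment perpendicular to the pair axis lies along the frame z-axis
  d1 <- ud(c(0, 0, 2)); d2 <- ud(c(0, 0, 2), c(6, 0, 0))
  fr <- local_frame(d1, d2)
  expect_equal(abs(sum(fr$z_axis * d2$moment)), vnorm_test(d2$moment),
               tolerance = 1e-9)
  sc <- rotation_scan(d1, d2)
  expect_equal(diff(range(sc$z$energies)), 0, tolerance = 1e-12)
  m <- find_min_angle(sc$z)
  expect_true(m$tie)
  expect_equal(m$angle_deg, 0)
})

test_that("minimum location ignores moment rescaling and the distance unit", {
  set.seed(29)
  for (rep in 1:5) {
    m1 <- rnorm(3); m2 <- rnorm(3); at2 <- runif(3, 5, 9)
    base <- rotation_scan(ud(m1), ud(m2, at2))
    scaled <- rotation_scan(ud(3.7 * m1), ud(0.4 * m2, at2))
    unit2 <- rotation_scan(ud(m1), ud(m2, at2), distance_unit = "angstrom")
    for (ax in c("x", "y", "z")) {
      expect_equal(scaled[[ax]]$min_angle_deg, base[[ax]]$min_angle_deg)
      expect_equal(unit2[[ax]]$min_angle_deg, base[[ax]]$min_angle_deg)
    }
  }
})

test_that("scans are symmetric for moments in the x-y plane scanned about x", {
  d1 <- ud(c(0, 1, 0)); d2 <- ud(c(0.6, 0.8, 0), c(5, 0, 0))
  # force the x-axis scan: frame x is the pair axis by construction
  sc <- rotation_scan(d1, d2)$x
  e <- sc$energies
  # energies at angle a and 360-a mirror each other
  expect_equal(e[2:36], rev(e[2:36]), tolerance = 1e-9)
})

test_that("translational arrangements hit their closed forms and keep |r|", {
  # unit moments perpendicular to the pair axis
  d1 <- ud(c(0, 0, 1)); d2 <- ud(c(0.2, 0.3, 0.9), c(6, 0, 0))
  arr <- translation_arrangements(d1, d2, distance_unit = "angstrom")
  expect_named(arr, c("side_by_side", "top_down", "staggered"))
  H2 <- vnorm_test(d2$moment)
  for (a in arr) {
    expect_equal(vnorm_test(a$d2$application_point - d1$application_point),
                 6, tolerance = 1e-9)
    expect_equal(vnorm_test(a$d2$moment), H2, tolerance = 1e-9)
  }
  # side-by-side parallel moments perpendicular to the displacement
  expect_equal(arr$side_by_side$energy0$value, -H2 / exp(6),
               tolerance = 1e-9)
  # top-down: moments along the displacement
  expect_equal(arr$top_down$energy0$value, 2 * H2 / exp(6), tolerance = 1e-9)
  # each arrangement carries fresh rotation scans on the same grid
  expect_equal(arr$staggered$scans$y$angles_deg, seq(0, 350, 10))
})

test_that("scans never mutate their input dipoles", {
  d1 <- ud(c(0, 1, 1)); d2 <- ud(c(1, 0.5, 0), c(5, 2, 0))
  snap <- unserialize(serialize(list(d1, d2), NULL))
  invisible(rotation_scan(d1, d2))
  invisible(translation_arrangements(d1, d2))
  expect_identical(list(d1, d2), snap)
})
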