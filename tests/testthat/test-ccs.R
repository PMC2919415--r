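test_that("a single sphere reproduces the analytic projected area", {
  m <- sphere_model("a", 0, 0, 0, 10, 1000)
  cc <- pa_ccs_spheres(m, seed = 3)
  expect_lt(abs(cc$value - pi * 100), 3 * cc$mc_stderr)
  # coincident spheres leave the union unchanged
  m2 <- sphere_model(c("a", "b"), c(0, 0), c(0, 0), c(0, 0),
                     c(10, 10), c(1, 1))
  cc2 <- pa_ccs_spheres(m2, seed = 3)
  expect_lt(abs(cc2$value - pi * 100), 3 * cc2$mc_stderr)
})

test_that("two-sphere estimates match the quadrature oracle", {
  r <- 10
  for (d in c(10, 15)) {
    m <- sphere_model(c("a", "b"), c(0, d), c(0, 0), c(0, 0), c(r, r), c(1, 1))
    cc <- pa_ccs_spheres(m, seed = 7)
    expect_lt(abs(cc$value - two_sphere_pa_oracle(r, r, d)),
              3 * cc$mc_stderr)
  }
})

test_that("atomic CCS uses element radii and the scale factor", {
  st <- structure(list(atoms = data.frame(
    element = "C", resid = "ALA", resno = 1, insert = "", chain = "A",
    x = 0, y = 0, z = 0, occ = 1, elety = "CA", type = "ATOM")),
    class = "ccs_structure")
  cc <- pa_ccs_atoms(st, seed = 5)
  expect_lt(abs(cc$value - pi * 2.2^2), 3 * max(cc$mc_stderr, 1e-4) + 0.05)
  cc2 <- pa_ccs_atoms(st, scale = 1.14, seed = 5)
  expect_equal(cc2$value, cc$value * 1.14)
  expect_error(pa_ccs_atoms(st, radii = collision_radii(default = NA)),
               "no collision")
})

test_that("CCS is invariant under rigid motion and scales quadratically", {
  spec <- fixture_spec(seed = 21, n_atoms = 120)
  st <- make_unit_structure(spec)
  cc <- pa_ccs_atoms(st, seed = 2)
  R <- rotation_matrix_for_tests()
  st2 <- st
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% t(R)
  st2$atoms$x <- xyz[, 1] + 40
  st2$atoms$y <- xyz[, 2]
  st2$atoms$z <- xyz[, 3] - 7
  cc2 <- pa_ccs_atoms(st2, seed = 22)
  expect_lt(abs(cc$value - cc2$value), 3 * (cc$mc_stderr + cc2$mc_stderr))
  # doubling all coordinates and radii quadruples the area
  m <- sphere_model(c("a", "b"), c(0, 12), c(0, 5), c(0, 0), c(8, 6), c(1, 1))
  big <- m
  big$x <- m$x * 2; big$y <- m$y * 2; big$z <- m$z * 2; big$radius <- m$radius * 2
  ca <- pa_ccs_spheres(m, seed = 9)
  cb <- pa_ccs_spheres(big, seed = 10)
  expect_lt(abs(cb$value - 4 * ca$value),
            3 * (cb$mc_stderr + 4 * ca$mc_stderr))
})

test_that("union area is monotone: adding a sphere never decreases CCS", {
  base <- sphere_model(c("a", "b"), c(0, 14), c(0, 0), c(0, 0), c(8, 8),
                       c(1, 1))
  cc0 <- pa_ccs_spheres(base, seed = 4)
  for (pos in list(c(7, 0, 0), c(0, 0, 20), c(-10, 5, 3))) {
    more <- rbind(base, sphere_model("c", pos[1], pos[2], pos[3], 6, 1))
    class(more) <- class(base)
    cc1 <- pa_ccs_spheres(more, seed = 4)
    expect_gt(cc1$value - cc0$value, -3 * (cc0$mc_stderr + cc1$mc_stderr))
  }
})

test_that("two far spheres approach additivity monotonically", {
  r <- 9
  vals <- vapply(c(18, 30, 60, 200), function(d) {
    m <- sphere_model(c("a", "b"), c(0, d), c(0, 0), c(0, 0), c(r, r), c(1, 1))
    pa_ccs_spheres(m, n_rotations = 400, seed = 8)$value
  }, 0)
  expect_true(all(diff(vals) > 0))
  expect_equal(vals[4], 2 * pi * r^2, tolerance = 0.01)
})

test_that("the linear missing-mass rule scales value and error", {
  acc <- structure(list(m_present = 96000, m_full = 100000,
                        f_missing = 0.04), class = "mass_account")
  cc <- structure(list(value = 1000, mc_stderr = 3, n_rotations = 300,
                       n_points = 4000, scale = 1, seed = 1),
                  class = "ccs_estimate")
  out <- linear_scale_ccs(cc, acc)
  expect_equal(out$value, 1000 * 100 / 96)   # 1041.67
  expect_equal(out$mc_stderr, 3 * 100 / 96)
  # the 2/3-power option
  out23 <- linear_scale_ccs(cc, acc, exponent = 2 / 3)
  expect_equal(out23$value, 1000 * (100 / 96)^(2 / 3))
  # no missing mass: unchanged
  acc0 <- structure(list(m_present = 1e5, m_full = 1e5, f_missing = 0),
                    class = "mass_account")
  expect_equal(linear_scale_ccs(cc, acc0)$value, 1000)
  # 13% missing (a gamma-subunit-like case) violates the 5% rule
  acc13 <- structure(list(m_present = 87000, m_full = 100000,
                          f_missing = 0.13), class = "mass_account")
  expect_error(linear_scale_ccs(cc, acc13), ">= 5%")
})

test_that("deviations classify against the tolerance", {
  expect_equal(ccs_deviation(1000, 1000)$deviation, 0)
  expect_true(ccs_deviation(1000, 1000)$within_error)
  d <- ccs_deviation(1110, 1000)
  expect_equal(d$deviation, 0.11)
  expect_false(d$within_error)
  expect_true(ccs_deviation(1110, 1000, rel_error = 0.12)$within_error)
})

test_that("the PA scale factor is recovered by least squares", {
  calc <- c(1000, 2000, 3500)
  expect_equal(fit_pa_scale(calc, calc * 1.14), 1.14)
})

test_that("CCS tables and radii tables round-trip", {
  tab <- data.frame(species = "x", n_subunits = 1:3,
                    ccs_A2 = c(4400, 7000, 9000), rel_error = 0.05)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_ccs_table(tab, tf)
  expect_equal(read_ccs_table(tf), tab)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_ccs_table(bad), "columns")

  ty <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("default: 2.0", "C: 1.91", "O: 1.66"), ty)
  cr <- read_collision_radii(ty)
  expect_equal(radii_for_elements(cr, c("C", "O", "N")), c(1.91, 1.66, 2.0))
})
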