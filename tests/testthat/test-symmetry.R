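test_that("symmetry expansion counts operators times lattice translations", {
  st <- make_unit_structure(fixture_spec(seed = 2, n_atoms = 80,
                                         operators = "identity"))
  b0 <- expand_symmetry(st, shell = 0)
  expect_length(b0$transforms, 1)
  b1 <- expand_symmetry(st, shell = 1)
  expect_length(b1$transforms, 27)   # 3^3 lattice translations
  # identity copy first
  expect_equal(b1$transforms[[1]]$t, c(0, 0, 0), tolerance = 1e-9)

  st4 <- make_unit_structure(fixture_spec(seed = 2, n_atoms = 80,
                                          operators = "ortho4"))
  b4 <- expand_symmetry(st4, shell = 1)
  expect_lte(length(b4$transforms), 108)   # 4 x 27 minus duplicates
  expect_gt(length(b4$transforms), 27)
})

test_that("duplicate operators are removed on expansion", {
  st <- make_unit_structure(fixture_spec(seed = 2, n_atoms = 80))
  ops <- list(list(R = diag(3), t = c(0, 0, 0)),
              list(R = diag(3), t = c(0, 0, 0)))
  b <- expand_symmetry(st, operators = ops, shell = 0)
  expect_length(b$transforms, 1)
})

test_that("fractional operators require a unit cell", {
  m <- beta_like_block()
  ops <- list(list(R = diag(3), t = c(0.5, 0, 0)))
  expect_error(expand_symmetry(m, operators = ops, shell = 0,
                               convention = "fractional"), "cell")
  b <- expand_symmetry(m, operators = ops, shell = 0,
                       cell = list(lengths = c(40, 40, 40),
                                   angles = c(90, 90, 90)),
                       convention = "fractional")
  expect_length(b$transforms, 2)   # identity added + the half-cell shift
  tmax <- max(vapply(b$transforms, function(tr) max(abs(tr$t)), 0))
  expect_equal(tmax, 20)   # 0.5 fractional of a 40 A cell
})

test_that("compactness sums pairwise COM distances", {
  d <- 30
  lin <- block_from_points(rbind(c(0, 0, 0), c(d, 0, 0), c(2 * d, 0, 0)))
  cands <- enumerate_candidates(lin, 3, cutoff = 1.5 * d)
  expect_equal(cands[[1]]$compactness, 4 * d)   # d + d + 2d
  tri <- block_from_points(rbind(c(0, 0, 0), c(d, 0, 0),
                                 c(d / 2, d * sqrt(3) / 2, 0)))
  ctri <- enumerate_candidates(tri, 3, cutoff = 1.5 * d)
  expect_equal(ctri[[1]]$compactness, 3 * d)
  expect_lt(ctri[[1]]$compactness, cands[[1]]$compactness)
})

test_that("compactness is invariant under global rigid motion", {
  set.seed(99)
  pts <- matrix(rnorm(12 * 3, sd = 20), ncol = 3)
  b1 <- block_from_points(pts)
  R <- rotation_matrix_for_tests()
  b2 <- block_from_points(sweep(pts %*% t(R), 2, c(30, -12, 5), `+`))
  cutoff <- 60
  c1 <- enumerate_candidates(b1, 4, cutoff = cutoff)
  c2 <- enumerate_candidates(b2, 4, cutoff = cutoff)
  expect_equal(vapply(c1, `[[`, 0, "compactness"),
               vapply(c2, `[[`, 0, "compactness"), tolerance = 1e-9)
})

test_that("enumeration agrees with brute force on random blocks", {
  for (sd in 1:6) {
    set.seed(sd)
    m <- sample(9:13, 1)
    pts <- matrix(rnorm(m * 3, sd = 18), ncol = 3)
    blk <- block_from_points(pts, unit_radius = 4)
    cutoff <- 28
    for (n in c(3, 4)) {
      mine <- enumerate_candidates(blk, n, cutoff = cutoff,
                                   clash_frac = Inf, max_candidates = 1e6)
      oracle <- brute_force_candidates(pts, n, cutoff)
      expect_equal(length(mine), length(oracle))
      if (length(mine) > 0) {
        expect_equal(mine[[1]]$members, oracle[[1]]$members)
        expect_equal(vapply(mine, `[[`, 0, "compactness"),
                     vapply(oracle, `[[`, 0, "compactness"),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("an isolated seed yields an empty result with a diagnostic", {
  pts <- rbind(c(0, 0, 0), c(500, 0, 0), c(520, 0, 0), c(540, 0, 0))
  blk <- block_from_points(pts)
  out <- enumerate_candidates(blk, 3, cutoff = 30)
  expect_length(out, 0)
  expect_match(attr(out, "diagnostic"), "no connected")
})

test_that("candidate ordering is deterministic", {
  set.seed(4)
  pts <- matrix(rnorm(12 * 3, sd = 16), ncol = 3)
  blk <- block_from_points(pts)
  c1 <- enumerate_candidates(blk, 4, cutoff = 30)
  c2 <- enumerate_candidates(blk, 4, cutoff = 30)
  expect_identical(lapply(c1, `[[`, "members"), lapply(c2, `[[`, "members"))
})

test_that("a planted rectangular tetramer is recovered stepwise", {
  # planar rectangular 4-copy motif plus decoys farther out
  a <- 24; b <- 30
  pts <- rbind(c(0, 0, 0), c(a, 0, 0), c(0, b, 0), c(a, b, 0),
               c(-a, -b, 0), c(2 * a, b, 0), c(a, 2 * b, 0),
               c(2 * a, 2 * b, 0))
  # the unit footprint overlaps neighbouring copies in projection, so the
  # archetype cross-sections genuinely discriminate line from L from square
  blk <- block_from_points(pts, unit_radius = 14)
  planted <- list(`2` = 1:2, `3` = 1:3, `4` = 1:4)
  tab <- do.call(rbind, lapply(2:4, function(n) {
    cc <- oligomer_ccs(candidate_oligomer(blk, list(members = planted[[as.character(n)]])),
                       n_rotations = 200, n_points = 2500, seed = 77)
    data.frame(species = "x", n_subunits = n, ccs_A2 = cc$value,
               rel_error = NA_real_)
  }))
  ser <- stepwise_series(blk, 4, tab, cutoff = 45, seed = 13)
  expect_null(ser$truncated)
  for (n in 2:4)
    expect_equal(fingerprint(pts[ser$series[[as.character(n)]]$members, ]),
                 fingerprint(pts[planted[[as.character(n)]], ]),
                 tolerance = 1e-6)
  # nesting invariant along the series
  for (n in 3:4)
    expect_true(all(ser$series[[as.character(n - 1)]]$members %in%
                      ser$series[[as.character(n)]]$members))
})

test_that("a series of one order is the building block alone", {
  blk <- block_from_points(rbind(c(0, 0, 0), c(25, 0, 0)))
  ser <- stepwise_series(blk, 1, NULL)
  expect_length(ser$series, 1)
  expect_equal(ser$series[["1"]]$members, 1L)
})

test_that("symmetric COM arrangements score higher than irregular ones", {
  sq <- rbind(c(0, 0, 0), c(20, 0, 0), c(20, 20, 0), c(0, 20, 0))
  set.seed(8)
  irr <- matrix(rnorm(12, sd = 15), ncol = 3)
  expect_gt(symmetry_score(sq), symmetry_score(irr))
})
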