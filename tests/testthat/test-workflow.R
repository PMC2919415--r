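make_account <- function(f) {
  structure(list(m_present = 1e5 * (1 - f), m_full = 1e5, f_missing = f),
            class = "mass_account")
}

test_that("routing follows the completion decision tree", {
  expect_equal(decide_path(make_account(0))$path, "complete")
  expect_equal(decide_path(make_account(0.03))$path, "linear_scaled")
  # DnaB-like: 75% missing with a 35% identity template
  expect_equal(decide_path(make_account(0.75),
                           list(seq_identity = 35, completeness = 25))$path,
               "homology")
  # SSB-like: 32% missing, no homolog
  expect_equal(decide_path(make_account(0.32))$path, "coarse_grained")
  expect_equal(decide_path(make_account(0.32),
                           list(seq_identity = 20, completeness = 50))$path,
               "coarse_grained")
  # ambiguous region: S.I. > 30 but template essentially complete
  expect_warning(
    pd <- decide_path(make_account(0.40),
                      list(seq_identity = 50, completeness = 98)),
    "ambiguous")
  expect_equal(pd$path, "coarse_grained")
})

test_that("routing is total: every input maps to exactly one path", {
  fs <- c(0, 0.01, 0.049, 0.05, 0.2, 0.75, 0.9)
  homs <- list(NULL, list(seq_identity = 10, completeness = 50),
               list(seq_identity = 50, completeness = 50),
               list(seq_identity = 50, completeness = 99))
  for (f in fs) for (h in homs) {
    pd <- suppressWarnings(decide_path(make_account(f), h))
    expect_true(pd$path %in% c("complete", "linear_scaled", "homology",
                               "coarse_grained"))
  }
})

test_that("conformer comparison picks the model closer to the data", {
  blk <- beta_like_block()
  ext <- generate_archetype(blk, 2, "linear")
  cmp <- generate_archetype(blk, 2, "collapsed")
  target <- oligomer_ccs(cmp, n_rotations = 200, n_points = 2500, seed = 3)
  res <- compare_conformers(ext, cmp, target$value, seed = 9)
  expect_equal(res$choice, "b")
  res2 <- compare_conformers(cmp, cmp, target$value, seed = 9)
  expect_equal(res2$choice, "tie")
  blk2 <- sphere_model("s", 0, 0, 0, 10, 999)
  expect_error(compare_conformers(ext, generate_archetype(blk2, 2, "linear"),
                                  1000), "composition")
})

test_that("the linear-scaled path propagates the mass-ratio factor", {
  spec <- fixture_spec(seed = 15, n_atoms = 160, gap_fraction = 0.025,
                       operators = "identity")
  st <- make_unit_structure(spec)
  acc <- mass_account(st)
  expect_lt(acc$f_missing, 0.05)
  expect_gt(acc$f_missing, 0)
  tab <- make_planted_ccs_table(st, "linear", c(1, 2, 3), noise = 0, seed = 3)
  rep <- run_pipeline(list(structure = st, ccs_table = tab, seed = 4,
                           use_symmetry = FALSE,
                           topologies = c("linear", "collapsed"),
                           n_values = 2:3))
  expect_equal(rep$decision$path, "linear_scaled")
  expect_match(rep$completion, "scale factor")
  # the trend CCS carries the scale: roughly mass-ratio above the planted
  fac <- acc$m_full / acc$m_present
  lin <- rep$trends$ccs_A2[rep$trends$topology == "linear" &
                             rep$trends$n == 2]
  expect_equal(lin / tab$ccs_A2[tab$n_subunits == 2], fac, tolerance = 0.02)
})

test_that("the coarse-grained path completes the block and conserves mass", {
  spec <- fixture_spec(seed = 16, n_atoms = 240, shape = "dumbbell",
                       gap_fraction = 0.3, operators = "identity")
  st <- make_unit_structure(spec)
  acc <- mass_account(st)
  expect_gt(acc$f_missing, 0.2)
  # a feasible monomer CCS target: somewhat above the resolved-part CCS
  base <- pa_ccs_atoms(st, n_rotations = 150, n_points = 2000, seed = 2)
  tab <- data.frame(species = "syn", n_subunits = c(1, 2),
                    ccs_A2 = c(base$value * 1.25, base$value * 2.1),
                    rel_error = NA_real_)
  rep <- run_pipeline(list(structure = st, ccs_table = tab, seed = 6,
                           use_symmetry = FALSE,
                           topologies = c("linear", "collapsed"),
                           n_values = 2))
  expect_equal(rep$decision$path, "coarse_grained")
  expect_s3_class(rep$block, "sphere_model")
  expect_true("missing" %in% rep$block$kind)
  expect_equal(sum(rep$block$mass), acc$m_full, tolerance = 1e-6)
})

test_that("reports are byte-identical across reruns (modulo nothing)", {
  spec <- fixture_spec(seed = 17, n_atoms = 120, operators = "P1")
  st <- make_unit_structure(spec)
  tab <- make_planted_ccs_table(st, "symmetry_mined", 1:3, noise = 0,
                                seed = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- list(structure = st, ccs_table = tab, seed = 9, n_values = 2:3,
              topologies = c("linear", "collapsed"))
  run_pipeline(c(cfg, list(out_dir = d1)))
  run_pipeline(c(cfg, list(out_dir = d2)))
  for (f in c("report.json", "trend_lines.csv", "ranking.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("a planted archetype stays within error while the bounds reject", {
  st <- make_unit_structure(fixture_spec(seed = 19, n_atoms = 160,
                                         operators = "identity"))
  tab <- make_planted_ccs_table(st, "ring", c(3, 4, 5), noise = 0, seed = 5)
  rep <- run_pipeline(list(structure = st, ccs_table = tab, seed = 7,
                           use_symmetry = FALSE, n_values = c(3, 4, 5)))
  ring <- rep$ranking[rep$ranking$topology == "ring", ]
  expect_true(all(ring$within_error))
  expect_true(all(abs(ring$deviation) < 0.05))
  # the collapsed lower bound under-estimates the ring series at n >= 4
  coll <- rep$ranking[rep$ranking$topology == "collapsed" &
                        rep$ranking$n >= 4, ]
  expect_true(all(coll$deviation < -0.05))
  expect_true(rep$selected != "no consistent model")
})
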