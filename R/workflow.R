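#' Decide the building-block completion path
#'
#' Deterministic routing of a structure through the completion decision tree:
#' a complete structure is used as is; below 5% missing mass the computed CCS
#' is linearly scaled; otherwise a homology model is used when a template
#' with sequence identity (S.I.) above 30% and structural completeness (S.C.)
#' below 95% exists; failing that the missing mass is represented by
#' coarse-grained spheres.  S.C. is the percentage of the full mass present
#' in the template structure.  The region S.I. > 30% with S.C. >= 95%, and
#' missing mass >= 5% with no homology information, route to the
#' coarse-grained path with a warning.
#'
#' @param account a [mass_account()] of the building-block structure.
#' @param homolog optional `list(seq_identity, completeness)` in percent
#'   describing the best available homology template.
#' @return a `path_decision`: list with `path` (one of `"complete"`,
#'   `"linear_scaled"`, `"homology"`, `"coarse_grained"`), the routing inputs
#'   and a human-readable `rationale`.
#' @export
decide_path <- function(account, homolog = NULL) {
  stopifnot(inherits(account, "mass_account"))
  f <- account$f_missing
  si <- homolog$seq_identity %||% NA_real_
  sc <- homolog$completeness %||% NA_real_
  if (f <= 1e-9) {
    path <- "complete"
    why <- "no mass missing from the structure"
  } else if (f < 0.05) {
    path <- "linear_scaled"
    why <- sprintf("%.1f%% missing mass is below the 5%% rule: scale the computed CCS linearly", 100 * f)
  } else if (!is.null(homolog) && is.finite(si) && si > 30 &&
             is.finite(sc) && sc < 95) {
    path <- "homology"
    why <- sprintf("homology template with S.I. %.0f%% > 30%% and S.C. %.0f%% < 95%%", si, sc)
  } else {
    path <- "coarse_grained"
    why <- if (!is.null(homolog) && is.finite(si) && si > 30)
      sprintf("template S.C. %.0f%% >= 95%% falls outside the homology rule; representing missing mass with coarse-grained spheres", sc)
    else
      sprintf("%.1f%% missing mass with no usable homology template (S.I. <= 30%% or none): coarse-grained completion", 100 * f)
    if (!is.null(homolog) && is.finite(si) && si > 30)
      warning("ambiguous routing (S.I. > 30% but S.C. >= 95%): using the coarse-grained path", call. = FALSE)
  }
  structure(list(path = path, f_missing = f, seq_identity = si,
                 structure_completeness = sc, rationale = why),
            class = "path_decision")
}

#' @export
print.path_decision <- function(x, ...) {
  cat("path_decision:", x$path, "-", x$rationale, "\n")
  invisible(x)
}

#' Run the full topology-modelling pipeline
#'
#' Orchestrates the workflow: mass accounting and path decision for the
#' building block; completion (linear CCS scaling, user-supplied homology
#' model, or coarse-grained spheres with a placed missing-mass sphere);
#' archetype trend lines; crystal-symmetry mining with stepwise nested
#' selection; and a final ranking of topologies against the measured CCS
#' series.  Fully reproducible from the configuration and seed.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{structure}{path to the building-block PDB (or a
#'       `ccs_structure`).}
#'     \item{ccs_table}{path to the experimental CCS CSV (or a data frame),
#'       columns species/n_subunits/ccs_A2/rel_error, in building-block
#'       units.}
#'     \item{fasta}{optional full-length sequences (named list or FASTA
#'       path).}
#'     \item{homolog}{optional list(model = path, seq_identity, completeness).}
#'     \item{n_values}{oligomer orders to rank (default 2..max in table).}
#'     \item{topologies}{archetypes for trend lines (default linear, ring,
#'       collapsed, edge_to_edge, stack_face).}
#'     \item{use_symmetry}{mine crystal symmetry (default TRUE when operators
#'       are available).}
#'     \item{tolerance}{within-error tolerance (default 0.10).}
#'     \item{scale}{PA scale factor (default 1).}
#'     \item{seed}{master seed (default 1).}
#'     \item{n_rotations, n_points}{CCS sampling (defaults 150 and 2000 for
#'       ranking-scale work).}
#'     \item{anchor}{anchor sphere label for missing-sphere placement
#'       (default the largest domain).}
#'     \item{out_dir}{optional directory for artifacts (trend CSV, candidate
#'       JSON, sphere/oligomer PDBs, report JSON).}
#'   }
#' @return a `ranking_report`: list with `decision`, `block` (the completed
#'   building block), `trends`, `mined` (a `stepwise_series` or NULL),
#'   `ranking` (per-order best topology data frame), `selected` (topology
#'   consistent with the whole series, or `"no consistent model"`), and the
#'   configuration echo.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- config
  seed <- cfg$seed %||% 1L
  tol <- cfg$tolerance %||% 0.10
  scale <- cfg$scale %||% 1
  n_rot <- cfg$n_rotations %||% 150L
  n_pts <- cfg$n_points %||% 2000L
  radii <- cfg$radii %||% collision_radii()

  st <- cfg$structure
  if (is.character(st)) st <- read_structure(st, fasta = cfg$fasta)
  ccs_tab <- cfg$ccs_table
  if (is.character(ccs_tab)) ccs_tab <- read_ccs_table(ccs_tab)
  if (is.null(ccs_tab)) stop("config must name a CCS table")
  n_values <- cfg$n_values %||% sort(unique(ccs_tab$n_subunits[ccs_tab$n_subunits >= 2]))
  topologies <- cfg$topologies %||% c("linear", "ring", "collapsed",
                                      "edge_to_edge", "stack_face")

  account <- mass_account(st)
  decision <- decide_path(account, cfg$homolog)

  # ----- building-block completion ------------------------------------
  monomer_row <- ccs_tab[ccs_tab$n_subunits == 1, , drop = FALSE]
  block <- st
  block_scale <- scale
  completion <- NULL
  if (decision$path == "linear_scaled") {
    # downstream CCS values of this block are scaled by the mass ratio
    block_scale <- scale * (account$m_full / account$m_present)
    completion <- sprintf("CCS linear scale factor %.4f", account$m_full / account$m_present)
  } else if (decision$path == "homology") {
    if (is.null(cfg$homolog$model))
      stop("homology path requires a user-supplied model (homolog$model)")
    block <- if (is.character(cfg$homolog$model))
      read_structure(cfg$homolog$model) else cfg$homolog$model
    completion <- "user-supplied homology model used as the building block"
  } else if (decision$path == "coarse_grained" && account$f_missing > 1e-9) {
    dec <- decompose_domains(st, k = cfg$cg$k %||% "auto",
                             cutoff = cfg$cg$cutoff %||% 8)
    cg <- build_sphere_model(st, dec, radii = radii, seed = seed)
    cg <- calibrate_radii(st, cg, radii = radii, seed = seed + 1,
                          n_rotations = n_rot, n_points = n_pts)
    miss_mass <- account$m_full - account$m_present
    r_miss <- missing_sphere_radius(cg, miss_mass)
    anchor <- cfg$anchor %||% cg$label[which.max(cg$mass)]
    if (nrow(monomer_row) == 1) {
      placed <- place_missing_sphere(cg, anchor, r_miss,
                                     monomer_row$ccs_A2,
                                     mass = miss_mass,
                                     rel_error = monomer_row$rel_error,
                                     seed = seed + 2)
      block <- placed$model
      completion <- sprintf(
        "missing mass (%.0f Da) placed as a %.1f A sphere at overlap %.2f, theta %.2f",
        miss_mass, r_miss, placed$scan$best$overlap, placed$scan$best$theta)
    } else {
      # no monomer measurement: attach the missing sphere tangent to the
      # anchor, pointing away from the model COM (most extended choice)
      block <- attach_tangent_sphere(cg, anchor, r_miss, miss_mass)
      completion <- sprintf(
        "missing mass (%.0f Da) attached tangent to %s (no monomer CCS restraint)",
        miss_mass, anchor)
    }
    attr(block, "sym_source") <- st
  } else if (decision$path == "coarse_grained") {
    completion <- "structure complete; used as is"
  }

  # ----- archetype trend lines ----------------------------------------
  trends <- trend_lines(block, topologies, n_values, experimental = ccs_tab,
                        radii = radii, scale = block_scale,
                        n_rotations = n_rot, n_points = n_pts, seed = seed)

  # ----- symmetry mining ----------------------------------------------
  sym_source <- if (inherits(block, "ccs_structure")) block
                else attr(block, "sym_source")
  mined <- NULL
  use_sym <- cfg$use_symmetry %||%
    (!is.null(sym_source) && !is.null(sym_source$sym_ops))
  if (isTRUE(use_sym)) {
    symblk <- expand_symmetry(sym_source, shell = cfg$shell %||% 1,
                              radii = radii)
    # mine with the completed block geometry but crystal transforms
    symblk$unit <- block
    symblk$unit_radius <- block_bounding_radius(block, radii)
    symblk$coms <- t(vapply(symblk$transforms, function(tr)
      as.numeric(tr$R %*% block_com(block, radii) + tr$t), numeric(3)))
    mined <- stepwise_series(symblk, max(n_values), ccs_tab,
                             tolerance = tol, scale = block_scale,
                             n_rotations = n_rot, n_points = n_pts,
                             seed = seed + 3,
                             max_candidates = cfg$max_candidates %||% 20)
  }

  # ----- ranking -------------------------------------------------------
  rank_rows <- list()
  for (n in n_values) {
    exp_row <- ccs_tab[ccs_tab$n_subunits == n, , drop = FALSE]
    if (nrow(exp_row) == 0) next
    sub <- trends[trends$n == n, , drop = FALSE]
    entries <- data.frame(topology = sub$topology, n = n, ccs = sub$ccs_A2)
    if (!is.null(mined) && as.character(n) %in% names(mined$series)) {
      cd <- mined$series[[as.character(n)]]
      entries <- rbind(entries, data.frame(topology = "symmetry_mined",
                                           n = n, ccs = cd$ccs))
    }
    dv <- lapply(entries$ccs, ccs_deviation, exp_ccs = exp_row$ccs_A2[1],
                 tolerance = tol)
    entries$deviation <- vapply(dv, `[[`, 0, "deviation")
    entries$within_error <- vapply(dv, `[[`, TRUE, "within_error")
    entries$best <- seq_len(nrow(entries)) == which.min(abs(entries$deviation))
    rank_rows[[as.character(n)]] <- entries
  }
  ranking <- do.call(rbind, c(rank_rows, make.row.names = FALSE))

  # a topology is consistent when it is within error at every ranked order
  by_topo <- split(ranking, ranking$topology)
  consistent <- names(by_topo)[vapply(by_topo, function(df)
    all(df$within_error), logical(1))]
  selected <- if (length(consistent) == 0) "no consistent model" else {
    mean_dev <- vapply(by_topo[consistent],
                       function(df) mean(abs(df$deviation)), 0)
    names(which.min(mean_dev))
  }

  report <- structure(list(
    decision = decision, account = account, completion = completion,
    block = block, trends = trends, mined = mined, ranking = ranking,
    selected = selected,
    config = list(seed = seed, tolerance = tol, scale = scale,
                  n_rotations = n_rot, n_points = n_pts,
                  n_values = n_values, topologies = topologies)),
    class = "ranking_report")

  if (!is.null(cfg$out_dir)) write_report_artifacts(report, cfg$out_dir)
  report
}

attach_tangent_sphere <- function(model, anchor, radius, mass) {
  ia <- which(model$label == anchor)
  a <- as.numeric(model[ia, c("x", "y", "z")])
  com <- colSums(model[, c("x", "y", "z")] * model$mass) / sum(model$mass)
  u <- a - com
  if (sqrt(sum(u^2)) < 1e-8) u <- c(1, 0, 0) else u <- u / sqrt(sum(u^2))
  ctr <- a + (model$radius[ia] + radius) * u
  out <- rbind(model, sphere_model("missing", ctr[1], ctr[2], ctr[3],
                                   radius, mass, kind = "missing"))
  class(out) <- class(model)
  out
}

#' @export
print.ranking_report <- function(x, ...) {
  print(x$decision)
  if (!is.null(x$completion)) cat("completion:", x$completion, "\n")
  cat("selected topology:", x$selected, "\n")
  best <- x$ranking[x$ranking$best, , drop = FALSE]
  for (i in seq_len(nrow(best)))
    cat(sprintf("  n = %d: best %s (deviation %+.1f%%)\n", best$n[i],
                best$topology[i], 100 * best$deviation[i]))
  invisible(x)
}

write_report_artifacts <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$trends, file.path(out_dir, "trend_lines.csv"),
            row.names = FALSE)
  write.csv(report$ranking, file.path(out_dir, "ranking.csv"),
            row.names = FALSE)
  if (inherits(report$block, "sphere_model"))
    write_sphere_pdb(report$block, file.path(out_dir, "building_block.pdb"))
  if (!is.null(report$mined))
    write_candidates_json(report$mined, file.path(out_dir, "candidates.json"))
  jsonlite::write_json(
    list(path = report$decision$path,
         f_missing = report$account$f_missing,
         selected = report$selected,
         ranking = report$ranking,
         config = report$config),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Compare two candidate conformers against a measured CCS
#'
#' Computes the CCS of two models of the same composition (for instance
#' head-to-head versus tail-to-tail dimer arrangements) and returns the one
#' closer to the measurement.
#'
#' @param model_a,model_b `oligomer_model`s or `sphere_model`s of identical
#'   composition (same total sphere count and mass).
#' @param exp_ccs measured CCS, square Angstrom.
#' @param scale,n_rotations,n_points,seed CCS settings.
#' @return list with `choice` (`"a"`, `"b"` or `"tie"`), `deviation_a`,
#'   `deviation_b` and the two estimates.
#' @export
compare_conformers <- function(model_a, model_b, exp_ccs, scale = 1,
                               n_rotations = 300, n_points = 4000, seed = 1) {
  get_ccs <- function(m, sd2)
    if (inherits(m, "oligomer_model"))
      oligomer_ccs(m, scale, n_rotations, n_points, sd2)
    else pa_ccs_spheres(m, n_rotations, n_points, sd2, scale)
  comp <- function(m) {
    s <- if (inherits(m, "oligomer_model")) assemble_oligomer(m) else m
    c(nrow(s), sum(s$mass))
  }
  ca <- comp(model_a); cb <- comp(model_b)
  if (ca[1] != cb[1] || abs(ca[2] - cb[2]) > 1e-6 * max(ca[2], cb[2]))
    stop("models differ in composition (", ca[1], " vs ", cb[1],
         " spheres, masses ", round(ca[2]), " vs ", round(cb[2]), " Da)")
  a <- get_ccs(model_a, seed)
  b <- get_ccs(model_b, seed + 1)
  da <- ccs_deviation(a, exp_ccs)$deviation
  db <- ccs_deviation(b, exp_ccs)$deviation
  tie_band <- 3 * (a$mc_stderr + b$mc_stderr) / exp_ccs
  choice <- if (abs(abs(da) - abs(db)) <= tie_band) "tie"
            else if (abs(da) < abs(db)) "a" else "b"
  list(choice = choice, deviation_a = da, deviation_b = db,
       ccs_a = a, ccs_b = b)
}
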