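# Orthogonalization matrix (columns = cell vectors) from cell lengths and
# angles in degrees, standard PDB convention.
cell_matrix <- function(cell) {
  a <- cell$lengths[1]; b <- cell$lengths[2]; c <- cell$lengths[3]
  al <- cell$angles[1] * pi / 180
  be <- cell$angles[2] * pi / 180
  ga <- cell$angles[3] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), c * cos(be),
           0, b * sin(ga), c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, c * v / sin(ga)), 3, 3, byrow = TRUE)
}

#' Expand crystal symmetry into a block of building-unit copies
#'
#' Applies every symmetry operator combined with every lattice translation
#' within `shell` unit cells along each axis to the building unit, yielding
#' the neighbourhood of crystal-packed copies from which candidate oligomers
#' are mined.  Identical transforms are deduplicated; the identity copy is
#' always present (index 1).
#'
#' @param unit the building unit: a `ccs_structure` (operators default to its
#'   REMARK 290 set) or a `sphere_model`.
#' @param operators list of `list(R, t)` operators; defaults to the unit's
#'   parsed symmetry operators.  The identity is added if absent.
#' @param shell number of lattice shells (default 1: translations -1..1 per
#'   axis).
#' @param cell unit cell (`list(lengths, angles)`); defaults to the unit's.
#'   Required whenever `shell > 0` or `convention = "fractional"`.
#' @param convention `"cartesian"` (REMARK 290 style, translations in
#'   Angstrom) or `"fractional"` (operators act on fractional coordinates).
#' @param radii collision radii (for atomic units' centre of mass).
#' @return a `sym_block`: list with `unit`, `transforms`, `coms` (matrix),
#'   and bookkeeping columns `ops` (data frame operator id and lattice shift).
#' @export
expand_symmetry <- function(unit, operators = NULL, shell = 1, cell = NULL,
                            convention = c("cartesian", "fractional"),
                            radii = collision_radii()) {
  convention <- match.arg(convention)
  if (is.null(operators) && inherits(unit, "ccs_structure"))
    operators <- unit$sym_ops
  if (is.null(operators) || length(operators) == 0)
    stop("no symmetry operators: supply `operators` or a structure with ",
         "REMARK 290 records")
  if (is.null(cell) && inherits(unit, "ccs_structure")) cell <- unit$cell

  if (convention == "fractional") {
    if (is.null(cell)) stop("fractional operators require a unit cell")
    M <- cell_matrix(cell)
    Minv <- solve(M)
    operators <- lapply(operators, function(op)
      list(R = M %*% op$R %*% Minv, t = as.numeric(M %*% op$t)))
  }
  has_id <- any(vapply(operators, function(o)
    max(abs(o$R - diag(3))) < 1e-6 && max(abs(o$t)) < 1e-4, logical(1)))
  if (!has_id)
    operators <- c(list(list(R = diag(3), t = numeric(3))), operators)

  shifts <- expand.grid(i = -shell:shell, j = -shell:shell, k = -shell:shell)
  if (shell > 0) {
    if (is.null(cell)) stop("lattice shells require a unit cell (CRYST1)")
    M <- cell_matrix(cell)
  } else M <- diag(3)

  com0 <- block_com(unit, radii)
  transforms <- list()
  meta <- list()
  seen <- character()
  for (oi in seq_along(operators)) {
    op <- operators[[oi]]
    for (si in seq_len(nrow(shifts))) {
      tvec <- op$t + as.numeric(M %*% as.numeric(shifts[si, ]))
      key <- paste(round(c(op$R, tvec), 4), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      transforms[[length(transforms) + 1]] <- list(R = op$R, t = tvec)
      meta[[length(meta) + 1]] <- data.frame(
        op = oi, i = shifts$i[si], j = shifts$j[si], k = shifts$k[si])
    }
  }
  # put the identity copy first
  is_id <- vapply(transforms, function(tr)
    max(abs(tr$R - diag(3))) < 1e-6 && max(abs(tr$t)) < 1e-4, logical(1))
  ord <- order(!is_id)
  transforms <- transforms[ord]
  meta <- do.call(rbind, meta)[ord, , drop = FALSE]
  coms <- t(vapply(transforms, function(tr)
    as.numeric(tr$R %*% com0 + tr$t), numeric(3)))
  structure(list(unit = unit, transforms = transforms, coms = coms,
                 ops = meta, radii = radii,
                 unit_radius = block_bounding_radius(unit, radii)),
            class = "sym_block")
}

#' @export
print.sym_block <- function(x, ...) {
  cat("sym_block:", length(x$transforms), "copies (unit radius",
      sprintf("%.1f", x$unit_radius), "A)\n")
  invisible(x)
}

# Sum of pairwise COM distances of the copies indexed by `members`.
compactness <- function(block, members) {
  p <- block$coms[members, , drop = FALSE]
  sum(stats::dist(p))
}

#' Enumerate compact candidate assemblies within a symmetry block
#'
#' Enumerates connected subsets of `n` copies that contain the reference
#' (identity) building block -- copies are neighbours when their COM distance
#' is at most `cutoff` -- and ranks them by compactness, the sum of pairwise
#' COM distances.  Candidates whose copy bounding spheres interpenetrate by
#' more than `clash_frac` of a sphere volume are discarded.
#'
#' @param block a [expand_symmetry()] result.
#' @param n assembly size (>= 2).
#' @param max_candidates number of candidates returned (default 500).
#' @param cutoff neighbour COM distance; default `1.2 * 2 * unit bounding
#'   radius` (near-touching copies).
#' @param clash_frac pairwise bounding-sphere volume-overlap limit
#'   (default 0.05).
#' @param required copy indices every candidate must contain (default the
#'   identity copy, index 1); used by [stepwise_series()] for nesting.
#' @param budget cap on enumeration nodes explored (default 200000).
#' @return list of `candidate_assembly` objects (members, compactness),
#'   sorted by ascending compactness; empty with attribute `"diagnostic"`
#'   when no connected subset exists.
#' @export
enumerate_candidates <- function(block, n, max_candidates = 500,
                                 cutoff = NULL, clash_frac = 0.05,
                                 required = 1L, budget = 200000) {
  stopifnot(inherits(block, "sym_block"))
  if (n < 2) stop("n must be >= 2")
  m <- nrow(block$coms)
  if (m < n) stop("block has fewer than n copies")
  if (is.null(cutoff)) cutoff <- 1.2 * 2 * block$unit_radius
  d <- as.matrix(stats::dist(block$coms))
  nb <- lapply(seq_len(m), function(i) which(d[i, ] <= cutoff & seq_len(m) != i))

  required <- sort(unique(as.integer(required)))
  results <- list()
  explored <- 0L

  # rooted ESU-style enumeration: each connected n-subset containing the
  # required seed is visited exactly once (extend only through exclusive
  # neighbours of the vertex just added)
  grow <- function(members, ext) {
    if (explored > budget) return()
    explored <<- explored + 1L
    if (length(members) == n) {
      results[[length(results) + 1]] <<- sort(members)
      return()
    }
    nbh <- unique(unlist(nb[members]))
    while (length(ext) > 0) {
      w <- ext[1]
      ext <- ext[-1]
      excl <- setdiff(nb[[w]], c(members, nbh))
      grow(c(members, w), c(ext, excl))
    }
  }
  if (length(required) > 1) {
    # the required set itself must be connected (it is a previously selected
    # assembly); if not, no candidate can contain it
    sub <- d[required, required, drop = FALSE] <= cutoff
    diag(sub) <- FALSE
    if (!network_connected(sub))
      return(structure(list(),
                       diagnostic = "required set not connected under cutoff"))
  }
  grow(required, setdiff(unique(unlist(nb[required])), required))

  if (length(results) == 0)
    return(structure(list(),
                     diagnostic = paste0("no connected ", n,
                                         "-subset under cutoff ", round(cutoff, 2))))

  comp <- vapply(results, function(mm) compactness(block, mm), 0)
  ord <- order(comp)
  results <- results[ord]; comp <- comp[ord]

  out <- list()
  for (i in seq_along(results)) {
    if (length(out) >= max_candidates) break
    mm <- results[[i]]
    if (max_pair_overlap(block, mm) > clash_frac) next
    out[[length(out) + 1]] <- structure(
      list(members = mm, compactness = comp[i], ccs = NULL,
           deviation = NULL, nested_parent = NULL),
      class = "candidate_assembly")
  }
  out
}

# Largest pairwise bounding-sphere volume-overlap fraction among members.
max_pair_overlap <- function(block, members) {
  R <- block$unit_radius
  p <- block$coms[members, , drop = FALSE]
  dd <- as.matrix(stats::dist(p))
  dmin <- min(dd[upper.tri(dd)])
  if (dmin >= 2 * R) return(0)
  lens <- pi * (4 * R + dmin) * (2 * R - dmin)^2 / 12
  lens / (4 / 3 * pi * R^3)
}

#' @export
print.candidate_assembly <- function(x, ...) {
  cat(sprintf("candidate_assembly: %d copies [%s], compactness %.1f A%s\n",
              length(x$members), paste(x$members, collapse = " "),
              x$compactness,
              if (!is.null(x$ccs)) sprintf(", CCS %.1f A^2", x$ccs) else ""))
  invisible(x)
}

# Oligomer view of a candidate (for CCS and PDB export).
candidate_oligomer <- function(block, cand) {
  new_oligomer(block$unit, block$transforms[cand$members],
               "symmetry_mined", block$radii)
}

# Crude point-group symmetry score of a COM arrangement: the number of
# nontrivial rotations (orders 2 and 3 about candidate axes) mapping the
# centred point set onto itself within `tol` per point.
symmetry_score <- function(points, tol = 1.0) {
  p <- sweep(points, 2, colMeans(points))
  n <- nrow(p)
  if (n < 2) return(0)
  axes <- list()
  ev <- eigen(crossprod(p) + diag(3) * 1e-9, symmetric = TRUE)$vectors
  for (i in 1:3) axes[[length(axes) + 1]] <- ev[, i]
  for (i in seq_len(n)) {
    v <- p[i, ]
    if (sqrt(sum(v^2)) > 1e-6) axes[[length(axes) + 1]] <- v / sqrt(sum(v^2))
  }
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    v <- (p[i, ] + p[j, ]) / 2
    if (sqrt(sum(v^2)) > 1e-6) axes[[length(axes) + 1]] <- v / sqrt(sum(v^2))
  }
  score <- 0
  seen <- character()
  for (ax in axes) for (ord in c(2, 3)) {
    key <- paste(round(abs(ax), 2), ord, collapse = ",")
    if (key %in% seen) next
    Rm <- rotation_about_axis(ax, 2 * pi / ord)
    q <- p %*% t(Rm)
    ok <- all(vapply(seq_len(n), function(i)
      min(sqrt(rowSums(sweep(p, 2, q[i, ])^2))) < tol, logical(1)))
    if (ok) { score <- score + 1; seen <- c(seen, key) }
  }
  score
}

#' Stepwise nested selection of symmetry-mined assemblies
#'
#' Builds candidate assemblies order by order: for each n from 2 to `n_max`
#' the candidate minimizing the absolute CCS deviation from the measured
#' value is selected, subject to containing the selected (n-1)-assembly
#' (every subcomplex shares n-1 building blocks with its lower-order
#' structure).  Near-ties (deviations within `tie_tol`) are broken first by a
#' higher point-group symmetry of the COM arrangement -- proteins show a
#' strong tendency for symmetric complexes -- then by lower compactness.
#' Orders with no measured CCS are selected by compactness alone.
#'
#' @param block a [expand_symmetry()] result.
#' @param n_max largest assembly order.
#' @param ccs_table experimental series (columns n_subunits, ccs_A2,
#'   rel_error), in building-block units.
#' @param tolerance within-error tolerance on the relative CCS deviation
#'   (default 0.10, the typical experimental error).
#' @param tie_tol absolute deviation difference treated as a tie
#'   (default 0.01).
#' @param max_candidates candidates evaluated per order (default 20 most
#'   compact; the nesting constraint keeps this exhaustive in practice).
#' @param cutoff,clash_frac as in [enumerate_candidates()].
#' @param scale,n_rotations,n_points,seed CCS settings.
#' @return a `stepwise_series`: list with `series` (selected
#'   `candidate_assembly` per n, CCS and deviation filled), and `report`
#'   (data frame n, ccs, deviation, within_error, symmetry, compactness).
#'   Stops early (partial series) when no candidate is within tolerance.
#' @export
stepwise_series <- function(block, n_max, ccs_table = NULL, tolerance = 0.10,
                            tie_tol = 0.01, max_candidates = 20,
                            cutoff = NULL, clash_frac = 0.05, scale = 1,
                            n_rotations = 150, n_points = 2000, seed = 11) {
  stopifnot(inherits(block, "sym_block"))
  series <- list()
  report <- list()
  prev <- 1L
  truncated <- NULL
  if (n_max >= 1) {
    base <- structure(list(members = 1L, compactness = 0, ccs = NULL,
                           deviation = NULL, nested_parent = NULL),
                      class = "candidate_assembly")
    series[["1"]] <- base
  }
  for (n in seq(2, length.out = max(0, n_max - 1))) {
    cands <- enumerate_candidates(block, n, max_candidates = max_candidates,
                                  cutoff = cutoff, clash_frac = clash_frac,
                                  required = prev)
    if (length(cands) == 0) {
      truncated <- paste0("no candidate at n = ", n, ": ",
                          attr(cands, "diagnostic") %||% "none connected")
      break
    }
    exp_row <- NULL
    if (!is.null(ccs_table)) {
      hit <- which(ccs_table$n_subunits == n)
      if (length(hit) > 0) exp_row <- ccs_table[hit[1], ]
    }
    for (i in seq_along(cands)) {
      cc <- oligomer_ccs(candidate_oligomer(block, cands[[i]]), scale,
                         n_rotations, n_points, seed)
      cands[[i]]$ccs <- cc$value
      if (!is.null(exp_row)) {
        dv <- ccs_deviation(cc$value, exp_row$ccs_A2, tolerance = tolerance)
        cands[[i]]$deviation <- dv$deviation
        cands[[i]]$within <- dv$within_error
      }
    }
    if (!is.null(exp_row)) {
      devs <- abs(vapply(cands, function(cd) cd$deviation, 0))
      best_dev <- min(devs)
      tied <- which(devs <= best_dev + tie_tol)
      if (length(tied) > 1) {
        sym <- vapply(tied, function(i) symmetry_score(
          block$coms[cands[[i]]$members, , drop = FALSE]), 0)
        comp <- vapply(tied, function(i) cands[[i]]$compactness, 0)
        tied <- tied[order(-sym, comp)]
      }
      pick <- cands[[tied[1]]]
      if (!isTRUE(pick$within)) {
        truncated <- sprintf(
          "no candidate within tolerance at n = %d (best |deviation| %.1f%%)",
          n, 100 * abs(pick$deviation))
        report[[as.character(n)]] <- data.frame(
          n = n, ccs = pick$ccs, deviation = pick$deviation,
          within_error = FALSE,
          symmetry = symmetry_score(block$coms[pick$members, , drop = FALSE]),
          compactness = pick$compactness)
        break
      }
    } else {
      pick <- cands[[1]]  # most compact
    }
    pick$nested_parent <- paste(prev, collapse = ",")
    series[[as.character(n)]] <- pick
    report[[as.character(n)]] <- data.frame(
      n = n, ccs = pick$ccs %||% NA_real_,
      deviation = pick$deviation %||% NA_real_,
      within_error = isTRUE(pick$within),
      symmetry = symmetry_score(block$coms[pick$members, , drop = FALSE]),
      compactness = pick$compactness)
    prev <- pick$members
  }
  structure(list(series = series,
                 report = if (length(report)) do.call(rbind, report)
                          else NULL,
                 truncated = truncated),
            class = "stepwise_series")
}

#' @export
print.stepwise_series <- function(x, ...) {
  cat("stepwise_series: orders", paste(names(x$series), collapse = ", "), "\n")
  if (!is.null(x$report)) print(x$report, row.names = FALSE)
  if (!is.null(x$truncated)) cat("truncated:", x$truncated, "\n")
  invisible(x)
}

#' Export candidate rankings as JSON
#'
#' @param candidates list of `candidate_assembly` objects (or a
#'   `stepwise_series`).
#' @param path output JSON path.
#' @export
write_candidates_json <- function(candidates, path) {
  if (inherits(candidates, "stepwise_series")) candidates <- candidates$series
  payload <- lapply(candidates, function(cd) list(
    members = cd$members, compactness = cd$compactness,
    ccs = cd$ccs, deviation = cd$deviation))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
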