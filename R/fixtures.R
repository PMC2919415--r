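#' Specification of a synthetic test unit
#'
#' Describes a synthetic poly-alanine building unit used to exercise the
#' pipeline without external structure downloads: atoms sampled at
#' protein-like density (0.8 Da per cubic Angstrom) inside a globular,
#' dumbbell or three-lobed envelope, an optional fraction of residues
#' declared in SEQRES but absent from the coordinates, and a crystal
#' symmetry environment.
#'
#' @param seed RNG seed; fixtures are reproducible from (spec, seed).
#' @param n_atoms atoms per unit (4 per residue: N, CA, C, O).
#' @param shape `"globule"`, `"dumbbell"` or `"trilobe"`.
#' @param gap_fraction fraction of residues present in SEQRES but without
#'   coordinates (a C-terminal truncation), in [0, 0.9].
#' @param operators `"identity"`, `"P1"` (identity operator with a lattice
#'   of near-tangent translational neighbours) or `"ortho4"` (four
#'   orthorhombic-like operators: identity plus three two-fold screws).
#' @param noise relative CCS noise for planted tables (>= 0).
#' @param planted_topology topology label used by
#'   [make_planted_ccs_table()].
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1, n_atoms = 200,
                         shape = c("globule", "dumbbell", "trilobe"),
                         gap_fraction = 0,
                         operators = c("identity", "P1", "ortho4"),
                         noise = 0, planted_topology = "ring") {
  shape <- match.arg(shape)
  operators <- match.arg(operators)
  if (gap_fraction < 0 || gap_fraction > 0.9)
    stop("gap_fraction must be in [0, 0.9]")
  if (noise < 0) stop("noise must be >= 0")
  structure(list(seed = seed, n_atoms = n_atoms, shape = shape,
                 gap_fraction = gap_fraction, operators = operators,
                 noise = noise, planted_topology = planted_topology),
            class = "fixture_spec")
}

#' Generate a synthetic building unit as PDB text
#'
#' Writes a poly-alanine unit matching a [fixture_spec()]: SEQRES declares
#' the full sequence, coordinates cover all but the gap fraction of residues,
#' CRYST1 and REMARK 290 describe the requested symmetry environment.
#'
#' @param spec a `fixture_spec`.
#' @param path optional output path; when given the PDB is written there.
#' @return the PDB lines (character vector), invisibly when `path` is given.
#' @export
make_unit <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  n_res <- max(8, round(spec$n_atoms / 4))
  mass <- n_res * 71.0788 + 18.015
  vol <- mass / 0.8

  geom <- switch(spec$shape,
    globule = {
      r <- (3 * vol / (4 * pi))^(1 / 3)
      list(lobes = list(c(0, 0, 0)), radius = r, edges = list())
    },
    dumbbell = {
      r <- (3 * (vol / 2) / (4 * pi))^(1 / 3)
      list(lobes = list(c(-1.3 * r, 0, 0), c(1.3 * r, 0, 0)),
           radius = r, edges = list(c(1, 2)))
    },
    trilobe = {
      r <- (3 * (vol / 3) / (4 * pi))^(1 / 3)
      ctrs <- ring_centers(3, 2.6 * r)
      list(lobes = lapply(1:3, function(i) ctrs[i, ]),
           radius = r, edges = list(c(1, 2), c(2, 3), c(3, 1)))
    })

  coords <- with_seed(spec$seed, {
    r <- geom$radius
    # linker residues evenly spaced between lobe surfaces keep the contact
    # network connected, as a polypeptide chain would
    link_pts <- list()
    for (e in geom$edges) {
      a <- geom$lobes[[e[1]]]; b <- geom$lobes[[e[2]]]
      u <- (b - a) / sqrt(sum((b - a)^2))
      pa <- a + (r - 2) * u
      pb <- b - (r - 2) * u
      m <- max(2, ceiling(sqrt(sum((pb - pa)^2)) / 4.5) + 1)
      for (t in seq(0, 1, length.out = m))
        link_pts[[length(link_pts) + 1]] <- pa + t * (pb - pa) + rnorm(3, 0, 0.8)
    }
    n_link <- length(link_pts)
    n_lobe <- n_res - n_link
    counts <- diff(round(seq(0, n_lobe, length.out = length(geom$lobes) + 1)))
    lobe_pts <- lapply(seq_along(geom$lobes), function(li) {
      pts <- t(vapply(seq_len(counts[li]), function(i) {
        repeat {
          p <- runif(3, -1, 1)
          if (sum(p^2) <= 1) break
        }
        geom$lobes[[li]] + r * p
      }, numeric(3)))
      # order residues along x so a C-terminal truncation removes a
      # spatially coherent cap, as a real construct boundary would
      pts[order(pts[, 1]), , drop = FALSE]
    })
    # chain order: lobe1, linker, lobe2, linker, ... (linkers interleaved)
    per_edge <- if (length(geom$edges) > 0) split(
      seq_len(n_link), rep(seq_along(geom$edges),
                           each = n_link / max(1, length(geom$edges))))
      else list()
    out <- matrix(0, 0, 3)
    for (li in seq_along(lobe_pts)) {
      out <- rbind(out, lobe_pts[[li]])
      if (li <= length(per_edge))
        out <- rbind(out, do.call(rbind, link_pts[per_edge[[li]]]))
    }
    out
  })

  n_gap <- round(spec$gap_fraction * n_res)
  present <- seq_len(n_res - n_gap)

  lines <- character()
  Rb <- max(sqrt(rowSums(coords^2))) + 4.5
  cell <- c(1.90, 1.95, 2.00) * Rb
  lines <- c(lines, sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    cell[1], cell[2], cell[3], 90, 90, 90))
  lines <- c(lines, remark290_lines(spec$operators, cell))

  three <- rep("ALA", n_res)
  for (i in seq(1, n_res, by = 13)) {
    chunk <- three[i:min(i + 12, n_res)]
    lines <- c(lines, sprintf("SEQRES %3d A %4d  %s",
                              (i - 1) %/% 13 + 1, n_res,
                              paste(chunk, collapse = " ")))
  }

  atom_defs <- list(c(" N  ", "N"), c(" CA ", "C"), c(" C  ", "C"),
                    c(" O  ", "O"))
  offsets <- with_seed(spec$seed + 1,
    matrix(rnorm(n_res * 4 * 3, 0, 0.9), ncol = 3))
  ser <- 0L
  for (i in present) {
    for (j in seq_along(atom_defs)) {
      ser <- ser + 1L
      off <- if (j == 2) c(0, 0, 0) else offsets[(i - 1) * 4 + j, ]
      p <- coords[i, ] + off
      lines <- c(lines, sprintf(
        "ATOM  %5d %s ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        ser, atom_defs[[j]][1], i, p[1], p[2], p[3], 1.0, 0.0,
        atom_defs[[j]][2]))
    }
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

remark290_lines <- function(operators, cell) {
  ops <- switch(operators,
    identity = list(list(R = diag(3), t = c(0, 0, 0))),
    P1 = list(list(R = diag(3), t = c(0, 0, 0))),
    ortho4 = list(
      list(R = diag(3), t = c(0, 0, 0)),
      list(R = diag(c(-1, -1, 1)), t = c(cell[1] / 2, 0, cell[3] / 2)),
      list(R = diag(c(-1, 1, -1)), t = c(0, cell[2] / 2, cell[3] / 2)),
      list(R = diag(c(1, -1, -1)), t = c(cell[1] / 2, cell[2] / 2, 0))))
  out <- character()
  for (k in seq_along(ops)) {
    op <- ops[[k]]
    for (row in 1:3)
      out <- c(out, sprintf(
        "REMARK 290   SMTRY%d %3d %9.6f %9.6f %9.6f %14.5f",
        row, k, op$R[row, 1], op$R[row, 2], op$R[row, 3], op$t[row]))
  }
  out
}

#' Read a generated unit back as a structure
#'
#' Convenience wrapper: writes the [make_unit()] text to a temporary file
#' and parses it with [read_structure()].
#'
#' @param spec a `fixture_spec`.
#' @return a `ccs_structure`.
#' @export
make_unit_structure <- function(spec) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  make_unit(spec, tf)
  read_structure(tf)
}

#' Generate a planted-topology experimental CCS table
#'
#' Builds the requested oligomers of a unit (an archetype, or the
#' compactness-selected nested series mined from the unit's crystal
#' symmetry), computes their projection-approximation CCS, perturbs the
#' values multiplicatively by the noise level and returns the CSV-shaped
#' table the pipeline consumes.  The planted geometries are attached as the
#' `"planted"` attribute for closed-loop recovery checks.
#'
#' @param unit a `ccs_structure` or `sphere_model` building unit.
#' @param topology an archetype label (see [generate_archetype()]) or
#'   `"symmetry_mined"`.
#' @param n_values oligomer orders to tabulate (include 1 for the monomer).
#' @param noise relative noise level (0 = exact).
#' @param seed RNG seed for the noise draw.
#' @param radii,scale,n_rotations,n_points CCS settings.
#' @return a data frame (species, n_subunits, ccs_A2, rel_error) with
#'   attribute `"planted"`: per-order list of `list(n, members, coms, ccs)`.
#' @export
make_planted_ccs_table <- function(unit, topology, n_values, noise = 0,
                                   seed = 1, radii = collision_radii(),
                                   scale = 1, n_rotations = 150,
                                   n_points = 2000) {
  planted <- list()
  rows <- list()
  if (identical(topology, "symmetry_mined")) {
    block <- expand_symmetry(unit, shell = 1, radii = radii)
    prev <- 1L
    for (n in sort(n_values)) {
      if (n == 1) {
        cc <- oligomer_ccs(new_oligomer(unit, list(list(R = diag(3),
                                                        t = c(0, 0, 0))),
                                        "unit", radii),
                           scale, n_rotations, n_points, seed)
        planted[[as.character(n)]] <- list(n = 1, members = 1L,
                                           coms = block$coms[1, , drop = FALSE],
                                           ccs = cc$value)
        rows[[as.character(n)]] <- data.frame(n = 1, ccs = cc$value)
        next
      }
      cands <- enumerate_candidates(block, n, required = prev)
      if (length(cands) == 0)
        stop("planted series cannot be grown to n = ", n)
      pick <- cands[[1]]  # most compact nested candidate
      cc <- oligomer_ccs(candidate_oligomer(block, pick), scale,
                         n_rotations, n_points, seed)
      planted[[as.character(n)]] <- list(
        n = n, members = pick$members,
        coms = block$coms[pick$members, , drop = FALSE], ccs = cc$value)
      rows[[as.character(n)]] <- data.frame(n = n, ccs = cc$value)
      prev <- pick$members
    }
  } else {
    for (n in sort(n_values)) {
      om <- generate_archetype(unit, n, topology, radii = radii, seed = seed)
      cc <- oligomer_ccs(om, scale, n_rotations, n_points, seed)
      a <- assemble_oligomer(om)
      coms <- t(vapply(split(a, a$copy), function(df)
        colSums(df[, c("x", "y", "z")] * df$mass) / sum(df$mass), numeric(3)))
      planted[[as.character(n)]] <- list(n = n, members = seq_len(n),
                                         coms = coms, ccs = cc$value)
      rows[[as.character(n)]] <- data.frame(n = n, ccs = cc$value)
    }
  }
  df <- do.call(rbind, rows)
  eps <- with_seed(seed + 500, rnorm(nrow(df), 0, 1))
  tab <- data.frame(species = "synthetic",
                    n_subunits = df$n,
                    ccs_A2 = df$ccs * (1 + noise * eps),
                    rel_error = if (noise > 0) noise else NA_real_)
  attr(tab, "planted") <- planted
  tab
}
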