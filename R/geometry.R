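# Effective (bounding) sphere radius of a building block: the radius of the
# smallest COM-centred sphere containing every member sphere/atom footprint.
block_bounding_radius <- function(block, radii = collision_radii()) {
  s <- block_spheres(block, radii)
  com <- block_com(block, radii)
  max(sqrt(rowSums(sweep(as.matrix(s[, c("x", "y", "z")]), 2, com)^2)) +
        s$radius)
}

# Uniform sphere-set view of a block (sphere model or atomic structure).
block_spheres <- function(block, radii = collision_radii()) {
  if (inherits(block, "sphere_model"))
    return(data.frame(x = block$x, y = block$y, z = block$z,
                      radius = block$radius, mass = block$mass))
  if (inherits(block, "ccs_structure")) {
    a <- block$atoms
    return(data.frame(x = a$x, y = a$y, z = a$z,
                      radius = radii_for_elements(radii, a$element),
                      mass = element_mass(a$element)))
  }
  stop("block must be a sphere_model or ccs_structure")
}

block_com <- function(block, radii = collision_radii()) {
  s <- block_spheres(block, radii)
  colSums(s[, c("x", "y", "z")] * s$mass) / sum(s$mass)
}

# Mass-weighted principal axes, longest first (rows of the returned matrix).
block_axes <- function(block, radii = collision_radii()) {
  s <- block_spheres(block, radii)
  com <- block_com(block, radii)
  xyz <- sweep(as.matrix(s[, c("x", "y", "z")]), 2, com)
  if (nrow(xyz) < 2) return(diag(3))
  cv <- crossprod(xyz * sqrt(s$mass / sum(s$mass)))
  ev <- eigen(cv, symmetric = TRUE)
  ax <- t(ev$vectors)          # rows: decreasing variance
  if (det(ev$vectors) < 0) ax[3, ] <- -ax[3, ]
  ax
}

# Extent of the block (footprint included) along a unit direction.
block_extent <- function(block, dir, radii = collision_radii()) {
  s <- block_spheres(block, radii)
  com <- block_com(block, radii)
  p <- as.matrix(sweep(as.matrix(s[, c("x", "y", "z")]), 2, com)) %*% dir
  max(p + s$radius) - min(p - s$radius)
}

rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  C <- 1 - c
  matrix(c(
    c + u[1]^2 * C, u[1] * u[2] * C - u[3] * s, u[1] * u[3] * C + u[2] * s,
    u[2] * u[1] * C + u[3] * s, c + u[2]^2 * C, u[2] * u[3] * C - u[1] * s,
    u[3] * u[1] * C - u[2] * s, u[3] * u[2] * C + u[1] * s, c + u[3]^2 * C),
    3, 3, byrow = TRUE)
}

new_oligomer <- function(block, transforms, topology, radii) {
  n <- length(transforms)
  structure(list(block = block, transforms = transforms,
                 topology = topology, n = n, radii = radii),
            class = "oligomer_model")
}

#' @export
print.oligomer_model <- function(x, ...) {
  cat("oligomer_model:", x$n, "copies,", x$topology, "topology\n")
  invisible(x)
}

#' Generate an archetypal oligomer from a building block
#'
#' Places `n` rigid copies of a building block in an idealized geometric
#' arrangement.  The contact rule is tangency of per-copy bounding spheres
#' with a configurable allowed overlap fraction (default 10%, mimicking
#' packed protein interfaces), so the centre spacing is
#' `2 * R * (1 - overlap)` with `R` the block's bounding radius.  Topologies:
#'
#' * `linear`: collinear centres along the block's longest principal axis.
#' * `ring` (n >= 3): centres on a regular n-gon.
#' * `double_tiered_ring` (even n): two stacked (n/2)-gons, the upper tier
#'   rotated half a step.
#' * `collapsed`: quasi-spherical packing minimizing the sum of pairwise
#'   centre distances (greedy insertion + local refinement; seeded).
#' * `stack_face`: axial stacking along the shortest principal axis, spacing
#'   from the block extent along that axis (flat faces meet).
#' * `stack_end`: stacking along the longest principal axis with alternate
#'   copies flipped 180 degrees about the stacking axis (head-to-head vs
#'   tail-to-tail alternation).
#' * `edge_to_edge`: lateral tangency along the middle principal axis.
#'
#' All copies keep the block's orientation except `stack_end`.
#'
#' @param block a `sphere_model` or `ccs_structure`.
#' @param n number of copies (>= 1).
#' @param topology one of the labels above.
#' @param overlap allowed bounding-sphere overlap fraction (default 0.10).
#' @param radii collision radii (needed for atomic blocks).
#' @param seed seed for the collapsed-packing refinement.
#' @return an `oligomer_model` (block + list of rigid transforms).
#' @export
generate_archetype <- function(block, n, topology = c(
                                 "linear", "ring", "double_tiered_ring",
                                 "collapsed", "stack_face", "stack_end",
                                 "edge_to_edge"),
                               overlap = 0.10, radii = collision_radii(),
                               seed = 1) {
  topology <- match.arg(topology)
  if (n < 1) stop("n must be >= 1")
  if (topology == "ring" && n > 1 && n < 3)
    stop("ring topology needs n >= 3")
  if (topology == "double_tiered_ring" && n %% 2 != 0 && n > 1)
    stop("double-tiered ring needs even n")

  ident <- list(R = diag(3), t = c(0, 0, 0))
  if (n == 1) return(new_oligomer(block, list(ident), topology, radii))

  R <- block_bounding_radius(block, radii)
  s <- 2 * R * (1 - overlap)
  ax <- block_axes(block, radii)
  com <- block_com(block, radii)

  centers <- switch(topology,
    linear = outer(seq_len(n) - 1, s * ax[1, ]),
    ring = ring_centers(n, s),
    double_tiered_ring = {
      m <- n / 2
      lower <- ring_centers(max(m, 1), s)
      upper <- sweep(lower %*% rotation_about_axis(c(0, 0, 1), pi / max(m, 1)),
                     2, c(0, 0, s), `+`)
      rbind(lower, upper)
    },
    collapsed = collapsed_centers(n, contact_spheres(block, radii, com),
                                  overlap, s, seed),
    stack_face = outer(seq_len(n) - 1,
                       (1 - overlap) * block_extent(block, ax[3, ], radii) *
                         ax[3, ]),
    stack_end = outer(seq_len(n) - 1,
                      (1 - overlap) * block_extent(block, ax[1, ], radii) *
                        ax[1, ]),
    edge_to_edge = outer(seq_len(n) - 1,
                         (1 - overlap) * block_extent(block, ax[2, ], radii) *
                           ax[2, ]))

  transforms <- lapply(seq_len(n), function(i) {
    Ri <- diag(3)
    if (topology == "stack_end" && i %% 2 == 0)
      Ri <- rotation_about_axis(ax[1, ], pi)
    # rotate about the block COM, then move the COM to the target centre
    list(R = Ri, t = as.numeric(centers[i, ]) + com - as.numeric(Ri %*% com))
  })
  new_oligomer(block, transforms, topology, radii)
}

ring_centers <- function(n, s) {
  if (n == 1) return(matrix(0, 1, 3))
  rc <- s / (2 * sin(pi / n))
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(rc * cos(th), rc * sin(th), 0)
}

# COM-relative contact spheres used for the collapsed packing's no-overlap
# constraints: the block's own spheres, or for large atomic blocks a
# deterministic k-means reduction to <= 25 enclosing spheres.
contact_spheres <- function(block, radii, com) {
  s <- block_spheres(block, radii)
  xyz <- sweep(as.matrix(s[, c("x", "y", "z")]), 2, com)
  if (nrow(s) <= 40) return(list(off = xyz, r = s$radius))
  k <- 25
  km <- with_seed(2203L, kmeans(xyz, centers = k, nstart = 5, iter.max = 50))
  off <- km$centers
  r <- vapply(seq_len(k), function(i) {
    sel <- km$cluster == i
    max(sqrt(rowSums(sweep(xyz[sel, , drop = FALSE], 2, off[i, ])^2)) +
          s$radius[sel])
  }, 0)
  list(off = off, r = r)
}

# Greedy insertion + centroid-pull refinement of a packing minimizing the
# sum of pairwise centre distances.  Copies keep the block orientation; the
# no-overlap constraint acts between the contact spheres of different copies
# (centre distance >= (1 - overlap) * sum of radii), so elongated blocks can
# pack side-by-side -- the collapsed archetype is the lower CCS bound.
collapsed_centers <- function(n, contact, overlap, s_max, seed) {
  off <- contact$off
  rr <- contact$r
  feasible <- function(p, placed) {
    for (q in seq_len(nrow(placed))) {
      dvec <- p - placed[q, ]
      for (i in seq_len(nrow(off))) {
        w <- sweep(off, 2, off[i, ] + dvec, `-`)  # off_j - off_i - dvec
        lim <- (1 - overlap) * (rr + rr[i])
        if (any(rowSums(w^2) < lim^2 * 0.998)) return(FALSE)
      }
    }
    TRUE
  }
  # smallest t >= 0 so that a copy at base + t*u clears every placed copy:
  # sphere i of the new copy sits at off_i + base + t*u, sphere j of placed
  # copy q at off_j + c_q; with w = off_j + c_q - off_i - base the constraint
  # |t*u - w| >= lim is violated for t inside the roots (u.w) +/- sqrt(disc)
  min_approach <- function(base, u, placed) {
    t_req <- 0
    for (q in seq_len(nrow(placed))) {
      for (i in seq_len(nrow(off))) {
        w <- sweep(off, 2, off[i, ] + base - placed[q, ], `-`)
        lim <- (1 - overlap) * (rr + rr[i])
        b <- as.numeric(w %*% u)
        disc <- b^2 - (rowSums(w^2) - lim^2)
        hit <- disc > 0
        if (any(hit))
          t_req <- max(t_req, b[hit] + sqrt(disc[hit]))
      }
    }
    t_req
  }
  dirs <- icosahedron_vertices()
  extra <- with_seed(seed, {
    m <- matrix(rnorm(3 * 20), ncol = 3)
    m / sqrt(rowSums(m^2))
  })
  dirs <- rbind(dirs, extra)
  pts <- matrix(0, 1, 3)
  for (copy in seq_len(n - 1)) {
    best <- NULL; best_score <- Inf
    for (j in seq_len(nrow(pts))) for (d in seq_len(nrow(dirs))) {
      u <- dirs[d, ]
      t_star <- min_approach(pts[j, ], u, pts)
      if (!is.finite(t_star) || t_star > 2 * s_max) next
      p <- pts[j, ] + t_star * u
      score <- sum(sqrt(rowSums(sweep(pts, 2, p)^2)))
      if (score < best_score && feasible(p, pts)) {
        best_score <- score; best <- p
      }
    }
    if (is.null(best)) best <- pts[nrow(pts), ] + s_max * dirs[copy, ]
    pts <- rbind(pts, best)
  }
  for (sweep_i in 1:4) {
    step <- s_max / 8 / sweep_i
    for (j in seq_len(nrow(pts))) {
      ctr <- colMeans(pts[-j, , drop = FALSE])
      dir <- ctr - pts[j, ]
      nd <- sqrt(sum(dir^2))
      if (nd < 1e-9) next
      p <- pts[j, ] + min(step, nd) * dir / nd
      if (feasible(p, pts[-j, , drop = FALSE])) pts[j, ] <- p
    }
  }
  pts
}

icosahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  v / sqrt(rowSums(v^2))
}

#' Assemble an oligomer model into a flat sphere set
#'
#' Applies each copy's rigid transform to the block's spheres (or atoms with
#' their collision radii).
#'
#' @param model an `oligomer_model` or `candidate_assembly`.
#' @return data frame x/y/z/radius/mass/copy.
#' @export
assemble_oligomer <- function(model) {
  s <- block_spheres(model$block, model$radii %||% collision_radii())
  xyz <- as.matrix(s[, c("x", "y", "z")])
  out <- lapply(seq_along(model$transforms), function(i) {
    tr <- model$transforms[[i]]
    p <- xyz %*% t(tr$R)
    p <- sweep(p, 2, tr$t, `+`)
    data.frame(x = p[, 1], y = p[, 2], z = p[, 3],
               radius = s$radius, mass = s$mass, copy = i)
  })
  do.call(rbind, out)
}

#' CCS of an oligomer model
#'
#' Projection-approximation CCS of the assembled copies.
#'
#' @param model an `oligomer_model`.
#' @param scale,n_rotations,n_points,seed as in [pa_ccs_spheres()].
#' @return a `ccs_estimate`.
#' @export
oligomer_ccs <- function(model, scale = 1, n_rotations = 300,
                         n_points = 4000, seed = 1) {
  a <- assemble_oligomer(model)
  pa_ccs_core(as.matrix(a[, c("x", "y", "z")]), a$radius, scale,
              n_rotations, n_points, seed)
}

#' CCS-versus-stoichiometry trend lines for archetypal topologies
#'
#' Generates each requested archetype at each oligomer order and computes its
#' CCS; used to bound and classify candidate architectures against a measured
#' CCS series (the elongated linear arrangement bounds from above, the
#' collapsed packing from below).
#'
#' @param block building block (`sphere_model` or `ccs_structure`).
#' @param topologies character vector of archetype labels.
#' @param n_values oligomer orders to generate.
#' @param experimental optional CCS table (columns n_subunits, ccs_A2) echoed
#'   into the result.
#' @param overlap,radii,scale,n_rotations,n_points,seed settings passed to
#'   generation and CCS evaluation.
#' @return a `trend_line` data frame (topology, n, ccs_A2) with the
#'   experimental series as attribute `"experimental"`.
#' @export
trend_lines <- function(block, topologies, n_values, experimental = NULL,
                        overlap = 0.10, radii = collision_radii(), scale = 1,
                        n_rotations = 300, n_points = 4000, seed = 1) {
  if (length(topologies) == 0) stop("topologies must be non-empty")
  rows <- list()
  for (tp in topologies) for (n in n_values) {
    if (tp == "ring" && n > 1 && n < 3) next
    if (tp == "double_tiered_ring" && n > 1 && n %% 2 != 0) next
    om <- generate_archetype(block, n, tp, overlap, radii, seed)
    cc <- oligomer_ccs(om, scale, n_rotations, n_points, seed)
    rows[[length(rows) + 1]] <- data.frame(topology = tp, n = n,
                                           ccs_A2 = cc$value,
                                           mc_stderr = cc$mc_stderr)
  }
  out <- do.call(rbind, rows)
  attr(out, "experimental") <- experimental
  class(out) <- c("trend_line", "data.frame")
  out
}

#' Write an oligomer model as a multi-copy pseudo-atom PDB
#'
#' Spheres of each copy are written as HETATM pseudo-atoms with the copy
#' index as the residue number and the sphere radius in the B-factor column.
#'
#' @param model an `oligomer_model`.
#' @param path output path.
#' @export
write_oligomer_pdb <- function(model, path) {
  a <- assemble_oligomer(model)
  chains <- c(LETTERS, letters, 0:9)
  lines <- sprintf(
    "HETATM%5d  S   SPH %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(a)), chains[(a$copy - 1) %% length(chains) + 1],
    a$copy, a$x, a$y, a$z, 1.0, pmin(a$radius, 999.99))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
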