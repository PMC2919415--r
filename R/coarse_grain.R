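#' Elastic-network domain decomposition
#'
#' Builds a Gaussian network model on C-alpha atoms (Kirchhoff matrix of the
#' contact graph under a distance cutoff), extracts the slowest nontrivial
#' modes, and clusters residues by their displacement pattern into rigid
#' domains.  With `k = "auto"`, the largest k <= 3 is chosen for which the
#' k - 1 slowest nontrivial eigenvalues are well separated from the bulk of
#' the spectrum (a rigid-domain signature), every domain holds at least 15%
#' of the residues, and domain boundaries cut at most 10% of the network
#' contacts; a compact single-body structure therefore stays one domain.
#'
#' @param structure a `ccs_structure` with C-alpha atoms.
#' @param k number of domains, or `"auto"`.
#' @param cutoff elastic-network contact cutoff in Angstrom (default 8).
#' @return a `domain_decomposition`: data frame `residues` (chain, resno,
#'   domain), `k`, and `cutoff`.
#' @export
decompose_domains <- function(structure, k = "auto", cutoff = 8) {
  ca <- structure$atoms[structure$atoms$elety == "CA" &
                        structure$atoms$type == "ATOM", , drop = FALSE]
  n <- nrow(ca)
  if (n < 4) stop("need at least 4 C-alpha atoms")
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  adj <- d <= cutoff & upper.tri(d)
  adj <- adj | t(adj)
  if (!network_connected(adj))
    stop("elastic network is disconnected at cutoff ", cutoff,
         " A; increase the cutoff")

  auto <- identical(k, "auto")
  if (auto) {
    lab <- rep(1L, n)
    kk <- 1L
    modes <- gnm_slow_modes(adj, 2)
    ev <- gnm_eigenvalues(adj)
    for (try_k in c(3L, 2L)) {
      if (n < 2 * try_k) next
      if (!slow_mode_gap(ev, try_k)) next
      cand <- cluster_modes(modes, try_k)
      if (accept_decomposition(cand, adj, try_k)) { lab <- cand; kk <- try_k; break }
    }
  } else {
    kk <- as.integer(k)
    if (kk < 1) stop("k must be >= 1")
    if (n < 2 * kk) stop("need at least ", 2 * kk, " residues for k = ", kk)
    lab <- if (kk == 1) rep(1L, n)
           else cluster_modes(gnm_slow_modes(adj, max(2, kk - 1)), kk)
  }
  lab <- relabel_by_first(lab)
  structure(list(
    residues = data.frame(chain = ca$chain, resno = ca$resno,
                          domain = lab, stringsAsFactors = FALSE),
    k = max(lab), cutoff = cutoff),
    class = "domain_decomposition")
}

network_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# Slowest nontrivial GNM modes: eigenvectors of the Kirchhoff matrix for the
# smallest nonzero eigenvalues.
gnm_slow_modes <- function(adj, n_modes) {
  n <- nrow(adj)
  K <- -1 * adj
  diag(K) <- rowSums(adj)
  e <- eigen(K, symmetric = TRUE)
  idx <- order(e$values)[-1]          # drop the uniform zero mode
  e$vectors[, idx[seq_len(min(n_modes, length(idx)))], drop = FALSE]
}

cluster_modes <- function(modes, k) {
  km <- with_seed(7421L, kmeans(modes, centers = k, nstart = 25, iter.max = 50))
  km$cluster
}

gnm_eigenvalues <- function(adj) {
  K <- -1 * adj
  diag(K) <- rowSums(adj)
  sort(eigen(K, symmetric = TRUE, only.values = TRUE)$values)[-1]
}

# k rigid domains show as k - 1 near-zero Kirchhoff eigenvalues well
# separated from the bulk: all k - 1 slow eigenvalues below 0.08 x the
# median, with a clear spectral gap to the next one.
slow_mode_gap <- function(ev, k) {
  slow <- ev[seq_len(k - 1)]
  all(slow < 0.08 * stats::median(ev)) && ev[k] / ev[k - 1] >= 1.7
}

accept_decomposition <- function(lab, adj, k) {
  if (length(unique(lab)) != k) return(FALSE)
  frac <- tabulate(lab, k) / length(lab)
  if (any(frac < 0.15)) return(FALSE)
  cut_edges <- sum(adj & outer(lab, lab, `!=`)) / 2
  tot_edges <- sum(adj) / 2
  cut_edges / tot_edges <= 0.10
}

relabel_by_first <- function(lab) {
  first <- vapply(unique(lab), function(l) which(lab == l)[1], 0L)
  map <- order(first)
  match(lab, unique(lab)[map])
}

#' Build a sphere model from a domain decomposition
#'
#' One sphere per domain, placed at the domain's mass-weighted centre.  The
#' initial radius reproduces the domain's own projection-approximation CCS
#' (`r = sqrt(CCS/pi)`); the sphere mass is the domain's residue mass, with
#' each chain's water mass distributed over its domains so that the model
#' mass equals the structure's present mass exactly.
#'
#' @param structure a `ccs_structure`.
#' @param decomposition a [decompose_domains()] result; `NULL` for a single
#'   whole-structure sphere.
#' @param radii collision radii for the per-domain CCS.
#' @param n_rotations,n_points,seed Monte-Carlo settings for the per-domain
#'   CCS used to size the spheres.
#' @return a `sphere_model` with one sphere per domain.
#' @export
build_sphere_model <- function(structure, decomposition = NULL,
                               radii = collision_radii(),
                               n_rotations = 150, n_points = 2000, seed = 1) {
  atoms <- structure$atoms[structure$atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0) stop("structure has no protein atoms")
  if (is.null(decomposition)) {
    ca <- atoms[atoms$elety == "CA", , drop = FALSE]
    dec <- data.frame(chain = ca$chain, resno = ca$resno, domain = 1L)
  } else dec <- decomposition$residues

  key <- paste(atoms$chain, atoms$resno)
  dom <- dec$domain[match(key, paste(dec$chain, dec$resno))]
  if (any(is.na(dom))) stop("decomposition does not cover the structure")
  tab <- residue_mass_table("average")

  k <- max(dec$domain)
  out <- vector("list", k)
  # distribute each chain's water over its domains by residue count
  water <- rep(0, k)
  for (ch in unique(dec$chain)) {
    cnt <- tabulate(dec$domain[dec$chain == ch], k)
    water <- water + tab$water * cnt / sum(cnt)
  }
  for (d in seq_len(k)) {
    sub <- atoms[dom == d, , drop = FALSE]
    heavy <- sub[sub$element != "H", , drop = FALSE]
    w <- element_mass(heavy$element)
    com <- colSums(heavy[, c("x", "y", "z")] * w) / sum(w)
    ccs <- pa_ccs_core(as.matrix(heavy[, c("x", "y", "z")]),
                       radii_for_elements(radii, heavy$element),
                       1, n_rotations, n_points, seed + d)
    res <- dec[dec$domain == d, , drop = FALSE]
    aa <- vapply(seq_len(nrow(res)), function(i) {
      r <- sub$resid[sub$chain == res$chain[i] & sub$resno == res$resno[i]][1]
      bio3d::aa321(r)
    }, "")
    m <- sum(tab$aa[aa], na.rm = TRUE) + water[d]
    out[[d]] <- data.frame(label = paste0("domain", d),
                           x = com[1], y = com[2], z = com[3],
                           radius = sqrt(ccs$value / pi), mass = m)
  }
  df <- do.call(rbind, out)
  sphere_model(df$label, df$x, df$y, df$z, df$radius, df$mass,
               kind = "domain")
}

#' Calibrate sphere radii against the atomic CCS
#'
#' Multiplies all radii of a coarse-grained model by a single factor, found by
#' bisection, so that the model's projection-approximation CCS matches that of
#' the atomic structure it was derived from to within `tol` (default 1%).  A
#' single global factor preserves the relative domain sizes.
#'
#' @param atomic the source `ccs_structure`.
#' @param model the `sphere_model` derived from it.
#' @param tol relative CCS agreement required (default 0.01).
#' @param max_iter maximum bisection steps (default 60).
#' @param radii,scale,n_rotations,n_points,seed CCS settings used for both
#'   models during calibration.
#' @return the calibrated `sphere_model` (attribute `"calibration_factor"`
#'   holds the factor applied).
#' @export
calibrate_radii <- function(atomic, model, tol = 0.01, max_iter = 60,
                            radii = collision_radii(), scale = 1,
                            n_rotations = 300, n_points = 4000, seed = 99) {
  target <- pa_ccs_atoms(atomic, radii, scale, n_rotations, n_points, seed)$value
  eval_cg <- function(fac) {
    m <- model
    m$radius <- m$radius * fac
    pa_ccs_spheres(m, n_rotations, n_points, seed, scale)$value
  }
  lo <- 0.25; hi <- 4
  while (eval_cg(lo) > target && lo > 1e-3) lo <- lo / 2
  while (eval_cg(hi) < target && hi < 64) hi <- hi * 2
  fac <- 1
  for (i in seq_len(max_iter)) {
    fac <- (lo + hi) / 2
    v <- eval_cg(fac)
    if (abs(v - target) / target <= tol / 4) break
    if (v < target) lo <- fac else hi <- fac
  }
  achieved <- abs(eval_cg(fac) - target) / target
  if (achieved > tol)
    stop(sprintf("radius calibration did not converge: %.2f%% > %.2f%%",
                 100 * achieved, 100 * tol))
  out <- model
  out$radius <- out$radius * fac
  attr(out, "calibration_factor") <- fac
  attr(out, "atomic_ccs") <- target
  out
}

#' Radius of the sphere representing unresolved residues
#'
#' The missing segment is represented as a single sphere whose density equals
#' the mean density of the resolved domains: `rho = sum(m_i) /
#' sum(4/3 pi r_i^3)` over the non-missing spheres, giving
#' `r = (3 m_missing / (4 pi rho))^(1/3)`.
#'
#' @param model a `sphere_model` with at least one non-missing sphere.
#' @param missing_mass mass of the unresolved residues in Da (> 0).
#' @return the sphere radius in Angstrom.
#' @export
missing_sphere_radius <- function(model, missing_mass) {
  if (!(missing_mass > 0)) stop("missing mass must be positive")
  known <- model[model$kind != "missing", , drop = FALSE]
  if (nrow(known) == 0) stop("model needs at least one non-missing sphere")
  rho <- sum(known$mass) / sum(4 / 3 * pi * known$radius^3)
  (3 * missing_mass / (4 * pi * rho))^(1 / 3)
}

#' Place the missing-residue sphere under a CCS restraint
#'
#' Scans candidate positions of the missing-mass sphere around an anchor
#' sphere and keeps the one whose model CCS best matches the measured CCS.
#' The sphere centre is constrained to the plane spanned by the anchor-to-
#' model-COM axis and a fixed perpendicular, parameterized by the overlap
#' with the anchor (fraction of the anchor radius; 0 = tangent, 1 = buried to
#' the anchor centre depth) and the angle theta around the anchor.
#'
#' @param model the calibrated `sphere_model` of the resolved part.
#' @param anchor label of the anchor sphere.
#' @param radius radius of the missing sphere (see [missing_sphere_radius()]).
#' @param exp_ccs measured CCS of the complete unit, square Angstrom.
#' @param mass mass assigned to the missing sphere (Da).
#' @param rel_error relative experimental error; used as the infeasibility
#'   tolerance when supplied (default 10%).
#' @param n_overlap,n_theta grid resolution (defaults 21 x 36).
#' @param n_rotations,n_points,seed Monte-Carlo CCS settings for the scan.
#' @return list with `model` (the completed `sphere_model`) and `scan` (a
#'   `placement_scan`: data frame overlap/theta/ccs plus `best`).
#' @export
place_missing_sphere <- function(model, anchor, radius, exp_ccs, mass,
                                 rel_error = NULL, n_overlap = 21,
                                 n_theta = 36, n_rotations = 100,
                                 n_points = 1500, seed = 5) {
  ia <- which(model$label == anchor)
  if (length(ia) != 1) stop("anchor sphere '", anchor, "' not found")
  if (!(radius > 0)) stop("radius must be positive")
  tol <- if (!is.null(rel_error) && is.finite(rel_error) && rel_error > 0)
    rel_error else 0.10

  a <- as.numeric(model[ia, c("x", "y", "z")])
  com <- colSums(model[, c("x", "y", "z")] * model$mass) / sum(model$mass)
  u <- a - com
  if (sqrt(sum(u^2)) < 1e-8) u <- c(1, 0, 0) else u <- u / sqrt(sum(u^2))
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))

  ra <- model$radius[ia]
  overlaps <- seq(0, 1, length.out = n_overlap)
  thetas <- seq(0, 2 * pi, length.out = n_theta + 1)[seq_len(n_theta)]
  grid <- expand.grid(overlap = overlaps, theta = thetas)
  ccs_at <- function(o, th) {
    d <- ra + radius - o * ra
    ctr <- a + d * (cos(th) * u + sin(th) * v)
    m <- rbind(model[, c("x", "y", "z", "radius")],
               data.frame(x = ctr[1], y = ctr[2], z = ctr[3], radius = radius))
    pa_ccs_core(as.matrix(m[, c("x", "y", "z")]), m$radius, 1,
                n_rotations, n_points, seed)$value
  }
  grid$ccs <- mapply(ccs_at, grid$overlap, grid$theta)

  # near-ties resolve toward the most compact (deepest-overlap) placement
  dev <- abs(grid$ccs - exp_ccs)
  tied <- which(dev <= min(dev) + 1e-3 * exp_ccs)
  best <- tied[order(-grid$overlap[tied], grid$theta[tied])][1]
  if (min(grid$ccs) > exp_ccs * (1 + tol))
    stop(sprintf(paste0(
      "infeasible placement: most compact CCS %.1f A^2 exceeds measured ",
      "%.1f A^2 by more than %.0f%%; revise the sphere radius or the model"),
      min(grid$ccs), exp_ccs, 100 * tol))

  o <- grid$overlap[best]; th <- grid$theta[best]
  d <- ra + radius - o * ra
  ctr <- a + d * (cos(th) * u + sin(th) * v)
  add <- sphere_model("missing", ctr[1], ctr[2], ctr[3], radius, mass,
                      kind = "missing")
  out <- rbind(model, add)
  class(out) <- class(model)
  scan <- structure(list(anchor = anchor, grid = grid,
                         best = list(overlap = o, theta = th,
                                     ccs = grid$ccs[best])),
                    class = "placement_scan")
  list(model = out, scan = scan)
}

#' @export
print.placement_scan <- function(x, ...) {
  cat(sprintf(
    "placement_scan: anchor %s, best overlap %.2f, theta %.2f rad, CCS %.1f A^2\n",
    x$anchor, x$best$overlap, x$best$theta, x$best$ccs))
  invisible(x)
}

#' Export a placement scan as CSV
#'
#' @param scan a `placement_scan`.
#' @param path CSV output path (columns overlap, theta, ccs).
#' @export
write_placement_scan <- function(scan, path) {
  write.csv(scan$grid, path, row.names = FALSE)
  invisible(path)
}
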