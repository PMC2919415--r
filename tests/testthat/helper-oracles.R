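# Independent numeric oracles.  These never call the package's Monte-Carlo
# path: the two-disk oracle integrates the closed-form union area over
# orientations by quadrature, and the subset oracle enumerates exhaustively.

# Area of the union of two disks with radii r1, r2 and centre distance s.
two_disk_union_area <- function(r1, r2, s) {
  if (s >= r1 + r2) return(pi * r1^2 + pi * r2^2)
  if (s <= abs(r1 - r2)) return(pi * max(r1, r2)^2)
  d1 <- (s^2 + r1^2 - r2^2) / (2 * s)
  d2 <- s - d1
  lens <- r1^2 * acos(pmin(pmax(d1 / r1, -1), 1)) - d1 * sqrt(pmax(r1^2 - d1^2, 0)) +
          r2^2 * acos(pmin(pmax(d2 / r2, -1), 1)) - d2 * sqrt(pmax(r2^2 - d2^2, 0))
  pi * r1^2 + pi * r2^2 - lens
}

# Orientationally averaged projected area of two spheres at 3D centre
# distance d: the projected centre distance is d * sqrt(1 - u^2) with
# u = cos(theta) uniform on [0, 1] for a random viewing axis.
two_sphere_pa_oracle <- function(r1, r2, d) {
  if (d < 1e-12) return(pi * max(r1, r2)^2)
  stats::integrate(function(u) vapply(u, function(ui)
    two_disk_union_area(r1, r2, d * sqrt(1 - ui^2)), 0),
    0, 1, rel.tol = 1e-10)$value
}

# Exhaustive best-compactness connected n-subset containing `required`.
brute_force_candidates <- function(coms, n, cutoff, required = 1L) {
  m <- nrow(coms)
  d <- as.matrix(stats::dist(coms))
  others <- setdiff(seq_len(m), required)
  if (length(required) + 0 > n) stop("bad n")
  combos <- utils::combn(others, n - length(required))
  out <- list()
  for (j in seq_len(ncol(combos))) {
    mem <- sort(c(required, combos[, j]))
    sub <- d[mem, mem, drop = FALSE] <= cutoff
    diag(sub) <- FALSE
    # connectivity by BFS
    seen <- logical(n); seen[1] <- TRUE; queue <- 1L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(sub[v, ] & !seen)
      seen[nb] <- TRUE; queue <- c(queue, nb)
    }
    if (!all(seen)) next
    out[[length(out) + 1]] <- list(members = mem,
                                   compactness = sum(d[mem, mem][upper.tri(d[mem, mem])]))
  }
  out[order(vapply(out, `[[`, 0, "compactness"))]
}
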