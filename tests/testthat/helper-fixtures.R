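# Small fixture builders shared across the suite.  Everything is generated
# in code; nothing is read from disk except through tempfiles.

write_tiny_pdb <- function(path, n_obs = 3, n_seqres = 5, sym_ops = 0,
                           altloc = FALSE) {
  lines <- c(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    50, 60, 70, 90, 90, 90))
  if (sym_ops > 0) {
    ops <- list(list(R = diag(3), t = c(0, 0, 0)),
                list(R = diag(c(-1, -1, 1)), t = c(25, 0, 35)),
                list(R = diag(c(-1, 1, -1)), t = c(0, 30, 35)),
                list(R = diag(c(1, -1, -1)), t = c(25, 30, 0)))[seq_len(sym_ops)]
    for (k in seq_along(ops)) for (row in 1:3)
      lines <- c(lines, sprintf(
        "REMARK 290   SMTRY%d %3d %9.6f %9.6f %9.6f %14.5f",
        row, k, ops[[k]]$R[row, 1], ops[[k]]$R[row, 2], ops[[k]]$R[row, 3],
        ops[[k]]$t[row]))
  }
  if (n_seqres > 0)
    lines <- c(lines, sprintf("SEQRES   1 A %4d  %s", n_seqres,
                              paste(rep("ALA", n_seqres), collapse = " ")))
  ser <- 0L
  for (i in seq_len(n_obs)) {
    for (at in list(c(" N  ", "N"), c(" CA ", "C"))) {
      ser <- ser + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %s ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        ser, at[1], i, i * 3.8, 0, 0, 1.0, 0.0, at[2]))
    }
  }
  if (altloc) {
    lines <- c(lines,
      "ATOM    901  CB AALA A   1       1.000   1.000   1.000  0.40  0.00           C",
      "ATOM    902  CB BALA A   1       2.000   2.000   2.000  0.60  0.00           C")
  }
  writeLines(c(lines, "END"), path)
  path
}

# A compact beta-monomer-like block: three overlapping spheres at the
# vertices of an equilateral triangle.
beta_like_block <- function() {
  sphere_model(paste0("lobe", 1:3),
               x = c(8, -4, -4), y = c(0, 6.93, -6.93), z = c(0, 0, 0),
               radius = rep(9, 3), mass = rep(1e4, 3))
}

# Two 50-residue globular lobes joined by a 5-residue linker, CA traces
# only; the domain boundary is inside the linker by construction.
dumbbell_ca_pdb <- function(path, seed = 1) {
  set.seed(seed)
  ca <- matrix(0, 105, 3)
  for (i in 1:50)   ca[i, ] <- c(-16, 0, 0) + runif(3, -8, 8)
  for (i in 51:55)  ca[i, ] <- c((i - 53) * 3.5, runif(2, -1, 1))
  for (i in 56:105) ca[i, ] <- c(16, 0, 0) + runif(3, -8, 8)
  lines <- vapply(seq_len(105), function(i) sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    i, i, ca[i, 1], ca[i, 2], ca[i, 3], 1.0, 0.0), "")
  writeLines(c(lines, "END"), path)
  path
}

# Build a sym_block directly from a matrix of copy COM positions (pure
# translations of a small spherical unit); used by the enumeration oracle
# tests where the crystal origin of the copies is irrelevant.
block_from_points <- function(points, unit_radius = 5) {
  unit <- sphere_model("u", 0, 0, 0, unit_radius, 1000)
  transforms <- lapply(seq_len(nrow(points)), function(i)
    list(R = diag(3), t = as.numeric(points[i, ])))
  structure(list(unit = unit, transforms = transforms,
                 coms = points,
                 ops = data.frame(op = 1, i = 0, j = 0, k = 0),
                 radii = collision_radii(),
                 unit_radius = unit_radius),
            class = "sym_block")
}

fingerprint <- function(coms) sort(as.numeric(stats::dist(coms)))

# A fixed non-trivial proper rotation (about z then x).
rotation_matrix_for_tests <- function() {
  rz <- matrix(c(cos(1), -sin(1), 0, sin(1), cos(1), 0, 0, 0, 1), 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cos(0.5), -sin(0.5), 0, sin(0.5), cos(0.5)), 3, byrow = TRUE)
  rx %*% rz
}
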