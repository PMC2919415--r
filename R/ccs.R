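#' Per-element collision radii
#'
#' Hard-sphere radii used by the projection approximation.  The default is a
#' single 2.2 Angstrom radius for every heavy atom; per-element overrides can
#' be supplied.  A global scale factor (see [pa_ccs_atoms()], [fit_pa_scale()])
#' absorbs the calibration of the projection approximation against measured
#' cross-sections, so the absolute radii mainly set relative atom footprints.
#'
#' @param default radius (Angstrom) for elements without an override; `NA`
#'   to make unlisted elements an error.
#' @param ... named per-element radii, e.g. `C = 1.91, O = 1.66`.
#' @return a `collision_radii` object.
#' @export
collision_radii <- function(default = 2.2, ...) {
  over <- c(...)
  if (length(over) > 0 && any(over <= 0)) stop("radii must be positive")
  if (!is.na(default) && default <= 0) stop("default radius must be positive")
  structure(list(radii = over, default = default), class = "collision_radii")
}

#' Read a per-element collision-radii table from YAML
#'
#' The file holds a mapping of element symbol to radius in Angstrom, with an
#' optional `default` key.
#'
#' @param path YAML file path.
#' @return a `collision_radii` object.
#' @export
read_collision_radii <- function(path) {
  y <- yaml::read_yaml(path)
  default <- y$default %||% 2.2
  y$default <- NULL
  do.call(collision_radii, c(list(default = default), y))
}

radii_for_elements <- function(radii, elements) {
  stopifnot(inherits(radii, "collision_radii"))
  if (length(radii$radii) == 0) {
    if (is.na(radii$default)) stop("no collision radii available")
    return(rep(radii$default, length(elements)))
  }
  r <- radii$radii[toupper(elements)]
  miss <- is.na(r)
  if (any(miss)) {
    if (is.na(radii$default))
      stop("no collision radius for element(s): ",
           paste(unique(elements[miss]), collapse = ", "))
    r[miss] <- radii$default
  }
  unname(r)
}

new_ccs_estimate <- function(value, mc_stderr, n_rotations, n_points,
                             scale, seed) {
  if (!(value > 0)) stop("CCS must be positive")
  structure(list(value = value, mc_stderr = mc_stderr,
                 n_rotations = n_rotations, n_points = n_points,
                 scale = scale, seed = seed),
            class = "ccs_estimate")
}

#' @export
print.ccs_estimate <- function(x, ...) {
  cat(sprintf("CCS %.1f +/- %.1f A^2 (scale %.4g, %d rotations x %d points)\n",
              x$value, x$mc_stderr, x$scale, x$n_rotations, x$n_points))
  invisible(x)
}

pa_ccs_core <- function(centers, radii, scale, n_rotations, n_points, seed) {
  if (n_rotations < 1) stop("n_rotations must be >= 1")
  if (n_points < 100) stop("n_points must be >= 100")
  areas <- with_seed(seed,
    pa_projection_areas(centers, radii, as.integer(n_rotations),
                        as.integer(n_points)))
  se <- if (n_rotations > 1) sd(areas) / sqrt(n_rotations) else 0
  new_ccs_estimate(mean(areas) * scale, se * scale,
                   n_rotations, n_points, scale, seed)
}

#' Projection-approximation CCS of a sphere model
#'
#' Estimates the orientationally averaged projected area of the union of
#' spheres by Monte Carlo: uniformly random orientations (quaternion method),
#' and uniform point sampling over the tight bounding box of each projection.
#' The Monte-Carlo standard error is estimated from the between-orientation
#' spread.  Deterministic for a fixed seed.
#'
#' @param model a `sphere_model` (or any data frame with x/y/z/radius).
#' @param n_rotations number of random orientations (default 300).
#' @param n_points sample points per orientation (default 4000).
#' @param seed RNG seed; the caller's RNG state is left untouched.
#' @param scale multiplicative calibration factor applied to the result.
#' @return a `ccs_estimate` with `value` and `mc_stderr` in square Angstrom.
#' @export
pa_ccs_spheres <- function(model, n_rotations = 300, n_points = 4000,
                           seed = 1, scale = 1) {
  if (nrow(model) < 1) stop("empty sphere model")
  if (any(model$radius <= 0)) stop("all sphere radii must be positive")
  pa_ccs_core(as.matrix(model[, c("x", "y", "z")]), model$radius,
              scale, n_rotations, n_points, seed)
}

#' Projection-approximation CCS of an atomic structure
#'
#' Identical contract to [pa_ccs_spheres()], with one hard sphere per atom
#' using per-element collision radii, multiplied by a global scale factor.
#' The unscaled projection approximation systematically underestimates
#' measured cross-sections (scattering is ignored); the scale factor treats
#' that as a uniform systematic error.
#'
#' @inheritParams pa_ccs_spheres
#' @param structure a `ccs_structure`.
#' @param radii a [collision_radii()] table.
#' @param scale global calibration factor (default 1).
#' @return a `ccs_estimate`.
#' @export
pa_ccs_atoms <- function(structure, radii = collision_radii(), scale = 1,
                         n_rotations = 300, n_points = 4000, seed = 1) {
  atoms <- structure$atoms
  if (is.null(atoms) || nrow(atoms) < 1) stop("structure has no atoms")
  r <- radii_for_elements(radii, atoms$element)
  pa_ccs_core(as.matrix(atoms[, c("x", "y", "z")]), r,
              scale, n_rotations, n_points, seed)
}

#' Linear missing-mass correction of a CCS
#'
#' When less than 5% of a protein's mass is unresolved in the structure, the
#' computed CCS is scaled up to account for the absent residues instead of
#' modelling them explicitly.  The default rule is linear in the mass ratio,
#' `value * (m_full/m_present)`; `exponent = 2/3` gives the area-of-a-
#' uniform-density-body alternative.
#'
#' @param ccs a `ccs_estimate`.
#' @param account a [mass_account()].
#' @param exponent exponent on the mass ratio (default 1, linear in mass).
#' @return the corrected `ccs_estimate` (standard error scaled identically).
#' @export
linear_scale_ccs <- function(ccs, account, exponent = 1) {
  stopifnot(inherits(ccs, "ccs_estimate"), inherits(account, "mass_account"))
  if (account$f_missing >= 0.05)
    stop("missing-mass fraction ", sprintf("%.1f%%", 100 * account$f_missing),
         " is >= 5%: linear scaling does not apply; use the homology or ",
         "coarse-grained completion path")
  fac <- (account$m_full / account$m_present)^exponent
  out <- ccs
  out$value <- ccs$value * fac
  out$mc_stderr <- ccs$mc_stderr * fac
  out
}

#' Signed relative deviation of a model CCS from a measurement
#'
#' @param model_ccs a `ccs_estimate` or a bare numeric CCS in square Angstrom.
#' @param exp_ccs measured CCS in square Angstrom (> 0).
#' @param rel_error optional relative measurement error; when supplied it is
#'   used as the within-error tolerance.
#' @param tolerance within-error tolerance when `rel_error` is absent
#'   (default 0.10: agreement within the typical 10% experimental error).
#' @return list with `deviation` = (model - exp)/exp, `within_error`, and the
#'   `tolerance` applied.
#' @export
ccs_deviation <- function(model_ccs, exp_ccs, rel_error = NULL,
                          tolerance = 0.10) {
  if (inherits(model_ccs, "ccs_estimate")) model_ccs <- model_ccs$value
  if (!(exp_ccs > 0)) stop("experimental CCS must be positive")
  tol <- if (!is.null(rel_error) && is.finite(rel_error) && rel_error > 0)
    rel_error else tolerance
  dev <- (model_ccs - exp_ccs) / exp_ccs
  list(deviation = dev, within_error = abs(dev) <= tol, tolerance = tol)
}

#' Fit the global projection-approximation scale factor
#'
#' Least-squares fit of `measured ~ scale * calculated` through the origin on
#' user-supplied pairs of unscaled calculated and measured CCS values, for
#' calibrating [pa_ccs_atoms()] against structures whose cross-sections are
#' known.
#'
#' @param calculated numeric vector of unscaled PA CCS values.
#' @param measured numeric vector of measured CCS values (same length).
#' @return the fitted scale factor.
#' @export
fit_pa_scale <- function(calculated, measured) {
  stopifnot(length(calculated) == length(measured), length(calculated) >= 1,
            all(calculated > 0), all(measured > 0))
  sum(calculated * measured) / sum(calculated^2)
}

#' Read/write experimental CCS tables
#'
#' CCS series are CSV tables with columns `species`, `n_subunits`, `ccs_A2`
#' and `rel_error` (relative measurement error, may be NA).
#'
#' @param path CSV file path.
#' @return `read_ccs_table()` returns the validated data frame.
#' @export
read_ccs_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "n_subunits", "ccs_A2", "rel_error")
  if (!all(need %in% names(df)))
    stop("CCS table must have columns: ", paste(need, collapse = ", "))
  if (any(df$ccs_A2 <= 0)) stop("CCS values must be positive")
  df
}

#' @rdname read_ccs_table
#' @param table a CCS data frame.
#' @export
write_ccs_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
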