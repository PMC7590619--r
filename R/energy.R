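#' Energy backend contract
#'
#' A backend is the deterministic, pure map from a search-space point to an
#' energy in eV — the role an electronic-structure code plays in a real
#' structure search. Bundled analytic backends let the whole workflow run
#' and be certified at desk scale.
#'
#' @param fn Function taking a numeric point (or a matrix of points in
#'   rows) and returning energies in eV. Must be deterministic.
#' @param space The [search_space()] over which the backend is defined.
#' @param name Short identifier.
#' @return An object of class `energy_backend`.
#' @export
energy_backend <- function(fn, space, name = "backend") {
  stopifnot(is.function(fn), inherits(space, "surf_space"))
  structure(list(fn = fn, space = space, name = name),
            class = "energy_backend")
}

#' @export
print.energy_backend <- function(x, ...) {
  cat(sprintf("<energy_backend> %s (%dD: %s)\n", x$name,
              space_dim(x$space), paste(x$space$name, collapse = ", ")))
  invisible(x)
}

#' Evaluate a backend at one or more points
#'
#' @param backend An [energy_backend()].
#' @param p Point, matrix of points (rows) or data frame.
#' @return Numeric vector of energies in eV.
#' @export
backend_eval <- function(backend, p) {
  P <- space_points(backend$space, p)
  e <- apply(P, 1, function(row) backend$fn(row))
  as.numeric(e)
}

#' Adsorption energy from total energies
#'
#' `E_ads = E_tot - (E_surface + E_molecule)`: the interaction energy of
#' the combined system relative to the relaxed clean surface and the
#' isolated molecule at infinite separation (zero of energy).
#'
#' @param e_tot Total energy of the combined system (eV).
#' @param e_surface Energy of the clean surface slab (eV).
#' @param e_molecule Energy of the isolated molecule (eV).
#' @return Adsorption energy in eV (negative = bound).
#' @examples
#' adsorption_energy(-10, -6, -3)  # -1
#' @export
adsorption_energy <- function(e_tot, e_surface, e_molecule) {
  stopifnot(is.finite(e_tot), is.finite(e_surface), is.finite(e_molecule))
  e_tot - (e_surface + e_molecule)
}

# Hexagonal-lattice corrugation in fractional coordinates of the orthogonal
# cell: the first star of reciprocal vectors of the triangular surface
# lattice. Range [-1/2, 1]; equals 1 on atoms (top sites), -1/2 in hollows.
# Invariant under the half-cell translation (a lattice vector of the
# centred-rectangular description) and under 120-degree rotation about an
# atom.
hex_corrugation <- function(x, y) {
  (cos(2 * pi * (x - y)) + cos(4 * pi * y) + cos(2 * pi * (x + y))) / 3
}

smoothstep <- function(u) u^2 * (3 - 2 * u)

#' Parameters of the bundled analytic adsorption surface
#'
#' The toy 6D potential emulates the phenomenology of a bulky molecule on a
#' close-packed metal: a Morse-type well in the height `z` with a steep
#' repulsive wall near 4 Angstrom, two orientation families in `beta` — a
#' deep "O-down" chemisorption-like family and a shallow "H-down"
#' physisorption-like family — weak corrugation across the surface cell
#' with the exact twofold (half-cell) and threefold (top-site) symmetries
#' of fcc(111), a threefold azimuthal (`gamma`) modulation strongest at the
#' top site, and a single-well `alpha` modulation. It makes no claim to any
#' real material's energetics.
#'
#' @param depth_O Depth of the global (O-down, hollow-site) minimum in eV.
#' @param depth_H Depth of the shallow-family minima in eV.
#' @param z0_O,z0_H Equilibrium heights of the two families in Angstrom.
#' @param steepness Morse decay constant in 1/Angstrom.
#' @param c_xy,c_gamma,c_alpha Relative corrugation / angular modulation
#'   amplitudes (dimensionless, in `[0, 1)`).
#' @return A parameter list of class `toy_adsorption_params`.
#' @export
toy_adsorption_params <- function(depth_O = 0.96, depth_H = 0.65,
                                  z0_O = 4.5, z0_H = 5.2,
                                  steepness = 1.6,
                                  c_xy = 0.1, c_gamma = 0.15,
                                  c_alpha = 0.08) {
  stopifnot(depth_O > 0, depth_H > 0, steepness > 0,
            c_xy >= 0, c_xy < 1, c_gamma >= 0, c_gamma < 1,
            c_alpha >= 0, c_alpha < 1)
  structure(as.list(environment()), class = "toy_adsorption_params")
}

#' Bundled analytic 6D adsorption surface
#'
#' Closed form (angles in degrees, `d2r` the degree-to-radian factor):
#' with `corr = hex_corrugation(x, y)`, `site = (1 - corr) / 1.5` (0 at the
#' top site, 1 in the hollows), `w_top = 0.5 + 0.5 (corr + 1/2) / 1.5`,
#' `s = smoothstep((1 + cos beta) / 2)`,
#' `D = depth_H + (depth_O - depth_H) s`, `z0 = z0_H + (z0_O - z0_H) s`,
#' the amplitude is
#' `A = D (1 + c_xy site) / (1 + c_xy) * (1 - c_gamma w_top (1 - cos 3 gamma)/2) * (1 - c_alpha (1 - cos alpha)/2)`
#' and the energy is `E = A (exp(-2 k (z - z0)) - 2 exp(-k (z - z0)))`.
#'
#' The energy vanishes as `z -> Inf` (desorption limit) and its global
#' minima sit exactly at the four hollow sites with `beta = 0`,
#' `alpha = 0`, `gamma` in `{0, +/-120}`, `z = z0_O`, with energy
#' `-depth_O` (default -0.96 eV). See [toy_adsorption_minima()] for the
#' full documented minima manifest.
#'
#' @param pose Named 6D pose (or matrix/data frame of poses).
#' @param params A [toy_adsorption_params()].
#' @return Energy (eV), vectorized over poses.
#' @export
toy_adsorption_pes <- function(pose, params = toy_adsorption_params()) {
  sp <- pose_space()
  P <- space_points(sp, pose)
  d2r <- pi / 180
  corr <- hex_corrugation(P[, "x"], P[, "y"])
  site <- (1 - corr) / 1.5
  w_top <- 0.5 + 0.5 * (corr + 0.5) / 1.5
  s <- smoothstep((1 + cos(P[, "beta"] * d2r)) / 2)
  D <- params$depth_H + (params$depth_O - params$depth_H) * s
  z0 <- params$z0_H + (params$z0_O - params$z0_H) * s
  A <- D *
    (1 + params$c_xy * site) / (1 + params$c_xy) *
    (1 - params$c_gamma * w_top * (1 - cos(3 * P[, "gamma"] * d2r)) / 2) *
    (1 - params$c_alpha * (1 - cos(P[, "alpha"] * d2r)) / 2)
  t <- P[, "z"] - z0
  k <- params$steepness
  unname(A * (exp(-2 * k * t) - 2 * exp(-k * t)))
}

#' @rdname toy_adsorption_pes
#' @export
toy_adsorption_backend <- function(params = toy_adsorption_params()) {
  energy_backend(function(p) toy_adsorption_pes(rbind(p), params),
                 pose_space(), name = "toy_adsorption")
}

#' Minima manifest of the bundled adsorption surface
#'
#' The 24 analytic minima of [toy_adsorption_pes()]: the four hollow sites
#' of the orthogonal cell crossed with the two orientation families
#' (`beta = 0` deep, `beta = -180` shallow) and the three equivalent
#' azimuths (`gamma = 0, +/-120`), all at `alpha = 0` and the family
#' equilibrium height. Each entry is an exact stationary point by symmetry;
#' [find_minima()] started from the manifest drifts by less than 1e-6.
#'
#' @param params A [toy_adsorption_params()].
#' @return Tibble of poses with columns `x, y, z, alpha, beta, gamma,
#'   energy, family`.
#' @export
toy_adsorption_minima <- function(params = toy_adsorption_params()) {
  hollows <- rbind(c(0, 1 / 3), c(0, -1 / 3), c(-0.5, 1 / 6), c(-0.5, -1 / 6))
  fam <- tibble(
    beta = c(0, -180),
    z = c(params$z0_O, params$z0_H),
    energy = c(-params$depth_O, -params$depth_H),
    family = c("O-down", "H-down")
  )
  grid <- tidyr::expand_grid(
    hollow = seq_len(nrow(hollows)),
    f = seq_len(nrow(fam)),
    gamma = c(0, 120, -120)
  )
  tibble(
    x = hollows[grid$hollow, 1],
    y = hollows[grid$hollow, 2],
    z = fam$z[grid$f],
    alpha = 0,
    beta = fam$beta[grid$f],
    gamma = grid$gamma,
    energy = fam$energy[grid$f],
    family = fam$family[grid$f]
  )
}

#' One-dimensional Morse height curve
#'
#' `E(z) = depth (exp(-2 k (z - z0)) - 2 exp(-k (z - z0)))`: a single
#' documented analytic minimum of `-depth` at `z = z0`, with a steep
#' repulsive wall below it and a dispersive tail. Defaults echo a typical
#' physisorption height curve (minimum -0.847 eV at 4.14 Angstrom).
#'
#' @param depth Well depth in eV.
#' @param z0 Equilibrium height in Angstrom.
#' @param steepness Decay constant in 1/Angstrom.
#' @param z_range Search bounds in Angstrom.
#' @return An [energy_backend()] with attribute-accessible truth in
#'   `$truth` (list with `z0` and `energy`).
#' @export
morse_backend <- function(depth = 0.847, z0 = 4.14, steepness = 1.7,
                          z_range = c(3, 7)) {
  sp <- search_space("z", z_range[1], z_range[2], periodic = FALSE)
  b <- energy_backend(function(p) {
    t <- p[[1]] - z0
    depth * (exp(-2 * steepness * t) - 2 * exp(-steepness * t))
  }, sp, name = "morse_1d")
  b$truth <- list(z0 = z0, energy = -depth)
  b
}

# Periodic bump: 1 at t = 0 (mod 1), decaying with sharpness kappa.
periodic_bump <- function(t, kappa) exp(kappa * (cos(2 * pi * t) - 1))

#' Two-well periodic translational surface
#'
#' A 2D energy landscape over fractional surface coordinates with two
#' identical minima related by the half-cell translation — the qualitative
#' shape of a flat molecular translation landscape on fcc(111). Exactly
#' invariant under [twofold_translation()] and cell translations.
#'
#' @param depth Well depth in eV.
#' @param kappa Well sharpness (dimensionless).
#' @param center Fractional location of the first well.
#' @return An [energy_backend()] with `$truth` listing both minima (the
#'   cross-talk between wells is below 1e-9 eV at the defaults).
#' @export
two_well_backend <- function(depth = 0.3, kappa = 5,
                             center = c(-0.05, -0.08)) {
  sp <- search_space(c("x", "y"), c(-0.5, -0.5), c(0.5, 0.5), periodic = TRUE)
  c2 <- wrap_point(sp, center + 0.5)
  fn <- function(p) {
    -depth * (periodic_bump(p[[1]] - center[1], kappa) *
                periodic_bump(p[[2]] - center[2], kappa) +
              periodic_bump(p[[1]] - c2[1], kappa) *
                periodic_bump(p[[2]] - c2[2], kappa))
  }
  b <- energy_backend(fn, sp, name = "two_well_2d")
  b$truth <- list(minima = rbind(center, c2), energy = -depth)
  b
}

#' Six-well periodic mining fixture
#'
#' A 2D periodic landscape with six planted wells of graded depth, used to
#' certify minima mining against a brute-force dense-grid oracle. Well
#' centres and depths are fixed; the exact minima (slightly shifted from
#' the centres by inter-well cross-talk) are returned by
#' [six_well_minima()], which certifies each by tightly converged local
#' descent from the planted centre.
#'
#' @return An [energy_backend()] over fractional `(x, y)` in
#'   `[-0.5, 0.5]^2`, with `$wells` (centres, depths, sharpness).
#' @export
six_well_backend <- function() {
  centers <- rbind(
    c(-0.35, -0.30), c(0.05, -0.32), c(0.38, -0.10),
    c(-0.28, 0.12), c(0.10, 0.18), c(-0.05, 0.42)
  )
  depths <- c(1.0, 0.9, 0.8, 0.7, 0.6, 0.5)
  kappa <- 8
  sp <- search_space(c("x", "y"), c(-0.5, -0.5), c(0.5, 0.5), periodic = TRUE)
  fn <- function(p) {
    -sum(depths * periodic_bump(p[[1]] - centers[, 1], kappa) *
           periodic_bump(p[[2]] - centers[, 2], kappa))
  }
  b <- energy_backend(fn, sp, name = "six_well_2d")
  b$wells <- list(centers = centers, depths = depths, kappa = kappa)
  b
}

#' @rdname six_well_backend
#' @param backend A [six_well_backend()].
#' @return `six_well_minima()`: tibble of the six certified minima
#'   (`x`, `y`, `energy`).
#' @export
six_well_minima <- function(backend = six_well_backend()) {
  centers <- backend$wells$centers
  res <- lapply(seq_len(nrow(centers)), function(i) {
    fit <- optim(centers[i, ], function(p) backend$fn(p),
                 method = "L-BFGS-B",
                 lower = centers[i, ] - 0.2, upper = centers[i, ] + 0.2,
                 control = list(factr = 1e1, pgtol = 1e-12, maxit = 500))
    drift <- sqrt(sum((fit$par - centers[i, ])^2))
    c(fit$par, energy = fit$value, drift = drift)
  })
  res <- do.call(rbind, res)
  tibble(x = res[, 1], y = res[, 2], energy = res[, "energy"],
         drift = res[, "drift"])
}

#' Replay backend over tabulated energies
#'
#' Exact lookup of precomputed `(point, energy)` records with
#' tolerance matching; queries not in the table are errors — no
#' interpolation, since the Gaussian process is the interpolator.
#'
#' @param records Tibble/data frame with one column per dimension of
#'   `space` plus `energy_eV` (or `energy`).
#' @param space The [search_space()].
#' @param tol Matching tolerance per (wrapped) coordinate.
#' @return An [energy_backend()].
#' @export
tabulated_backend <- function(records, space, tol = 1e-6) {
  records <- as_tibble(records)
  ecol <- intersect(c("energy_eV", "energy"), names(records))[1]
  if (is.na(ecol)) abort("records need an energy_eV (or energy) column")
  pts <- space_points(space, records)
  energies <- records[[ecol]]
  # conflicting duplicates are a construction-time error
  for (i in seq_len(nrow(pts))) {
    if (i == nrow(pts)) break
    j <- seq(i + 1, nrow(pts))
    d <- sweep(pts[j, , drop = FALSE], 2, pts[i, ])
    for (k in which(space$periodic)) {
      d[, k] <- d[, k] - space$period[k] * round(d[, k] / space$period[k])
    }
    hit <- j[rowSums(abs(d) >= tol) == 0]
    if (any(abs(energies[hit] - energies[i]) > 1e-12)) {
      abort("tabulated_backend: duplicate points with conflicting energies")
    }
  }
  fn <- function(p) {
    d <- sweep(pts, 2, as.numeric(p))
    for (k in which(space$periodic)) {
      d[, k] <- d[, k] - space$period[k] * round(d[, k] / space$period[k])
    }
    hit <- which(rowSums(abs(d) >= tol) == 0)
    if (!length(hit)) abort("tabulated_backend: query point not in table")
    energies[hit[1]]
  }
  energy_backend(fn, space, name = "tabulated")
}
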