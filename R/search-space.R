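#' Define a bounded, periodicity-aware search space
#'
#' A search space is the domain over which the potential energy surface (PES)
#' is modelled: one row per degree of freedom, with finite bounds and a flag
#' marking dimensions that wrap around (fractional surface translations,
#' rotation angles). Periodic dimensions have period `upper - lower`.
#'
#' @param name Character vector of dimension names.
#' @param lower,upper Numeric vectors of bounds (finite, `lower < upper`).
#' @param periodic Logical vector; `TRUE` for wrapping dimensions.
#' @return A tibble of class `surf_space` with columns `name`, `lower`,
#'   `upper`, `periodic` and `period` (`NA` for non-periodic dimensions).
#' @examples
#' search_space(
#'   name     = c("x", "z"),
#'   lower    = c(-0.5, 4),
#'   upper    = c(0.5, 7),
#'   periodic = c(TRUE, FALSE)
#' )
#' @export
search_space <- function(name, lower, upper, periodic = FALSE) {
  n <- length(name)
  periodic <- rep_len(periodic, n)
  stopifnot(length(lower) == n, length(upper) == n)
  if (!all(is.finite(lower)) || !all(is.finite(upper))) {
    abort("search_space bounds must be finite")
  }
  if (any(upper <= lower)) abort("search_space requires lower < upper")
  if (anyDuplicated(name)) abort("dimension names must be unique")
  out <- tibble(
    name = as.character(name),
    lower = as.numeric(lower),
    upper = as.numeric(upper),
    periodic = as.logical(periodic),
    period = ifelse(periodic, upper - lower, NA_real_)
  )
  class(out) <- c("surf_space", class(out))
  out
}

#' The six-dimensional adsorbate pose space
#'
#' Convenience constructor for the rigid-body pose domain used throughout:
#' fractional surface translations `x`, `y` on `[-0.5, 0.5]` (periodic),
#' adsorption height `z` in Angstrom, and rotation angles `alpha`, `beta`,
#' `gamma` in degrees on `[-180, 180]` (periodic).
#'
#' @param z_range Height bounds in Angstrom (default `c(4, 7)`).
#' @param gamma_range Range for the azimuthal angle; a threefold top site
#'   symmetry can curtail it to `c(-60, 60)`.
#' @return A [search_space()].
#' @export
pose_space <- function(z_range = c(4, 7), gamma_range = c(-180, 180)) {
  search_space(
    name     = c("x", "y", "z", "alpha", "beta", "gamma"),
    lower    = c(-0.5, -0.5, z_range[1], -180, -180, gamma_range[1]),
    upper    = c(0.5, 0.5, z_range[2], 180, 180, gamma_range[2]),
    periodic = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  )
}

space_dim <- function(space) nrow(space)

#' Wrap a point into the canonical intervals of a search space
#'
#' Periodic coordinates are reduced modulo their period onto
#' `[lower, upper)`; non-periodic coordinates pass through unchanged.
#'
#' @param space A [search_space()].
#' @param p Numeric vector or matrix (points in rows).
#' @return Wrapped coordinates with the same shape as `p`.
#' @export
wrap_point <- function(space, p) {
  if (is.matrix(p)) {
    for (j in which(space$periodic)) {
      v <- ((p[, j] - space$lower[j]) %% space$period[j]) + space$lower[j]
      # guard against numeric fuzz mapping upper-bound hits past the interval
      v[v >= space$upper[j]] <- space$lower[j]
      p[, j] <- v
    }
    return(p)
  }
  per <- space$periodic
  p[per] <- ((p[per] - space$lower[per]) %% space$period[per]) +
    space$lower[per]
  hit <- per & (p >= space$upper)
  p[hit] <- space$lower[hit]
  p
}

# Per-dimension displacement honouring periodic wrap-around (shortest image).
space_delta <- function(space, p, q) {
  d <- p - q
  per <- space$periodic
  d[per] <- d[per] - space$period[per] * round(d[per] / space$period[per])
  d
}

# Normalized (by span) wrapped distance components, used for deduplication.
space_norm_delta <- function(space, p, q) {
  abs(space_delta(space, p, q)) / (space$upper - space$lower)
}

in_bounds <- function(space, p, tol = 1e-9) {
  all(p >= space$lower - tol & p <= space$upper + tol)
}

# Seeded Latin-hypercube design over the space, points in rows.
space_design <- function(space, n, seed = NULL) {
  if (n == 0) {
    return(matrix(numeric(0), 0, space_dim(space),
                  dimnames = list(NULL, space$name)))
  }
  if (!is.null(seed)) set.seed(seed)
  u <- lhs::randomLHS(n, space_dim(space))
  pts <- sweep(u, 2, space$upper - space$lower, "*")
  pts <- sweep(pts, 2, space$lower, "+")
  colnames(pts) <- space$name
  pts
}

# Coerce a data frame / named vector / matrix to a points matrix in the
# dimension order of `space`.
space_points <- function(space, p) {
  if (is.data.frame(p)) {
    missing <- setdiff(space$name, names(p))
    if (length(missing)) {
      abort(paste0("missing dimension column(s): ",
                   paste(missing, collapse = ", ")))
    }
    p <- as.matrix(p[space$name])
  } else if (is.null(dim(p))) {
    if (!is.null(names(p)) && all(space$name %in% names(p))) {
      p <- p[space$name]
    }
    if (length(p) != space_dim(space)) abort("point has wrong dimension")
    p <- matrix(p, 1, dimnames = list(NULL, space$name))
  } else {
    if (ncol(p) != space_dim(space)) abort("points have wrong dimension")
    colnames(p) <- space$name
  }
  storage.mode(p) <- "double"
  p
}

points_tibble <- function(space, pts) {
  as_tibble(as.data.frame(space_points(space, pts)))
}
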