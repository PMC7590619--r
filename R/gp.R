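#' Product kernel with per-dimension periodicity
#'
#' The surrogate's covariance function is a product over search dimensions
#' of one-dimensional kernels, scaled by a signal variance: squared
#' exponential `exp(-d^2 / (2 l^2))` for non-periodic dimensions and the
#' exponentiated sine-squared kernel
#' `exp(-2 sin^2(pi d / P) / (2 pi l / P)^2)` for periodic dimensions with
#' period `P` — parameterized so that `l` is in coordinate units and the
#' small-distance behaviour matches the squared exponential. Periodic
#' dimensions are exactly periodic: `k(p, p + P e_i) = k(p, p)`.
#'
#' @param space A [search_space()]; periods are taken from it.
#' @param lengthscales Positive per-dimension lengthscales, in the units of
#'   each coordinate (Angstrom, fractional units, degrees).
#' @param signal_var Signal variance in eV^2.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(space, lengthscales, signal_var = 1) {
  d <- space_dim(space)
  lengthscales <- rep_len(as.numeric(lengthscales), d)
  if (any(lengthscales <= 0)) abort("lengthscales must be positive")
  if (signal_var < 0) abort("signal variance must be non-negative")
  structure(
    list(space = space, lengthscales = lengthscales,
         signal_var = as.numeric(signal_var)),
    class = "kernel_spec"
  )
}

#' Evaluate the kernel between two points
#'
#' @param spec A [kernel_spec()].
#' @param p,q Points (named or positional numeric vectors).
#' @return Covariance in eV^2; symmetric in `p` and `q`.
#' @export
kernel_eval <- function(spec, p, q) {
  space <- spec$space
  p <- drop(space_points(space, p)); q <- drop(space_points(space, q))
  if (length(p) != space_dim(space) || length(q) != space_dim(space)) {
    abort("kernel_eval: dimension mismatch")
  }
  drop(kernel_cross(spec, matrix(p, 1), matrix(q, 1)))
}

# Cross-covariance matrix between rows of X (n x d) and rows of Y (m x d).
kernel_cross <- function(spec, X, Y) {
  space <- spec$space
  n <- nrow(X); m <- nrow(Y)
  logk <- matrix(0, n, m)
  for (j in seq_len(space_dim(space))) {
    D <- outer(X[, j], Y[, j], "-")
    l <- spec$lengthscales[j]
    if (space$periodic[j]) {
      lhat <- 2 * pi * l / space$period[j]
      logk <- logk - 2 * sin(pi * D / space$period[j])^2 / lhat^2
    } else {
      logk <- logk - 0.5 * (D / l)^2
    }
  }
  spec$signal_var * exp(logk)
}

# Cholesky with escalating jitter 1e-8 -> 1e-4 (x10 steps).
chol_jitter <- function(K) {
  jit <- 0
  for (j in c(0, 1e-8 * 10^(0:4))) {
    L <- tryCatch(chol(K + diag(j, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = j))
  }
  abort("covariance matrix singular even after jitter escalation to 1e-4")
}

gp_neg_lml <- function(log_par, X, y_c, space, noise) {
  d <- ncol(X)
  spec <- kernel_spec(space, exp(log_par[seq_len(d)]), exp(log_par[d + 1]))
  K <- kernel_cross(spec, X, X) + diag(noise, nrow(X))
  cj <- tryCatch(chol_jitter(K), error = function(e) NULL)
  if (is.null(cj)) return(1e10)
  a <- backsolve(cj$L, forwardsolve(t(cj$L), y_c))
  0.5 * sum(y_c * a) + sum(log(diag(cj$L))) + 0.5 * length(y_c) * log(2 * pi)
}

#' Fit a Gaussian-process surrogate to a sampled dataset
#'
#' Energies are centred by a constant prior mean set to the maximum observed
#' energy, which biases unexplored regions pessimistically so that
#' lower-confidence-bound exploration is driven by the posterior variance.
#' Kernel hyperparameters (per-dimension lengthscales and the signal
#' variance) maximize the log marginal likelihood via multi-restart L-BFGS
#' in log space; the observation noise is fixed at a small floor because
#' backend energies are deterministic.
#'
#' @param dataset Tibble with one column per search dimension plus `energy`
#'   (eV); duplicate points (within `1e-6`) are collapsed first.
#' @param space The [search_space()].
#' @param noise Observation noise variance in eV^2 (floor `1e-6`).
#' @param restarts Number of random restarts for hyperparameter fitting.
#' @param seed Seed making the restart draws reproducible.
#' @param lengthscale_bounds Optional `d x 2` matrix of lower/upper
#'   lengthscale bounds; defaults span from 2% to twice each dimension's
#'   extent (one period for periodic dimensions).
#' @return An object of class `surf_gp`.
#' @export
fit_gp <- function(dataset, space, noise = 1e-6, restarts = 5, seed = 0,
                   lengthscale_bounds = NULL) {
  dataset <- dedup_dataset(as_tibble(dataset), space)
  if (nrow(dataset) < 2) abort("fit_gp needs at least 2 distinct points")
  X <- space_points(space, dataset)
  y <- dataset$energy
  if (!all(is.finite(y))) abort("energies must be finite")
  if (noise <= 0) abort("noise variance must be positive")
  prior_mean <- max(y)
  y_c <- y - prior_mean
  d <- space_dim(space)

  span <- space$upper - space$lower
  if (is.null(lengthscale_bounds)) {
    lengthscale_bounds <- cbind(0.02 * span, 2 * span)
  }
  var_y <- max(stats::var(y_c), 1e-8)
  sig_bounds <- c(1e-8, 100 * var_y)
  lo <- log(c(lengthscale_bounds[, 1], sig_bounds[1]))
  hi <- log(c(lengthscale_bounds[, 2], sig_bounds[2]))

  set.seed(seed)
  starts <- rbind(
    log(c(0.3 * span, max(var_y, 1e-4))),
    matrix(runif(restarts * (d + 1), rep(lo, each = restarts),
                 rep(hi, each = restarts)), restarts, d + 1)
  )
  starts <- pmin(pmax(starts, rep(lo, each = nrow(starts))),
                 rep(hi, each = nrow(starts)))

  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[s, ], gp_neg_lml, method = "L-BFGS-B",
            lower = lo, upper = hi,
            X = X, y_c = y_c, space = space, noise = noise,
            control = list(maxit = 200)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort("hyperparameter optimization failed in all restarts")

  spec <- kernel_spec(space, exp(best$par[seq_len(d)]), exp(best$par[d + 1]))
  K <- kernel_cross(spec, X, X) + diag(noise, nrow(X))
  cj <- chol_jitter(K)
  alpha <- backsolve(cj$L, forwardsolve(t(cj$L), y_c))

  structure(
    list(
      space = space, kernel = spec, noise = noise, jitter = cj$jitter,
      prior_mean = prior_mean, X = X, y = y, L = cj$L, alpha = alpha,
      log_marginal_likelihood = -best$value, n = nrow(X)
    ),
    class = "surf_gp"
  )
}

#' @export
print.surf_gp <- function(x, ...) {
  cat(sprintf(
    "<surf_gp> %d points, %dD; signal sd %.4f eV, noise sd %.4f eV, lml %.2f\n",
    x$n, space_dim(x$space), sqrt(x$kernel$signal_var), sqrt(x$noise),
    x$log_marginal_likelihood
  ))
  cat("lengthscales:",
      paste(sprintf("%s=%.3g", x$space$name, x$kernel$lengthscales),
            collapse = ", "), "\n")
  invisible(x)
}

#' Posterior mean and variance of the surrogate
#'
#' Standard Gaussian-process conditioning: at query points `p`, the
#' posterior mean is the most probable model of the PES and the posterior
#' variance quantifies model uncertainty (it shrinks to the noise floor at
#' training points and reverts to the signal variance far from data along
#' non-periodic dimensions). The returned variance is that of the latent
#' function (observation noise not added), floored at zero.
#'
#' @param model A fitted [fit_gp()] model.
#' @param p A point, matrix of points (rows) or data frame.
#' @return A tibble with columns `mean` (eV) and `variance` (eV^2), one row
#'   per query point.
#' @export
posterior <- function(model, p) {
  stopifnot(inherits(model, "surf_gp"))
  P <- space_points(model$space, p)
  Ks <- kernel_cross(model$kernel, model$X, P)      # n x m
  mean <- model$prior_mean + drop(crossprod(Ks, model$alpha))
  V <- forwardsolve(t(model$L), Ks)
  var <- pmax(model$kernel$signal_var - colSums(V^2), 0)
  tibble(mean = as.numeric(mean), variance = as.numeric(var))
}

posterior_mean_fn <- function(model) {
  function(p) posterior(model, p)$mean
}

# Allocation-light single-point posterior used inside optimizer hot loops.
# Returns function(p) -> c(mean, var); numerically identical to posterior().
gp_post_fast <- function(model) {
  X <- model$X
  alpha <- model$alpha
  pm <- model$prior_mean
  ls <- model$kernel$lengthscales
  sv <- model$kernel$signal_var
  per <- model$space$periodic
  period <- model$space$period
  Lt <- t(model$L)
  d <- ncol(X)
  function(p) {
    logk <- 0
    for (j in seq_len(d)) {
      D <- X[, j] - p[j]
      logk <- logk - if (per[j]) {
        2 * sin(pi * D / period[j])^2 / (2 * pi * ls[j] / period[j])^2
      } else {
        0.5 * (D / ls[j])^2
      }
    }
    k <- sv * exp(logk)
    v <- forwardsolve(Lt, k)
    c(pm + sum(k * alpha), max(sv - sum(v * v), 0))
  }
}

gp_mean_fast <- function(model) {
  post <- gp_post_fast(model)
  function(p) post(p)[1]
}

#' Posterior standard deviation
#'
#' The square root of the posterior variance; the per-minimum confidence
#' measure reported alongside predicted energies.
#'
#' @inheritParams posterior
#' @return Numeric vector of standard deviations in eV.
#' @export
posterior_std <- function(model, p) {
  sqrt(posterior(model, p)$variance)
}

#' Tidy and glance methods for fitted surrogates
#'
#' `tidy()` returns one row per dimension with the fitted lengthscale;
#' `glance()` returns one-row model-level summaries.
#'
#' @param x A `surf_gp` model.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.surf_gp <- function(x, ...) {
  tibble(
    dimension = x$space$name,
    periodic = x$space$periodic,
    period = x$space$period,
    lengthscale = x$kernel$lengthscales
  )
}

#' @rdname tidy.surf_gp
#' @export
glance.surf_gp <- function(x, ...) {
  tibble(
    n = x$n,
    dims = space_dim(x$space),
    signal_var = x$kernel$signal_var,
    noise = x$noise,
    jitter = x$jitter,
    prior_mean = x$prior_mean,
    log_marginal_likelihood = x$log_marginal_likelihood
  )
}
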