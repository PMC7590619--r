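#' Settings for an active-learning structure search
#'
#' @param space The [search_space()].
#' @param budget Maximum number of new backend evaluations (>= 0).
#' @param init_n Number of seeded quasi-random (Latin hypercube) initial
#'   points, evaluated with the backend before the loop. Ignored in favour
#'   of `warm` records when those are supplied and `init_n = 0`.
#' @param warm Optional warm-start records: tibble with search-dimension
#'   columns (missing dimensions are filled from `fill`) plus `energy`.
#' @param fill Named values used to embed lower-dimensional warm records in
#'   the full space (low-dimensional scan recycling).
#' @param sym_ops List of symmetry maps (see [augment_dataset()]) applied
#'   to every stored record; symmetry images do not count as evaluations.
#' @param elcb_delta Confidence parameter of the exploration schedule.
#' @param eta_const Optional constant overriding the schedule (`eta(t) =
#'   eta_const`).
#' @param location_tol Named per-dimension convergence tolerances; defaults
#'   are 0.02 fractional units in `x`/`y`, 0.1 Angstrom in `z`, 5 degrees
#'   in angles, otherwise 2% of the span.
#' @param energy_tol Convergence tolerance on minima energies (eV).
#' @param window Stability window (iterations) for convergence.
#' @param seed Master seed; all randomness (designs, restarts, multistarts)
#'   derives from it, making [run_search()] reproducible bit for bit.
#' @param snapshot_starts Multistart count for per-iteration minima
#'   snapshots (the final mining pass uses [find_minima()]'s full count).
#' @param fit_restarts Hyperparameter restarts per refit.
#' @param noise GP noise variance (eV^2).
#' @param track_minima Record a minima snapshot each iteration (needed for
#'   convergence on all minima; disable for speed).
#' @return An object of class `search_settings`.
#' @export
search_settings <- function(space, budget = 30, init_n = 5, warm = NULL,
                            fill = NULL, sym_ops = list(),
                            elcb_delta = 0.1, eta_const = NULL,
                            location_tol = NULL, energy_tol = 0.02,
                            window = 10, seed = 0,
                            snapshot_starts = 16, fit_restarts = 5,
                            noise = 1e-6, track_minima = TRUE) {
  stopifnot(inherits(space, "surf_space"), budget >= 0, window >= 1,
            energy_tol > 0)
  if (is.null(location_tol)) {
    location_tol <- vapply(seq_len(nrow(space)), function(i) {
      nm <- space$name[i]
      if (nm %in% c("x", "y")) 0.02
      else if (nm == "z") 0.1
      else if (nm %in% c("alpha", "beta", "gamma", "theta", "phi", "omega")) 5
      else 0.02 * (space$upper[i] - space$lower[i])
    }, numeric(1))
    names(location_tol) <- space$name
  }
  location_tol <- location_tol[space$name]
  if (any(!is.finite(location_tol)) || any(location_tol <= 0)) {
    abort("location_tol must be positive for every dimension")
  }
  structure(
    list(space = space, budget = as.integer(budget),
         init_n = as.integer(init_n), warm = warm, fill = fill,
         sym_ops = sym_ops, elcb_delta = elcb_delta, eta_const = eta_const,
         location_tol = location_tol, energy_tol = energy_tol,
         window = as.integer(window), seed = as.integer(seed),
         snapshot_starts = as.integer(snapshot_starts),
         fit_restarts = as.integer(fit_restarts), noise = noise,
         track_minima = isTRUE(track_minima)),
    class = "search_settings"
  )
}

#' Exploratory lower confidence bound acquisition
#'
#' `elcb(p, t) = mean(p) - eta(t) * sd(p)`, minimized to pick the next
#' evaluation. The exploration weight follows the schedule
#' `eta(t) = sqrt(2 log(t^(d/2 + 2) pi^2 / (3 delta)))` with `delta = 0.1`
#' by default, growing slowly with iteration `t` and dimension `d` so that
#' exploration never dies out; a constant override is available.
#'
#' @param model A fitted [fit_gp()] surrogate.
#' @param p Query point(s).
#' @param t Iteration index (>= 1).
#' @param delta Schedule confidence parameter.
#' @param eta_const Optional constant exploration weight.
#' @return Acquisition value(s); lower is better.
#' @export
elcb <- function(model, p, t, delta = 0.1, eta_const = NULL) {
  post <- posterior(model, p)
  eta <- eta_const %||% elcb_eta(t, space_dim(model$space), delta)
  post$mean - eta * sqrt(post$variance)
}

elcb_eta <- function(t, d, delta = 0.1) {
  sqrt(2 * log(t^(d / 2 + 2) * pi^2 / (3 * delta)))
}

#' Optimize the acquisition function
#'
#' Global minimizer of [elcb()] over the bounded, periodicity-aware space:
#' multistart L-BFGS descent from a seeded Latin hypercube (plus the
#' incumbent best observed point), with periodic dimensions widened by a
#' quarter period on each side during descent and results wrapped back.
#'
#' @param model A fitted [fit_gp()] model.
#' @param settings A [search_settings()].
#' @param t Iteration index (enters the exploration schedule and the
#'   multistart seed).
#' @param n_starts Number of multistarts.
#' @return The chosen point as a named numeric vector with attribute
#'   `acquisition` (its eLCB value).
#' @export
next_acquisition <- function(model, settings, t, n_starts = 24) {
  space <- settings$space
  eta <- settings$eta_const %||%
    elcb_eta(t, space_dim(space), settings$elcb_delta)
  post <- gp_post_fast(model)
  obj <- function(p) {
    mv <- post(p)
    mv[1] - eta * sqrt(mv[2])
  }
  inc <- model$X[which.min(model$y), , drop = FALSE]
  starts <- rbind(space_design(space, n_starts,
                               seed = settings$seed * 1000L + t),
                  inc)
  res <- optimize_multistart(obj, space, starts)
  best <- res$points[which.min(res$values), ]
  structure(setNames(best, space$name),
            acquisition = min(res$values))
}

# Multistart bounded L-BFGS with periodic widening; returns converged
# endpoints (wrapped) and their objective values.
optimize_multistart <- function(obj, space, starts,
                                factr = 1e4, pgtol = 1e-8, maxit = 200) {
  lo <- space$lower; hi <- space$upper
  widen <- ifelse(space$periodic, 0.25 * (hi - lo), 0)
  pts <- matrix(NA_real_, nrow(starts), space_dim(space))
  vals <- rep(NA_real_, nrow(starts))
  conv <- rep(FALSE, nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], obj, method = "L-BFGS-B",
            lower = lo - widen, upper = hi + widen,
            control = list(factr = factr, pgtol = pgtol, maxit = maxit)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    pts[i, ] <- wrap_point(space, fit$par)
    vals[i] <- fit$value
    conv[i] <- fit$convergence == 0
  }
  ok <- !is.na(vals)
  if (!any(ok)) abort("all optimizer restarts failed")
  list(points = pts[ok, , drop = FALSE], values = vals[ok],
       converged = conv[ok])
}

#' Assemble the initial dataset for a search
#'
#' Warm-start records are wrapped into the space (violators of non-periodic
#' bounds dropped with a warning), lower-dimensional records are embedded
#' using the `fill` values, duplicates are collapsed, requested
#' quasi-random points are evaluated with the backend, and symmetry
#' augmentation is applied when configured.
#'
#' @param settings A [search_settings()].
#' @param backend An [energy_backend()]; only needed when `init_n > 0`.
#' @return The initial dataset tibble (dimension columns, `energy`,
#'   `provenance`).
#' @export
bo_initialize <- function(settings, backend = NULL) {
  space <- settings$space
  data <- NULL
  if (!is.null(settings$warm)) {
    warm <- as_tibble(settings$warm)
    ecol <- intersect(c("energy", "energy_eV"), names(warm))[1]
    if (is.na(ecol)) abort("warm records need an energy column")
    names(warm)[names(warm) == ecol] <- "energy"
    missing <- setdiff(space$name, names(warm))
    if (length(missing)) {
      fills <- settings$fill
      if (is.null(fills) || !all(missing %in% names(fills))) {
        abort(paste0("warm records missing dimension(s) ",
                     paste(missing, collapse = ", "),
                     " and no fill values supplied"))
      }
      for (nm in missing) warm[[nm]] <- fills[[nm]]
    }
    pts <- wrap_point(space, space_points(space, warm))
    ok <- apply(pts, 1, function(p) in_bounds(space, p))
    if (!all(ok)) {
      warn(sprintf("bo_initialize: dropped %d warm record(s) outside bounds",
                   sum(!ok)))
    }
    data <- points_tibble(space, pts[ok, , drop = FALSE])
    data$energy <- warm$energy[ok]
    data$provenance <- "scanned"
  }
  if (settings$init_n > 0) {
    if (is.null(backend)) abort("backend required to evaluate initial points")
    pts <- space_design(space, settings$init_n, seed = settings$seed)
    qr <- points_tibble(space, pts)
    qr$energy <- backend_eval(backend, pts)
    qr$provenance <- "acquired"
    data <- if (is.null(data)) qr else dplyr::bind_rows(data, qr)
  }
  if (is.null(data) || nrow(data) == 0) abort("empty initial dataset")
  data <- dedup_dataset(data, space)
  if (length(settings$sym_ops)) {
    data <- augment_dataset(data, settings$sym_ops, space)
  }
  data
}

#' Run the active-learning structure search
#'
#' The core loop: fit the Gaussian-process surrogate to all stored
#' energies, minimize the eLCB acquisition to choose the next pose,
#' evaluate it with the energy backend, append the observation (plus its
#' symmetry images, which do not count as evaluations), and repeat until
#' the budget is exhausted or every minimum of the surrogate has been
#' stable in location, energy and count over the convergence window. Every
#' backend call is logged in the history. With a fixed seed, backend and
#' settings the run is deterministic.
#'
#' @param backend An [energy_backend()].
#' @param settings A [search_settings()].
#' @param dataset Optional existing dataset to resume from (overrides
#'   initialization).
#' @param log_file Optional path; every backend evaluation is appended as a
#'   JSON line (`iteration`, `point`, `energy`, `wall_time_s` —
#'   informational only).
#' @return An object of class `surf_search`: list with `dataset` (tibble),
#'   `model` (final [fit_gp()]), `history` (one row per backend
#'   evaluation), `convergence` (a `convergence_report`), `minima` (final
#'   snapshot) and `settings`.
#' @export
run_search <- function(backend, settings, dataset = NULL, log_file = NULL) {
  space <- settings$space
  if (is.null(dataset)) dataset <- bo_initialize(settings, backend)

  history <- list()
  snapshots <- list()
  blacklist <- NULL
  failures <- 0L
  converged_early <- FALSE
  model <- NULL

  for (t in seq_len(settings$budget)) {
    model <- fit_gp(dataset, space, noise = settings$noise,
                    restarts = settings$fit_restarts, seed = settings$seed)
    pt <- next_acquisition(model, settings, t)
    if (!is.null(blacklist) &&
        any(apply(blacklist, 1, function(b)
          all(space_norm_delta(space, pt, b) < 1e-6)))) {
      # nudge away from a blacklisted point deterministically
      pt <- wrap_point(space, pt + 1e-3 * (space$upper - space$lower))
    }
    acq_chosen <- attr(pt, "acquisition")
    inc <- model$X[which.min(model$y), ]
    acq_incumbent <- as.numeric(elcb(model, matrix(inc, 1), t,
                                     delta = settings$elcb_delta,
                                     eta_const = settings$eta_const))
    t0 <- proc.time()[["elapsed"]]
    e <- tryCatch(backend_eval(backend, pt), error = function(err) NULL)
    if (!is.null(log_file) && !is.null(e) && is.finite(e)) {
      line <- jsonlite::toJSON(
        list(iteration = t, point = setNames(as.numeric(pt), space$name),
             energy = e, wall_time_s = proc.time()[["elapsed"]] - t0),
        auto_unbox = TRUE, digits = NA
      )
      cat(line, "\n", file = log_file, append = TRUE, sep = "")
    }
    if (is.null(e) || !is.finite(e)) {
      blacklist <- rbind(blacklist, as.numeric(pt))
      failures <- failures + 1L
      if (failures >= 5L) {
        warn("run_search: repeated backend failures; returning partial results")
        break
      }
      next
    }
    failures <- 0L

    new_rec <- points_tibble(space, matrix(as.numeric(pt), 1))
    new_rec$energy <- e
    new_rec$provenance <- "acquired"
    if (length(settings$sym_ops)) {
      new_rec <- augment_dataset(new_rec, settings$sym_ops, space)
    }
    dataset <- dedup_dataset(dplyr::bind_rows(dataset, new_rec), space)

    snap <- NULL
    best_loc <- rep(NA_real_, space_dim(space))
    best_val <- NA_real_
    if (settings$track_minima) {
      refit <- fit_gp(dataset, space, noise = settings$noise,
                      restarts = settings$fit_restarts, seed = settings$seed)
      snap <- find_minima(refit, n_starts = settings$snapshot_starts,
                          seed = settings$seed)
      if (nrow(snap) > 0) {
        best <- snap[which.min(snap$E_B), ]
        best_loc <- as.numeric(best[1, space$name])
        best_val <- best$E_B[1]
      }
      snapshots[[length(snapshots) + 1L]] <- snap
    }

    rec <- points_tibble(space, matrix(as.numeric(pt), 1))
    rec$iteration <- t
    rec$energy <- e
    rec$acquisition <- acq_chosen
    rec$acquisition_incumbent <- acq_incumbent
    rec$best_min_value <- best_val
    rec$n_minima <- if (is.null(snap)) NA_integer_ else nrow(snap)
    history[[length(history) + 1L]] <- rec

    if (settings$track_minima && length(snapshots) >= settings$window + 1L) {
      report <- convergence_check(snapshots, settings)
      if (report$converged) {
        converged_early <- TRUE
        break
      }
    }
  }

  model <- fit_gp(dataset, space, noise = settings$noise,
                  restarts = settings$fit_restarts, seed = settings$seed)
  minima <- find_minima(model, seed = settings$seed)
  report <- if (length(snapshots) >= settings$window + 1L) {
    convergence_check(snapshots, settings)
  } else {
    structure(list(converged = converged_early, drifts = NULL,
                   n_snapshots = length(snapshots)),
              class = "convergence_report")
  }

  history_tb <- if (length(history)) dplyr::bind_rows(history) else
    tibble(iteration = integer(0))
  structure(
    list(dataset = dataset, model = model, history = history_tb,
         convergence = report, minima = minima, snapshots = snapshots,
         settings = settings),
    class = "surf_search"
  )
}

#' @export
print.surf_search <- function(x, ...) {
  cat(sprintf(
    "<surf_search> %d stored points (%d evaluations), %d minima, converged: %s\n",
    nrow(x$dataset), nrow(x$history), nrow(x$minima),
    x$convergence$converged
  ))
  invisible(x)
}

#' Convergence of the minima over a stability window
#'
#' The search is converged when, across the last `window + 1` minima
#' snapshots, (i) the number of minima is stable, and (ii) every minimum of
#' the latest snapshot can be matched in each snapshot of the window with
#' per-dimension location drift below the tolerance and energy drift below
#' the energy tolerance — convergence with respect to the coordinates and
#' energy of all the minima, not only the global one.
#'
#' @param snapshots List of minima tibbles (as produced during
#'   [run_search()]), oldest first.
#' @param settings A [search_settings()].
#' @return An object of class `convergence_report`: `converged`, per-minimum
#'   `drifts` tibble (max location drift per dimension, energy drift),
#'   `count_stable` and `n_snapshots`.
#' @export
convergence_check <- function(snapshots, settings) {
  space <- settings$space
  w <- settings$window
  if (length(snapshots) < w + 1L) {
    abort("convergence_check needs at least window + 1 snapshots")
  }
  recent <- tail(snapshots, w + 1L)
  counts <- vapply(recent, nrow, integer(1))
  count_stable <- length(unique(counts)) == 1L
  latest <- recent[[length(recent)]]

  drifts <- NULL
  all_within <- count_stable && nrow(latest) > 0
  if (nrow(latest) > 0 && count_stable) {
    loc_drift <- matrix(0, nrow(latest), space_dim(space))
    e_drift <- numeric(nrow(latest))
    for (i in seq_len(nrow(latest))) {
      p <- as.numeric(latest[i, space$name])
      for (s in head(recent, -1)) {
        if (nrow(s) == 0) { all_within <- FALSE; next }
        dmat <- t(apply(space_points(space, s), 1,
                        function(q) abs(space_delta(space, p, q))))
        if (nrow(s) == 1) dmat <- matrix(dmat, 1)
        j <- which.min(rowSums(sweep(dmat, 2,
                                     settings$location_tol, "/")^2))
        loc_drift[i, ] <- pmax(loc_drift[i, ], dmat[j, ])
        e_drift[i] <- max(e_drift[i], abs(latest$E_B[i] - s$E_B[j]))
      }
      if (any(loc_drift[i, ] >= settings$location_tol) ||
          e_drift[i] >= settings$energy_tol) {
        all_within <- FALSE
      }
    }
    drifts <- points_tibble(space, loc_drift)
    names(drifts) <- paste0("drift_", space$name)
    drifts$drift_energy <- e_drift
  }
  structure(
    list(converged = isTRUE(all_within), count_stable = count_stable,
         drifts = drifts, n_snapshots = length(snapshots)),
    class = "convergence_report"
  )
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence_report> converged: %s (snapshots: %d)\n",
              x$converged, x$n_snapshots))
  invisible(x)
}

#' @rdname tidy.surf_gp
#' @export
tidy.surf_search <- function(x, ...) x$minima

#' @rdname tidy.surf_gp
#' @export
glance.surf_search <- function(x, ...) {
  tibble(
    n_points = nrow(x$dataset),
    n_evaluations = nrow(x$history),
    n_minima = nrow(x$minima),
    best_energy = if (nrow(x$minima)) min(x$minima$E_B) else NA_real_,
    converged = x$convergence$converged
  )
}
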