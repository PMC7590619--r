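# Resolve (energy function, space) from a fitted surrogate, a backend, or
# a bare function with an explicit space.
energy_surface <- function(object, space = NULL) {
  if (inherits(object, "surf_gp")) {
    list(fn = gp_mean_fast(object),
         space = object$space, model = object)
  } else if (inherits(object, "energy_backend")) {
    list(fn = object$fn, space = object$space, model = NULL)
  } else if (is.function(object)) {
    if (is.null(space)) abort("a bare function needs an explicit space")
    list(fn = object, space = space, model = NULL)
  } else {
    abort("object must be a surf_gp, energy_backend or function")
  }
}

#' Mine all minima of an energy surface
#'
#' Multistart local descent (bounded L-BFGS) on the posterior mean of a
#' fitted surrogate — or directly on an analytic backend — from a seeded
#' quasi-random design. Converged endpoints are deduplicated with a
#' periodic metric (merged when every normalized wrapped component differs
#' by less than `dedup_tol`, keeping the lowest-energy representative),
#' certified as interior minima by a positive-definite numeric Hessian, and
#' sorted by energy. For surrogate models the posterior standard deviation
#' `sigma_B` is attached per minimum.
#'
#' @param object A [fit_gp()] model, an [energy_backend()], or a function
#'   (with `space` supplied).
#' @param space Required when `object` is a bare function.
#' @param n_starts Multistart count (default 512, suitable for up to six
#'   dimensions).
#' @param seed Seed for the start design.
#' @param dedup_tol Merge tolerance on normalized wrapped coordinates.
#' @param hess_tol Minimum Hessian eigenvalue for a candidate to count as a
#'   minimum (rejects flat-region stalls and saddles).
#' @return Tibble with one row per minimum: the location columns, `E_B`
#'   (predicted energy, eV), `sigma_B` (model standard deviation, eV; `NA`
#'   for non-surrogate surfaces) and `grad_norm` (stationarity
#'   certificate).
#' @export
find_minima <- function(object, space = NULL, n_starts = 512, seed = 0,
                        dedup_tol = 0.02, hess_tol = 1e-7) {
  surf <- energy_surface(object, space)
  space <- surf$space
  f <- function(p) as.numeric(surf$fn(p))

  starts <- space_design(space, n_starts, seed = seed)
  res <- tryCatch(
    optimize_multistart(f, space, starts,
                        factr = 1e1, pgtol = 1e-10, maxit = 500),
    error = function(e) NULL
  )
  empty <- tibble::as_tibble(setNames(
    as.data.frame(matrix(numeric(0), 0, space_dim(space))), space$name))
  empty$E_B <- numeric(0); empty$sigma_B <- numeric(0)
  empty$grad_norm <- numeric(0)
  if (is.null(res)) {
    warn("find_minima: no descent converged")
    return(empty)
  }

  # boundary-stuck endpoints on non-periodic dimensions are not minima of
  # the interior landscape
  interior <- apply(res$points, 1, function(p) {
    np <- !space$periodic
    all(p[np] > space$lower[np] + 1e-8) && all(p[np] < space$upper[np] - 1e-8)
  })
  pts <- res$points[interior, , drop = FALSE]
  vals <- res$values[interior]
  if (nrow(pts) == 0) {
    warn("find_minima: no interior minima found")
    return(empty)
  }

  ord <- order(vals)
  pts <- pts[ord, , drop = FALSE]; vals <- vals[ord]
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!keep[i]) next
    j <- which(keep); j <- j[j > i]
    for (jj in j) {
      if (all(space_norm_delta(space, pts[i, ], pts[jj, ]) < dedup_tol)) {
        keep[jj] <- FALSE
      }
    }
  }
  pts <- pts[keep, , drop = FALSE]; vals <- vals[keep]

  # stationarity certificate: positive-definite Hessian, small gradient
  ok <- logical(nrow(pts))
  gnorm <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    g <- pracma::grad(f, pts[i, ])
    H <- pracma::hessian(f, pts[i, ])
    ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
    gnorm[i] <- sqrt(sum(g^2))
    ok[i] <- min(ev) > hess_tol
  }
  pts <- pts[ok, , drop = FALSE]; vals <- vals[ok]; gnorm <- gnorm[ok]
  if (nrow(pts) == 0) {
    warn("find_minima: no certified minima")
    return(empty)
  }

  out <- points_tibble(space, pts)
  out$E_B <- vals
  out$sigma_B <- if (!is.null(surf$model)) {
    posterior_std(surf$model, pts)
  } else NA_real_
  out$grad_norm <- gnorm
  out[order(out$E_B), ]
}

#' Verify mined minima against the energy backend
#'
#' For each mined minimum, evaluates the backend energy `E_D` at the mined
#' location (`delta_E_D = E_D - E_B` measures surrogate accuracy) and,
#' optionally, performs a local descent on the backend energy in pose
#' space — the desk-scale counterpart of a full structural relaxation —
#' giving the relaxed energy `E_rel` and its change
#' `delta_E_rel = E_rel - E_D`.
#'
#' @param records A minima tibble from [find_minima()].
#' @param backend An [energy_backend()] over the same space.
#' @param descend Perform the local descent filling `E_rel`?
#' @return `records` with columns `E_D`, `delta_E_D` and (if `descend`)
#'   `E_rel`, `delta_E_rel` appended. Backend failures leave the fields
#'   `NA`.
#' @export
verify_minimum <- function(records, backend, descend = TRUE) {
  space <- backend$space
  n <- nrow(records)
  E_D <- rep(NA_real_, n); E_rel <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- as.numeric(records[i, space$name])
    E_D[i] <- tryCatch(backend_eval(backend, p), error = function(e) NA_real_)
    if (descend && is.finite(E_D[i])) {
      res <- tryCatch(
        optimize_multistart(function(q) as.numeric(backend$fn(q)), space,
                            matrix(p, 1), factr = 1e1, pgtol = 1e-10),
        error = function(e) NULL
      )
      if (!is.null(res)) E_rel[i] <- min(res$values, E_D[i])
    }
  }
  records$E_D <- E_D
  records$delta_E_D <- E_D - records$E_B
  if (descend) {
    records$E_rel <- E_rel
    records$delta_E_rel <- E_rel - E_D
  }
  records
}

#' Two-dimensional cross-section of the modelled PES
#'
#' Evaluates the surface on a tensor grid over two free dimensions with all
#' remaining dimensions clamped — the standard way to visualize a
#' high-dimensional surrogate and to measure translational barriers on the
#' x-y plane.
#'
#' @param object A [fit_gp()] model or [energy_backend()].
#' @param fixed Named values of the clamped dimensions.
#' @param free_dims Character vector naming exactly two free dimensions.
#' @param grid Integer pair: grid shape (default 100 x 100).
#' @return An object of class `cross_section`: tibble `values` with the two
#'   free coordinates and `energy`, plus `free_dims`, `fixed` and `grid`.
#' @export
cross_section <- function(object, fixed, free_dims, grid = c(100, 100)) {
  surf <- energy_surface(object)
  space <- surf$space
  if (length(free_dims) != 2 || !all(free_dims %in% space$name)) {
    abort("free_dims must name exactly two search dimensions")
  }
  if (any(free_dims %in% names(fixed))) {
    abort("free_dims and fixed dimensions overlap")
  }
  clamped <- setdiff(space$name, free_dims)
  if (!all(clamped %in% names(fixed))) {
    abort(paste0("missing fixed value(s) for: ",
                 paste(setdiff(clamped, names(fixed)), collapse = ", ")))
  }
  i1 <- match(free_dims[1], space$name); i2 <- match(free_dims[2], space$name)
  g1 <- seq(space$lower[i1], space$upper[i1], length.out = grid[1])
  g2 <- seq(space$lower[i2], space$upper[i2], length.out = grid[2])
  pts <- matrix(NA_real_, grid[1] * grid[2], space_dim(space))
  colnames(pts) <- space$name
  gg <- expand.grid(v1 = g1, v2 = g2)
  pts[, i1] <- gg$v1
  pts[, i2] <- gg$v2
  for (nm in clamped) pts[, nm] <- fixed[[nm]]
  e <- if (!is.null(surf$model)) {
    posterior(surf$model, pts)$mean
  } else {
    apply(pts, 1, function(p) as.numeric(surf$fn(p)))
  }
  values <- tibble(!!free_dims[1] := gg$v1, !!free_dims[2] := gg$v2,
                   energy = as.numeric(e))
  structure(list(values = values, free_dims = free_dims,
                 fixed = fixed, grid = grid),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> %s x %s (%d x %d), energy range [%.3f, %.3f] eV\n",
              x$free_dims[1], x$free_dims[2], x$grid[1], x$grid[2],
              min(x$values$energy), max(x$values$energy)))
  invisible(x)
}

#' Minimum-energy-path barrier by the nudged elastic band
#'
#' Relaxes a chain of images between two minima on the energy restricted to
#' the chosen free dimensions (remaining coordinates clamped at the first
#' minimum), using spring coupling along the path tangent, the standard
#' perpendicular projection of the true force, and a climbing image that
#' converges the highest image onto the saddle point. Periodic dimensions
#' are interpolated along the shortest wrapped displacement. The barrier is
#' the maximum image energy minus the energy of the first minimum, an upper
#' bound to the true barrier.
#'
#' @param object A [fit_gp()] model, [energy_backend()] or function (then
#'   supply `space`).
#' @param min_a,min_b The two minima (named vectors or one-row tibbles).
#' @param n_images Number of images including endpoints.
#' @param free_dims Dimensions the path moves in (default: all).
#' @param space Needed for a bare function.
#' @param spring Spring constant (eV per squared coordinate unit).
#' @param maxit Maximum relaxation steps.
#' @param force_tol Convergence threshold on the maximum band force.
#' @return Object of class `barrier_path`: `images` tibble (path
#'   coordinates and energies), `barrier` (eV), `converged`.
#' @export
neb_barrier <- function(object, min_a, min_b, n_images = 21,
                        free_dims = NULL, space = NULL, spring = 1,
                        maxit = 600, force_tol = 1e-4) {
  surf <- energy_surface(object, space)
  space <- surf$space
  free_dims <- free_dims %||% space$name
  fi <- match(free_dims, space$name)
  if (anyNA(fi)) abort("unknown free dimension")
  pa <- as.numeric(space_points(space, min_a))
  pb <- as.numeric(space_points(space, min_b))
  if (all(abs(space_delta(space, pa, pb)) < 1e-12)) {
    abort("neb_barrier needs two distinct minima")
  }

  full <- function(q) {
    p <- pa
    p[fi] <- q
    as.numeric(surf$fn(p))
  }
  # endpoints and shortest-image straight path in the free coordinates
  qa <- pa[fi]
  qb <- qa + space_delta(space, pb, pa)[fi]
  tgrid <- seq(0, 1, length.out = n_images)
  Q <- vapply(tgrid, function(s) qa + s * (qb - qa), numeric(length(fi)))
  Q <- if (length(fi) == 1) matrix(Q, ncol = 1) else t(Q)

  grad_f <- function(q) pracma::grad(full, q)
  E <- apply(Q, 1, full)
  V <- matrix(0, n_images, length(fi))     # FIRE velocities
  dt <- 0.05; dt_max <- 0.3; n_up <- 0L
  a_fire <- 0.1
  converged <- FALSE

  for (it in seq_len(maxit)) {
    G <- t(apply(Q, 1, grad_f))
    if (length(fi) == 1) G <- matrix(G, n_images, 1)
    Fb <- matrix(0, n_images, length(fi))
    climb <- which.max(E[-c(1, n_images)]) + 1L
    for (i in 2:(n_images - 1)) {
      dp <- Q[i + 1, ] - Q[i, ]
      dm <- Q[i, ] - Q[i - 1, ]
      tau <- dp / max(sqrt(sum(dp^2)), 1e-12) +
        dm / max(sqrt(sum(dm^2)), 1e-12)
      tau <- tau / max(sqrt(sum(tau^2)), 1e-12)
      g <- G[i, ]
      if (i == climb) {
        Fb[i, ] <- -g + 2 * sum(g * tau) * tau
      } else {
        f_spring <- spring * (sqrt(sum(dp^2)) - sqrt(sum(dm^2)))
        Fb[i, ] <- -(g - sum(g * tau) * tau) + f_spring * tau
      }
    }
    fmax <- max(abs(Fb))
    if (fmax < force_tol) { converged <- TRUE; break }
    # FIRE update
    P <- sum(V * Fb)
    if (P > 0) {
      n_up <- n_up + 1L
      if (n_up > 5L) { dt <- min(dt * 1.1, dt_max); a_fire <- a_fire * 0.99 }
      vn <- sqrt(sum(V^2)); fn <- sqrt(sum(Fb^2))
      if (fn > 0) V <- (1 - a_fire) * V + a_fire * vn * Fb / fn
    } else {
      V[] <- 0; dt <- dt * 0.5; a_fire <- 0.1; n_up <- 0L
    }
    V <- V + dt * Fb
    step <- dt * V
    smax <- max(abs(step))
    if (smax > 0.05 * max(space$upper[fi] - space$lower[fi])) {
      step <- step * (0.05 * max(space$upper[fi] - space$lower[fi]) / smax)
    }
    Q[2:(n_images - 1), ] <- Q[2:(n_images - 1), ] +
      step[2:(n_images - 1), , drop = FALSE]
    E <- apply(Q, 1, full)
  }
  if (!converged) {
    warn("neb_barrier: path relaxation did not fully converge; returning best path")
  }
  imgs <- matrix(rep(pa, each = n_images), n_images)
  imgs[, fi] <- Q
  imgs <- wrap_point(space, imgs)
  images <- points_tibble(space, imgs)
  images$energy <- E
  images$image <- seq_len(n_images)
  structure(
    list(images = images, barrier = max(E) - E[1],
         free_dims = free_dims, converged = converged),
    class = "barrier_path"
  )
}

#' @export
print.barrier_path <- function(x, ...) {
  cat(sprintf("<barrier_path> %d images in (%s), barrier %.4f eV%s\n",
              nrow(x$images), paste(x$free_dims, collapse = ", "),
              x$barrier, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' In-place rotational energy profile and barrier
#'
#' Rotates the adsorbate in place about one angular coordinate with all
#' other pose coordinates clamped at a minimum, modelling the
#' one-dimensional energy profile with a short active-learning search
#' (budget of backend evaluations, default 15). The rotation barrier
#' `V` is the peak-to-valley range of the fitted one-dimensional surrogate
#' mean.
#'
#' @param backend An [energy_backend()].
#' @param minimum Pose (named vector or one-row tibble) to rotate about.
#' @param angle_dim Name of the angular dimension (default `"gamma"`).
#' @param budget Total backend evaluations allowed.
#' @param init_n How many of those evaluations seed the model.
#' @param seed Seed.
#' @return Object of class `rotation_profile`: `profile` tibble (angle,
#'   energy on a dense grid of the surrogate mean), `barrier` (eV),
#'   `n_evaluations`, `model`.
#' @export
rotation_profile <- function(backend, minimum, angle_dim = "gamma",
                             budget = 15, init_n = 5, seed = 0) {
  space <- backend$space
  ai <- match(angle_dim, space$name)
  if (is.na(ai)) abort("unknown angle dimension")
  if (!space$periodic[ai]) abort("rotation_profile needs a periodic angle")
  p0 <- as.numeric(space_points(space, minimum))
  sp1 <- search_space(angle_dim, space$lower[ai], space$upper[ai],
                      periodic = TRUE)
  b1 <- energy_backend(function(q) {
    p <- p0
    p[ai] <- q[[1]]
    as.numeric(backend$fn(p))
  }, sp1, name = paste0("rotation_", angle_dim))

  st <- search_settings(sp1, budget = budget - init_n, init_n = init_n,
                        seed = seed, track_minima = FALSE)
  run <- run_search(b1, st)
  grid <- seq(sp1$lower, sp1$upper, length.out = 361)
  mu <- posterior(run$model, matrix(grid, ncol = 1))$mean
  structure(
    list(profile = tibble(!!angle_dim := grid, energy = mu),
         barrier = max(mu) - min(mu),
         n_evaluations = nrow(run$dataset %>%
                                dplyr::filter(.data$provenance != "symmetry-image")),
         model = run$model, dataset = run$dataset),
    class = "rotation_profile"
  )
}

#' @export
print.rotation_profile <- function(x, ...) {
  cat(sprintf("<rotation_profile> barrier %.4f eV from %d evaluations\n",
              x$barrier, x$n_evaluations))
  invisible(x)
}

#' Classify minima by the bonding species closest to the surface
#'
#' Assembles the molecule-on-slab configuration at each mined pose and
#' labels the minimum by the element of the molecule atom nearest the
#' surface (via [lowest_atom()]). Within each class, minima are numbered by
#' predicted energy, most strongly bound first (ties broken by location,
#' lexicographically), giving labels like `"O1"`, `"O2"`, `"H1"`.
#'
#' @param records Minima tibble (pose columns plus `E_B`).
#' @param molecule A [rigid_molecule()].
#' @param slab A [build_slab()] model.
#' @param space Pose space of the records.
#' @return `records` with `class` and `label` columns, sorted class-first
#'   (classes ordered by their most strongly bound member), then by energy.
#' @export
classify_minima <- function(records, molecule, slab, space = pose_space()) {
  if (nrow(records) == 0) {
    records$class <- character(0); records$label <- character(0)
    return(records)
  }
  cls <- vapply(seq_len(nrow(records)), function(i) {
    config <- place_molecule(molecule, records[i, space$name], slab)
    lowest_atom(config)$element
  }, character(1))
  records$class <- cls
  ord_cols <- c(list(records$E_B), as.list(records[space$name]))
  ord <- do.call(order, ord_cols)
  records <- records[ord, ]
  records <- dplyr::group_by(records, .data$class)
  records <- dplyr::mutate(records, label = paste0(.data$class,
                                                   dplyr::row_number()))
  records <- dplyr::ungroup(records)
  class_rank <- records %>%
    dplyr::group_by(.data$class) %>%
    dplyr::summarise(best = min(.data$E_B), .groups = "drop") %>%
    dplyr::arrange(.data$best)
  records$class <- factor(records$class, levels = class_rank$class)
  records <- dplyr::arrange(records, .data$class, .data$E_B)
  records$class <- as.character(records$class)
  records
}
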