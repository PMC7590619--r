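test_that("a convex bowl yields exactly one minimum at its centre", {
  sp <- search_space(c("a", "b"), c(-1, -1), c(1, 1))
  f <- function(p) (p[1] - 0.2)^2 + 2 * (p[2] + 0.3)^2
  mins <- find_minima(f, space = sp, n_starts = 32, seed = 1)
  expect_equal(nrow(mins), 1)
  expect_lt(abs(mins$a - 0.2), 1e-4)
  expect_lt(abs(mins$b + 0.3), 1e-4)
  expect_true(is.na(mins$sigma_B))
})

test_that("a 120-degree cosine on the full circle has three equivalent minima", {
  sp <- search_space("g", -180, 180, periodic = TRUE)
  f <- function(p) 0.05 * (1 - cos(3 * p[1] * pi / 180))
  mins <- find_minima(f, space = sp, n_starts = 64, seed = 2)
  expect_equal(nrow(mins), 3)
  expect_equal(sort(round(mins$g)), c(-120, 0, 120))
  expect_lt(diff(range(mins$E_B)), 1e-9)
})

test_that("all six planted wells are mined to dense-grid-oracle accuracy", {
  b <- six_well_backend()
  mins <- find_minima(b, n_starts = 512, seed = 1)
  expect_equal(nrow(mins), 6)

  # brute-force oracle: dense periodic grid scan locates every basin, then
  # an independent simplex (Nelder-Mead) refinement polishes each one
  ng <- 120
  g <- seq(-0.5, 0.5 - 1 / ng, length.out = ng)
  E <- outer(seq_len(ng), seq_len(ng), Vectorize(function(i, j) {
    b$fn(c(g[i], g[j]))
  }))
  is_loc_min <- function(i, j) {
    e <- E[i, j]
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      if (E[(i + di - 1) %% ng + 1, (j + dj - 1) %% ng + 1] < e) return(FALSE)
    }
    TRUE
  }
  cand <- which(outer(seq_len(ng), seq_len(ng), Vectorize(is_loc_min)),
                arr.ind = TRUE)
  oracle <- t(apply(cand, 1, function(ij) {
    fit <- optim(c(g[ij[1]], g[ij[2]]), b$fn, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 2000))
    c(fit$par, fit$value)
  }))
  oracle <- oracle[order(oracle[, 3]), , drop = FALSE]
  expect_equal(nrow(oracle), 6)

  expect_equal(mins$E_B, oracle[, 3], tolerance = 1e-6)
  for (i in 1:6) {
    expect_lt(max(abs(surfsearch:::space_delta(b$space,
                                               as.numeric(mins[i, c("x", "y")]),
                                               oracle[i, 1:2]))), 1e-4)
  }

  # certified manifest agrees with the oracle too
  truth <- six_well_minima(b)
  expect_equal(truth$energy, oracle[, 3], tolerance = 1e-8)
  expect_true(all(truth$drift < 1e-2))
})

test_that("the mined set is stable when the multistart count doubles", {
  b <- six_well_backend()
  m1 <- find_minima(b, n_starts = 256, seed = 3)
  m2 <- find_minima(b, n_starts = 512, seed = 3)
  expect_equal(nrow(m1), nrow(m2))
  expect_equal(m1$E_B, m2$E_B, tolerance = 1e-8)
})

test_that("every mined minimum carries a stationarity certificate", {
  b <- six_well_backend()
  mins <- find_minima(b, n_starts = 256, seed = 4)
  expect_true(all(mins$grad_norm < 1e-4))
})

test_that("backend verification fills E_D, the deltas and the descent", {
  # surrogate trained densely on a smooth backend reproduces its energies
  sp <- search_space("q", 0, 1)
  f <- function(p) -0.8 * exp(-((p[1] - 0.4) / 0.25)^2)
  b <- energy_backend(f, sp, "gauss_well")
  set.seed(6)
  d <- tibble::tibble(q = seq(0, 1, length.out = 25))
  d$energy <- vapply(d$q, function(q) f(q), numeric(1))
  m <- fit_gp(d, sp, noise = 1e-10)
  mins <- find_minima(m, n_starts = 64, seed = 1)
  expect_equal(nrow(mins), 1)
  ver <- verify_minimum(mins, b)
  expect_lt(abs(ver$delta_E_D), 1e-3)
  expect_identical(ver$delta_E_D, ver$E_D - ver$E_B)
  expect_lte(ver$E_rel, ver$E_D + 1e-9)
  expect_identical(ver$delta_E_rel, ver$E_rel - ver$E_D)
})

test_that("cross-sections evaluate the posterior pointwise on the grid", {
  b <- toy_adsorption_backend()
  fixed <- c(z = 4.5, alpha = 0, beta = 0, gamma = 0)
  cs <- cross_section(b, fixed, c("x", "y"), grid = c(25, 25))
  expect_equal(nrow(cs$values), 625)
  expect_equal(cs$grid, c(25, 25))
  i <- c(1, 313, 625)
  direct <- vapply(i, function(k) {
    toy_adsorption_pes(c(x = cs$values$x[k], y = cs$values$y[k], fixed))
  }, numeric(1))
  expect_equal(cs$values$energy[i], direct, tolerance = 1e-12)

  # a section through the deep family bottoms out within one grid cell of
  # one of the (degenerate) hollow-site minima
  man <- toy_adsorption_minima()
  man <- man[man$beta == 0 & man$gamma == 0, ]
  cs2 <- cross_section(b, c(z = man$z[1], alpha = 0, beta = 0, gamma = 0),
                       c("x", "y"), grid = c(100, 100))
  expect_equal(dim(cs2$values), c(10000L, 3L))
  k <- which.min(cs2$values$energy)
  dists <- vapply(seq_len(nrow(man)), function(i) {
    max(abs(surfsearch:::space_delta(b$space,
                                     c(cs2$values$x[k], cs2$values$y[k],
                                       man$z[1], 0, 0, 0),
                                     as.numeric(man[i, b$space$name]))))
  }, numeric(1))
  expect_lt(min(dists), 1.5 / 100)

  expect_error(cross_section(b, c(x = 0, z = 4.5, alpha = 0, beta = 0,
                                  gamma = 0), c("x", "y")), "overlap")
  expect_error(cross_section(b, c(alpha = 0), c("x", "y")), "missing fixed")
})

test_that("the double-well barrier is recovered to 1e-3 by the elastic band", {
  b <- double_well_backend()
  bp <- neb_barrier(b, c(q = -1), c(q = 1), n_images = 21)
  expect_true(bp$converged)
  expect_equal(bp$barrier, 1, tolerance = 1e-3)
  # endpoints are the two minima
  expect_equal(bp$images$q[c(1, 21)], c(-1, 1))
  # symmetric wells: direction does not matter
  bp2 <- neb_barrier(b, c(q = 1), c(q = -1), n_images = 21)
  expect_equal(bp2$barrier, bp$barrier, tolerance = 1e-6)
})

test_that("elastic-band barriers respect their lower bounds", {
  sp <- search_space("q", -1.5, 1.5)
  flat <- energy_backend(function(p) 0.25, sp, "flat")
  bpf <- suppressWarnings(neb_barrier(flat, c(q = -1), c(q = 1)))
  expect_lt(abs(bpf$barrier), 1e-9)

  tilted <- energy_backend(function(p) 0.3 * p[[1]], sp, "tilted")
  bpt <- suppressWarnings(neb_barrier(tilted, c(q = -1), c(q = 1)))
  expect_gte(bpt$barrier, max(0, 0.3 * 1 - 0.3 * (-1)) - 1e-9)

  expect_error(neb_barrier(flat, c(q = 0.3), c(q = 0.3)), "distinct")
})

test_that("in-place rotation profiles respect the budget and amplitude", {
  b <- threefold_rotor_backend(amplitude = 0.06)
  rp <- rotation_profile(b, c(gamma = 0), budget = 15, seed = 1)
  expect_lte(rp$n_evaluations, 15)
  expect_equal(rp$barrier, 0.12, tolerance = 0.05 * 0.12)
  # maxima of the threefold profile are 120 degrees apart (peaks counted on
  # the circle: the duplicate wrap point at +180 is dropped)
  prof <- rp$profile[-nrow(rp$profile), ]
  e <- prof$energy
  circ_peak <- e > c(tail(e, 1), head(e, -1)) & e > c(e[-1], e[1])
  pk <- sort(prof$gamma[circ_peak])
  expect_equal(length(pk), 3)
  expect_equal(round(diff(pk)), c(120, 120))

  # a backend constant in the angle gives a null barrier
  sp <- search_space(c("z", "gamma"), c(4, -180), c(7, 180),
                     periodic = c(FALSE, TRUE))
  bc <- energy_backend(function(p) -exp(-(p[[1]] - 5)^2), sp, "gamma_flat")
  rpc <- suppressWarnings(   # a flat profile has no certified minima
    rotation_profile(bc, c(z = 5, gamma = 0), budget = 15, seed = 1)
  )
  expect_lt(rpc$barrier, 1e-3)
})

test_that("minima are classified by the species facing the surface", {
  fx <- camphor_fixture()
  out <- classify_minima(fx$records, fx$molecule, fx$slab)
  expect_equal(sum(out$class == "O"), 5)
  expect_equal(sum(out$class == "H"), 3)
  # the O-down family binds more strongly than the H-down family
  expect_lt(max(out$E_B[out$class == "O"]), min(out$E_B[out$class == "H"]))
  # numbering is by energy, most strongly bound first
  o <- out[out$class == "O", ]
  expect_equal(o$label, paste0("O", 1:5))
  expect_true(!is.unsorted(o$E_B))
  # deterministic under record permutation
  out2 <- classify_minima(fx$records[sample(1:8), ], fx$molecule, fx$slab)
  expect_equal(out2$label, out$label)
  expect_equal(out2$E_B, out$E_B)
})
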