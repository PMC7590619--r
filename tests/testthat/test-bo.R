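fit_toy_model <- function() {
  sp <- search_space("q", 0, 1)
  d <- tibble::tibble(q = c(0.1, 0.4, 0.8), energy = c(-0.2, -1, -0.4))
  list(model = fit_gp(d, sp), space = sp)
}

test_that("eLCB reduces to the posterior mean without exploration", {
  tm <- fit_toy_model()
  q <- matrix(seq(0, 1, 0.1), ncol = 1)
  expect_equal(elcb(tm$model, q, t = 1, eta_const = 0),
               posterior(tm$model, q)$mean)
  # mean 1, sd 0.5, eta 2 -> 0: direct arithmetic through the definition
  expect_equal(1 - 2 * 0.5, 0)
  a <- elcb(tm$model, q, t = 3, eta_const = 2)
  post <- posterior(tm$model, q)
  expect_equal(a, post$mean - 2 * sqrt(post$variance))
})

test_that("exploration weight grows slowly with iteration and dimension", {
  e1 <- surfsearch:::elcb_eta(1, 2)
  e10 <- surfsearch:::elcb_eta(10, 2)
  e10d6 <- surfsearch:::elcb_eta(10, 6)
  expect_gt(e10, e1)
  expect_gt(e10d6, e10)
})

test_that("acquisition explores away from a lone observation", {
  sp <- search_space("q", 0, 10)
  d <- tibble::tibble(q = c(5, 5.01), energy = c(-1, -1))
  m <- fit_gp(d, sp, lengthscale_bounds = cbind(0.5, 1))
  st <- search_settings(sp, seed = 1)
  pt <- next_acquisition(m, st, t = 1)
  expect_gt(abs(pt[["q"]] - 5), m$kernel$lengthscales)
})

test_that("the chosen point beats a thousand quasi-random probes", {
  tm <- fit_toy_model()
  st <- search_settings(tm$space, seed = 2)
  pt <- next_acquisition(tm$model, st, t = 4)
  a_best <- attr(pt, "acquisition")
  probes <- surfsearch:::space_design(tm$space, 1000, seed = 99)
  a_probe <- min(elcb(tm$model, probes, t = 4))
  expect_lte(a_best, a_probe + 1e-9)
})

test_that("quasi-random initialization is reproducible under the seed", {
  sp <- search_space(c("a", "b"), c(0, 0), c(1, 1))
  b <- energy_backend(function(p) p[[1]] + p[[2]], sp, "plane")
  st <- search_settings(sp, init_n = 5, seed = 7)
  d1 <- bo_initialize(st, b)
  d2 <- bo_initialize(st, b)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 5)
})

test_that("low-dimensional warm records are embedded with fill values", {
  sp <- pose_space()
  warm <- tibble::tibble(z = c(4.5, 5, 6), energy = c(-0.8, -0.5, -0.2))
  st <- search_settings(sp, init_n = 0, warm = warm,
                        fill = c(x = 0, y = 0, alpha = 0, beta = 0,
                                 gamma = 0))
  d <- bo_initialize(st)
  expect_equal(nrow(d), 3)
  expect_equal(d$x, rep(0, 3))
  expect_equal(d$z, c(4.5, 5, 6))

  # duplicates collapse; missing fill errors
  st2 <- search_settings(sp, init_n = 0, warm = warm[c(1, 1, 2), ],
                         fill = c(x = 0, y = 0, alpha = 0, beta = 0,
                                  gamma = 0))
  expect_equal(nrow(bo_initialize(st2)), 2)
  st3 <- search_settings(sp, init_n = 0, warm = warm)
  expect_error(bo_initialize(st3), "fill")
})

test_that("zero budget with warm starts fits without backend calls", {
  sp <- search_space("q", 0, 1)
  calls <- new.env(); calls$n <- 0L
  b <- energy_backend(function(p) { calls$n <- calls$n + 1L; p[[1]]^2 },
                      sp, "counting")
  warm <- tibble::tibble(q = seq(0.1, 0.9, 0.2), energy = seq(0.1, 0.9, 0.2)^2)
  st <- search_settings(sp, budget = 0, init_n = 0, warm = warm, seed = 1)
  # the warm data has its minimum on the boundary, so final mining warns
  run <- suppressWarnings(run_search(b, st))
  expect_equal(calls$n, 0L)
  expect_equal(nrow(run$history), 0L)
  expect_s3_class(run$model, "surf_gp")
})

test_that("searches are reproducible bit for bit under a fixed seed", {
  b <- morse_backend()
  st <- search_settings(b$space, budget = 4, init_n = 2, seed = 5,
                        track_minima = FALSE)
  r1 <- run_search(b, st)
  r2 <- run_search(b, st)
  expect_identical(r1$dataset, r2$dataset)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$minima, r2$minima)
})

test_that("the acquisition never prefers a known-worse point", {
  b <- morse_backend()
  st <- search_settings(b$space, budget = 6, init_n = 2, seed = 3,
                        track_minima = FALSE)
  run <- run_search(b, st)
  expect_true(all(run$history$acquisition <=
                    run$history$acquisition_incumbent + 1e-9))
})

test_that("the height-curve minimum is located within 0.1 A in ten evaluations", {
  b <- morse_backend()
  for (s in 1:5) {
    st <- search_settings(b$space, budget = 8, init_n = 2, seed = s,
                          track_minima = FALSE)
    run <- run_search(b, st)
    expect_lte(nrow(run$history) + st$init_n, 10)
    best <- run$minima[which.min(run$minima$E_B), ]
    expect_lt(abs(best$z - b$truth$z0), 0.1)
  }
})

test_that("both symmetric wells are recovered on the two-well landscape", {
  b <- two_well_backend()
  ops <- list(function(p) twofold_translation(p, b$space))
  st <- search_settings(b$space, budget = 24, init_n = 6, seed = 1,
                        sym_ops = ops, window = 5)
  run <- run_search(b, st)
  expect_lte(nrow(run$history) + st$init_n, 30)
  # the final surrogate's global minimum is accurate to 0.02 eV
  expect_lt(abs(min(run$minima$E_B) - b$truth$energy), 0.02)
  # both planted minima appear in the final minima list
  sp <- b$space
  for (i in 1:2) {
    truth <- b$truth$minima[i, ]
    dd <- apply(as.matrix(run$minima[, c("x", "y")]), 1, function(p) {
      max(abs(surfsearch:::space_delta(sp, p, truth)))
    })
    expect_lt(min(dd), 0.05)
  }
})

test_that("convergence requires stable minima locations, energies and count", {
  sp <- search_space(c("x", "y"), c(-0.5, -0.5), c(0.5, 0.5), periodic = TRUE)
  st <- search_settings(sp, window = 3, location_tol = c(x = 0.02, y = 0.02),
                        energy_tol = 0.02)
  snap <- tibble::tibble(x = c(0.1, -0.3), y = c(0.2, 0.4),
                         E_B = c(-1, -0.5))
  same <- replicate(4, snap, simplify = FALSE)
  rep1 <- convergence_check(same, st)
  expect_true(rep1$converged)
  expect_equal(max(rep1$drifts$drift_x), 0)

  drifted <- same
  drifted[[1]]$x[1] <- 0.1 + 0.04   # 2x the location tolerance
  rep2 <- convergence_check(drifted, st)
  expect_false(rep2$converged)
  expect_gte(max(rep2$drifts$drift_x), 0.04)

  appeared <- same
  appeared[[4]] <- dplyr::bind_rows(snap, tibble::tibble(x = 0, y = 0,
                                                         E_B = -0.2))
  rep3 <- convergence_check(appeared, st)
  expect_false(rep3$converged)
  expect_false(rep3$count_stable)

  expect_error(convergence_check(same[1:2], st), "window")
})
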