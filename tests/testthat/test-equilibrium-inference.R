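# Fixed-point solver: plain and Anderson modes, stopping rule, spectral
# radius diagnostics.

affine_refiner <- function(A, b) {
  as_refiner(function(m) {
    matrix(A %*% as.numeric(m) + b, nrow(m), ncol(m))
  }, "affine")
}

test_that("identity map converges immediately to the input", {
  ident <- as_refiner(function(m) m)
  set.seed(101)
  s <- rand_structure(5)
  res <- fixed_point_refine(ident, s, solver_config())
  expect_true(res$converged)
  expect_equal(res$n_iter, 1L)
  expect_equal(res$refined$coords, s$coords)
  expect_length(res$residual_rmsd_trace, res$n_iter)
})

test_that("plain and Anderson reach the analytic fixed point of contractions", {
  set.seed(103)
  n <- 4
  dim <- 3 * n
  x0 <- matrix(rnorm(dim, sd = 3), n, 3)
  # phi(x) = 0.5 x + c has fixed point 2c
  cc <- rnorm(dim)
  phi <- affine_refiner(diag(0.5, dim), cc)
  xstar <- matrix(2 * cc, n, 3)

  for (mode in c("plain", "anderson")) {
    cfg <- solver_config(mode = mode, tol = 1e-6)
    res <- fixed_point_refine(phi, x0, cfg)
    expect_true(res$converged)
    expect_lt(sqrt(sum((res$refined - xstar)^2) / n), 1e-5)
    expect_true(all(diff(c(10, res$residual_rmsd_trace)) < 0) ||
                  mode == "anderson")
  }
  # Anderson takes no more iterations than plain on every tested map
  for (rep in 1:5) {
    A <- matrix(rnorm(dim^2, sd = 0.1), dim, dim)
    A <- A / max(Mod(eigen(A, only.values = TRUE)$values)) * runif(1, 0.3, 0.8)
    b <- rnorm(dim)
    phi <- affine_refiner(A, b)
    np <- fixed_point_refine(phi, x0, solver_config(mode = "plain",
                                                    tol = 1e-8))$n_iter
    na <- fixed_point_refine(phi, x0, solver_config(mode = "anderson",
                                                    tol = 1e-8))$n_iter
    expect_lte(na, np)
    xs <- matrix(solve(diag(dim) - A, b), n, 3)
    ra <- fixed_point_refine(phi, x0, solver_config(mode = "anderson",
                                                    tol = 1e-8))$refined
    expect_lt(sqrt(sum((ra - xs)^2) / n), 1e-6)
  }
})

test_that("anderson step reduces to the plain update and honors beta", {
  set.seed(107)
  x <- rnorm(12)
  g <- rnorm(12)
  # history 1, beta 1: identical to phi(x) = x + g
  nxt <- anderson_step(list(x), list(g), beta = 1)
  expect_equal(as.numeric(nxt), x + g, tolerance = 1e-15)
  expect_equal(attr(nxt, "alpha"), 1)
  # beta 0, history 1: stationary
  nxt0 <- anderson_step(list(x), list(g), beta = 0)
  expect_equal(as.numeric(nxt0), x, tolerance = 1e-15)
})

test_that("anderson coefficients match a constrained least-squares oracle", {
  set.seed(109)
  for (rep in 1:10) {
    h <- sample(2:5, 1)
    dim <- 30
    G <- matrix(rnorm(dim * h), dim, h)
    X <- matrix(rnorm(dim * h), dim, h)
    nxt <- anderson_step(asplit(X, 2), asplit(G, 2), beta = 1, reg = 0)
    alpha <- attr(nxt, "alpha")
    # independent oracle: KKT system of min |G a|^2 s.t. sum(a) = 1
    KKT <- rbind(cbind(2 * crossprod(G), rep(1, h)), c(rep(1, h), 0))
    sol <- solve(KKT, c(rep(0, h), 1))
    expect_equal(alpha, sol[seq_len(h)], tolerance = 1e-6)
    expect_equal(sum(alpha), 1, tolerance = 1e-10)
  }
})

test_that("plain and Anderson agree on nonlinear contractive maps", {
  set.seed(113)
  # smooth contraction: x -> 0.6 tanh(x) + c (componentwise, Lipschitz 0.6)
  cc <- matrix(rnorm(9, sd = 0.5), 3, 3)
  phi <- as_refiner(function(m) 0.6 * tanh(m) + cc)
  x0 <- matrix(rnorm(9, sd = 2), 3, 3)
  tol <- 1e-5
  rp <- fixed_point_refine(phi, x0, solver_config(mode = "plain", tol = tol,
                                                  max_iter = 500))
  ra <- fixed_point_refine(phi, x0, solver_config(mode = "anderson",
                                                  tol = tol))
  expect_true(rp$converged && ra$converged)
  expect_lt(sqrt(sum((rp$refined - ra$refined)^2) / 3), 10 * tol)
  # residual bound at the returned point: |phi(x*) - x*|/sqrt(N) <= tol(1+L)
  r <- predict(phi, ra$refined) - ra$refined
  expect_lte(sqrt(sum(r^2) / 3), tol * (1 + 0.6) + 1e-12)
})

test_that("non-finite iterates raise a numerical failure carrying the trace", {
  k <- 0
  bad <- as_refiner(function(m) {
    k <<- k + 1
    if (k >= 3) m * NaN else m + 1
  })
  err <- tryCatch(
    fixed_point_refine(bad, matrix(0, 2, 3), solver_config(mode = "plain")),
    aefm_numerical_failure = function(e) e)
  expect_s3_class(err, "aefm_numerical_failure")
  expect_length(err$trace, 2)
})

test_that("the alternative stopping metric divides by N, not sqrt(N)", {
  # constant-step map: per-atom step 0.02 => rmsd stays 0.02 (> tol) but
  # |dx|/N = 0.02 sqrt(9)/9 = 0.0067 (<= tol) for 9 atoms
  step <- matrix(0.02 / sqrt(3), 9, 3)
  walker <- as_refiner(function(m) m + step)
  x0 <- matrix(0, 9, 3)
  res_rmsd <- fixed_point_refine(walker, x0,
                                 solver_config(mode = "plain", max_iter = 20))
  res_norm <- fixed_point_refine(walker, x0,
                                 solver_config(mode = "plain", max_iter = 20,
                                               stop_metric = "norm_over_n"))
  expect_false(res_rmsd$converged)
  expect_true(res_norm$converged)
  expect_equal(res_norm$n_iter, 1L)
})

test_that("spectral radius matches known spectra and dense eigensolves", {
  # known diagonal spectrum
  A <- diag(c(0.9, 0.5, 0.1))
  lin <- as_refiner(function(m) matrix(A %*% as.numeric(m), 1, 3))
  rho <- spectral_radius(lin, matrix(rnorm(3), 1, 3))
  expect_equal(as.numeric(rho), 0.9, tolerance = 1e-3)

  # identity map: 1 up to finite-difference roundoff in the JVP
  ident <- as_refiner(function(m) m)
  expect_equal(as.numeric(spectral_radius(ident, matrix(rnorm(12), 4, 3))),
               1.0, tolerance = 1e-9)

  # dense eigendecomposition oracle on random linear maps up to dim 36
  set.seed(127)
  for (n in c(2, 6, 12)) {
    dim <- 3 * n
    M <- matrix(rnorm(dim^2, sd = 1 / sqrt(dim)), dim, dim)
    lin <- as_refiner(function(m) matrix(M %*% as.numeric(m), n, 3))
    truth <- max(Mod(eigen(M, only.values = TRUE)$values))
    est <- spectral_radius(lin, matrix(rnorm(dim), n, 3),
                           n_power_iters = dim, rtol = 1e-6)
    expect_equal(as.numeric(est), truth, tolerance = 1e-3)
  }
})

test_that("refine_batch isolates failures and summarizes convergence", {
  ident <- as_refiner(function(m) m)
  set.seed(131)
  batch <- lapply(1:5, function(i) rand_structure(4))
  rb <- refine_batch(ident, batch, solver_config())
  expect_equal(rb$summary$convergence_rate, 1)
  expect_true(all(rb$summary$iterations == 1L))

  # solver defaults follow the method: tol 0.01, cap 100, beta 1, m 5
  cfg <- solver_config()
  expect_equal(cfg$tol, 0.01)
  expect_equal(cfg$max_iter, 100L)
  expect_equal(cfg$beta, 1.0)
  expect_equal(cfg$history_m, 5L)
  expect_equal(cfg$mode, "anderson")
})

test_that("refining a rigidly moved input moves the refined output rigidly", {
  tmpl <- generate_templates(template_spec(15, atoms_min = 4, atoms_max = 6,
                                           seed = 44))
  fit <- train_refiner(tmpl, train_config(sigma = 0.15, epochs = 15,
                                          batch_size = 4, seed = 9),
                       reference_net_config(layers = 2, hidden = 16,
                                            n_basis = 8, seed = 9))
  set.seed(137)
  s <- corrupt(tmpl[[1]], 0.15)
  cfg <- solver_config(max_iter = 30)
  base <- fixed_point_refine(fit$model, s, cfg)
  R <- rand_rotation()
  t <- rnorm(3, sd = 2)
  moved <- set_coords(s, sweep(s$coords %*% t(R), 2, t, "+"))
  res <- fixed_point_refine(fit$model, moved, cfg)
  expect_equal(res$refined$coords,
               sweep(base$refined$coords %*% t(R), 2, t, "+"),
               tolerance = 1e-4)
})
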