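test_that("a zero-residual start converges immediately", {
  t <- seq(0, 5, 0.1)
  y <- exp(-0.5 * t)
  res <- levmar(function(p) exp(-p * t) - y,
                function(p) matrix(-t * exp(-p * t), ncol = 1),
                init = 0.5)
  expect_equal(res$ssr, 0)
  expect_true(res$converged)
  expect_lte(res$n_iter, 2L)
})

test_that("LM recovers an exponential rate to high precision", {
  t <- seq(0, 5, 0.1)
  y <- exp(-0.5 * t)
  res <- levmar(function(p) exp(-p * t) - y,
                function(p) matrix(-t * exp(-p * t), ncol = 1),
                init = 0.1)
  expect_lt(abs(res$params - 0.5), 1e-8)
  expect_true(res$converged)
  # independent oracle: coarse grid search refined by bisection on the
  # derivative of the cost
  ssr <- function(k) sum((exp(-k * t) - y)^2)
  grid <- seq(0.01, 2, by = 1e-4)
  k0 <- grid[which.min(vapply(grid, ssr, numeric(1)))]
  dssr <- function(k) sum(2 * (exp(-k * t) - y) * (-t * exp(-k * t)))
  lo <- k0 - 2e-4; hi <- k0 + 2e-4
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (dssr(mid) > 0) hi <- mid else lo <- mid
  }
  expect_lt(abs(res$params - (lo + hi) / 2), 1e-6)
})

test_that("an iteration-starved fit reports non-convergence honestly", {
  t <- seq(0, 5, 0.1)
  y <- exp(-0.5 * t)
  res <- levmar(function(p) exp(-p * t) - y,
                function(p) matrix(-t * exp(-p * t), ncol = 1),
                init = 5, opts = fit_options(max_iter = 1L))
  expect_false(res$converged)
  expect_true(all(is.finite(res$params)))
})

test_that("accepted LM steps never increase the cost", {
  # monotonicity: final ssr never exceeds the initial cost, across inits
  tm <- oracle_grid(5, 0.02)
  cp <- oracle_aif(tm)
  std <- model_spec("standard_tofts")
  y <- model_ct(c(ktrans = 0.2, kep = 1.2), std, tm, cp)
  for (init in list(c(0.01, 0.1), c(1, 5), c(0.5, 0.01))) {
    ssr0 <- sum((model_ct(setNames(init, std$param_names), std, tm, cp)
                 - y)^2)
    res <- levmar(
      function(p) model_ct(setNames(p, std$param_names), std, tm, cp) - y,
      function(p) model_jacobian(setNames(p, std$param_names), std,
                                 tm, cp)$jac,
      init = init)
    expect_lte(res$ssr, ssr0)
    expect_lt(abs(res$params[1] - 0.2), 1e-6)
  }
})

test_that("voxelwise results are identical for any worker count", {
  tm <- oracle_grid(4, 0.02)
  cp <- oracle_aif(tm)
  std <- model_spec("standard_tofts")
  set.seed(3)
  truth <- cbind(ktrans = runif(12, 0.05, 0.3), kep = runif(12, 0.2, 2))
  curves <- apply(truth, 1, function(p)
    model_ct(c(ktrans = unname(p[1]), kep = unname(p[2])), std, tm, cp))
  f1 <- fit_voxels_parallel(curves, std, tm, cp, n_workers = 1)
  f3 <- fit_voxels_parallel(curves, std, tm, cp, n_workers = 3)
  expect_identical(f1, f3)
})

test_that("noise-free extended-model curves are recovered voxelwise", {
  tm <- oracle_grid(5, 0.02)
  cp <- oracle_aif(tm)
  ext <- model_spec("extended_tofts")
  set.seed(7)
  truth <- cbind(ktrans = runif(100, 0.02, 0.3),
                 kep = runif(100, 0.1, 2), vp = runif(100, 0.001, 0.1))
  curves <- apply(truth, 1, function(p)
    model_ct(c(ktrans = unname(p[1]), kep = unname(p[2]), vp = unname(p[3])), ext, tm, cp))
  fits <- fit_voxels_parallel(curves, ext, tm, cp)
  expect_true(all(fits$converged))
  expect_lt(max(abs(fits$ktrans - truth[, "ktrans"]) / truth[, "ktrans"]),
            1e-3)
  expect_lt(max(abs(fits$kep - truth[, "kep"]) / truth[, "kep"]), 1e-3)
  expect_equal(fits$ve, fits$ktrans / fits$kep)
})

test_that("standard-model recovery stays under 0.5% RMS over the grid", {
  tm <- oracle_grid(5, 0.02)
  cp <- oracle_aif(tm)
  std <- model_spec("standard_tofts")
  grid <- expand.grid(ktrans = c(0.05, 0.2, 0.35), ve = c(0.05, 0.2, 0.5))
  curves <- apply(grid, 1, function(p)
    model_ct(c(ktrans = unname(p[1]), kep = unname(p[1] / p[2])), std, tm, cp))
  fits <- fit_voxels_parallel(curves, std, tm, cp)
  rel <- (fits$ktrans - grid$ktrans) / grid$ktrans
  expect_lt(100 * sqrt(mean(rel^2)), 0.5)
})

test_that("all-NaN curves are skipped without disturbing neighbours", {
  tm <- oracle_grid(3, 0.02)
  cp <- oracle_aif(tm)
  std <- model_spec("standard_tofts")
  good <- model_ct(c(ktrans = 0.1, kep = 0.5), std, tm, cp)
  curves <- cbind(good, NaN, good)
  fits <- fit_voxels_parallel(curves, std, tm, cp)
  expect_equal(fits$skipped, c(FALSE, TRUE, FALSE))
  expect_equal(fits$ktrans[c(1, 3)], rep(0.1, 2), tolerance = 1e-6)
  expect_equal(fits$ktrans[2], 0)
  empty <- fit_voxels_parallel(matrix(numeric(0), nrow = length(tm)),
                               std, tm, cp)
  expect_equal(nrow(empty), 0L)
})

test_that("the in-package solver agrees with an independent optimizer", {
  tm <- oracle_grid(5, 0.02)
  cp <- oracle_aif(tm)
  std <- model_spec("standard_tofts")
  y <- model_ct(c(ktrans = 0.17, kep = 0.9), std, tm, cp)
  # perturb so the minimum is not exactly at the truth
  set.seed(21)
  y <- y + rnorm(length(y), 0, 1e-4)
  ours <- fit_voxels_parallel(y, std, tm, cp)
  ref <- minpack.lm::nls.lm(
    par = c(0.1, 0.5),
    fn = function(p) model_ct(c(ktrans = unname(p[1]), kep = unname(p[2])), std, tm, cp) - y)
  expect_equal(ours$ktrans, ref$par[1], tolerance = 1e-5)
  expect_equal(ours$kep, ref$par[2], tolerance = 1e-5)
})
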