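test_that("exponential-kernel convolution matches closed forms", {
  tm <- oracle_grid(5, 0.01)
  n <- length(tm)
  expect_equal(conv_exp_trapz(tm, rep(0, n), 0.7), rep(0, n))
  # kep = 0: plain cumulative integral of a unit AIF
  expect_equal(conv_exp_trapz(tm, rep(1, n), 0)[n], 5, tolerance = 1e-12)
  # constant Cp: K(t) = (1 - exp(-kep t)) / kep
  k <- conv_exp_trapz(tm, rep(1, n), 0.2)
  expect_equal(k[n], (1 - exp(-1)) / 0.2, tolerance = 1e-4)
  expect_equal(k[1], 0)
  expect_error(conv_exp_trapz(c(0, 2, 1), rep(1, 3), 1), "increasing")
})

test_that("the interval recursion equals the direct composite trapezoid", {
  set.seed(5)
  for (i in 1:10) {
    tm <- sort(c(0, cumsum(runif(60, 0.005, 0.1))))
    cp <- oracle_aif(tm) + runif(length(tm), 0, 0.2)
    kep <- runif(1, 0, 8)
    expect_equal(conv_exp_trapz(tm, cp, kep),
                 conv_exp_trapz_direct(tm, cp, kep), tolerance = 1e-12)
  }
  # large kep * t where the direct exp(kep s) form would overflow
  tm <- seq(0, 11, by = 1 / 120)
  expect_true(all(is.finite(conv_exp_trapz(tm, oracle_aif(tm), 35))))
})

test_that("trapezoid convolution error decreases at second order", {
  kep <- 0.8
  closed <- function(t) (1 - exp(-kep * t)) / kep
  err <- vapply(c(0.04, 0.02, 0.01), function(dt) {
    tm <- seq(0, 4, by = dt)
    max(abs(conv_exp_trapz(tm, rep(1, length(tm)), kep) - closed(tm)))
  }, numeric(1))
  expect_gt(err[1] / err[2], 3.5)
  expect_gt(err[2] / err[3], 3.5)
})

test_that("model predictions follow the Tofts-Kety forms", {
  tm <- oracle_grid(5, 0.01)
  cp <- rep(1, length(tm))
  n <- length(tm)
  # plasma-only: pure vp scaling of the AIF
  po <- model_ct(c(vp = 0.05), model_spec("plasma_only"), tm, 2 * cp)
  expect_equal(po[3], 0.1)
  # extended with constant Cp against the closed form
  ct <- model_ct(c(ktrans = 0.1, kep = 0.2, vp = 0.05),
                 model_spec("extended_tofts"), tm, cp)
  expect_equal(ct[n], 0.1 * (1 - exp(-1)) / 0.2 + 0.05, tolerance = 1e-4)
  # standard with no transfer is identically zero
  expect_equal(model_ct(c(ktrans = 0, kep = 0.5),
                        model_spec("standard_tofts"), tm, cp),
               rep(0, n))
})

test_that("the model family nests bit-exactly", {
  tm <- oracle_grid(4, 0.02)
  cp <- oracle_aif(tm)
  ext0 <- model_ct(c(ktrans = 0.12, kep = 0.6, vp = 0),
                   model_spec("extended_tofts"), tm, cp)
  std <- model_ct(c(ktrans = 0.12, kep = 0.6),
                  model_spec("standard_tofts"), tm, cp)
  expect_identical(ext0, std)
  std0 <- model_ct(c(ktrans = 0, kep = 0.6),
                   model_spec("standard_tofts"), tm, cp)
  po0 <- model_ct(c(vp = 0), model_spec("plasma_only"), tm, cp)
  expect_identical(std0, po0)
})

test_that("analytic Jacobians match central finite differences", {
  tm <- oracle_grid(5, 0.01)
  cp <- oracle_aif(tm)
  ext <- model_spec("extended_tofts")
  fd_jac <- function(p, param_fn) {
    h <- 1e-6
    vapply(seq_along(p), function(j) {
      hi <- p; lo <- p
      hi[j] <- hi[j] + h; lo[j] <- lo[j] - h
      (param_fn(hi) - param_fn(lo)) / (2 * h)
    }, numeric(length(tm)))
  }
  p0 <- c(ktrans = 0.1, kep = 0.2, vp = 0.05)
  je <- model_jacobian(p0, ext, tm, cp)
  expect_identical(unname(je$jac[, "vp"]), cp)      # dCt/dvp = Cp exactly
  fd <- fd_jac(p0, function(p) model_ct(p, ext, tm, cp))
  scale <- apply(abs(fd), 2, max)
  expect_lt(max(abs(je$jac - fd) / rep(scale, each = length(tm))), 1e-4)

  # (ktrans, ve, vp) parameterization against finite differences
  p1 <- c(ktrans = 0.1, ve = 0.4, vp = 0.05)
  jv <- model_jacobian(p1, ext, tm, cp, parameterization = "ktrans_ve_vp")
  fd1 <- fd_jac(unname(p1[1:2]), function(p)
    model_ct(c(ktrans = p[1], ve = p[2], vp = 0.05), ext, tm, cp))
  scale1 <- apply(abs(fd1), 2, max)
  expect_lt(max(abs(jv$jac[, 1:2] - fd1) /
                  rep(scale1, each = length(tm))), 1e-4)
})

test_that("ve sensitivity vanishes with Ktrans and requires ve > 0", {
  tm <- oracle_grid(3, 0.02)
  cp <- oracle_aif(tm)
  ext <- model_spec("extended_tofts")
  j0 <- model_jacobian(c(ktrans = 0, ve = 0.3, vp = 0.02), ext, tm, cp,
                       parameterization = "ktrans_ve_vp")
  expect_equal(unname(j0$jac[, "ve"]), rep(0, length(tm)))
  expect_error(
    model_jacobian(c(ktrans = 0.1, ve = 0, vp = 0), ext, tm, cp,
                   parameterization = "ktrans_ve_vp"), "ve")
})

test_that("ve derivation guards the no-efflux case", {
  expect_equal(derive_ve(0.1, 0.2), 0.5)
  expect_equal(derive_ve(0.1, 0), 0)
  expect_equal(derive_ve(0, 1), 0)
  expect_equal(derive_ve(c(0.1, 0.3), c(0.2, 0)), c(0.5, 0))
  expect_error(derive_ve(-0.1, 1), "non-negative")
})

test_that("low ve worsens the conditioning of the standard Jacobian", {
  tm <- oracle_grid(5, 0.01)
  cp <- oracle_aif(tm)
  std <- model_spec("standard_tofts")
  kappa_at <- function(ve) {
    j <- model_jacobian(c(ktrans = 0.1, ve = ve), std, tm, cp,
                        parameterization = "ktrans_ve_vp")$jac
    kappa(j, exact = TRUE)
  }
  expect_gt(kappa_at(0.01), kappa_at(0.5))
})

test_that("the model bitmask decodes to distinct power-of-two bits", {
  specs <- models_from_bitmask(7)
  expect_equal(vapply(specs, `[[`, integer(1), "bit"), c(1L, 2L, 4L))
  expect_equal(vapply(specs, `[[`, integer(1), "n_params"), 1:3)
  expect_equal(length(models_from_bitmask(6)), 2L)
  expect_error(models_from_bitmask(0), "bitmask")
})
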