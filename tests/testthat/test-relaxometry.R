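test_that("SPGR forward signal matches the closed form and its limits", {
  acq <- acq_params(tr = 0.0079, flip_deg = 20)
  expect_equal(spgr_signal(1000, 0, acq), 0)
  expect_equal(spgr_signal(1000, 1, acq), 39.7525357466, tolerance = 1e-10)
  # 90 degrees: S = s0 (1 - E1); saturates at s0 for fast relaxation
  acq90 <- acq_params(tr = 0.0079, flip_deg = 90)
  expect_equal(spgr_signal(500, 2, acq90), 500 * (1 - exp(-2 * 0.0079)))
  expect_equal(spgr_signal(500, 1e6, acq90), 500, tolerance = 1e-8)
  expect_error(acq_params(tr = -1, flip_deg = 20), "tr")
  expect_error(acq_params(tr = 0.005, flip_deg = 200), "flip")
})

test_that("SPGR signal is monotone in s0 and in r1 below 90 degrees", {
  acq <- acq_params(tr = 0.01, flip_deg = 25)
  r1 <- seq(0.1, 8, length.out = 40)
  s <- spgr_signal(1000, r1, acq)
  expect_true(all(diff(s) > 0))
  expect_true(all(spgr_signal(seq(100, 1000, 100), 1, acq) ==
                    cummax(spgr_signal(seq(100, 1000, 100), 1, acq))))
})

test_that("DESPOT1 linearization is exact on noise-free signals", {
  flips <- seq(2, 20, by = 2)
  acq <- acq_params(tr = 0.0079, flip_deg = flips)
  sig <- spgr_signal(1000, 1, acq)[, 1]
  est <- despot1_init(sig, acq)
  expect_equal(unname(est["s0"]), 1000, tolerance = 1e-9)
  expect_equal(unname(est["r1"]), 1, tolerance = 1e-9)
  expect_error(despot1_init(rep(0, length(flips)), acq), "degenerate")
  expect_error(despot1_init(sig, acq_params(tr = 0.0079,
                                            flip_deg = rep(10, 10))),
               "distinct")
})

test_that("a supercritical DESPOT1 slope is clamped to a finite rate", {
  # two-point construction giving a regression slope > 1
  acq <- acq_params(tr = 0.0079, flip_deg = c(10, 20))
  th <- c(10, 20) * pi / 180
  s1 <- 100
  target_slope <- 1.5
  s2 <- s1 * (1 / sin(th[1]) - target_slope / tan(th[1])) /
    (1 / sin(th[2]) - target_slope / tan(th[2]))
  est <- despot1_init(c(s1, s2), acq)
  expect_true(is.finite(est["r1"]) && est["r1"] >= 0)
})

test_that("multiflip map fitting recovers noise-free parameters", {
  flips <- seq(2, 20, by = 2)
  acq <- acq_params(tr = 0.0079, flip_deg = flips)
  for (r1_true in c(0.2, 2, 5)) {
    mf <- multiflip_image(1000, r1_true, flips, tr = 0.0079)
    maps <- fit_r1_maps(mf, acq)
    expect_true(all(maps$fitted_mask))
    expect_lt(max(abs(maps$r10 - r1_true) / r1_true), 1e-6)
    expect_lt(max(abs(maps$s0 - 1000) / 1000), 1e-6)
  }
})

test_that("low-intensity voxels fall outside the fitted mask", {
  flips <- seq(2, 20, by = 2)
  acq <- acq_params(tr = 0.0079, flip_deg = flips)
  mf <- multiflip_image(1000, 2, flips, tr = 0.0079, nx = 3, ny = 3)
  dim_mf <- dim(mf$data)
  mf$data[, 2, 2] <- 0.01 * max(mf$data)   # 1% of max: below the 10% cutoff
  maps <- fit_r1_maps(mf, acq)
  expect_false(maps$fitted_mask[2, 2])
  expect_equal(maps$r10[2, 2], 0)          # sentinel
  expect_equal(sum(maps$fitted_mask), 8)
  all_fit <- fit_r1_maps(mf, acq, intensity_frac = 0)
  expect_true(all(all_fit$fitted_mask))
})

test_that("signal inversion round-trips the forward model", {
  acq <- acq_params(tr = 0.0079, flip_deg = 20)
  sig <- spgr_signal(1000, c(1, 2), acq)
  ds <- dynamic_series(c(0, 1), matrix(sig, ncol = 1))
  rel <- invert_spgr(ds, relaxation_maps(r10 = 1, s0 = 1000), acq)
  expect_equal(rel$r1_t[2, 1], 2, tolerance = 1e-9)
  # identity enhancement: s(t) = 1 recovers r10 exactly
  flat <- dynamic_series(c(0, 1, 2), matrix(rep(sig[1], 3), ncol = 1))
  rel2 <- invert_spgr(flat, relaxation_maps(r10 = 1, s0 = 1000), acq)
  expect_equal(as.vector(rel2$r1_t), rep(1, 3), tolerance = 1e-12)
})

test_that("inversion recovers dynamic R1 across the parameter space", {
  set.seed(11)
  for (i in 1:40) {
    r10 <- runif(1, 0.1, 10); r1t <- runif(1, 0.1, 10)
    th <- runif(1, 5, 40); tr <- runif(1, 0.003, 0.015)
    acq <- acq_params(tr = tr, flip_deg = th)
    s0 <- runif(1, 100, 10000)
    sig <- spgr_signal(s0, c(r10, r1t), acq)
    ds <- dynamic_series(c(0, 1), matrix(sig, ncol = 1))
    rel <- invert_spgr(ds, relaxation_maps(r10 = r10, s0 = s0), acq)
    expect_lt(abs(rel$r1_t[2, 1] - r1t) / r1t, 1e-8)
  }
})

test_that("inversion depends only on the normalized signal", {
  acq <- acq_params(tr = 0.005, flip_deg = 30)
  sig <- spgr_signal(1000, c(1, 2, 3), acq)
  ds1 <- dynamic_series(0:2, matrix(sig, ncol = 1))
  ds2 <- dynamic_series(0:2, matrix(7.3 * sig, ncol = 1))
  r1 <- invert_spgr(ds1, relaxation_maps(r10 = 1, s0 = 1000), acq)
  r2 <- invert_spgr(ds2, relaxation_maps(r10 = 1, s0 = 7300), acq)
  expect_equal(r1$r1_t, r2$r1_t, tolerance = 1e-12)
})

test_that("degenerate log arguments become NaN sentinels, not errors", {
  acq <- acq_params(tr = 0.005, flip_deg = 30)
  s0_sig <- spgr_signal(1000, 1, acq)
  # s = 30 puts the log argument in its negative window for these settings
  ds <- dynamic_series(0:1, matrix(c(s0_sig, 30 * s0_sig), ncol = 1))
  rel <- invert_spgr(ds, relaxation_maps(r10 = 1, s0 = 1000), acq)
  expect_true(is.nan(rel$r1_t[2, 1]))
  expect_equal(rel$n_invalid, 1L)
})

test_that("concentration conversion is a scaled rate difference", {
  acq <- acq_params(tr = 0.005, flip_deg = 30)
  maps <- relaxation_maps(r10 = 1, s0 = 1000)
  sig <- spgr_signal(1000, c(1, 1 + 4.5, 1 - 0.45), acq)
  ds <- dynamic_series(c(0, 60, 120), matrix(sig, ncol = 1))
  conc <- r1_to_concentration(invert_spgr(ds, maps, acq), maps,
                              relaxivity = 4.5)
  expect_equal(conc$ct[1, 1], 0, tolerance = 1e-10)
  expect_equal(conc$ct[2, 1], 1, tolerance = 1e-8)     # delta R1 = r1
  expect_equal(conc$ct[3, 1], -0.1, tolerance = 1e-8)  # negatives preserved
  expect_equal(conc$t_min, c(0, 1, 2))
  expect_error(r1_to_concentration(invert_spgr(ds, maps, acq), maps,
                                   relaxivity = 0), "relaxivity")
})
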