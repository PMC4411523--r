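test_that("phantom layouts carry the full parameter grids", {
  std <- phantom_spec("standard")
  ext <- phantom_spec("extended")
  expect_equal(nrow(phantom_regions(std)), 30L)
  expect_equal(nrow(phantom_regions(ext)), 108L)
  expect_equal(sum(phantom_regions(ext)$ktrans > 0), 90L)
  expect_equal(std$ktrans_values, c(0.01, 0.02, 0.05, 0.1, 0.2, 0.35))
  expect_equal(std$ve_values, c(0.01, 0.05, 0.1, 0.2, 0.5))
  expect_equal(ext$vp_values, c(0.001, 0.005, 0.01, 0.02, 0.05, 0.1))
  expect_error(phantom_spec("standard", ktrans_values = numeric(0)),
               "non-empty")
})

test_that("the generated standard phantom tiles 10x10 patches", {
  sp <- phantom_spec("standard", n_time = 11L)
  ph <- generate_phantom(sp)
  d <- dim(ph$series$data)
  expect_equal(d, c(11L, 60L + 10L, 50L))      # tissue 60 x 50 + strip
  expect_equal(sum(ph$tissue_mask), 30L * 100L)
  expect_equal(ph$vessel_rows, 61:70)
  # every voxel within a patch is identical
  r1 <- ph$series$data[, 1:10, 1:10]
  expect_true(all(apply(r1, 1, function(m) length(unique(as.vector(m))))
                  == 1L))
  # truth maps agree with the region table
  expect_equal(ph$truth_maps$ktrans[1, 1], 0.01)
  expect_equal(ph$truth_maps$ktrans[55, 45], 0.35)
  expect_equal(ph$truth_maps$ve[1, 45], 0.5)
})

test_that("a transferless, plasma-free phantom stays at baseline", {
  sp <- phantom_spec("standard", ktrans_values = 0, ve_values = 0.1,
                     patch_shape = c(2L, 2L), n_time = 51L,
                     strip_rows = 2L)
  ph <- generate_phantom(sp)
  tis <- ph$series$data[, 1:2, 1:2]
  expect_equal(max(tis) - min(tis), 0)
})

test_that("noise-free region subsampling loses nothing", {
  sp <- tiny_phantom_spec()
  ph <- generate_phantom(sp)
  # all voxels of a region share one curve, so one voxel represents all
  cells <- which(ph$region_map == 7)
  curves <- flatten_series(ph)[, cells]
  expect_true(all(curves == curves[, 1]))
})

test_that("zero noise and a fixed seed behave as contracts promise", {
  sp <- tiny_phantom_spec()
  ph <- generate_phantom(sp)
  expect_identical(add_rician_noise(ph$series, noise_spec(0)), ph$series)
  n1 <- add_rician_noise(ph$series, noise_spec(0.2, seed = 9),
                         exclude_rows = ph$vessel_rows)
  n2 <- add_rician_noise(ph$series, noise_spec(0.2, seed = 9),
                         exclude_rows = ph$vessel_rows)
  expect_identical(n1$data, n2$data)
  # strip untouched when the AIF is kept noise-free
  expect_identical(n1$data[, ph$vessel_rows, ],
                   ph$series$data[, ph$vessel_rows, ])
  expect_false(identical(n1$data[, 1, 1], ph$series$data[, 1, 1]))
})

test_that("zero-signal Rician noise has the Rayleigh mean", {
  n <- 1e5
  series <- dynamic_series(1, matrix(0, 1, n))
  sigma0 <- 3
  out <- add_rician_noise(series, noise_spec(0.2, seed = 2),
                          baseline = sigma0 / 0.2)
  expect_equal(mean(out$data), sigma0 * sqrt(pi / 2), tolerance = 0.01)
})

test_that("high-SNR Rician noise approaches the Gaussian level", {
  n <- 2e4
  level <- 1000; sigma0 <- 0.05 * level          # SNR 20
  series <- dynamic_series(1, matrix(level, 1, n))
  out <- add_rician_noise(series, noise_spec(0.05, seed = 4),
                          baseline = level)
  expect_equal(sd(out$data), sigma0, tolerance = 0.05)
})

test_that("the vessel strip round-trips the population AIF", {
  sp <- tiny_phantom_spec(quantize = FALSE)
  ph <- generate_phantom(sp)
  aif <- extract_aif(ph$series, ph$vessel_rows, sp$acq,
                     r10_blood = sp$r10_blood, relaxivity = sp$relaxivity)
  ref <- ph$aif$cp
  nz <- ref > 0.1
  expect_lt(max(abs(aif$cp[nz] - ref[nz]) / ref[nz]), 1e-6)
  # constant baseline strip means zero concentration
  flat <- dynamic_series(ph$series$t,
                         array(100, dim = dim(ph$series$data)))
  aif0 <- extract_aif(flat, ph$vessel_rows, sp$acq)
  expect_equal(max(abs(aif0$cp)), 0, tolerance = 1e-10)
  expect_error(extract_aif(ph$series, 10000L, sp$acq), "rows")
})
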