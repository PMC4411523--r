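# Shared fixtures, built in code.

# a smooth AIF on a uniform grid (minutes), for quadrature/fitting oracles
oracle_grid <- function(t_end = 5, dt = 0.01) seq(0, t_end, by = dt)

oracle_aif <- function(t_min) aif_population(t_min * 60, t0_s = 15)

# small phantom spec for module-level tests (fast; not the study defaults)
tiny_phantom_spec <- function(layout = "standard", ...) {
  phantom_spec(layout, patch_shape = c(2L, 2L), n_time = 201L, dt = 1,
               strip_rows = 2L, ...)
}

# direct O(N^2) composite trapezoid of Cp(s) exp(kep (s - t_i)), the
# independent oracle for the interval-recursion implementation
conv_exp_trapz_direct <- function(t_min, cp, kep) {
  n <- length(t_min)
  out <- numeric(n)
  for (i in seq(2, n)) {
    f <- cp[1:i] * exp(kep * (t_min[1:i] - t_min[i]))
    out[i] <- sum(diff(t_min[1:i]) * (f[-i] + f[-1]) / 2)
  }
  out
}

# time x voxel matrix view of a phantom's series
flatten_series <- function(ph) {
  d <- dim(ph$series$data)
  matrix(ph$series$data, nrow = d[1], ncol = d[2] * d[3])
}

# forward multiflip SPGR image series (flip-first), all voxels identical
multiflip_image <- function(s0, r1, flips_deg, tr, nx = 4L, ny = 4L) {
  acq <- acq_params(tr = tr, flip_deg = flips_deg)
  sig <- spgr_signal(s0, r1, acq)[, 1L]
  data <- array(rep(sig, nx * ny), dim = c(length(flips_deg), nx, ny))
  dynamic_series(seq_along(flips_deg), data)
}
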