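#' Population arterial input function
#'
#' Parametric population AIF used by the synthetic phantom generator: a
#' biexponential washout modulated by a smooth bolus arrival,
#' \deqn{C_p(\tau) = D (a_1 e^{-m_1\tau} + a_2 e^{-m_2\tau})(1 - e^{-m_3\tau}),}
#' with \eqn{\tau = t - t_0} in minutes and Cp = 0 before the bolus
#' arrival t0. Default amplitudes/decay rates give a curve peaking near
#' 6 mM about 30 s after arrival with a slow washout, the familiar shape
#' of a gadolinium bolus population AIF.
#'
#' @param t_s Time vector in seconds.
#' @param t0_s Bolus arrival time in seconds (default 30).
#' @param dose Overall amplitude scale (default 0.75).
#' @param a1,a2 Amplitudes (mM) of the fast/slow washout terms.
#' @param m1,m2 Washout rates (1/min).
#' @param m3 Bolus rise rate (1/min).
#' @return Cp(t) in mM, same length as `t_s`.
#' @export
aif_population <- function(t_s, t0_s = 30, dose = 0.75,
                           a1 = 3.99, m1 = 0.144,
                           a2 = 4.78, m2 = 0.0111, m3 = 12) {
  tau <- (t_s - t0_s) / 60
  cp <- dose * (a1 * exp(-m1 * tau) + a2 * exp(-m2 * tau)) *
    (1 - exp(-m3 * tau))
  cp[tau <= 0] <- 0
  cp
}

#' Specification of a QIBA-layout digital reference object
#'
#' Describes a synthetic DCE phantom laid out like the QIBA Tofts-Kety
#' digital reference objects: a grid of homogeneous parameter patches
#' (every combination of the parameter value lists) above a vessel strip
#' that carries the AIF signal. The `"standard"` layout uses the QIBA v6
#' grids (6 Ktrans x 5 ve = 30 regions, vp = 0); the `"extended"` layout
#' uses the QIBA v4 grids (6 Ktrans x 3 ve x 6 vp = 108 regions).
#'
#' @param layout `"standard"` or `"extended"`.
#' @param ktrans_values,ve_values,vp_values Parameter value lists
#'   (1/min, -, -); defaults are the QIBA grids for the chosen layout.
#' @param patch_shape Voxels per region, default `c(10, 10)`.
#' @param n_time Number of dynamics, default 661.
#' @param dt Frame spacing in seconds, default 0.5.
#' @param acq [acq_params()]; default TR = 5 ms, flip 30 degrees.
#' @param r10_tissue,r10_blood Pre-contrast R1 in 1/s (defaults 1/1.0 and
#'   1/1.4).
#' @param s0 Equilibrium signal scale, default 50000 (chosen so that the
#'   short-TR SPGR signal spans a realistic 12-bit-like DICOM intensity
#'   range).
#' @param quantize Round signals to integers, as in the DICOM-delivered
#'   reference objects? Default TRUE.
#' @param strip_rows Height of the vessel strip in voxels, default 10.
#' @param relaxivity Contrast relaxivity in 1/s/mM, default 4.5.
#' @param t0_s Bolus arrival in seconds, default 30 (leaves pre-contrast
#'   baseline frames for SER/normalization).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(layout = c("standard", "extended"),
                         ktrans_values = NULL, ve_values = NULL,
                         vp_values = NULL,
                         patch_shape = c(10L, 10L),
                         n_time = 661L, dt = 0.5,
                         acq = acq_params(tr = 0.005, flip_deg = 30),
                         r10_tissue = 1.0, r10_blood = 1 / 1.4,
                         s0 = 50000, strip_rows = 10L, quantize = TRUE,
                         relaxivity = 4.5, t0_s = 30) {
  layout <- match.arg(layout)
  if (is.null(ktrans_values))
    ktrans_values <- if (layout == "standard")
      c(0.01, 0.02, 0.05, 0.1, 0.2, 0.35) else
      c(0, 0.01, 0.02, 0.05, 0.1, 0.2)
  if (is.null(ve_values))
    ve_values <- if (layout == "standard")
      c(0.01, 0.05, 0.1, 0.2, 0.5) else c(0.1, 0.2, 0.5)
  if (is.null(vp_values))
    vp_values <- if (layout == "standard") numeric(0) else
      c(0.001, 0.005, 0.01, 0.02, 0.05, 0.1)
  if (length(ktrans_values) < 1L || length(ve_values) < 1L)
    stop("parameter value lists must be non-empty", call. = FALSE)
  if (layout == "extended" && length(vp_values) < 1L)
    stop("extended layout needs vp values", call. = FALSE)
  if (any(c(ktrans_values, ve_values, vp_values) < 0))
    stop("parameter values must be >= 0", call. = FALSE)
  if (any(patch_shape < 1L)) stop("patch_shape must be positive",
                                  call. = FALSE)
  structure(
    list(layout = layout, ktrans_values = ktrans_values,
         ve_values = ve_values, vp_values = vp_values,
         patch_shape = as.integer(patch_shape),
         n_time = as.integer(n_time), dt = dt, acq = acq,
         r10_tissue = r10_tissue, r10_blood = r10_blood, s0 = s0,
         strip_rows = as.integer(strip_rows), quantize = isTRUE(quantize),
         relaxivity = relaxivity, t0_s = t0_s),
    class = "phantom_spec")
}

#' Region table of a phantom spec
#'
#' One row per homogeneous region: the Cartesian product of the parameter
#' value lists, with the patch-grid position of each region.
#'
#' @param spec [phantom_spec()].
#' @return Tibble with `region`, `patch_row`, `patch_col`, `ktrans`,
#'   `ve`, `vp`, `kep`.
#' @export
phantom_regions <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$layout == "standard") {
    g <- expand.grid(ve_i = seq_along(spec$ve_values),
                     kt_i = seq_along(spec$ktrans_values))
    tb <- tibble::tibble(
      patch_row = g$kt_i, patch_col = g$ve_i,
      ktrans = spec$ktrans_values[g$kt_i],
      ve = spec$ve_values[g$ve_i], vp = 0)
  } else {
    # row blocks: ktrans (outer) x ve (inner); columns: vp
    g <- expand.grid(vp_i = seq_along(spec$vp_values),
                     ve_i = seq_along(spec$ve_values),
                     kt_i = seq_along(spec$ktrans_values))
    tb <- tibble::tibble(
      patch_row = (g$kt_i - 1L) * length(spec$ve_values) + g$ve_i,
      patch_col = g$vp_i,
      ktrans = spec$ktrans_values[g$kt_i],
      ve = spec$ve_values[g$ve_i],
      vp = spec$vp_values[g$vp_i])
  }
  tb$region <- seq_len(nrow(tb))
  tb$kep <- ifelse(tb$ve > 0, tb$ktrans / tb$ve, 0)
  tb[, c("region", "patch_row", "patch_col", "ktrans", "ve", "vp", "kep")]
}

# refine a time grid: `oversample` subintervals per acquisition interval
refine_grid <- function(t, oversample) {
  if (oversample <= 1L) return(list(t = t, keep = seq_along(t)))
  n <- length(t)
  fine <- c(unlist(lapply(seq_len(n - 1L), function(i)
    seq(t[i], t[i + 1L], length.out = oversample + 1L)[-(oversample + 1L)])),
    t[n])
  list(t = fine, keep = seq(1L, length(fine), by = oversample))
}

#' Generate a synthetic QIBA-layout phantom
#'
#' Builds the dynamic SPGR signal of the digital reference object
#' described by `spec`: per-region tissue concentration from the
#' Tofts-Kety forward model, converted to R1(t) via the relaxivity and to
#' signal via the SPGR equation, tiled into homogeneous patches, with a
#' vessel strip at the bottom carrying the AIF signal. The forward model
#' is integrated on a time grid `oversample` times finer than the
#' acquisition grid and then sampled at the acquisition times, so the
#' generated data are not trivially consistent with the fitting
#' quadrature (as with the real reference objects).
#'
#' @param spec [phantom_spec()].
#' @param oversample Forward-integration refinement factor, default 10.
#' @return A `dce_phantom`: list with `series` ([dynamic_series()], time x
#'   rows x cols), `truth` (region tibble from [phantom_regions()]),
#'   `truth_maps` (list of ktrans/ve/vp/kep spatial maps, NA on the
#'   strip), `tissue_mask`, `region_map`, `vessel_rows`, `aif` (list with
#'   `t`, `cp`), and `spec`.
#' @export
generate_phantom <- function(spec, oversample = 10L) {
  stopifnot(inherits(spec, "phantom_spec"))
  regions <- phantom_regions(spec)
  t_s <- (seq_len(spec$n_time) - 1L) * spec$dt
  fine <- refine_grid(t_s, oversample)
  cp_fine <- aif_population(fine$t, t0_s = spec$t0_s)
  t_fine_min <- fine$t / 60
  cp <- cp_fine[fine$keep]

  ext <- model_spec("extended_tofts")
  curves <- vapply(seq_len(nrow(regions)), function(i) {
    ct_fine <- model_ct(
      c(ktrans = regions$ktrans[i], kep = regions$kep[i],
        vp = regions$vp[i]),
      ext, t_fine_min, cp_fine)
    ct_fine[fine$keep]
  }, numeric(spec$n_time))                     # n_time x n_region

  # region signal: R1(t) = R10 + r1 * Ct, then SPGR forward
  sig <- apply(curves, 2L, function(ct)
    spgr_signal(spec$s0, spec$r10_tissue + spec$relaxivity * pmax(ct, 0),
                spec$acq))

  pr <- spec$patch_shape[1L]; pc <- spec$patch_shape[2L]
  n_prow <- max(regions$patch_row); n_pcol <- max(regions$patch_col)
  h_tis <- n_prow * pr; w <- n_pcol * pc
  h <- h_tis + spec$strip_rows
  data <- array(0, dim = c(spec$n_time, h, w))
  region_map <- matrix(NA_integer_, h, w)
  for (i in seq_len(nrow(regions))) {
    rows <- (regions$patch_row[i] - 1L) * pr + seq_len(pr)
    cols <- (regions$patch_col[i] - 1L) * pc + seq_len(pc)
    data[, rows, cols] <- sig[, i]
    region_map[rows, cols] <- regions$region[i]
  }
  # vessel strip: blood R1 follows the AIF directly
  strip_sig <- spgr_signal(spec$s0,
                           spec$r10_blood + spec$relaxivity * cp, spec$acq)
  vessel_rows <- h_tis + seq_len(spec$strip_rows)
  data[, vessel_rows, ] <- strip_sig
  if (isTRUE(spec$quantize)) data <- round(data)

  truth_maps <- lapply(c("ktrans", "ve", "vp", "kep"), function(nm) {
    m <- matrix(NA_real_, h, w)
    ok <- !is.na(region_map)
    m[ok] <- regions[[nm]][region_map[ok]]
    m
  })
  names(truth_maps) <- c("ktrans", "ve", "vp", "kep")

  structure(
    list(series = dynamic_series(t_s, data), truth = regions,
         truth_maps = truth_maps,
         tissue_mask = !is.na(region_map), region_map = region_map,
         vessel_rows = vessel_rows,
         aif = list(t = t_s, cp = cp), spec = spec),
    class = "dce_phantom")
}

#' Noise specification for Rician noise injection
#'
#' @param sigma_rel Noise standard deviation relative to the pre-contrast
#'   baseline signal, >= 0 (e.g. 0.2).
#' @param seed RNG seed for reproducible noise.
#' @param noise_aif Also corrupt the vessel strip? Default FALSE (the AIF
#'   is kept noise-free).
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(sigma_rel, seed = 1L, noise_aif = FALSE) {
  if (sigma_rel < 0) stop("`sigma_rel` must be >= 0", call. = FALSE)
  structure(list(sigma_rel = sigma_rel, seed = as.integer(seed),
                 noise_aif = isTRUE(noise_aif)),
            class = "noise_spec")
}

with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Add Rician noise to a dynamic series
#'
#' Adds complex Gaussian noise of standard deviation
#' `sigma_rel * baseline` independently to the real and imaginary
#' channels and takes the magnitude, `|S + n_r + i n_i|`, turning the
#' noise distribution Rician. The baseline is the global mean of the
#' first `n_pre` dynamics over the noised voxels (the mean pre-contrast
#' tissue signal) unless given explicitly. Rows listed in `exclude_rows`
#' (e.g. a vessel strip, when `noise$noise_aif` is FALSE) are returned
#' untouched. Seeded and reproducible; the caller's RNG state is
#' preserved.
#'
#' @param series [dynamic_series()].
#' @param noise [noise_spec()].
#' @param exclude_rows Spatial row indices to leave noise-free (ignored
#'   when `noise$noise_aif` is TRUE).
#' @param baseline Optional explicit baseline signal level.
#' @param n_pre Pre-contrast dynamics defining the baseline, default 3.
#' @return A new [dynamic_series()] with noisy magnitude data.
#' @export
add_rician_noise <- function(series, noise, exclude_rows = integer(0),
                             baseline = NULL, n_pre = 3L) {
  stopifnot(inherits(series, "dynamic_series"),
            inherits(noise, "noise_spec"))
  if (noise$sigma_rel == 0) return(series)
  data <- series$data
  d <- dim(data)
  sm <- flatten_time_first(data)
  # the first spatial dimension indexes image rows; map excluded rows to
  # flattened voxel columns
  keep_rows <- if (noise$noise_aif) integer(0) else exclude_rows
  vox_row <- rep_len(seq_len(d[2L]), ncol(sm))
  noised <- which(!(vox_row %in% keep_rows))
  if (is.null(baseline))
    baseline <- mean(sm[seq_len(min(n_pre, d[1L])), noised, drop = FALSE])
  sd0 <- noise$sigma_rel * baseline
  block <- sm[, noised, drop = FALSE]
  out <- with_preserved_seed(noise$seed, {
    nr <- matrix(stats::rnorm(length(block), 0, sd0), nrow(block))
    ni <- matrix(stats::rnorm(length(block), 0, sd0), nrow(block))
    sqrt((block + nr)^2 + ni^2)
  })
  sm[, noised] <- out
  dynamic_series(series$t, array(sm, dim = d))
}

#' Extract the arterial input function from a vessel strip
#'
#' Averages the signal over the vessel-strip rows at each time point,
#' inverts the SPGR equation at the blood pre-contrast R1 (normalizing by
#' the pre-contrast baseline of the strip), and converts the resulting
#' R1(t) to plasma concentration.
#'
#' @param series [dynamic_series()] with data time x rows x cols.
#' @param vessel_rows Row indices of the vessel strip.
#' @param acq [acq_params()] (scalar flip).
#' @param r10_blood Blood pre-contrast R1 in 1/s, default 1/1.4.
#' @param relaxivity 1/s/mM, default 4.5.
#' @param n_pre Pre-contrast dynamics for baseline normalization.
#' @return List with `t` (seconds) and `cp` (mM).
#' @export
extract_aif <- function(series, vessel_rows, acq, r10_blood = 1 / 1.4,
                        relaxivity = 4.5, n_pre = 3L) {
  stopifnot(inherits(series, "dynamic_series"))
  d <- dim(series$data)
  if (length(d) != 3L)
    stop("extract_aif expects a time x rows x cols series", call. = FALSE)
  if (length(vessel_rows) < 1L || any(vessel_rows < 1L) ||
      any(vessel_rows > d[2L]))
    stop("`vessel_rows` must index rows of the image", call. = FALSE)
  strip <- series$data[, vessel_rows, , drop = FALSE]
  curve <- apply(strip, 1L, mean)
  one <- dynamic_series(series$t, matrix(curve, ncol = 1L))
  maps <- relaxation_maps(r10 = r10_blood, s0 = NA_real_,
                          fitted_mask = TRUE)
  rel <- invert_spgr(one, maps, acq, s0_from = "baseline", n_pre = n_pre)
  conc <- r1_to_concentration(rel, maps, relaxivity)
  list(t = series$t, cp = as.vector(conc$ct))
}
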