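#' Spoiled gradient echo (SPGR) steady-state signal
#'
#' Forward signal model for a spoiled gradient-recalled echo sequence,
#' \deqn{S = S_0 \sin\theta \frac{1 - e^{-R_1 T_R}}{1 - \cos\theta\, e^{-R_1 T_R}},}
#' neglecting R2* decay (TE << 1/R2*). Vectorizes over `s0`, `r1` and the
#' flip angles in `acq`: if `acq$flip_deg` has length > 1 the result is a
#' matrix with one row per flip angle and one column per voxel.
#'
#' @param s0 Equilibrium signal S(x,0) (signal units), scalar or vector.
#' @param r1 Longitudinal relaxation rate in 1/s, scalar or vector, >= 0.
#' @param acq [acq_params()] holding TR (s) and flip angle(s) (degrees).
#'
#' @return Signal value(s): a vector when `acq` has a single flip angle,
#'   otherwise a `n_flip x n_voxel` matrix.
#' @export
#' @examples
#' acq <- acq_params(tr = 0.0079, flip_deg = 20)
#' spgr_signal(1000, 1, acq)   # ~39.75
spgr_signal <- function(s0, r1, acq) {
  stopifnot_acq(acq)
  if (any(r1 < 0, na.rm = TRUE))
    stop("`r1` must be non-negative", call. = FALSE)
  e1 <- exp(-r1 * acq$tr)
  if (length(acq$flip_rad) == 1L) {
    th <- acq$flip_rad
    return(s0 * sin(th) * (1 - e1) / (1 - cos(th) * e1))
  }
  sth <- sin(acq$flip_rad)
  cth <- cos(acq$flip_rad)
  # outer over flips (rows) x voxels (cols)
  num <- outer(sth, s0 * (1 - e1))
  den <- 1 - outer(cth, e1)
  num / den
}

#' Linearized (DESPOT1) initialization of the SPGR fit
#'
#' Linear estimate of (S0, R1) from multiflip SPGR signals: regressing
#' S/sin(theta) on S/tan(theta) gives slope E1 = exp(-R1 TR) and intercept
#' S0 (1 - E1). Exact for noise-free data; used to initialize the
#' Levenberg-Marquardt refinement in [fit_r1_maps()]. The slope is clamped
#' into (0, 1) before the log so noisy inputs still yield finite rates.
#'
#' @param signals Numeric vector of signals, one per flip angle in `acq`.
#' @param acq [acq_params()] with as many flip angles as `signals`.
#'
#' @return Named numeric vector `c(s0 = ..., r1 = ...)`.
#' @export
despot1_init <- function(signals, acq) {
  stopifnot_acq(acq)
  th <- acq$flip_rad
  if (length(th) < 2L || length(unique(acq$flip_deg)) < 2L)
    stop("despot1_init needs >= 2 distinct flip angles", call. = FALSE)
  if (length(signals) != length(th))
    stop("length(signals) must match the number of flip angles", call. = FALSE)
  y <- signals / sin(th)
  x <- signals / tan(th)
  sxx <- sum((x - mean(x))^2)
  if (!is.finite(sxx) || sxx <= 0)
    stop("degenerate regression in despot1_init (constant predictor)",
         call. = FALSE)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  eps <- 1e-8
  slope <- min(max(slope, eps), 1 - eps)
  r1 <- -log(slope) / acq$tr
  s0 <- intercept / (1 - slope)
  c(s0 = s0, r1 = r1)
}

#' Fit R1 and S0 maps from multiflip SPGR data
#'
#' Voxelwise nonlinear fit of the SPGR signal equation to variable flip
#' angle data. Voxels whose mean multiflip intensity falls below
#' `intensity_frac` of the global maximum mean intensity are excluded
#' (they are dominated by noise); the remaining voxels are fitted by
#' Levenberg-Marquardt starting from the DESPOT1 linearization. Results
#' are independent of `n_workers`.
#'
#' @param multiflip [dynamic_series()] whose first dimension indexes flip
#'   angles (matching `acq$flip_deg`).
#' @param acq [acq_params()] with the multiflip angles.
#' @param intensity_frac Exclusion cutoff as a fraction of the maximum
#'   mean intensity; default 0.10.
#' @param opts [fit_options()] for the LM refinement.
#' @param n_workers Worker processes for the voxel loop.
#'
#' @return A `relaxation_maps` object: list with `r10` (1/s), `s0`,
#'   `fitted_mask` (logical), all shaped like the spatial grid. Unfitted
#'   voxels carry 0.
#' @export
fit_r1_maps <- function(multiflip, acq, intensity_frac = 0.10,
                        opts = fit_options(), n_workers = 1L) {
  stopifnot(inherits(multiflip, "dynamic_series"))
  stopifnot_acq(acq)
  if (length(acq$flip_deg) != multiflip$n_time)
    stop("number of flip angles must match the series' first dimension",
         call. = FALSE)
  sm <- as_series_matrix(multiflip)      # n_flip x n_voxel
  mean_img <- colMeans(sm)
  keep <- is.finite(mean_img) & mean_img >= intensity_frac * max(mean_img, 0)
  if (intensity_frac <= 0) keep <- is.finite(mean_img)
  if (!any(keep))
    warning("no voxel exceeds the intensity cutoff; empty R1 map returned")

  idx <- which(keep)
  fit_one <- function(j) {
    sig <- sm[, j]
    init <- tryCatch(despot1_init(sig, acq),
                     error = function(e) c(s0 = max(sig), r1 = 1))
    init["r1"] <- max(init["r1"], 1e-6)
    init["s0"] <- max(init["s0"], 1e-12)
    res <- levmar(
      residual_fn = function(p) spgr_signal(p[1L], max(p[2L], 0), acq) - sig,
      jacobian_fn = function(p) spgr_jacobian(p[1L], max(p[2L], 0), acq),
      init = unname(init), opts = opts)
    c(res$params[1L], res$params[2L])
  }
  fitted <- run_indexed_parallel(idx, fit_one, n_workers)

  nv <- ncol(sm)
  r10 <- numeric(nv); s0 <- numeric(nv)
  if (length(idx)) {
    r10[idx] <- pmax(vapply(fitted, `[`, numeric(1), 2L), 0)
    s0[idx] <- pmax(vapply(fitted, `[`, numeric(1), 1L), 0)
  }
  relaxation_maps(
    r10 = unflatten_spatial(r10, multiflip$spatial_dim),
    s0 = unflatten_spatial(s0, multiflip$spatial_dim),
    fitted_mask = unflatten_spatial(keep, multiflip$spatial_dim))
}

# analytic Jacobian of the SPGR model in (s0, r1)
spgr_jacobian <- function(s0, r1, acq) {
  th <- acq$flip_rad
  e1 <- exp(-r1 * acq$tr)
  den <- 1 - cos(th) * e1
  d_s0 <- sin(th) * (1 - e1) / den
  # dS/dE1 = s0 sin(th) (cos(th) - 1)/den^2 ; dE1/dr1 = -tr e1
  d_r1 <- s0 * sin(th) * (cos(th) - 1) / den^2 * (-acq$tr * e1)
  cbind(d_s0, d_r1, deparse.level = 0)
}

#' Relaxation maps container
#'
#' @param r10 Map of pre-contrast relaxation rate R1(x,0) in 1/s.
#' @param s0 Map of equilibrium signal S(x,0).
#' @param fitted_mask Logical map of voxels actually fitted.
#' @return A `relaxation_maps` object.
#' @export
relaxation_maps <- function(r10, s0, fitted_mask = NULL) {
  if (is.null(fitted_mask)) fitted_mask <- array(TRUE, dim = dim2(r10))
  structure(list(r10 = r10, s0 = s0, fitted_mask = fitted_mask),
            class = "relaxation_maps")
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Invert the SPGR signal equation to a dynamic R1 series
#'
#' Converts a dynamic SPGR signal series to effective relaxation rates
#' R1(x,t) by inverting the signal equation on the normalized signal
#' s(x,t) = S(x,t)/S(x,0):
#' \deqn{R_1(t) = -\frac{1}{T_R}\log\frac{1 - s + s E_{10} - E_{10}\cos\theta}
#'   {1 - s\cos\theta + s E_{10}\cos\theta - E_{10}\cos\theta},}
#' with \eqn{E_{10} = e^{-R_1(x,0) T_R}}. All sin(theta) terms cancel in
#' this form, which reduces sensitivity to B1 transmit inhomogeneity.
#' Samples where the log argument is non-positive (possible in noisy data)
#' are set to NaN and counted, never fatal.
#'
#' @param series Dynamic [dynamic_series()] acquired at a single flip angle.
#' @param maps [relaxation_maps()] covering the series' spatial grid. The
#'   `s0` map is used for normalization when `s0_from = "map"`.
#' @param acq [acq_params()] with a scalar flip angle.
#' @param s0_from `"map"` to normalize by `maps$s0`; `"baseline"` to
#'   normalize by the mean of the first `n_pre` dynamics converted to the
#'   equilibrium scale via the forward model at R1(x,0).
#' @param n_pre Pre-contrast dynamics used when `s0_from = "baseline"`.
#'
#' @return A `relaxation_series` object: list with `r1_t` (time x voxels,
#'   1/s), `s_norm`, `n_invalid` (count of NaN sentinels), `t`,
#'   `spatial_dim`.
#' @export
invert_spgr <- function(series, maps, acq,
                        s0_from = c("map", "baseline"), n_pre = 3L) {
  stopifnot(inherits(series, "dynamic_series"),
            inherits(maps, "relaxation_maps"))
  stopifnot_acq(acq)
  s0_from <- match.arg(s0_from)
  if (length(acq$flip_rad) != 1L)
    stop("dynamic inversion requires a scalar flip angle", call. = FALSE)
  sm <- as_series_matrix(series)                  # n_time x n_voxel
  r10 <- as.vector(maps$r10)
  if (length(r10) != ncol(sm))
    stop("relaxation maps do not cover the series' spatial grid",
         call. = FALSE)

  if (s0_from == "map") {
    s0 <- as.vector(maps$s0)
  } else {
    n_pre <- min(n_pre, series$n_time)
    base <- colMeans(sm[seq_len(n_pre), , drop = FALSE])
    # baseline signal corresponds to S(R10); rescale to equilibrium S0
    unit <- spgr_signal(1, r10, acq)
    s0 <- ifelse(unit > 0, base / unit, 0)
  }
  s0[!is.finite(s0) | s0 <= 0] <- NA_real_
  s_norm <- sweep(sm, 2L, s0 * spgr_signal(1, r10, acq), "/")

  cth <- cos(acq$flip_rad)
  e10 <- exp(-r10 * acq$tr)
  # num = 1 - s + s*e10 - e10*cth ; den = 1 - s*cth + s*e10*cth - e10*cth
  num <- 1 - s_norm + sweep(s_norm, 2L, e10, "*") -
    matrix(e10 * cth, nrow(sm), ncol(sm), byrow = TRUE)
  den <- 1 - s_norm * cth + sweep(s_norm * cth, 2L, e10, "*") -
    matrix(e10 * cth, nrow(sm), ncol(sm), byrow = TRUE)
  arg <- num / den
  bad <- !is.finite(arg) | arg <= 0
  arg[bad] <- NA_real_
  r1_t <- -log(arg) / acq$tr
  r1_t[bad] <- NaN
  structure(
    list(r1_t = r1_t, s_norm = s_norm, n_invalid = sum(bad),
         t = series$t, spatial_dim = series$spatial_dim),
    class = "relaxation_series")
}

#' Convert a dynamic R1 series to tracer concentration
#'
#' Tissue contrast agent concentration from the change in longitudinal
#' relaxation rate: \eqn{C_t(x,t) = (R_1(x,t) - R_1(x,0)) / r_1}, with
#' `relaxivity` r1 in 1/s/mM (default 4.5, Gd-DTPA at 3 T). Negative
#' concentrations are preserved (handled downstream); NaN propagates.
#'
#' @param rel `relaxation_series` from [invert_spgr()].
#' @param maps [relaxation_maps()] supplying R1(x,0).
#' @param relaxivity Contrast agent relaxivity in 1/s/mM, > 0.
#'
#' @return A `concentration_series` object: list with `ct` (time x voxels,
#'   mM), `t_min` (time in minutes), `relaxivity`, `spatial_dim`.
#' @export
r1_to_concentration <- function(rel, maps, relaxivity = 4.5) {
  stopifnot(inherits(rel, "relaxation_series"),
            inherits(maps, "relaxation_maps"))
  if (!is.numeric(relaxivity) || length(relaxivity) != 1L || relaxivity <= 0)
    stop("`relaxivity` must be a single positive number (1/s/mM)",
         call. = FALSE)
  ct <- sweep(rel$r1_t, 2L, as.vector(maps$r10), "-") / relaxivity
  structure(
    list(ct = ct, t_min = rel$t / 60, relaxivity = relaxivity,
         spatial_dim = rel$spatial_dim),
    class = "concentration_series")
}
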