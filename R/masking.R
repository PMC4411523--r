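#' Signal enhancement ratio (SER) map
#'
#' Per-voxel ratio of the mean signal over the last `n_post` dynamics to
#' the mean over the first `n_pre` dynamics. Requires at least
#' `n_pre + n_post` time points (i.e. an acquisition with pre-contrast
#' baseline frames). Voxels with a zero (or non-finite) leading mean get
#' SER = 0 and are flagged.
#'
#' @param series [dynamic_series()].
#' @param n_pre,n_post Leading / trailing dynamic counts, default 3.
#' @return A `ser_map`: list with `ser` (spatial map), `n_pre`, `n_post`,
#'   `zero_baseline` (logical map of flagged voxels).
#' @export
compute_ser <- function(series, n_pre = 3L, n_post = 3L) {
  stopifnot(inherits(series, "dynamic_series"))
  n_pre <- as.integer(n_pre); n_post <- as.integer(n_post)
  if (series$n_time < n_pre + n_post)
    stop("series has fewer than n_pre + n_post dynamics", call. = FALSE)
  sm <- as_series_matrix(series)
  lead <- colMeans(sm[seq_len(n_pre), , drop = FALSE])
  trail <- colMeans(sm[series$n_time - n_post + seq_len(n_post), ,
                       drop = FALSE])
  zero <- !is.finite(lead) | lead == 0
  ser <- ifelse(zero, 0, trail / lead)
  structure(
    list(ser = unflatten_spatial(ser, series$spatial_dim),
         n_pre = n_pre, n_post = n_post,
         zero_baseline = unflatten_spatial(zero, series$spatial_dim)),
    class = "ser_map")
}

#' Automatic processing mask from an SER map
#'
#' Voxels whose SER lies strictly above `cutoff` (default 2.0) enter the
#' processing mask. The tie rule is strict: SER exactly equal to the
#' cutoff is excluded.
#'
#' @param sermap A `ser_map` from [compute_ser()].
#' @param cutoff SER threshold, >= 0; default 2.0.
#' @return A `processing_mask`: list with logical `mask` and
#'   `source = "ser_auto"`.
#' @export
auto_mask <- function(sermap, cutoff = 2.0) {
  stopifnot(inherits(sermap, "ser_map"))
  if (cutoff < 0) stop("`cutoff` must be >= 0", call. = FALSE)
  structure(list(mask = sermap$ser > cutoff, source = "ser_auto"),
            class = "processing_mask")
}

#' Clamp fitted parameters to physiological intervals
#'
#' ve and vp are clamped to [0, 1] and Ktrans to [0, 5] /min; kep is
#' recomputed as Ktrans/ve where ve > 0 (else 0) so the invariant
#' kep = Ktrans/ve survives clamping. Residual columns (`ssr`,
#' `chisq_red`) are left untouched: they describe the original,
#' unclamped fit.
#'
#' @param fits A `dce_fit_tbl` from [fit_voxels_parallel()] (or any data
#'   frame with `ktrans`, `ve`, `vp` columns; `kep` optional).
#' @return The input with clamped parameter columns.
#' @export
clamp_params <- function(fits) {
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  fits$ktrans <- clamp(fits$ktrans, 0, 5)
  fits$ve <- clamp(fits$ve, 0, 1)
  fits$vp <- clamp(fits$vp, 0, 1)
  if (!is.null(fits[["kep"]]))
    fits$kep <- ifelse(fits$ve > 0, fits$ktrans / fits$ve, 0)
  fits
}

#' Reduced chi-squared of a fit
#'
#' `ssr / (n_points - n_params)`; used to compare alternative models at a
#' fixed voxel. Unit noise variance is assumed (no per-voxel sigma is
#' estimated), which is valid for model comparison at a voxel.
#'
#' @param ssr Sum of squared residuals (vectorized).
#' @param n_points Number of time points.
#' @param n_params Number of fitted parameters; must be < `n_points`.
#' @return Reduced chi-squared value(s).
#' @export
reduced_chisq <- function(ssr, n_points, n_params) {
  if (any(n_points <= n_params))
    stop("n_points must exceed n_params", call. = FALSE)
  ssr / (n_points - n_params)
}

#' Select the best model per voxel by reduced chi-squared
#'
#' Given fits of several models to the same voxels, picks per voxel the
#' model with the smallest reduced chi-squared; ties break toward the
#' model with fewer parameters. Skipped voxels stay skipped.
#'
#' @param fits Named list of `dce_fit_tbl` objects (names irrelevant; the
#'   model id is read from each table), all over the same voxels.
#' @return A `dce_fit_tbl` with the winning parameters per voxel plus
#'   `model_id` and `model_bit` columns.
#' @export
select_best_model <- function(fits) {
  if (length(fits) < 1L) stop("need at least one fitted model", call. = FALSE)
  specs <- lapply(fits, function(f) model_spec(attr(f, "model_id")))
  nv <- nrow(fits[[1L]])
  for (f in fits) stopifnot(nrow(f) == nv)
  np <- vapply(specs, `[[`, integer(1), "n_params")
  ord <- order(np)           # fewer-parameter models first -> win ties
  fits <- fits[ord]; specs <- specs[ord]; np <- np[ord]
  cr <- sapply(fits, `[[`, "chisq_red")
  cr <- matrix(cr, nrow = nv)
  cr[!is.finite(cr)] <- Inf
  winner <- apply(cr, 1L, which.min)   # first (fewest-param) wins ties
  out <- fits[[1L]]
  for (k in seq_along(fits)) {
    sel <- winner == k
    if (!any(sel)) next
    out[sel, ] <- fits[[k]][sel, ]
  }
  out$model_id <- unname(vapply(specs, `[[`, character(1), "id")[winner])
  out$model_bit <- unname(vapply(specs, `[[`, integer(1), "bit")[winner])
  attr(out, "model_id") <- "best_of"
  out
}
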