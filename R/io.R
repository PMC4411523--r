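#' Read a DCE analysis input bundle from a MAT v5 file
#'
#' The file must contain `t` (seconds), `Cp` (mM) and `DCEdata`
#' (time-first dynamic array), plus either precomputed `R10`/`S0` maps or
#' multiflip data `T1data`/`T1flip` (flip angles in degrees). Optional
#' variables (`mask`, `models`, `relaxivity`, `TR`, `DCEflip`, `outfile`)
#' default when absent: models = 2 (Standard Tofts-Kety), relaxivity =
#' 4.5 /s/mM, TR = 0.005 s, DCEflip = 30 degrees.
#'
#' @param path Path to a MAT v5 file.
#' @return An `input_bundle`: list with `series` ([dynamic_series()]),
#'   `cp`, `maps` or `multiflip`+`t1flip`, `mask`, `models`,
#'   `relaxivity`, `acq`, `outfile`.
#' @export
read_input_mat <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  vars <- read_mat5(path)
  for (req in c("t", "Cp", "DCEdata"))
    if (is.null(vars[[req]]))
      stop("required variable '", req, "' missing from ", path,
           call. = FALSE)
  t <- as.vector(vars$t)
  cp <- as.vector(vars$Cp)
  data <- vars$DCEdata
  if (is.null(dim(data))) data <- matrix(data, ncol = 1L)
  if (dim(data)[1L] != length(t))
    stop("DCEdata first dimension (", dim(data)[1L],
         ") does not match length(t) (", length(t), ")", call. = FALSE)
  if (length(cp) != length(t))
    stop("Cp length does not match t", call. = FALSE)

  has_maps <- !is.null(vars$R10) && !is.null(vars$S0)
  has_multiflip <- !is.null(vars$T1data) && !is.null(vars$T1flip)
  if (!has_maps && !has_multiflip)
    stop("input must contain either R10/S0 maps or T1data/T1flip ",
         "multiflip data", call. = FALSE)

  tr <- if (!is.null(vars$TR)) as.numeric(vars$TR)[1L] else 0.005
  flip <- if (!is.null(vars$DCEflip)) as.numeric(vars$DCEflip)[1L] else 30
  bundle <- list(
    series = dynamic_series(t, data),
    cp = cp,
    maps = if (has_maps) relaxation_maps(r10 = vars$R10, s0 = vars$S0)
           else NULL,
    multiflip = if (has_multiflip) vars$T1data else NULL,
    t1flip = if (has_multiflip) as.vector(vars$T1flip) else NULL,
    mask = if (!is.null(vars$mask)) vars$mask != 0 else NULL,
    models = if (!is.null(vars$models)) as.integer(vars$models)[1L] else 2L,
    relaxivity = if (!is.null(vars$relaxivity))
      as.numeric(vars$relaxivity)[1L] else 4.5,
    acq = acq_params(tr = tr, flip_deg = flip),
    outfile = if (!is.null(vars$outfile)) as.character(vars$outfile)
              else NULL)
  class(bundle) <- "input_bundle"
  bundle
}

#' Write DCE analysis results to a MAT v5 file
#'
#' Serializes the named result maps (`Ktrans`, `kep`, `ve`, `vp`,
#' `resid`, `modelmap`, `R10`, `S0`, `SER`, `mask`) of a pipeline run.
#' Only maps present in `results` are written.
#'
#' @param results Named list of result maps (see [fit_dce()]).
#' @param path Output MAT path.
#' @return `path`, invisibly.
#' @export
write_output_mat <- function(results, path) {
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("`results` must be a fully named list", call. = FALSE)
  write_mat5(results, path)
}

#' Run the full DCE-MRI analysis pipeline
#'
#' The whole chain on an input bundle: T1/S0 mapping from multiflip data
#' (when supplied; otherwise the provided R10/S0 maps are used), SER
#' computation and automatic masking (unless a mask was supplied), signal
#' inversion to R1(t), conversion to tracer concentration, voxelwise
#' Tofts-Kety fitting of every model in the bitmask, per-voxel model
#' selection by reduced chi-squared, and parameter clamping.
#'
#' @param bundle An `input_bundle` from [read_input_mat()] or built in
#'   code.
#' @param ser_cutoff SER threshold for the automatic mask, default 2.0.
#' @param opts [fit_options()].
#' @param n_workers Workers for voxel loops.
#' @param verbose Print per-stage progress/rates.
#' @return Named list of maps shaped like the spatial grid: `Ktrans`
#'   (1/min), `kep` (1/min), `ve`, `vp`, `resid` (SSR), `modelmap`
#'   (winning model bit), `R10`, `S0`, `SER`, `mask`, plus `fits` (the
#'   per-voxel tibble) and `outfile`.
#' @export
fit_dce <- function(bundle, ser_cutoff = 2.0, opts = fit_options(),
                    n_workers = 1L, verbose = FALSE) {
  stopifnot(inherits(bundle, "input_bundle"))
  say <- function(...) if (verbose) message(...)
  series <- bundle$series
  spatial <- series$spatial_dim

  if (!is.null(bundle$multiflip)) {
    t1acq <- acq_params(tr = bundle$acq$tr, flip_deg = bundle$t1flip)
    mf <- dynamic_series(seq_along(bundle$t1flip) - 1, bundle$multiflip)
    t0 <- proc.time()[["elapsed"]]
    maps <- fit_r1_maps(mf, t1acq, opts = opts, n_workers = n_workers)
    dt_fit <- proc.time()[["elapsed"]] - t0
    say(sprintf("R1 mapping: %d voxels in %.2f s (%.0f vox/s)",
                sum(maps$fitted_mask), dt_fit,
                sum(maps$fitted_mask) / max(dt_fit, 1e-9)))
  } else {
    maps <- bundle$maps
  }

  sermap <- compute_ser(series)
  if (is.null(bundle$mask)) {
    mask <- auto_mask(sermap, cutoff = ser_cutoff)$mask
    say(sprintf("auto mask: %d of %d voxels with SER > %g",
                sum(mask), length(mask), ser_cutoff))
  } else {
    mask <- bundle$mask
  }

  rel <- invert_spgr(series, maps, bundle$acq, s0_from = "map")
  conc <- r1_to_concentration(rel, maps, bundle$relaxivity)
  sel <- which(as.vector(mask))
  curves <- conc$ct[, sel, drop = FALSE]
  mspecs <- models_from_bitmask(bundle$models)
  t0 <- proc.time()[["elapsed"]]
  fits <- lapply(mspecs, function(ms)
    fit_voxels_parallel(curves, ms, conc$t_min, bundle$cp,
                        opts = opts, n_workers = n_workers))
  best <- if (length(fits) > 1L) select_best_model(fits) else {
    f <- fits[[1L]]
    f$model_id <- attr(f, "model_id")
    f$model_bit <- model_spec(attr(f, "model_id"))$bit
    f
  }
  best <- clamp_params(best)
  dt_fit <- proc.time()[["elapsed"]] - t0
  say(sprintf("model fitting: %d voxels in %.2f s (%.1f vox/s)",
              length(sel), dt_fit, length(sel) / max(dt_fit, 1e-9)))

  put <- function(vals) {
    m <- numeric(prod(spatial))
    m[sel] <- vals
    unflatten_spatial(m, spatial)
  }
  list(
    Ktrans = put(best$ktrans), kep = put(best$kep),
    ve = put(best$ve), vp = put(best$vp),
    resid = put(ifelse(is.na(best$ssr), 0, best$ssr)),
    modelmap = put(best$model_bit),
    R10 = maps$r10, S0 = maps$s0, SER = sermap$ser,
    mask = array(as.numeric(mask), dim = dim2(mask)),
    fits = best,
    outfile = bundle$outfile)
}
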