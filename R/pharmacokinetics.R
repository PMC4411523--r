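#' Tofts-Kety model family
#'
#' The three tissue models fitted by the package, selectable singly or in
#' combination through a bitmask (1 = plasma-only, 2 = Standard Tofts-Kety,
#' 4 = Extended Tofts-Kety, OR-combinable).
#'
#' @param id One of `"plasma_only"`, `"standard_tofts"`, `"extended_tofts"`.
#' @return A `model_spec`: list with `id`, `bit`, `param_names`, `n_params`.
#' @export
#' @examples
#' model_spec("standard_tofts")
model_spec <- function(id = c("standard_tofts", "extended_tofts",
                              "plasma_only")) {
  id <- match.arg(id)
  info <- switch(id,
    plasma_only    = list(bit = 1L, param_names = "vp"),
    standard_tofts = list(bit = 2L, param_names = c("ktrans", "kep")),
    extended_tofts = list(bit = 4L, param_names = c("ktrans", "kep", "vp")))
  structure(list(id = id, bit = info$bit, param_names = info$param_names,
                 n_params = length(info$param_names)),
            class = "model_spec")
}

#' Decode a model bitmask into model specs
#'
#' @param bitmask Integer OR of model bits (1 plasma-only, 2 standard,
#'   4 extended), e.g. `6` fits standard and extended.
#' @return List of [model_spec()] objects.
#' @export
models_from_bitmask <- function(bitmask) {
  bitmask <- as.integer(bitmask)
  if (is.na(bitmask) || bitmask < 1L || bitmask > 7L)
    stop("model bitmask must be an integer in 1..7", call. = FALSE)
  ids <- c("plasma_only", "standard_tofts", "extended_tofts")
  out <- list()
  for (k in 1:3)
    if (bitwAnd(bitmask, bitwShiftL(1L, k - 1L)) != 0L)
      out[[length(out) + 1L]] <- model_spec(ids[k])
  out
}

check_grid <- function(t_min, cp) {
  if (length(t_min) != length(cp))
    stop("`t_min` and `cp` must share one grid", call. = FALSE)
  if (length(t_min) >= 2L && any(diff(t_min) <= 0))
    stop("`t_min` must be strictly increasing", call. = FALSE)
  if (t_min[1L] < 0) stop("`t_min` must start at >= 0", call. = FALSE)
}

#' Exponential-kernel convolution of the AIF by the trapezoidal rule
#'
#' Computes \eqn{K(t_i) = \int_0^{t_i} C_p(s) e^{k_{ep}(s - t_i)} ds} by the
#' composite trapezoidal rule on the (possibly non-uniform) acquisition
#' grid, with K(t_1) = 0. Evaluation uses the exact interval recursion
#' \eqn{K_i = e^{-k_{ep}\Delta_i} K_{i-1} + \tfrac{\Delta_i}{2}
#' (C_{p,i-1} e^{-k_{ep}\Delta_i} + C_{p,i})}, which reproduces the direct
#' composite-trapezoid sum bit-for-bit (the kernel factorizes across
#' intervals) while remaining stable for large `kep * t` where the direct
#' form would overflow.
#'
#' @param t_min Strictly increasing time vector in minutes, `t_min[1] >= 0`.
#' @param cp AIF plasma concentration in mM on the same grid.
#' @param kep Efflux rate constant in 1/min, >= 0.
#' @return Vector of K(t) in min*mM, same length as `t_min`.
#' @export
conv_exp_trapz <- function(t_min, cp, kep) {
  check_grid(t_min, cp)
  if (!is.numeric(kep) || length(kep) != 1L || is.na(kep))
    stop("`kep` must be a single number", call. = FALSE)
  n <- length(t_min)
  out <- numeric(n)
  if (n == 1L) return(out)
  dt <- diff(t_min)
  ek <- exp(-kep * dt)
  for (i in 2:n)
    out[i] <- ek[i - 1L] * out[i - 1L] +
      dt[i - 1L] / 2 * (cp[i - 1L] * ek[i - 1L] + cp[i])
  out
}

# trapezoid of Cp(s) (s - t_i) exp(kep (s - t_i)) via the same recursion:
# M_i = e^{-kep d}(M_{i-1} - d K_{i-1}) - d^2/2 Cp_{i-1} e^{-kep d}
conv_exp_trapz_dkep <- function(t_min, cp, kep) {
  n <- length(t_min)
  out <- numeric(n)
  if (n == 1L) return(out)
  dt <- diff(t_min)
  ek <- exp(-kep * dt)
  k <- conv_exp_trapz(t_min, cp, kep)
  for (i in 2:n) {
    d <- dt[i - 1L]
    out[i] <- ek[i - 1L] * (out[i - 1L] - d * k[i - 1L]) -
      d^2 / 2 * cp[i - 1L] * ek[i - 1L]
  }
  out
}

as_pk_params <- function(params, spec) {
  p <- as.list(params)
  if (is.null(names(p)) || any(!nzchar(names(p))))
    names(p) <- spec$param_names[seq_along(p)]
  has_kep <- !is.null(p[["kep"]])
  has_ve <- !is.null(p[["ve"]])
  for (nm in c("ktrans", "kep", "ve", "vp"))
    if (is.null(p[[nm]])) p[[nm]] <- 0
  if (!has_kep && has_ve && p$ve > 0) p$kep <- p$ktrans / p$ve
  if (!has_ve && has_kep)
    p$ve <- if (p$ktrans >= 0 && p$kep > 0) p$ktrans / p$kep else 0
  p
}

#' Predicted tissue concentration under a Tofts-Kety model
#'
#' Extended model: \eqn{C_t(t) = K^{trans} \int_0^t C_p(s)
#' e^{k_{ep}(s-t)} ds + v_p C_p(t)}; the Standard model drops the `vp`
#' term; the plasma-only model sets Ktrans = 0 so \eqn{C_t = v_p C_p}.
#' The integral is evaluated with [conv_exp_trapz()].
#'
#' @param params Named vector/list with the parameters the model uses:
#'   `ktrans` (1/min), `kep` (1/min), `vp`. `ve` may be given instead of
#'   `kep` (then kep = ktrans/ve).
#' @param spec [model_spec()].
#' @param t_min Time in minutes (strictly increasing).
#' @param cp AIF in mM on the same grid.
#' @return Predicted Ct(t) in mM.
#' @export
model_ct <- function(params, spec, t_min, cp) {
  stopifnot(inherits(spec, "model_spec"))
  p <- as_pk_params(params, spec)
  switch(spec$id,
    plasma_only = p$vp * cp,
    standard_tofts = p$ktrans * conv_exp_trapz(t_min, cp, p$kep),
    extended_tofts = p$ktrans * conv_exp_trapz(t_min, cp, p$kep) +
      p$vp * cp)
}

#' Analytic Jacobian of a Tofts-Kety model
#'
#' Partial derivatives of the predicted Ct with respect to the fit
#' parameters, one column per parameter, evaluated with the same
#' trapezoidal quadrature as [model_ct()].
#'
#' In the `"ktrans_kep_vp"` parameterization (the one used for fitting,
#' which conditions better than fitting ve directly):
#' dCt/dKtrans = K(t), dCt/dkep = Ktrans * M(t), dCt/dvp = Cp(t), where
#' K is the convolution integral and M its kep-derivative. In the
#' `"ktrans_ve_vp"` parameterization: dCt/dKtrans = K(t) +
#' (Ktrans/ve) M(t) and dCt/dve = -(Ktrans^2/ve^2) M(t).
#'
#' @inheritParams model_ct
#' @param parameterization `"ktrans_kep_vp"` (default) or `"ktrans_ve_vp"`.
#' @return A `model_eval`: list with `ct_pred` and `jac`
#'   (`length(t_min) x spec$n_params`, columns ordered as the fit
#'   parameters).
#' @export
model_jacobian <- function(params, spec, t_min, cp,
                           parameterization = c("ktrans_kep_vp",
                                                "ktrans_ve_vp")) {
  stopifnot(inherits(spec, "model_spec"))
  parameterization <- match.arg(parameterization)
  p <- as_pk_params(params, spec)
  n <- length(t_min)
  if (spec$id == "plasma_only") {
    jac <- matrix(cp, ncol = 1L, dimnames = list(NULL, "vp"))
    return(structure(list(ct_pred = p$vp * cp, jac = jac),
                     class = "model_eval"))
  }
  if (parameterization == "ktrans_ve_vp") {
    ve <- p$ve
    if (ve <= 0)
      stop("ve must be > 0 under the ktrans_ve_vp parameterization",
           call. = FALSE)
    kep <- p$ktrans / ve
    kk <- conv_exp_trapz(t_min, cp, kep)
    mm <- conv_exp_trapz_dkep(t_min, cp, kep)
    d_ktrans <- kk + (p$ktrans / ve) * mm
    d_ve <- -(p$ktrans^2 / ve^2) * mm
    cols <- cbind(ktrans = d_ktrans, ve = d_ve)
    ct <- p$ktrans * kk
  } else {
    kk <- conv_exp_trapz(t_min, cp, p$kep)
    mm <- conv_exp_trapz_dkep(t_min, cp, p$kep)
    cols <- cbind(ktrans = kk, kep = p$ktrans * mm)
    ct <- p$ktrans * kk
  }
  if (spec$id == "extended_tofts") {
    cols <- cbind(cols, vp = cp)
    ct <- ct + p$vp * cp
  }
  structure(list(ct_pred = ct, jac = cols), class = "model_eval")
}

#' Extravascular extracellular volume fraction from Ktrans and kep
#'
#' ve = Ktrans / kep when kep > 0. When kep = 0 there is no measurable
#' efflux and no estimable ve; the guarded value 0 is returned.
#'
#' @param ktrans Transfer constant in 1/min, >= 0 (vectorized).
#' @param kep Efflux rate constant in 1/min, >= 0 (vectorized).
#' @return ve (dimensionless), same length as the inputs.
#' @export
derive_ve <- function(ktrans, kep) {
  if (any(ktrans < 0, na.rm = TRUE) || any(kep < 0, na.rm = TRUE))
    stop("`ktrans` and `kep` must be non-negative", call. = FALSE)
  ifelse(kep > 0, ktrans / kep, 0)
}
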