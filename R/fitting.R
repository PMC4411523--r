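#' Options for the Levenberg-Marquardt solver
#'
#' @param max_iter Maximum iterations (>= 1).
#' @param lambda0 Initial damping factor.
#' @param tol_g Gradient (infinity-norm) tolerance.
#' @param tol_x Relative step-size tolerance.
#' @param tol_f Relative cost-reduction tolerance.
#' @return A `fit_options` list.
#' @export
fit_options <- function(max_iter = 200L, lambda0 = 1e-3,
                        tol_g = 1e-8, tol_x = 1e-8, tol_f = 1e-8) {
  if (max_iter < 1L) stop("`max_iter` must be >= 1", call. = FALSE)
  if (any(c(lambda0, tol_g, tol_x, tol_f) <= 0))
    stop("damping and tolerances must be > 0", call. = FALSE)
  structure(list(max_iter = as.integer(max_iter), lambda0 = lambda0,
                 tol_g = tol_g, tol_x = tol_x, tol_f = tol_f),
            class = "fit_options")
}

#' Levenberg-Marquardt nonlinear least squares
#'
#' Damped Gauss-Newton iteration on the normal equations
#' `(J'J + lambda diag(J'J)) dx = -J'r`, with the damping multiplied by 10
#' on a rejected step and divided by 10 on an accepted one. Accepted steps
#' never increase the sum of squared residuals. Terminates when the
#' gradient, the relative step, or the relative cost reduction falls below
#' its tolerance, or at `max_iter` (then `converged = FALSE` and the best
#' parameters seen are returned). Fully deterministic. All fitting in this
#' package goes through this routine; no external solver is called.
#'
#' @param residual_fn Function of the parameter vector returning residuals
#'   (model minus data), length N >= length(init).
#' @param jacobian_fn Function of the parameter vector returning the
#'   `N x p` Jacobian of the residuals.
#' @param init Initial parameter vector.
#' @param opts [fit_options()].
#' @return A `fit_result`: list with `params`, `ssr`, `chisq_red`
#'   (= ssr/(N-p)), `n_iter`, `converged`.
#' @export
levmar <- function(residual_fn, jacobian_fn, init, opts = fit_options()) {
  x <- as.numeric(init)
  p <- length(x)
  r <- residual_fn(x)
  n <- length(r)
  if (n < p) stop("need at least as many residuals as parameters",
                  call. = FALSE)
  ssr <- sum(r^2)
  lambda <- opts$lambda0
  converged <- FALSE
  iter <- 0L
  while (iter < opts$max_iter) {
    iter <- iter + 1L
    jac <- jacobian_fn(x)
    g <- crossprod(jac, r)                 # gradient/2
    if (max(abs(g)) < opts$tol_g) { converged <- TRUE; break }
    jtj <- crossprod(jac)
    dd <- diag(jtj)
    dd[dd < .Machine$double.eps] <- .Machine$double.eps
    accepted <- FALSE
    repeat {
      a <- jtj + lambda * diag(dd, nrow = p)
      dx <- tryCatch(solve(a, -g), error = function(e) NULL)
      if (!is.null(dx) && all(is.finite(dx))) {
        x_new <- x + as.vector(dx)
        r_new <- residual_fn(x_new)
        ssr_new <- sum(r_new^2)
        if (is.finite(ssr_new) && ssr_new <= ssr) {
          step_small <- max(abs(dx)) <= opts$tol_x * (opts$tol_x + max(abs(x)))
          f_small <- (ssr - ssr_new) <= opts$tol_f * max(ssr, .Machine$double.eps)
          x <- x_new; r <- r_new; ssr <- ssr_new
          lambda <- max(lambda / 10, 1e-14)
          accepted <- TRUE
          if (step_small || f_small) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e14) break
    }
    if (!accepted) { converged <- TRUE; break }  # no productive step exists
    if (converged) break
  }
  structure(
    list(params = x, ssr = ssr,
         chisq_red = if (n > p) ssr / (n - p) else NA_real_,
         n_iter = iter, converged = converged),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> params =", paste(signif(x$params, 6), collapse = ", "),
      "; ssr =", format(x$ssr), "; iter =", x$n_iter,
      if (x$converged) "(converged)\n" else "(not converged)\n")
  invisible(x)
}

# deterministic indexed parallel map: contiguous chunks, reassembled by
# index, so results are identical for every worker count
run_indexed_parallel <- function(idx, fn, n_workers = 1L) {
  n_workers <- max(1L, as.integer(n_workers))
  if (length(idx) == 0L) return(list())
  if (n_workers == 1L || length(idx) < 2L ||
      .Platform$OS.type == "windows")
    return(lapply(idx, fn))
  chunks <- split(idx, ceiling(seq_along(idx) /
                                 ceiling(length(idx) / n_workers)))
  parts <- parallel::mclapply(chunks, function(ch) lapply(ch, fn),
                              mc.cores = n_workers, mc.preschedule = FALSE)
  do.call(c, unname(parts))
}

#' Fit a Tofts-Kety model to many voxel concentration curves
#'
#' Voxelwise nonlinear least squares of one tissue model against per-voxel
#' concentration curves. Fitting runs in the (Ktrans, kep, vp)
#' parameterization (better conditioned than fitting ve directly); ve is
#' derived afterwards as Ktrans/kep. Voxels are split into contiguous
#' index blocks across workers and reassembled by index, so the result is
#' bit-for-bit identical for every `n_workers`. Curves containing NaN are
#' flagged `skipped` and not fitted.
#'
#' @param curves Numeric matrix, `length(t_min) x n_voxel`, tissue
#'   concentration in mM (one column per voxel).
#' @param spec [model_spec()].
#' @param t_min Time vector in minutes.
#' @param cp AIF in mM on the same grid.
#' @param opts [fit_options()].
#' @param n_workers Worker processes (default 1).
#' @param init Optional initial values, named for the fit parameters;
#'   defaults Ktrans = 0.1 /min, kep = 0.5 /min, vp = 0.01.
#'
#' @return A tibble with one row per voxel: `voxel`, `ktrans`, `kep`,
#'   `ve`, `vp`, `ssr`, `chisq_red`, `n_iter`, `converged`, `skipped`,
#'   carrying the model id in attribute `"model_id"` and class
#'   `dce_fit_tbl`.
#' @export
fit_voxels_parallel <- function(curves, spec, t_min, cp,
                                opts = fit_options(), n_workers = 1L,
                                init = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  check_grid(t_min, cp)
  if (is.null(dim(curves))) curves <- matrix(curves, ncol = 1L)
  if (nrow(curves) != length(t_min))
    stop("curves must have length(t_min) rows", call. = FALSE)
  defaults <- c(ktrans = 0.1, kep = 0.5, vp = 0.01)
  if (!is.null(init)) defaults[names(init)] <- init
  x0 <- unname(defaults[spec$param_names])

  nv <- ncol(curves)
  ok <- unname(!apply(curves, 2L, function(x) any(!is.finite(x))))
  fit_one <- function(j) {
    y <- curves[, j]
    res <- levmar(
      residual_fn = function(p) model_ct(pk_vec(p, spec), spec, t_min, cp) - y,
      jacobian_fn = function(p) model_jacobian(pk_vec(p, spec), spec,
                                               t_min, cp)$jac,
      init = x0, opts = opts)
    res
  }
  fits <- run_indexed_parallel(which(ok), fit_one, n_workers)

  out <- tibble::tibble(
    voxel = seq_len(nv),
    ktrans = 0, kep = 0, ve = 0, vp = 0,
    ssr = NA_real_, chisq_red = NA_real_,
    n_iter = NA_integer_, converged = NA, skipped = !ok)
  if (any(ok)) {
    ii <- which(ok)
    pm <- do.call(rbind, lapply(fits, function(f)
      full_params(f$params, spec)))
    out$ktrans[ii] <- pm[, "ktrans"]
    out$kep[ii] <- pm[, "kep"]
    out$ve[ii] <- pm[, "ve"]
    out$vp[ii] <- pm[, "vp"]
    out$ssr[ii] <- vapply(fits, `[[`, numeric(1), "ssr")
    out$chisq_red[ii] <- vapply(fits, `[[`, numeric(1), "chisq_red")
    out$n_iter[ii] <- vapply(fits, `[[`, integer(1), "n_iter")
    out$converged[ii] <- vapply(fits, `[[`, logical(1), "converged")
  }
  attr(out, "model_id") <- spec$id
  class(out) <- c("dce_fit_tbl", class(out))
  out
}

# raw LM parameter vector -> named vector in model order
pk_vec <- function(p, spec) stats::setNames(p, spec$param_names)

# expand a raw fit vector to the full (ktrans, kep, ve, vp) set
full_params <- function(p, spec) {
  v <- stats::setNames(p, spec$param_names)
  ktrans <- if ("ktrans" %in% names(v)) unname(v["ktrans"]) else 0
  kep <- if ("kep" %in% names(v)) unname(v["kep"]) else 0
  vp <- if ("vp" %in% names(v)) unname(v["vp"]) else 0
  c(ktrans = ktrans, kep = kep,
    ve = derive_ve(max(ktrans, 0), max(kep, 0)), vp = vp)
}
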