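#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a single fit result
#'
#' @param x A `fit_result` from [levmar()].
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.fit_result <- function(x, ...) {
  nms <- names(x$params)
  if (is.null(nms)) nms <- paste0("p", seq_along(x$params))
  tibble::tibble(term = nms, estimate = unname(x$params))
}

#' @rdname tidy.fit_result
#' @return For `glance()`: a one-row tibble with `ssr`, `chisq_red`,
#'   `n_iter`, `converged`.
#' @export
glance.fit_result <- function(x, ...) {
  tibble::tibble(ssr = x$ssr, chisq_red = x$chisq_red,
                 n_iter = x$n_iter, converged = x$converged)
}

#' Tidy a validation report
#'
#' @param x A `dce_validation_report` from [run_validation()].
#' @param ... Unused.
#' @return The per-parameter metrics tibble (`parameter`, `rms_pct`,
#'   `max_pct`, `ccc`, `n`).
#' @export
tidy.dce_validation_report <- function(x, ...) x$metrics

#' @rdname tidy.dce_validation_report
#' @return For `glance()`: one-row tibble of run metadata.
#' @export
glance.dce_validation_report <- function(x, ...) {
  tibble::as_tibble(x$meta[c("layout", "models", "sigma_rel", "n_voxels",
                             "n_time", "elapsed_s",
                             "fit_rate_vox_per_s")])
}
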