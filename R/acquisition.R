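#' Acquisition parameters for a spoiled gradient echo sequence
#'
#' Bundles the repetition time and flip angle(s) of an SPGR acquisition.
#' Flip angles are given in degrees at every public boundary and converted
#' to radians internally, once.
#'
#' @param tr Repetition time in seconds (> 0).
#' @param flip_deg Flip angle(s) in degrees, each in (0, 180). A scalar for
#'   a dynamic series, a vector for a multiflip T1 series.
#' @param te Echo time in seconds (informational only; the signal model
#'   assumes TE << 1/R2*).
#'
#' @return An object of class `acq_params` with elements `tr`, `flip_deg`,
#'   `flip_rad` and `te`.
#' @export
#' @examples
#' acq_params(tr = 0.0079, flip_deg = 20)
acq_params <- function(tr, flip_deg, te = NULL) {
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("`tr` must be a single positive number (seconds)", call. = FALSE)
  if (!is.numeric(flip_deg) || length(flip_deg) < 1L ||
      any(!is.finite(flip_deg)) || any(flip_deg <= 0) || any(flip_deg >= 180))
    stop("`flip_deg` entries must lie in (0, 180) degrees", call. = FALSE)
  structure(
    list(tr = tr, flip_deg = flip_deg, flip_rad = flip_deg * pi / 180,
         te = te),
    class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat("<acq_params> TR =", format(x$tr * 1e3), "ms; flip =",
      paste(format(x$flip_deg), collapse = ", "), "deg\n")
  invisible(x)
}

stopifnot_acq <- function(acq) {
  if (!inherits(acq, "acq_params"))
    stop("`acq` must be created with acq_params()", call. = FALSE)
  acq
}
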