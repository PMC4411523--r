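#' Time-first dynamic series
#'
#' Container for a dynamic acquisition: a time vector in SI seconds and a
#' data array whose *first* dimension is time, over a 0-3 dimensional
#' spatial grid (a single voxel curve, a vector of voxels, or an image).
#'
#' @param t Numeric vector of imaging time points in seconds, non-decreasing.
#' @param data Numeric vector/matrix/array; `dim(data)[1]` (or `length(data)`
#'   for a vector) must equal `length(t)`.
#'
#' @return An object of class `dynamic_series` with elements `t`, `data`,
#'   `n_time` and `spatial_dim`.
#' @export
dynamic_series <- function(t, data) {
  t <- as.numeric(t)
  if (length(t) < 1L || any(!is.finite(t)) || is.unsorted(t))
    stop("`t` must be a finite non-decreasing time vector", call. = FALSE)
  if (is.null(dim(data))) data <- matrix(as.numeric(data), ncol = 1L)
  if (dim(data)[1L] != length(t))
    stop("first dimension of `data` (", dim(data)[1L],
         ") must match length(t) (", length(t), ")", call. = FALSE)
  structure(
    list(t = t, data = data, n_time = length(t),
         spatial_dim = dim(data)[-1L]),
    class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  cat("<dynamic_series>", x$n_time, "time points over a",
      paste(x$spatial_dim, collapse = " x "), "grid;",
      "t in [", format(min(x$t)), ",", format(max(x$t)), "] s\n")
  invisible(x)
}

# time-first array -> time x n_voxel matrix (column-major spatial order)
flatten_time_first <- function(data) {
  d <- dim(data)
  matrix(data, nrow = d[1L], ncol = prod(d[-1L]))
}

# inverse of flatten_time_first for per-voxel (non-time) quantities
unflatten_spatial <- function(x, spatial_dim) {
  if (length(spatial_dim) <= 1L) return(as.vector(x))
  array(x, dim = spatial_dim)
}

as_series_matrix <- function(series) {
  stopifnot(inherits(series, "dynamic_series"))
  flatten_time_first(series$data)
}
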