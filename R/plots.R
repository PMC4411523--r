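#' Plot a spatial parameter map
#'
#' Heatmap of a fitted (or truth) parameter map, e.g. `Ktrans` from
#' [fit_dce()].
#'
#' @param map Numeric matrix (rows x cols).
#' @param name Fill legend label.
#' @return A ggplot object.
#' @export
plot_parameter_map <- function(map, name = "value") {
  stopifnot(is.matrix(map))
  df <- tibble::tibble(
    row = rep(seq_len(nrow(map)), times = ncol(map)),
    col = rep(seq_len(ncol(map)), each = nrow(map)),
    value = as.vector(map))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = name) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Autoplot a validation report
#'
#' Per-region mean absolute relative error of Ktrans, arranged on the
#' phantom's patch grid — the error-map view of a validation run.
#'
#' @param object A `dce_validation_report`.
#' @param parameter `"ktrans"` or `"ve"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.dce_validation_report <- function(object,
                                           parameter = c("ktrans", "ve"),
                                           ...) {
  parameter <- match.arg(parameter)
  errcol <- paste0("mean_abs_err_", parameter)
  truecol <- paste0(parameter, "_true")
  df <- object$region_errors
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$ve_true), y = factor(.data$ktrans_true),
    fill = 100 * .data[[errcol]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "|rel. error| (%)") +
    ggplot2::labs(x = "true ve", y = "true Ktrans (1/min)",
                  title = sprintf("%s recovery error (%s layout, sigma = %g)",
                                  parameter, object$meta$layout,
                                  object$meta$sigma_rel)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an extracted AIF
#'
#' @param aif List with `t` (seconds) and `cp` (mM), as returned by
#'   [extract_aif()].
#' @return A ggplot object.
#' @export
plot_aif <- function(aif) {
  df <- tibble::tibble(t_min = aif$t / 60, cp = aif$cp)
  ggplot2::ggplot(df, ggplot2::aes(.data$t_min, .data$cp)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time (min)", y = "Cp (mM)") +
    ggplot2::theme_minimal()
}
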