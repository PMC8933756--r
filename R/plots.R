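#' Plot an axial slice of a scalar map
#'
#' @param maps a [scalar_maps()] result.
#' @param which map name (`"fa"`, `"md"`, `"ad"`, `"rd"`).
#' @param z 0-based axial slice index.
#' @return a ggplot object.
#' @export
plot_slice <- function(maps, which = "fa", z = 0) {
  stopifnot(inherits(maps, "scalar_maps"))
  m <- maps[[which]][, , z + 1]
  df <- tidyr::expand_grid(x = seq_len(nrow(m)) - 1L,
                           y = seq_len(ncol(m)) - 1L)
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = toupper(which)) +
    ggplot2::labs(x = "x (voxel)", y = "y (voxel)",
                  title = sprintf("%s, axial slice z = %d", toupper(which), z))
}

#' @export
autoplot.alps_measurement <- function(object, ...) {
  df <- tibble::tibble(
    component = factor(c("Dxx proj", "Dxx assoc", "Dyy proj", "Dzz assoc"),
                       levels = c("Dxx proj", "Dxx assoc", "Dyy proj",
                                  "Dzz assoc")),
    role = c("perivascular (x)", "perivascular (x)",
             "perpendicular", "perpendicular"),
    diffusivity = c(object$dxx_proj, object$dxx_assoc,
                    object$dyy_proj, object$dzz_assoc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$diffusivity,
                                   fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::labs(y = "diffusivity (1e-3 mm²/s)", x = NULL,
                  title = sprintf("Perivascular-space index = %.3f",
                                  object$index))
}

#' @export
autoplot.alps_bilateral <- function(object, ...) {
  autoplot(object$hemispheres[[1]], ...) +
    ggplot2::labs(subtitle = sprintf("bilateral mean index = %.3f",
                                     object$index))
}

#' Forest-style plot of the index correlations in a report
#'
#' @param report an `alps_stats_report`.
#' @return a ggplot object.
#' @export
plot_correlations <- function(report) {
  df <- report$fig3_correlations
  df$y <- factor(df$y, levels = rev(unique(df$y)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$y,
                                   color = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "Pearson r with perivascular-space index", y = NULL,
                  color = "p < alpha")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
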