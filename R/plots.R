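# ggplot2 views of the pipeline's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_hline geom_col
#'   geom_histogram geom_raster labs theme_minimal scale_fill_gradient
#'   geom_vline facet_wrap coord_equal
NULL

#' @export
ggplot2::autoplot

#' Plot an FSC curve
#'
#' FSC against spatial frequency with the 0.5 and 0.143 thresholds.
#'
#' @param object an `fsc_curve` from [compute_fsc()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.fsc_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$frequency, y = .data$fsc)) +
    geom_line(linewidth = 0.7) +
    geom_hline(yintercept = c(0.5, 0.143), linetype = "dashed",
               colour = "grey40") +
    labs(x = "spatial frequency (1/Å)", y = "FSC") +
    theme_minimal()
}

#' Histogram of particle tilt angles
#'
#' @param object a `tilt_stats` from [tilt_statistics()].
#' @param binwidth degrees.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.tilt_stats <- function(object, binwidth = 5, ...) {
  ggplot(as_tibble(object), aes(x = .data$tilt)) +
    geom_histogram(binwidth = binwidth, boundary = 0, fill = "steelblue",
                   colour = "white") +
    geom_vline(xintercept = attr(object, "mean"), linetype = "dashed") +
    labs(x = "tilt to membrane normal (deg)", y = "particles") +
    theme_minimal()
}

#' Histogram of nearest-neighbour distances
#'
#' @param object an `nn_stats` from [nn_distances()].
#' @param binwidth Angstrom.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.nn_stats <- function(object, binwidth = 10, ...) {
  ggplot(as_tibble(object), aes(x = .data$nn_dist)) +
    geom_histogram(binwidth = binwidth, boundary = 0, fill = "steelblue",
                   colour = "white") +
    geom_vline(xintercept = attr(object, "min"), linetype = "dashed") +
    labs(x = "nearest-neighbour distance (Å)", y = "particles") +
    theme_minimal()
}

#' Relative-abundance bar chart
#'
#' @param object an `empai_table` with `relative_abundance_pct` (see
#'   [relative_abundance()]).
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.empai_table <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), !is.na(.data$relative_abundance_pct))
  df$protein <- stats::reorder(df$protein, df$relative_abundance_pct)
  ggplot(df, aes(x = .data$relative_abundance_pct, y = .data$protein)) +
    geom_col(fill = "steelblue") +
    labs(x = "relative abundance (%)", y = NULL) +
    theme_minimal()
}

#' Central slice of a density map
#'
#' @param map a [density_map()].
#' @param axis slicing axis (`"x"`, `"y"` or `"z"`).
#' @param index 1-based slice index (default: centre).
#' @return a ggplot raster of the slice (dark = low density).
#' @export
plot_slice <- function(map, axis = c("z", "x", "y"), index = NULL) {
  axis <- match.arg(axis)
  d <- dim(map$grid)
  ai <- match(axis, c("x", "y", "z"))
  if (is.null(index)) index <- ceiling(d[ai] / 2)
  sl <- switch(axis, x = map$grid[index, , ], y = map$grid[, index, ],
               z = map$grid[, , index])
  df <- expand.grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  df$value <- as.numeric(sl)
  ggplot(df, aes(x = .data$i, y = .data$j, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white") +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = "density") +
    theme_minimal()
}

#' @export
tidy.fit_result <- function(x, ...) {
  tibble(term = c("phi", "theta", "psi", "shift_x", "shift_y", "shift_z"),
         estimate = c(x$rotation, x$shift))
}

#' @export
tidy.tilt_stats <- function(x, ...) as_tibble(x)

#' @export
tidy.nn_stats <- function(x, ...) as_tibble(x)
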