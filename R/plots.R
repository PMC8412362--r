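#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of each result type:
#' daily flux traces for a cell, trend-index distributions, change
#' vectors in CWD:AET space, and the bivariate zone scatter. All return
#' a ggplot object for further styling.
#'
#' @param object A result object from this package.
#' @param cell Which cell to draw (daily plots; default: first).
#' @param vars Flux columns to draw (daily plots).
#' @param ... Ignored.
#' @return A ggplot object.
#' @name wb-autoplot
NULL

#' @rdname wb-autoplot
#' @method autoplot wb_daily
#' @export
autoplot.wb_daily <- function(object, cell = NULL,
                              vars = c("swe", "soil_water", "pet",
                                       "aet", "cwd"), ...) {
  cell <- cell %||% object$cell[1]
  x <- object[object$cell == cell, c("date", vars)]
  long <- tidyr::pivot_longer(x, dplyr::all_of(vars),
                              names_to = "flux", values_to = "mm")
  ggplot2::ggplot(long, ggplot2::aes(.data$date, .data$mm,
                                     color = .data$flux)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "mm (state) / mm per day (flux)",
                  title = paste("Daily water balance, cell", cell))
}

#' @rdname wb-autoplot
#' @method autoplot wb_trends
#' @export
autoplot.wb_trends <- function(object, ...) {
  x <- tibble::as_tibble(as.data.frame(object))
  ggplot2::ggplot(x, ggplot2::aes(.data$normalized_index)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~variable, scales = "free") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "normalized change (fraction of mean per decade)",
                  y = "cells")
}

#' @rdname wb-autoplot
#' @method autoplot wb_change_vectors
#' @export
autoplot.wb_change_vectors <- function(object, ...) {
  x <- tibble::as_tibble(as.data.frame(object))
  ggplot2::ggplot(x) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$cwd1, y = .data$aet1,
                   xend = .data$cwd2, yend = .data$aet2,
                   color = .data$direction_class),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::labs(x = "CWD (mm)", y = "AET (mm)",
                  color = "direction",
                  title = "Two-period change vectors in CWD:AET space")
}

#' @rdname wb-autoplot
#' @method autoplot wb_zones
#' @export
autoplot.wb_zones <- function(object, ...) {
  x <- tibble::as_tibble(as.data.frame(object))
  ggplot2::ggplot(x, ggplot2::aes(.data$cwd, .data$aet,
                                  color = .data$zone)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "CWD (mm)", y = "AET (mm)",
                  title = "Equal-count bivariate AET:CWD zones")
}

#' Map a per-cell value on the grid
#'
#' Tile map of any per-cell column, given `row`/`col` (or `x`/`y`)
#' positions, e.g. trend slopes or zone labels joined back to the
#' attribute table.
#'
#' @param x Data frame with `row`, `col` and the value column.
#' @param value Column name to map.
#' @return A ggplot object.
#' @export
plot_cell_map <- function(x, value) {
  stopifnot(all(c("row", "col", value) %in% names(x)))
  ggplot2::ggplot(x, ggplot2::aes(.data$col, -.data$row,
                                  fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = value)
}
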