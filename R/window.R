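#' Rectangular survey window
#'
#' A plot window is the rectangular region (in metres) on which patterns are
#' simulated and networks are built. The default is the 200 m x 200 m survey
#' area used for the null-model batteries; empirical stands are typically
#' 100 m x 100 m.
#'
#' @param width,height Side lengths in metres.
#' @param xmin,ymin Lower-left corner (defaults to the origin).
#' @return A named numeric vector `c(xmin, xmax, ymin, ymax)` of class
#'   `plot_window`.
#' @examples
#' plot_window(200, 200)
#' win_area(plot_window(100, 100))
#' @export
plot_window <- function(width = 200, height = 200, xmin = 0, ymin = 0) {
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0) {
    abort("`width` and `height` must be positive numbers.")
  }
  structure(
    c(xmin = xmin, xmax = xmin + width, ymin = ymin, ymax = ymin + height),
    class = "plot_window"
  )
}

as_plot_window <- function(x) {
  if (inherits(x, "plot_window")) return(x)
  x <- as.numeric(x)
  if (length(x) != 4) abort("A window must be c(xmin, xmax, ymin, ymax).")
  if (x[2] <= x[1] || x[4] <= x[3]) {
    abort("Window must satisfy xmax > xmin and ymax > ymin.")
  }
  structure(setNames(x, c("xmin", "xmax", "ymin", "ymax")), class = "plot_window")
}

#' @rdname plot_window
#' @param window A `plot_window` (or a numeric `c(xmin, xmax, ymin, ymax)`).
#' @export
win_area <- function(window) {
  window <- as_plot_window(window)
  unname((window[2] - window[1]) * (window[4] - window[3]))
}

win_sides <- function(window) {
  window <- as_plot_window(window)
  unname(c(window[2] - window[1], window[4] - window[3]))
}

#' @export
print.plot_window <- function(x, ...) {
  cat(sprintf(
    "<plot_window> [%g, %g] x [%g, %g] m (area %g m^2)\n",
    x[1], x[2], x[3], x[4], win_area(x)
  ))
  invisible(x)
}
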