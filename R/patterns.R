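#' Marked tree patterns
#'
#' A tree pattern is a tibble with one row per tree and columns `id`, `x`,
#' `y` (metres) and optionally `crown_radius` (metres), carrying its survey
#' window and provenance as attributes. All simulators return tree patterns;
#' the network builders accept any data frame with these columns.
#'
#' @param df A data frame with at least `x` and `y` columns.
#' @param window A [plot_window()]; if `NULL` the bounding box of the points
#'   is used (with a warning, since border corrections depend on the window).
#' @param provenance Character tag recording how the pattern arose
#'   (a null-model name or `"empirical"`).
#' @return A tibble of class `tree_pattern`.
#' @export
as_tree_pattern <- function(df, window = NULL, provenance = "empirical") {
  df <- tibble::as_tibble(df)
  if (!all(c("x", "y") %in% names(df))) {
    abort("A tree pattern needs `x` and `y` columns.")
  }
  if (!"id" %in% names(df)) df$id <- seq_len(nrow(df))
  df <- df[, c("id", "x", "y", intersect("crown_radius", names(df)))]
  if (is.null(window)) {
    if (nrow(df) > 0) {
      warn("No window supplied; using the bounding box of the points.")
      window <- as_plot_window(c(min(df$x), max(df$x), min(df$y), max(df$y)))
    } else {
      abort("Cannot infer a window from an empty pattern.")
    }
  }
  window <- as_plot_window(window)
  inside <- df$x >= window[1] & df$x <= window[2] &
    df$y >= window[3] & df$y <= window[4]
  if (!all(inside)) abort("All points must lie inside the window.")
  if ("crown_radius" %in% names(df) &&
      any(!is.na(df$crown_radius) & df$crown_radius <= 0)) {
    abort("`crown_radius` values must be positive.")
  }
  new_tree_pattern(df, window, provenance)
}

new_tree_pattern <- function(df, window, provenance) {
  structure(
    tibble::as_tibble(df),
    window = as_plot_window(window),
    provenance = provenance,
    class = c("tree_pattern", class(tibble::tibble()))
  )
}

#' @rdname as_tree_pattern
#' @param pattern A `tree_pattern`.
#' @export
pattern_window <- function(pattern) {
  w <- attr(pattern, "window", exact = TRUE)
  if (is.null(w)) abort("Pattern carries no window; see `as_tree_pattern()`.")
  as_plot_window(w)
}

#' Estimate the point intensity of a pattern
#'
#' The intensity estimate is the tree count divided by the window area,
#' in trees per square metre. This is how the simulation intensity `kappa`
#' is matched to an empirical stand.
#'
#' @param pattern A `tree_pattern` (or data frame plus explicit `window`).
#' @param window Optional window overriding the pattern's own.
#' @return Estimated intensity (per m^2); 0 with a warning for an empty
#'   pattern.
#' @examples
#' pat <- simulate_pattern("csr", seed = 1)
#' estimate_intensity(pat)
#' @export
estimate_intensity <- function(pattern, window = NULL) {
  window <- if (is.null(window)) pattern_window(pattern) else as_plot_window(window)
  n <- nrow(pattern)
  if (n == 0) {
    warn("Empty pattern; intensity reported as 0.")
    return(0)
  }
  n / win_area(window)
}
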