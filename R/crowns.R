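#' Crown-radius distributions and random labelling
#'
#' Crown radii are attached to simulated points by random labelling:
#' i.i.d. draws from a marginal distribution, independent of tree location.
#' The validation battery uses radii uniform on 2-5 m; empirical stands are
#' matched with a maximum-likelihood gamma fit of their observed radii.
#'
#' @param lo,hi Lower and upper bound in metres, `lo < hi`.
#' @return A list of class `crown_distribution`.
#' @examples
#' crown_uniform(2, 5)
#' crown_gamma(shape = 4, rate = 2)
#' @export
crown_uniform <- function(lo = 2, hi = 5) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi || lo < 0) {
    abort("Need 0 <= lo < hi for a uniform crown distribution.")
  }
  structure(list(kind = "uniform", lo = lo, hi = hi), class = "crown_distribution")
}

#' @rdname crown_uniform
#' @param shape,rate Gamma parameters, both `> 0`.
#' @export
crown_gamma <- function(shape, rate) {
  if (shape <= 0 || rate <= 0) abort("Gamma `shape` and `rate` must be > 0.")
  structure(
    list(kind = "gamma", shape = shape, rate = rate),
    class = "crown_distribution"
  )
}

#' @export
print.crown_distribution <- function(x, ...) {
  if (x$kind == "uniform") {
    cat(sprintf("<crown_distribution> uniform on [%g, %g] m\n", x$lo, x$hi))
  } else {
    cat(sprintf(
      "<crown_distribution> gamma(shape = %.4g, rate = %.4g), mean %.3g m\n",
      x$shape, x$rate, x$shape / x$rate
    ))
  }
  invisible(x)
}

draw_crowns <- function(dist, n) {
  switch(dist$kind,
    uniform = runif(n, dist$lo, dist$hi),
    gamma = rgamma(n, shape = dist$shape, rate = dist$rate)
  )
}

#' Assign crown radii to a pattern (random labelling)
#'
#' @param pattern A tree pattern (see [as_tree_pattern()]).
#' @param dist A [crown_uniform()] or [crown_gamma()] distribution.
#' @param seed Optional integer seed.
#' @return The pattern with a `crown_radius` column; point order unchanged.
#' @examples
#' pat <- simulate_pattern("csr", seed = 1) |> assign_crown_radii(seed = 2)
#' range(pat$crown_radius)
#' @export
assign_crown_radii <- function(pattern, dist = crown_uniform(2, 5), seed = NULL) {
  if (!inherits(dist, "crown_distribution")) {
    abort("`dist` must be a crown_distribution (crown_uniform()/crown_gamma()).")
  }
  if (!is.null(seed)) set.seed(seed)
  out <- pattern
  out$crown_radius <- draw_crowns(dist, nrow(pattern))
  out
}

#' Maximum-likelihood gamma fit of crown radii
#'
#' @param radii Positive crown radii in metres (at least 10).
#' @return A [crown_gamma()] distribution with the fitted parameters.
#' @examples
#' r <- rgamma(500, shape = 4, rate = 2)
#' fit_crown_gamma(r)
#' @export
fit_crown_gamma <- function(radii) {
  radii <- radii[!is.na(radii)]
  if (length(radii) < 10) abort("Need at least 10 crown radii to fit.")
  if (any(radii <= 0)) abort("Crown radii must all be positive.")
  if (diff(range(radii)) < sqrt(.Machine$double.eps)) {
    abort("Crown radii are (nearly) constant; the gamma fit is degenerate.")
  }
  fit <- fitdistrplus::fitdist(as.numeric(radii), "gamma", method = "mle")
  est <- fit$estimate
  crown_gamma(shape = unname(est["shape"]), rate = unname(est["rate"]))
}
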