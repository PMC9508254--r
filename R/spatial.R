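# Second-order point-pattern statistics: Ripley's K, Besag's L, the pair
# correlation function, and Monte-Carlo simulation envelopes.

default_r_grid <- function(window, n = 513) {
  rmax <- min(win_sides(window)) / 4
  seq(0, rmax, length.out = n)
}

# Ordered-pair distances and edge-correction weights for a rectangular
# window. Returns d (ordered pairs, both directions) and w (weight of each
# ordered pair, centred on its first point).
pair_weights <- function(x, y, window, rmax, correction) {
  n <- length(x)
  dmat <- as.matrix(dist(cbind(x, y)))
  up <- which(dmat <= rmax & upper.tri(dmat), arr.ind = TRUE)
  i <- c(up[, 1], up[, 2])
  j <- c(up[, 2], up[, 1])
  d <- dmat[cbind(i, j)]
  w <- switch(correction,
    none = rep(1, length(d)),
    translation = {
      sides <- win_sides(window)
      dx <- abs(x[i] - x[j])
      dy <- abs(y[i] - y[j])
      (sides[1] * sides[2]) / ((sides[1] - dx) * (sides[2] - dy))
    },
    isotropic = iso_weight(x[i], y[i], d, window)
  )
  list(d = d, w = w)
}

# Ripley's isotropic correction in a rectangle: 1 / (fraction of the circle
# of radius d centred on the point that falls inside the window). Edge arcs
# outside each near boundary are removed; arcs double-counted at a corner
# (when d^2 > dl^2 + db^2) are added back.
iso_weight <- function(px, py, d, window) {
  dl <- px - window[1]
  dr <- window[2] - px
  db <- py - window[3]
  dt <- window[4] - py
  edge_arc <- function(de) 2 * acos(pmin(de / d, 1))
  corner_arc <- function(a, b) {
    ifelse(
      a^2 + b^2 < d^2,
      acos(pmin(a / d, 1)) + acos(pmin(b / d, 1)) - pi / 2,
      0
    )
  }
  exterior <- edge_arc(dl) + edge_arc(dr) + edge_arc(db) + edge_arc(dt) -
    corner_arc(dl, db) - corner_arc(dl, dt) -
    corner_arc(dr, db) - corner_arc(dr, dt)
  1 / (1 - exterior / (2 * pi))
}

#' Ripley's K function
#'
#' Estimates `K(r) = |W| / (N (N - 1)) * sum over ordered pairs of
#' e_ij * 1[d_ij <= r]`, where `e_ij` is an edge-correction weight. Under
#' complete spatial randomness `K(r) = pi r^2`. The default correction is
#' Ripley's isotropic correction; `"translation"` and `"none"` are
#' available.
#'
#' @param pattern A tree pattern (at least 2 points) with a window.
#' @param r Ascending distances in metres; default 513 values from 0 to a
#'   quarter of the shorter window side. Values beyond that guideline
#'   trigger a warning, not an error.
#' @param correction `"isotropic"`, `"translation"` or `"none"`.
#' @return A tibble `r`, `theo` (`pi r^2`), `k`.
#' @examples
#' pat <- simulate_pattern("csr", plot_window(100, 100), seed = 1)
#' head(ripley_k(pat))
#' @export
ripley_k <- function(pattern, r = NULL, correction = c("isotropic", "translation", "none")) {
  correction <- match.arg(correction)
  window <- pattern_window(pattern)
  n <- nrow(pattern)
  if (n < 2) abort("Ripley's K needs at least 2 points.")
  if (is.null(r)) r <- default_r_grid(window)
  if (is.unsorted(r) || any(r < 0)) abort("`r` must be ascending and non-negative.")
  guideline <- min(win_sides(window)) / 4
  if (max(r) > guideline * (1 + 1e-9)) {
    warn(sprintf(
      "max(r) = %.3g exceeds the quarter-window guideline (%.3g m); estimates there are unreliable.",
      max(r), guideline
    ))
  }
  pw <- pair_weights(pattern$x, pattern$y, window, max(r), correction)
  ord <- order(pw$d)
  dsort <- pw$d[ord]
  cw <- cumsum(pw$w[ord])
  idx <- findInterval(r, dsort)
  k <- win_area(window) / (n * (n - 1)) * c(0, cw)[idx + 1]
  tibble::tibble(r = r, theo = pi * r^2, k = k)
}

#' Besag's L function
#'
#' `L(r) = sqrt(K(r) / pi)` linearises Ripley's K: under complete spatial
#' randomness `L(r) = r`. The centred variant `L(r) - r` is available with
#' `centered = TRUE`.
#'
#' @param k Output of [ripley_k()] (a tibble with `r` and `k`), or a tree
#'   pattern (K is then estimated first with `...` passed on).
#' @param centered Subtract `r`.
#' @param ... Passed to [ripley_k()] when `k` is a pattern.
#' @return A tibble `r`, `theo`, `l`.
#' @examples
#' besag_l(tibble::tibble(r = 0:3, k = pi * (0:3)^2))
#' @export
besag_l <- function(k, centered = FALSE, ...) {
  if (!is.data.frame(k)) k <- ripley_k(k, ...)
  if (any(k$k < -1e-12)) abort("K values must be non-negative.")
  l <- sqrt(pmax(k$k, 0) / pi)
  theo <- k$r
  if (centered) {
    l <- l - k$r
    theo <- theo - k$r
  }
  tibble::tibble(r = k$r, theo = theo, l = l)
}

#' Pair correlation function
#'
#' Kernel estimator `g(r) = sum over ordered pairs of e_ij * kern_h(r -
#' d_ij) / (2 pi r lambda^2 |W|)` with an Epanechnikov kernel and the same
#' edge corrections as [ripley_k()]; `lambda^2` is estimated as
#' `N (N - 1) / |W|^2`. Under complete spatial randomness `g(r) = 1`;
#' `g > 1` indicates aggregation and `g < 1` regularity at that scale.
#'
#' @inheritParams ripley_k
#' @param bw Epanechnikov half-width in metres; default is Stoyan's rule
#'   `0.15 / sqrt(lambda)`.
#' @return A tibble `r`, `theo` (1), `g`. `r = 0` is excluded from the
#'   default grid (the estimator divides by `r`).
#' @examples
#' pat <- simulate_pattern("csr", plot_window(100, 100), seed = 1)
#' head(pcf(pat))
#' @export
pcf <- function(pattern, r = NULL, bw = NULL,
                correction = c("isotropic", "translation", "none")) {
  correction <- match.arg(correction)
  window <- pattern_window(pattern)
  n <- nrow(pattern)
  if (n < 2) abort("The pair correlation function needs at least 2 points.")
  if (is.null(r)) {
    r <- default_r_grid(window)
    r <- r[r > 0]
  }
  if (any(r <= 0)) abort("`r` must be strictly positive for the pcf.")
  if (is.null(bw)) bw <- 0.15 / sqrt(n / win_area(window))
  if (bw <= 0) abort("`bw` must be positive.")
  pw <- pair_weights(pattern$x, pattern$y, window, max(r) + bw, correction)
  ord <- order(pw$d)
  dsort <- pw$d[ord]
  wsort <- pw$w[ord]
  g <- vapply(r, function(rr) {
    lo <- findInterval(rr - bw, dsort) + 1
    hi <- findInterval(rr + bw, dsort)
    if (hi < lo) return(0)
    t <- (rr - dsort[lo:hi]) / bw
    sum(wsort[lo:hi] * 0.75 * (1 - t^2)) / bw
  }, numeric(1))
  g <- g * win_area(window) / (2 * pi * r * n * (n - 1))
  tibble::tibble(r = r, theo = 1, g = g)
}

#' Monte-Carlo simulation envelopes
#'
#' Simulates `n_sim` patterns under a null model, computes `L(r)` or `g(r)`
#' for each, and returns the pointwise minimum and maximum over the
#' simulations (a rank-1 envelope, exactly the min-max band). With an
#' observed pattern, its curve is returned alongside for comparison;
#' `estimate_kappa = TRUE` re-estimates the null intensity from the
#' observed pattern first.
#'
#' Crown marks play no role in the second-order statistics, so the
#' simulated patterns are unlabelled.
#'
#' @param null A [null_model()] (or model name).
#' @param observed Optional observed tree pattern.
#' @param window Simulation window; defaults to the observed pattern's.
#' @param statistic `"L"` or `"g"`.
#' @param n_sim Number of simulations (default 199).
#' @param seed Optional integer; replicate i uses seed `seed + i`.
#' @param r Distance grid (defaults as in [ripley_k()] / [pcf()]).
#' @param centered For `"L"`: use `L(r) - r`.
#' @param correction Edge correction, as in [ripley_k()].
#' @param estimate_kappa Re-estimate the null `kappa` from `observed`.
#' @return A tibble `r`, `lo`, `hi`, `mean` and (if observed) `observed`,
#'   of class `crownet_envelope`, with the null configuration and `n_sim`
#'   in attributes.
#' @examples
#' env <- mc_envelope("csr", window = plot_window(100, 100),
#'                    statistic = "L", n_sim = 9, seed = 1)
#' head(env)
#' @export
mc_envelope <- function(null, observed = NULL, window = NULL,
                        statistic = c("L", "g"), n_sim = 199, seed = NULL,
                        r = NULL, centered = FALSE,
                        correction = c("isotropic", "translation", "none"),
                        estimate_kappa = FALSE) {
  statistic <- match.arg(statistic)
  correction <- match.arg(correction)
  if (!inherits(null, "null_model")) null <- null_model(null)
  if (n_sim < 1) abort("`n_sim` must be at least 1.")
  if (is.null(window)) {
    if (is.null(observed)) abort("Supply `window` or an observed pattern.")
    window <- pattern_window(observed)
  }
  window <- as_plot_window(window)
  if (estimate_kappa) {
    if (is.null(observed)) abort("`estimate_kappa` needs an observed pattern.")
    null$kappa <- estimate_intensity(observed, window)
  }
  if (is.null(r)) {
    r <- default_r_grid(window)
    if (statistic == "g") r <- r[r > 0]
  }
  stat_fun <- function(pat) {
    if (statistic == "L") {
      besag_l(ripley_k(pat, r = r, correction = correction), centered = centered)$l
    } else {
      pcf(pat, r = r, correction = correction)$g
    }
  }
  sims <- matrix(NA_real_, nrow = length(r), ncol = n_sim)
  for (s in seq_len(n_sim)) {
    pat <- simulate_pattern(null, window, seed = if (is.null(seed)) NULL else seed + s)
    sims[, s] <- stat_fun(pat)
  }
  out <- tibble::tibble(
    r = r,
    lo = apply(sims, 1, min),
    hi = apply(sims, 1, max),
    mean = rowMeans(sims)
  )
  if (!is.null(observed)) out$observed <- stat_fun(observed)
  structure(
    out,
    statistic = statistic, n_sim = n_sim, null_model = null,
    centered = centered,
    class = c("crownet_envelope", class(tibble::tibble()))
  )
}
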