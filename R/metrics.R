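#' Whole-network characteristics
#'
#' Computes the standard bundle of network characteristics for a
#' [build_network()] result: node count `N`, edge count `E`, average node
#' degree `k = 2E/N`, clustering coefficient `C`, density
#' `D = 2E/(N(N-1))` and average shortest-path length `L`. For the directed
#' WCL network, `E` is the directed edge count and `k_weighted` the weighted
#' average degree, while `k`, `C`, `D` and `L` are computed on the
#' undirected skeleton (edge weights play no role in them), so they agree
#' with the CL network built on the same trees.
#'
#' `L` averages shortest-path hop counts over *connected* unordered pairs
#' only, so it stays finite on sparse realizations; the number of connected
#' pairs is reported alongside. An edgeless network yields `L = NA` with a
#' warning.
#'
#' The weighted average degree follows the literal substitution of the
#' summed edge weights for `E` in `k = 2E/N`: `k_weighted =
#' weighted_degree_factor * sum(CI_ij) / N` summed over directed edges, with
#' the factor-2 default; set `weighted_degree_factor = 1` for the
#' directed-sum-only variant.
#'
#' @param net A `competition_network`.
#' @param weighted_degree_factor 2 (default) or 1; see Details.
#' @return A one-row tibble: `net_type`, `N`, `E`, `k`, `C`, `D`, `L`,
#'   `k_weighted` (`NA` for unweighted networks), `n_connected_pairs`.
#' @examples
#' trees <- tibble::tibble(x = runif(50, 0, 50), y = runif(50, 0, 50))
#' network_metrics(build_network(trees, "cs"))
#' @export
network_metrics <- function(net, weighted_degree_factor = 2) {
  g <- skeleton(net)
  n <- igraph::vcount(g)
  e_u <- igraph::ecount(g)
  e <- nrow(net$edges)
  k <- if (n >= 1) 2 * e_u / n else NA_real_
  d <- if (n >= 2) 2 * e_u / (n * (n - 1)) else NA_real_
  cc <- if (n >= 1) clustering_from_graph(g) else NA_real_
  if (e_u > 0) {
    l <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
    comp <- igraph::components(g)
    npairs <- sum(choose(comp$csize, 2))
  } else {
    warn("Network has no edges; average path length is undefined (NA).")
    l <- NA_real_
    npairs <- 0
  }
  kw <- if (net$directed) {
    weighted_degree_factor * sum(net$edges$weight) / n
  } else {
    NA_real_
  }
  tibble::tibble(
    net_type = net$net_type, N = n, E = e, k = k, C = cc, D = d, L = l,
    k_weighted = kw, n_connected_pairs = npairs
  )
}

clustering_from_graph <- function(g) {
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Individual network characteristics
#'
#' Single-metric counterparts of [network_metrics()], each computed on the
#' undirected unweighted skeleton (for the directed WCL network the skeleton
#' is the CL graph).
#'
#' @param net A `competition_network`.
#' @return A scalar.
#' @examples
#' trees <- tibble::tibble(x = c(0, 5, 10), y = 0)
#' net <- build_network(trees, "cs", d_max = 6)
#' net_density(net)
#' net_path_length(net) # path graph: (1 + 1 + 2) / 3
#' @export
net_density <- function(net) {
  g <- skeleton(net)
  n <- igraph::vcount(g)
  if (n < 2) abort("Density is undefined for networks with fewer than 2 nodes.")
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' @rdname net_density
#' @param weighted For [net_average_degree()]: return the weighted average
#'   degree (directed networks only).
#' @param factor Factor applied to the summed weights (see
#'   [network_metrics()]).
#' @export
net_average_degree <- function(net, weighted = FALSE, factor = 2) {
  n <- nrow(net$nodes)
  if (n < 1) abort("Average degree is undefined for an empty network.")
  if (weighted) {
    if (!net$directed) abort("Weighted degree needs a weighted (WCL) network.")
    return(factor * sum(net$edges$weight) / n)
  }
  2 * igraph::ecount(skeleton(net)) / n
}

#' @rdname net_density
#' @export
net_clustering <- function(net) {
  clustering_from_graph(skeleton(net))
}

#' @rdname net_density
#' @param mode `"skeleton"` averages hop counts on the undirected skeleton;
#'   `"directed"` uses directed shortest paths (identical for WCL, where
#'   every edge is mutual).
#' @export
net_path_length <- function(net, mode = c("skeleton", "directed")) {
  mode <- match.arg(mode)
  g <- if (mode == "directed") as_igraph(net) else skeleton(net)
  if (igraph::ecount(g) == 0) abort("Average path length is undefined without edges.")
  igraph::mean_distance(g,
    directed = mode == "directed", unconnected = TRUE,
    weights = NA # hop counts, never the competition-index weights
  )
}

#' Per-node degrees, strengths and betweenness
#'
#' Betweenness is shortest-path betweenness on the undirected unweighted
#' skeleton, unnormalised, with path endpoints excluded. For weighted
#' (WCL) networks `strength` is the sum of incident edge weights
#' (`mode = "total"` counts both exerted and suffered competition,
#' consistent with the factor-2 weighted average degree).
#'
#' @param net A `competition_network`.
#' @param mode Strength mode for directed networks: `"total"`, `"out"`
#'   (competition exerted) or `"in"` (competition suffered).
#' @return A tibble: `id`, `x`, `y`, `crown_radius` (if present), `degree`,
#'   `strength` (`NA` for unweighted networks), `betweenness`.
#' @examples
#' trees <- tibble::tibble(x = c(0, 5, 10), y = 0)
#' node_metrics(build_network(trees, "cs", d_max = 6))
#' @export
node_metrics <- function(net, mode = c("total", "out", "in")) {
  mode <- match.arg(mode)
  g <- skeleton(net)
  ids <- igraph::V(g)$name
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  strength <- if (net$directed) {
    gd <- as_igraph(net)
    igraph::strength(gd, mode = mode)[ids]
  } else {
    rep(NA_real_, length(ids))
  }
  out <- net$nodes[match(ids, as.character(net$nodes$id)), , drop = FALSE]
  out$degree <- unname(deg)
  out$strength <- unname(strength)
  out$betweenness <- unname(btw)
  tibble::as_tibble(out)
}

#' Degree distribution of a network
#'
#' @param net A `competition_network`.
#' @param weighted Use per-node strengths (weighted degrees) instead of
#'   edge counts (directed networks only).
#' @return A tibble `id`, `value` with one row per node.
#' @export
degree_distribution_tbl <- function(net, weighted = FALSE) {
  nm <- node_metrics(net)
  tibble::tibble(
    id = nm$id,
    value = if (weighted) nm$strength else as.numeric(nm$degree)
  )
}

#' Metric identities from printed node/edge counts
#'
#' The average degree and density of an undirected network are functions of
#' the node and edge counts alone: `k = 2E/N`, `D = 2E/(N(N-1))`. This
#' helper reproduces tabulated `k` and `D` values from published `N` and
#' `E`.
#'
#' @param n_nodes,n_edges Undirected node and edge counts.
#' @return A tibble with `N`, `E`, `k`, `D`.
#' @examples
#' counts_to_metrics(271, 1146) # k = 8.458, D = 0.031
#' @export
counts_to_metrics <- function(n_nodes, n_edges) {
  if (any(n_nodes < 2)) abort("Need at least 2 nodes.")
  tibble::tibble(
    N = n_nodes, E = n_edges,
    k = 2 * n_edges / n_nodes,
    D = 2 * n_edges / (n_nodes * (n_nodes - 1))
  )
}

#' Spline-interpolated spatial field of a node metric
#'
#' Fits a thin-plate regression spline (via [mgcv::gam()]) to per-tree
#' metric values and evaluates it on a regular grid over the window,
#' producing the smooth spatial field used to map where competition
#' concentrates in a stand.
#'
#' @param trees A data frame with `x`, `y` columns (e.g. [node_metrics()]
#'   output).
#' @param values Numeric vector of per-tree values (defaults to
#'   `trees$degree` if present).
#' @param window A [plot_window()]; defaults to the pattern's window or the
#'   bounding box.
#' @param spacing Grid spacing in metres (default 2).
#' @param smoothing Optional smoothing parameter `sp` passed to the spline;
#'   `NULL` (default) selects it by generalized cross-validation, `0` gives
#'   (near-)exact interpolation at the tree locations.
#' @param k Spline basis dimension; defaults to `min(n, 50)` (or `n` when
#'   `smoothing = 0`).
#' @param at Optional data frame of `x`, `y` locations to evaluate at
#'   instead of the regular grid.
#' @return A tibble `x`, `y`, `value` of class `crownet_field`.
#' @examples
#' trees <- tibble::tibble(x = runif(30, 0, 50), y = runif(30, 0, 50))
#' fld <- interpolate_metric(trees, trees$x + trees$y, plot_window(50, 50))
#' @export
interpolate_metric <- function(trees, values = NULL, window = NULL,
                               spacing = 2, smoothing = NULL, k = NULL,
                               at = NULL) {
  trees <- tibble::as_tibble(trees)
  if (is.null(values)) {
    if (!"degree" %in% names(trees)) abort("Supply `values` (or a `degree` column).")
    values <- as.numeric(trees$degree)
  }
  n <- nrow(trees)
  if (n < 4) abort("Need at least 4 trees to interpolate.")
  if (qr(cbind(1, trees$x, trees$y))$rank < 3) {
    abort("Tree locations are collinear; the spline surface is degenerate.")
  }
  if (length(values) != n) abort("`values` must have one entry per tree.")
  if (is.null(window)) {
    window <- attr(trees, "window", exact = TRUE) %||%
      c(min(trees$x), max(trees$x), min(trees$y), max(trees$y))
  }
  window <- as_plot_window(window)
  if (is.null(k)) k <- if (!is.null(smoothing) && smoothing == 0) n else min(n, 50)
  k <- min(k, n)
  dat <- data.frame(x = trees$x, y = trees$y, v = values)
  fit <- if (is.null(smoothing)) {
    mgcv::gam(v ~ s(x, y, bs = "tp", k = k), data = dat, method = "GCV.Cp")
  } else {
    mgcv::gam(v ~ s(x, y, bs = "tp", k = k), data = dat, sp = smoothing)
  }
  grid <- if (is.null(at)) {
    expand.grid(
      x = seq(window[1], window[2], by = spacing),
      y = seq(window[3], window[4], by = spacing)
    )
  } else {
    data.frame(x = at$x, y = at$y)
  }
  grid$value <- as.numeric(predict(fit, newdata = grid))
  structure(
    tibble::as_tibble(grid),
    window = window, spacing = spacing,
    class = c("crownet_field", class(tibble::tibble()))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
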