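#' Crown-overlap competition index
#'
#' For two overlapping crowns (disks of radii `r_i`, `r_j` whose treetops are
#' `dist` apart, with `dist < r_i + r_j`) the overlap depth is
#' `R_ij = (r_i + r_j) - dist`, and the directed competition index exerted by
#' tree i on tree j scales that depth by the crown-size ratio:
#' `CI_ij = R_ij * r_i / r_j`, so the larger crown exerts the stronger
#' competition. The two directions satisfy `CI_ij * CI_ji = R_ij^2`.
#'
#' @param r_i,r_j Crown radii in metres, `> 0`.
#' @param dist Treetop distance in metres, `< r_i + r_j`.
#' @return A tibble with columns `overlap` (`R_ij`), `ci_ij`, `ci_ji`.
#'   Vectorised over its arguments.
#' @examples
#' competition_index(3, 2, 4) # overlap 1, ci_ij 1.5, ci_ji 0.667
#' @export
competition_index <- function(r_i, r_j, dist) {
  if (any(r_i <= 0) || any(r_j <= 0)) abort("Crown radii must be positive.")
  if (any(dist >= r_i + r_j)) {
    abort("`dist` must be smaller than r_i + r_j (crowns must overlap).")
  }
  overlap <- (r_i + r_j) - dist
  tibble::tibble(
    overlap = overlap,
    ci_ij = overlap * r_i / r_j,
    ci_ji = overlap * r_j / r_i
  )
}

#' Build a tree competition network
#'
#' Three network definitions are supported, all with individual trees as
#' nodes:
#'
#' * `"cs"` (competition for space): undirected edge whenever the pairwise
#'   treetop distance is strictly less than `d_max` (default 10 m).
#' * `"cl"` (competition for light): undirected edge whenever two crowns
#'   overlap, i.e. the distance is strictly less than the sum of crown radii.
#' * `"wcl"` (weighted competition for light): the CL edges, doubled into
#'   two directed edges weighted by [competition_index()].
#'
#' Boundary ties are not connected (strict inequalities). Coincident
#' treetops are permitted and overlap maximally. Trees without a (positive)
#' crown radius are silently excluded from CL/WCL -- but kept in CS -- and
#' the number dropped is recorded in the result.
#'
#' @param trees A data frame with columns `x`, `y` and, for `"cl"`/`"wcl"`,
#'   `crown_radius`; an `id` column is carried through (row number default).
#' @param type `"cs"`, `"cl"` or `"wcl"`.
#' @param d_max Connection radius in metres for `"cs"`.
#' @return A `competition_network`: a list with `nodes` (tibble), `edges`
#'   (tibble `from`, `to` and, for WCL, `weight`), `net_type`, `directed`
#'   and `n_dropped`.
#' @examples
#' trees <- tibble::tibble(x = c(0, 4, 20), y = 0, crown_radius = c(3, 2, 2))
#' build_network(trees, "cl")$edges
#' @export
build_network <- function(trees, type = c("cs", "cl", "wcl"), d_max = 10) {
  type <- match.arg(type)
  trees <- tibble::as_tibble(trees)
  if (!all(c("x", "y") %in% names(trees))) abort("`trees` needs `x` and `y` columns.")
  if (nrow(trees) < 1) abort("Need at least one tree.")
  if (!is.numeric(d_max) || d_max <= 0) abort("`d_max` must be positive.")
  if (!"id" %in% names(trees)) trees$id <- seq_len(nrow(trees))
  build_one_network(trees, type, d_max)
}

build_one_network <- function(trees, type, d_max, dmat = NULL) {
  n_dropped <- 0L
  if (type %in% c("cl", "wcl")) {
    keep <- if ("crown_radius" %in% names(trees)) {
      !is.na(trees$crown_radius) & trees$crown_radius > 0
    } else {
      rep(FALSE, nrow(trees))
    }
    n_dropped <- sum(!keep)
    if (all(!keep)) {
      warn(sprintf("No trees with crown radii; %s network is empty.", toupper(type)))
    }
    trees <- trees[keep, , drop = FALSE]
    if (!is.null(dmat)) dmat <- dmat[keep, keep, drop = FALSE]
  }
  n <- nrow(trees)
  if (n >= 2) {
    if (is.null(dmat)) dmat <- as.matrix(dist(cbind(trees$x, trees$y)))
    thr <- if (type == "cs") {
      d_max
    } else {
      outer(trees$crown_radius, trees$crown_radius, "+")
    }
    hit <- which(dmat < thr & upper.tri(dmat), arr.ind = TRUE)
    edges <- tibble::tibble(
      from = trees$id[hit[, 1]],
      to = trees$id[hit[, 2]]
    )
  } else {
    edges <- tibble::tibble(from = integer(), to = integer())
  }
  directed <- type == "wcl"
  if (directed) {
    if (nrow(edges) > 0) {
      i <- hit[, 1]
      j <- hit[, 2]
      ci <- competition_index(
        trees$crown_radius[i], trees$crown_radius[j], dmat[hit]
      )
      edges <- tibble::tibble(
        from = c(trees$id[i], trees$id[j]),
        to = c(trees$id[j], trees$id[i]),
        weight = c(ci$ci_ij, ci$ci_ji)
      )
    } else {
      edges$weight <- numeric()
    }
  }
  structure(
    list(
      nodes = trees,
      edges = edges,
      net_type = type,
      directed = directed,
      d_max = if (type == "cs") d_max else NA_real_,
      n_dropped = n_dropped
    ),
    class = "competition_network"
  )
}

# Build several network types from one pattern, computing the distance
# matrix once (CL/WCL subset it to the crowned trees).
build_networks <- function(trees, types, d_max = 10) {
  trees <- tibble::as_tibble(trees)
  if (!"id" %in% names(trees)) trees$id <- seq_len(nrow(trees))
  dmat <- if (nrow(trees) >= 2) as.matrix(dist(cbind(trees$x, trees$y))) else NULL
  setNames(
    lapply(types, function(tp) build_one_network(trees, tp, d_max, dmat = dmat)),
    types
  )
}

#' @export
print.competition_network <- function(x, ...) {
  cat(sprintf(
    "<competition_network> %s: %d nodes, %d %s edges%s\n",
    toupper(x$net_type), nrow(x$nodes), nrow(x$edges),
    if (x$directed) "directed" else "undirected",
    if (x$n_dropped > 0) sprintf(" (%d crownless trees dropped)", x$n_dropped) else ""
  ))
  invisible(x)
}

# igraph view of a network; isolated nodes are kept via the vertex table.
as_igraph <- function(net) {
  nodes <- data.frame(name = as.character(net$nodes$id))
  edges <- data.frame(
    from = as.character(net$edges$from),
    to = as.character(net$edges$to)
  )
  if (net$directed) edges$weight <- net$edges$weight
  igraph::graph_from_data_frame(edges, directed = net$directed, vertices = nodes)
}

# Undirected unweighted skeleton; for WCL this collapses each mutual pair of
# directed edges into one undirected edge, recovering the CL graph.
skeleton <- function(net) {
  g <- as_igraph(net)
  if (net$directed) {
    g <- igraph::as_undirected(g, mode = "collapse", edge.attr.comb = "ignore")
  }
  g
}
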