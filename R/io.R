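# Reading stem maps, and round-trippable writers for patterns and networks.

default_aliases <- function() {
  list(
    id = c("id", "tree_id", "tree", "stem_id"),
    x = c("x", "x_m", "easting", "utm_x"),
    y = c("y", "y_m", "northing", "utm_y"),
    crown_radius = c("crown_radius", "crown_r", "cr", "radius"),
    crown_area = c("crown_area", "crown_area_m2", "ca", "area"),
    plot = c("plot", "plot_id", "plot_label", "plotid")
  )
}

#' Read a stem-map CSV
#'
#' Parses a forest-inventory table with tree coordinates and crown sizes.
#' Column names are matched case-insensitively against an editable alias
#' table (see `aliases`); unknown columns are ignored. When only a crown
#' *area* `A` (m^2) is present, the crown radius is derived from the disk
#' model `R = sqrt(A / pi)`.
#'
#' @param path CSV file path.
#' @param plot Optional plot label; rows are filtered to that plot.
#' @param window Optional [plot_window()] for the resulting pattern; by
#'   default the bounding box of the retained trees is used (with a
#'   warning).
#' @param aliases Named list of accepted column names per canonical field,
#'   merged over [default_aliases()].
#' @return A tree pattern tibble (`id`, `x`, `y`, `crown_radius`).
#' @export
read_stem_map <- function(path, plot = NULL, window = NULL, aliases = list()) {
  al <- utils::modifyList(default_aliases(), aliases)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) {
    warn("Stem map is empty.")
    return(tibble::tibble(
      id = integer(), x = numeric(), y = numeric(), crown_radius = numeric()
    ))
  }
  lower <- tolower(names(raw))
  pick <- function(field) {
    hit <- match(tolower(al[[field]]), lower)
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0) NULL else raw[[hit[1]]]
  }
  x <- pick("x")
  y <- pick("y")
  if (is.null(x)) abort("Stem map lacks an x-coordinate column (tried: x, x_m, easting, utm_x).")
  if (is.null(y)) abort("Stem map lacks a y-coordinate column (tried: y, y_m, northing, utm_y).")
  out <- tibble::tibble(
    id = pick("id") %||% seq_along(x),
    x = as.numeric(x),
    y = as.numeric(y)
  )
  radius <- pick("crown_radius")
  if (is.null(radius)) {
    area <- pick("crown_area")
    if (!is.null(area)) {
      if (any(!is.na(area) & area < 0)) abort("`crown_area` must be non-negative.")
      radius <- sqrt(as.numeric(area) / pi)
    }
  }
  if (!is.null(radius)) {
    radius <- as.numeric(radius)
    radius[!is.na(radius) & radius <= 0] <- NA_real_
    out$crown_radius <- radius
  }
  plot_col <- pick("plot")
  if (!is.null(plot)) {
    if (is.null(plot_col)) abort("No plot-label column found to filter on.")
    out <- out[!is.na(plot_col) & plot_col == plot, , drop = FALSE]
  }
  if (!all(is.finite(out$x)) || !all(is.finite(out$y))) {
    abort("Stem map has non-finite coordinates.")
  }
  as_tree_pattern(out, window = window, provenance = "empirical")
}

#' Write / read a tree pattern as CSV
#'
#' The CSV has columns `id,x,y,crown_radius` (metres, 6 decimals) and a
#' leading comment line `# window xmin xmax ymin ymax` carrying the survey
#' window, so a write-read round trip reproduces the file exactly.
#'
#' @param pattern A tree pattern.
#' @param path File path.
#' @return `write_pattern()` returns `path` invisibly; `read_pattern()`
#'   returns the pattern.
#' @export
write_pattern <- function(pattern, path) {
  w <- pattern_window(pattern)
  num <- function(v) ifelse(is.na(v), "", sprintf("%.6f", v))
  crowns <- if ("crown_radius" %in% names(pattern)) {
    pattern$crown_radius
  } else {
    rep(NA_real_, nrow(pattern))
  }
  lines <- c(
    sprintf("# window %g %g %g %g", w[1], w[2], w[3], w[4]),
    "id,x,y,crown_radius",
    sprintf("%s,%s,%s,%s", pattern$id, num(pattern$x), num(pattern$y), num(crowns))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# window ", first)) {
    abort("Pattern file lacks the `# window xmin xmax ymin ymax` header line.")
  }
  w <- as.numeric(strsplit(sub("^# window ", "", first), " +")[[1]])
  df <- readr::read_csv(
    path,
    comment = "#", show_col_types = FALSE, progress = FALSE
  )
  if (all(is.na(df$crown_radius))) df$crown_radius <- NULL
  as_tree_pattern(df, window = w, provenance = "file")
}

#' Write / read a competition network
#'
#' GraphML keeps everything (node coordinates and crown radii, edge
#' weights, directedness, network type), so a write-read round trip
#' reproduces the network. The plain edge-list CSV (`source,target,weight`)
#' is a convenient export for other tools but loses isolated nodes and node
#' attributes.
#'
#' @param net A `competition_network`.
#' @param path Output path.
#' @param format `"graphml"` or `"edgelist"`; the default follows the file
#'   extension.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   (GraphML only) returns the network.
#' @export
write_network <- function(net, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "edgelist"
  }
  if (!format %in% c("graphml", "edgelist")) {
    abort(sprintf("Unsupported network format `%s`.", format))
  }
  if (format == "edgelist") {
    edges <- net$edges
    if (!"weight" %in% names(edges)) edges$weight <- NA_real_
    names(edges) <- c("source", "target", "weight")
    readr::write_csv(edges, path, progress = FALSE)
    return(invisible(path))
  }
  g <- as_igraph(net)
  nodes <- net$nodes
  ord <- match(igraph::V(g)$name, as.character(nodes$id))
  igraph::V(g)$x <- nodes$x[ord]
  igraph::V(g)$y <- nodes$y[ord]
  if ("crown_radius" %in% names(nodes)) {
    igraph::V(g)$crown_radius <- nodes$crown_radius[ord]
  }
  g <- igraph::set_graph_attr(g, "net_type", net$net_type)
  g <- igraph::set_graph_attr(g, "d_max", net$d_max)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  nodes <- tibble::tibble(
    id = va$name %||% as.character(seq_len(igraph::vcount(g))),
    x = va$x,
    y = va$y
  )
  if (!is.null(va$crown_radius)) nodes$crown_radius <- va$crown_radius
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- tibble::tibble(from = el[, 1], to = el[, 2])
  directed <- igraph::is_directed(g)
  if (directed) edges$weight <- igraph::E(g)$weight
  net_type <- igraph::graph_attr(g, "net_type") %||% if (directed) "wcl" else "cs"
  d_max <- igraph::graph_attr(g, "d_max") %||% NA_real_
  structure(
    list(
      nodes = nodes, edges = edges, net_type = net_type,
      directed = directed, d_max = d_max, n_dropped = 0L
    ),
    class = "competition_network"
  )
}
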