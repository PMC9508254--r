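# Brute-force oracles, deliberately naive and independent of the package's
# vectorised/igraph code paths.

# All-pairs thresholded edges by explicit double loop.
bf_cs_edges <- function(trees, d_max) {
  n <- nrow(trees)
  out <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- sqrt((trees$x[i] - trees$x[j])^2 + (trees$y[i] - trees$y[j])^2)
      if (d < d_max) out <- rbind(out, c(i, j))
    }
  }
  out
}

# A competition_network wrapping an arbitrary undirected graph given by an
# adjacency matrix (dummy coordinates; metrics never use them).
net_from_adj <- function(adj) {
  n <- nrow(adj)
  edges <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  structure(
    list(
      nodes = tibble::tibble(id = seq_len(n), x = seq_len(n), y = 0),
      edges = tibble::tibble(from = edges[, 1], to = edges[, 2]),
      net_type = "cs", directed = FALSE, d_max = NA_real_, n_dropped = 0L
    ),
    class = "competition_network"
  )
}

rand_adj <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  adj
}

# Hop-count shortest paths by Floyd-Warshall.
bf_dist <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

bf_avg_path_length <- function(adj) {
  d <- bf_dist(adj)
  vals <- d[upper.tri(d)]
  mean(vals[is.finite(vals)])
}

bf_clustering <- function(adj) {
  n <- nrow(adj)
  local <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    e <- sum(adj[nb, nb]) / 2
    local[i] <- 2 * e / (k * (k - 1))
  }
  mean(local)
}

# Number-of-shortest-paths matrix, then pair-by-pair betweenness
# (unnormalised, endpoints excluded).
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- bf_dist(adj)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  maxd <- max(d[is.finite(d)])
  for (len in seq_len(max(1, maxd))) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (d[s, t] == len) {
          pred <- which(adj[, t] == 1 & d[s, ] == len - 1)
          sigma[s, t] <- sum(sigma[s, pred])
        }
      }
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s >= t || s == v || t == v) next
        if (!is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  btw
}

# Naive translation-corrected K: explicit double loop, no sorting tricks.
bf_k_translation <- function(pattern, r) {
  w <- pattern_window(pattern)
  a <- w[2] - w[1]
  b <- w[4] - w[3]
  n <- nrow(pattern)
  k <- numeric(length(r))
  for (ri in seq_along(r)) {
    acc <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        dx <- abs(pattern$x[i] - pattern$x[j])
        dy <- abs(pattern$y[i] - pattern$y[j])
        d <- sqrt(dx^2 + dy^2)
        if (d <= r[ri]) acc <- acc + (a * b) / ((a - dx) * (b - dy))
      }
    }
    k[ri] <- acc * (a * b) / (n * (n - 1))
  }
  k
}

# Naive translation-corrected pcf with an Epanechnikov kernel.
bf_pcf_translation <- function(pattern, r, bw) {
  w <- pattern_window(pattern)
  a <- w[2] - w[1]
  b <- w[4] - w[3]
  n <- nrow(pattern)
  g <- numeric(length(r))
  for (ri in seq_along(r)) {
    acc <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        dx <- abs(pattern$x[i] - pattern$x[j])
        dy <- abs(pattern$y[i] - pattern$y[j])
        d <- sqrt(dx^2 + dy^2)
        t <- (r[ri] - d) / bw
        if (abs(t) < 1) {
          acc <- acc + (a * b) / ((a - dx) * (b - dy)) * 0.75 * (1 - t^2) / bw
        }
      }
    }
    g[ri] <- acc * (a * b) / (2 * pi * r[ri] * n * (n - 1))
  }
  g
}

# Deterministic uniform marks for small fixtures.
toy_trees <- function(n, seed, width = 50, height = 50, crowns = TRUE) {
  set.seed(seed)
  out <- tibble::tibble(
    id = seq_len(n),
    x = runif(n, 0, width),
    y = runif(n, 0, height)
  )
  if (crowns) out$crown_radius <- runif(n, 2, 5)
  out
}
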