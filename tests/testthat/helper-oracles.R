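# Independent brute-force oracles and small fixture builders.

# Floyd-Warshall all-pairs shortest paths; independent of the package's
# Dijkstra path (igraph).
fw_distances <- function(nodes, edges) {
  n <- nrow(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes$id, nodes$id))
  diag(D) <- 0
  idx <- stats::setNames(seq_len(n), nodes$id)
  for (k in seq_len(nrow(edges))) {
    i <- idx[as.character(edges$from[k])]
    j <- idx[as.character(edges$to[k])]
    D[i, j] <- min(D[i, j], edges$length[k])
    D[j, i] <- D[i, j]
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# Random weighted graph, possibly disconnected.
random_graph <- function(seed, max_nodes = 25) {
  set.seed(seed)
  n <- sample(3:max_nodes, 1)
  nodes <- data.frame(id = seq_len(n),
                      x = runif(n, 0, 1000), y = runif(n, 0, 1000))
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < 2.5 / n
  if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
  edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                      length = runif(sum(keep), 10, 400))
  list(nodes = nodes, edges = edges,
       network = road_network(nodes, edges))
}

# Path graph with given consecutive edge lengths, laid out on the x axis.
line_network <- function(lengths) {
  n <- length(lengths) + 1
  nodes <- data.frame(id = seq_len(n), x = cumsum(c(0, lengths)), y = 0)
  road_network(nodes, data.frame(from = seq_len(n - 1), to = 2:n,
                                 length = lengths))
}

# Cross/star network: one centre joined to `k` arms of given length.
star_network <- function(k = 4, arm = 100) {
  theta <- 2 * pi * seq_len(k) / k
  nodes <- data.frame(id = seq_len(k + 1),
                      x = c(0, arm * cos(theta)), y = c(0, arm * sin(theta)))
  road_network(nodes, data.frame(from = 1, to = 2:(k + 1), length = arm))
}

# Small random placement instance: geometric graph, random risks, random
# alerts. Used for greedy-vs-exhaustive comparisons.
random_instance <- function(seed, n_cand = 10, n_alerts = 30) {
  set.seed(seed)
  nodes <- data.frame(id = seq_len(n_cand),
                      x = runif(n_cand, 0, 700), y = runif(n_cand, 0, 700))
  edges <- do.call(rbind, lapply(seq_len(n_cand), function(i) {
    d <- sqrt((nodes$x - nodes$x[i])^2 + (nodes$y - nodes$y[i])^2)
    nn <- order(d)[2:3]
    data.frame(from = pmin(i, nn), to = pmax(i, nn))
  }))
  edges <- unique(edges)
  edges$length <- sqrt((nodes$x[edges$from] - nodes$x[edges$to])^2 +
                         (nodes$y[edges$from] - nodes$y[edges$to])^2)
  network <- road_network(nodes, edges)
  candidates <- data.frame(id = seq_len(n_cand), node = nodes$id,
                           x = nodes$x, y = nodes$y,
                           risk = sample(1:9, n_cand, replace = TRUE))
  alerts <- data.frame(id = seq_len(n_alerts),
                       x = runif(n_alerts, -100, 800),
                       y = runif(n_alerts, -100, 800))
  list(network = network, candidates = candidates, alerts = alerts)
}

# Naive double-loop coverage check (Euclidean 300 m).
naive_covered <- function(alerts, aeds, radius = 300) {
  vapply(seq_len(nrow(alerts)), function(i) {
    any(sqrt((aeds$x - alerts$x[i])^2 + (aeds$y - alerts$y[i])^2) <=
          radius + 1e-9)
  }, logical(1))
}

# Memoised full synthetic experiments shared across test files.
.experiment_cache <- new.env(parent = emptyenv())
get_experiment <- function(seed) {
  key <- as.character(seed)
  if (is.null(.experiment_cache[[key]])) {
    .experiment_cache[[key]] <- run_synthetic_experiment(seed = seed)
  }
  .experiment_cache[[key]]
}
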