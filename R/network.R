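# Road-network substrate: construction, intersections, isochrones, distances.

#' Construct a road network
#'
#' Builds an undirected, length-weighted walkable road network from a node
#' table and an edge table. All coordinates are planar metres in a shared
#' local frame (geographic inputs are projected at read time, see
#' [read_layer()]).
#'
#' @param nodes data.frame with columns `id` (integer, unique), `x`, `y`
#'   (metres).
#' @param edges data.frame with columns `from`, `to` (node ids) and `length`
#'   (metres, > 0). Self-loops are rejected.
#' @return An object of class `road_network`: a list with `nodes`, `edges`
#'   and the underlying `igraph` graph (vertex names are node ids, edge
#'   weights are lengths).
#' @examples
#' nodes <- data.frame(id = 1:3, x = c(0, 100, 350), y = 0)
#' net <- road_network(nodes, data.frame(from = c(1, 2), to = c(2, 3),
#'                                       length = c(100, 250)))
#' network_distance(net, 1, 3)
#' @export
road_network <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), all(c("id", "x", "y") %in% names(nodes)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!all(is.finite(nodes$x)) || !all(is.finite(nodes$y))) {
    stop("node coordinates must be finite")
  }
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = integer(), to = integer(), length = numeric())
  }
  stopifnot(all(c("from", "to", "length") %in% names(edges)))
  if (nrow(edges) > 0) {
    if (any(edges$length <= 0)) stop("edge lengths must be > 0")
    if (any(edges$from == edges$to)) stop("self-loop edges are not allowed")
    missing <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(missing) > 0) {
      stop("edges reference unknown nodes: ", paste(missing, collapse = ", "))
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to),
               weight = edges$length),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$id))
  )
  structure(list(nodes = nodes[, c("id", "x", "y")], edges = edges, graph = g),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat("road_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

.check_nodes <- function(network, ids) {
  unknown <- setdiff(ids, network$nodes$id)
  if (length(unknown) > 0) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "))
  }
}

#' Extract candidate AED locations at road intersections
#'
#' A candidate is any node where at least three road segments meet (graph
#' degree >= 3); degree-2 nodes are geometric bends, not intersections.
#' Candidate ids are assigned in ascending node-id order, so the result is
#' invariant under permutation of the edge list.
#'
#' @param network a [road_network()].
#' @return data.frame with columns `id` (candidate id), `node`, `x`, `y`.
#'   An empty network yields zero rows.
#' @export
extract_intersections <- function(network) {
  stopifnot(inherits(network, "road_network"))
  if (nrow(network$nodes) == 0) {
    return(data.frame(id = integer(), node = integer(),
                      x = numeric(), y = numeric()))
  }
  deg <- igraph::degree(network$graph)
  hubs <- sort(as.integer(names(deg)[deg >= 3]))
  idx <- match(hubs, network$nodes$id)
  data.frame(id = seq_along(hubs), node = hubs,
             x = network$nodes$x[idx], y = network$nodes$y[idx],
             row.names = NULL)
}

#' Network shortest-path distance between two nodes
#'
#' @param network a [road_network()].
#' @param u,v node ids.
#' @return Shortest-path length in metres; `Inf` when `u` and `v` lie in
#'   different components. Symmetric in its arguments.
#' @export
network_distance <- function(network, u, v) {
  stopifnot(inherits(network, "road_network"))
  .check_nodes(network, c(u, v))
  as.numeric(igraph::distances(network$graph, v = as.character(u),
                               to = as.character(v))[1, 1])
}

#' Walking-time isochrone around a network node
#'
#' The set of nodes reachable from `origin` within a travel-time budget at a
#' fixed walking speed; the equivalent radius is `budget * speed` metres.
#' The defaults encode a three-minute walk at 1.65 m/s, i.e. 297 m; a
#' five-minute budget (300 s) gives the 495 m decay radius used during
#' placement.
#'
#' @param network a [road_network()].
#' @param origin node id; must exist in the network.
#' @param budget travel-time budget in seconds (> 0).
#' @param speed walking speed in metres/second (> 0).
#' @return An object of class `isochrone`: list with `origin`, `budget`,
#'   `speed`, `radius` (= budget * speed), `reached` (node ids with
#'   shortest-path distance <= radius), `dist` (named distances) and `xy`
#'   (matrix of reached-node coordinates, used for spatial membership).
#' @export
isochrone <- function(network, origin, budget = 180, speed = 1.65) {
  stopifnot(inherits(network, "road_network"), budget > 0, speed > 0)
  .check_nodes(network, origin)
  d <- igraph::distances(network$graph, v = as.character(origin))[1, ]
  radius <- budget * speed
  keep <- d <= radius + 1e-9
  reached <- as.integer(names(d)[keep])
  idx <- match(reached, network$nodes$id)
  structure(list(origin = origin, budget = budget, speed = speed,
                 radius = radius, reached = reached,
                 dist = stats::setNames(as.numeric(d[keep]), reached),
                 origin_xy = c(network$nodes$x[match(origin, network$nodes$id)],
                               network$nodes$y[match(origin, network$nodes$id)]),
                 xy = cbind(x = network$nodes$x[idx], y = network$nodes$y[idx])),
            class = "isochrone")
}

#' @export
print.isochrone <- function(x, ...) {
  cat(sprintf("isochrone: origin %s, %.0f s at %.2f m/s (radius %.1f m), %d nodes reached\n",
              x$origin, x$budget, x$speed, x$radius, length(x$reached)))
  invisible(x)
}

# All-origins distance matrix restricted to candidate nodes; rows/cols named
# by candidate id. Shared by greedy placement and preprocessing.
candidate_distances <- function(network, candidates) {
  D <- igraph::distances(network$graph, v = as.character(candidates$node),
                         to = as.character(candidates$node))
  dimnames(D) <- list(candidates$id, candidates$id)
  D
}

# Reached-node coordinate sets for many candidates in one shortest-path call.
# Returns a list (per candidate, in row order) of coordinate matrices.
reached_coords <- function(network, candidates, budget = 180, speed = 1.65) {
  radius <- budget * speed
  D <- igraph::distances(network$graph, v = as.character(candidates$node))
  node_ids <- as.integer(colnames(D))
  idx <- match(node_ids, network$nodes$id)
  nx <- network$nodes$x[idx]
  ny <- network$nodes$y[idx]
  lapply(seq_len(nrow(D)), function(i) {
    keep <- D[i, ] <= radius + 1e-9
    cbind(x = nx[keep], y = ny[keep])
  })
}

#' Spatial membership test for an isochrone extent
#'
#' The isochrone's spatial extent is defined by its reached network nodes: in
#' `"snap"` mode a point lies inside iff its Euclidean distance to the nearest
#' reached node is at most `snap_tol` metres; `"disc"` mode uses a plain
#' Euclidean disc of the isochrone radius around the origin (useful for tiny
#' or degenerate test networks).
#'
#' @param iso an [isochrone()].
#' @param x,y point coordinates (vectorized).
#' @param mode `"snap"` (default) or `"disc"`.
#' @param snap_tol snap tolerance in metres (default 50).
#' @return logical vector.
#' @export
extent_contains <- function(iso, x, y, mode = c("snap", "disc"), snap_tol = 50) {
  mode <- match.arg(mode)
  stopifnot(inherits(iso, "isochrone"))
  if (length(x) == 0) return(logical(0))
  if (mode == "disc") {
    return(sqrt((x - iso$origin_xy[1])^2 + (y - iso$origin_xy[2])^2) <=
             iso$radius + 1e-9)
  }
  points_near(iso$xy, x, y, snap_tol)
}

# TRUE for points within `tol` metres (Euclidean) of any row of `xy`.
points_near <- function(xy, x, y, tol) {
  if (nrow(xy) == 0 || length(x) == 0) return(rep(FALSE, length(x)))
  res <- rep(FALSE, length(x))
  tol2 <- (tol + 1e-9)^2
  for (j in seq_len(nrow(xy))) {
    res <- res | ((x - xy[j, 1])^2 + (y - xy[j, 2])^2 <= tol2)
  }
  res
}

# Nearest network node (Euclidean) for arbitrary points; returns node ids and
# snap distances. Used to put off-network AEDs and alerts onto the graph.
snap_to_network <- function(network, x, y) {
  stopifnot(inherits(network, "road_network"), nrow(network$nodes) > 0)
  ids <- integer(length(x))
  dist <- numeric(length(x))
  nx <- network$nodes$x
  ny <- network$nodes$y
  for (i in seq_along(x)) {
    d2 <- (nx - x[i])^2 + (ny - y[i])^2
    j <- which.min(d2)
    ids[i] <- network$nodes$id[j]
    dist[i] <- sqrt(d2[j])
  }
  data.frame(node = ids, snap_dist = dist)
}
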