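# Road network, intersections, isochrones, distances, feature aggregation.

test_that("intersections are nodes of degree >= 3, in ascending node order", {
  star <- star_network(k = 3, arm = 100)
  cand <- extract_intersections(star)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$node, 1)

  path <- line_network(c(100, 250))
  expect_equal(nrow(extract_intersections(path)), 0)

  empty <- road_network(data.frame(id = integer(), x = numeric(),
                                   y = numeric()), NULL)
  expect_equal(nrow(extract_intersections(empty)), 0)

  city <- generate_city(city_params(grid_nx = 8, grid_ny = 8, seed = 7))
  cand <- extract_intersections(city$network)
  # independent tally over the raw edge list
  deg <- table(c(city$network$edges$from, city$network$edges$to))
  expect_equal(nrow(cand), sum(deg >= 3))
  expect_true(all(diff(cand$node) > 0))
})

test_that("intersection extraction is invariant under edge-list permutation", {
  g <- random_graph(42, max_nodes = 15)
  set.seed(1)
  perm <- g$edges[sample.int(nrow(g$edges)), ]
  expect_equal(extract_intersections(road_network(g$nodes, perm)),
               extract_intersections(g$network))
})

test_that("network invariants are enforced at construction", {
  nodes <- data.frame(id = 1:2, x = c(0, 1), y = 0)
  expect_error(road_network(nodes, data.frame(from = 1, to = 2, length = 0)),
               "lengths")
  expect_error(road_network(nodes, data.frame(from = 1, to = 1, length = 5)),
               "self-loop")
  expect_error(road_network(nodes, data.frame(from = 1, to = 3, length = 5)),
               "unknown")
})

test_that("isochrone radius is budget times speed and membership follows it", {
  net <- line_network(c(100, 250))
  iso3 <- isochrone(net, 1, budget = 180, speed = 1.65)
  expect_equal(iso3$radius, 297)
  expect_equal(isochrone(net, 1, budget = 300, speed = 1.65)$radius, 495)
  expect_setequal(iso3$reached, c(1, 2))  # 100 <= 297 < 350
  expect_true(1 %in% iso3$reached)        # origin always reached
  expect_error(isochrone(net, 99), "unknown")
})

test_that("isochrone membership is monotone in the budget", {
  for (seed in 1:10) {
    g <- random_graph(seed)
    origin <- g$nodes$id[1]
    r180 <- isochrone(g$network, origin, 180)$reached
    r300 <- isochrone(g$network, origin, 300)$reached
    expect_true(all(r180 %in% r300))
  }
})

test_that("network distances agree with Floyd-Warshall and handle identity", {
  g <- random_graph(11, max_nodes = 20)
  D <- fw_distances(g$nodes, g$edges)
  u <- g$nodes$id[2]; v <- g$nodes$id[nrow(g$nodes)]
  expect_equal(network_distance(g$network, u, u), 0)
  expect_equal(network_distance(g$network, u, v),
               D[as.character(u), as.character(v)])
  expect_equal(network_distance(g$network, u, v),
               network_distance(g$network, v, u))
  expect_error(network_distance(g$network, u, 9999), "unknown")

  two <- road_network(data.frame(id = 1:4, x = c(0, 1, 10, 11), y = 0),
                      data.frame(from = c(1, 3), to = c(2, 4),
                                 length = c(1, 1)))
  expect_identical(network_distance(two, 1, 3), Inf)
})

test_that("feature aggregation matches a direct point-in-extent scan", {
  net <- star_network(k = 4, arm = 100)
  cand <- extract_intersections(net)
  iso <- isochrone(net, cand$node[1])

  expect_equal(sum(aggregate_features(cand[1, ], iso, empty_pop <-
    data.frame(x = numeric(), y = numeric(), persons = numeric(),
               persons_female = numeric()),
    data.frame(x = numeric(), y = numeric(), category = character()))), 0)

  pop <- data.frame(x = 10, y = 0, persons = 10, persons_female = 6)
  f <- aggregate_features(cand[1, ], iso, pop,
                          data.frame(x = 1, y = 1,
                                     category = "public_building"))
  expect_equal(f$population, 10)
  expect_equal(f$sex_ratio, 0.6)
  expect_equal(f$n_public_buildings, 1)

  # brute-force oracle on a synthetic city candidate
  city <- generate_city(city_params(grid_nx = 8, grid_ny = 8, seed = 7))
  tab <- build_feature_table(city$network, city$candidates,
                             city$population, city$pois)
  i <- 1
  iso <- isochrone(city$network, city$candidates$node[i])
  inside <- vapply(seq_len(nrow(city$population)), function(j) {
    min(sqrt((iso$xy[, 1] - city$population$x[j])^2 +
               (iso$xy[, 2] - city$population$y[j])^2)) <= 50 + 1e-9
  }, logical(1))
  expect_equal(tab$population[i], sum(city$population$persons[inside]))
  inside_poi <- vapply(seq_len(nrow(city$pois)), function(j) {
    min(sqrt((iso$xy[, 1] - city$pois$x[j])^2 +
               (iso$xy[, 2] - city$pois$y[j])^2)) <= 50 + 1e-9
  }, logical(1))
  expect_equal(tab$n_parking_spaces[i],
               sum(city$pois$category[inside_poi] == "parking"))
})

test_that("population aggregation is additive over disjoint layers", {
  net <- star_network(k = 4, arm = 100)
  cand <- extract_intersections(net)
  iso <- isochrone(net, cand$node[1])
  set.seed(3)
  mk <- function(n) data.frame(x = runif(n, -150, 150),
                               y = runif(n, -150, 150),
                               persons = rpois(n, 20),
                               persons_female = 0)
  p1 <- mk(40); p2 <- mk(40)
  poi <- data.frame(x = numeric(), y = numeric(), category = character())
  expect_equal(aggregate_features(cand[1, ], iso, rbind(p1, p2), poi)$population,
               aggregate_features(cand[1, ], iso, p1, poi)$population +
                 aggregate_features(cand[1, ], iso, p2, poi)$population)
})

test_that("alert counting uses the same extent rule", {
  net <- star_network(k = 4, arm = 100)
  cand <- extract_intersections(net)
  iso <- isochrone(net, cand$node[1])
  expect_equal(count_alerts(cand[1, ], iso, data.frame(x = numeric(),
                                                       y = numeric())), 0L)
  at_centre <- data.frame(x = 0, y = 0)
  expect_equal(count_alerts(cand[1, ], iso, at_centre), 1L)
  far <- data.frame(x = 5000, y = 5000)
  expect_equal(count_alerts(cand[1, ], iso, far), 0L)
})

test_that("disc-mode extent is a plain Euclidean ball", {
  net <- line_network(c(100, 250))
  iso <- isochrone(net, 1)
  expect_true(extent_contains(iso, 296, 0, mode = "disc"))
  expect_false(extent_contains(iso, 298, 0, mode = "disc"))
})
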