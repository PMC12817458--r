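# Synthetic city: road grid, population hotspots, POIs, planted OHCA alert
# intensity, Poisson-sampled alerts, and a clustered status-quo AED set.

#' Parameters of the synthetic city
#'
#' The defaults describe the study conditions used throughout the package's
#' tests: a jittered 20 x 20 road grid at 150 m spacing (about 400
#' intersection candidates), 60,000 residents concentrated in three
#' Gaussian hotspots, POIs drawn from per-category spatial Poisson processes
#' concentrated near the hotspots, a planted alert intensity dominated by
#' population with positive contributions from public infrastructure, an
#' expected 1,000 alerts over a 5.64-year observation window, and 30
#' installed baseline AEDs clustered near the densest hotspot.
#'
#' @param grid_nx,grid_ny intersections per axis (>= 2 each).
#' @param spacing grid spacing in metres.
#' @param edge_jitter node-position jitter as a fraction of `spacing`.
#' @param pop_hotspots number of Gaussian population hotspots.
#' @param pop_total total residents allocated over tiles.
#' @param tile_spacing population tile spacing in metres.
#' @param poi_rates named vector, expected POIs per square kilometre per
#'   category.
#' @param intensity_weights named feature weights of the planted intensity
#'   (applied to z-scored features; population dominates).
#' @param years observation-window span in years.
#' @param expected_alerts expected total alert count over the window.
#' @param baseline_aeds number of installed status-quo AEDs.
#' @param snap_tol isochrone membership tolerance in metres.
#' @param seed RNG seed.
#' @return list of class `city_params`.
#' @export
city_params <- function(grid_nx = 20, grid_ny = 20, spacing = 150,
                        edge_jitter = 0.1, pop_hotspots = 3,
                        pop_total = 60000, tile_spacing = 75,
                        poi_rates = c(public_building = 3, residential = 8,
                                      industrial = 2, sport = 1.5,
                                      transport = 2, parking = 4),
                        intensity_weights = c(population = 1.5,
                                              n_public_buildings = 0.4,
                                              n_transport_stations = 0.4,
                                              n_sport_facilities = 0.2,
                                              n_parking_spaces = 0.2,
                                              residential_flag = 0.1),
                        years = 5.64, expected_alerts = 1000,
                        baseline_aeds = 30, snap_tol = 50, seed = 1) {
  stopifnot(spacing > 0, pop_total > 0, years > 0,
            all(is.finite(intensity_weights)),
            all(names(poi_rates) %in% POI_CATEGORIES))
  structure(as.list(environment()), class = "city_params")
}

#' Generate a synthetic city
#'
#' Builds a jittered grid road network (interior nodes have degree 4 and so
#' qualify as intersections), allocates the population to a tile grid by a
#' mixture of Gaussian hotspots with a uniform floor, and samples POIs per
#' category from spatial Poisson processes drawn preferentially near the
#' hotspots. Deterministic given `params$seed`.
#'
#' @param params a [city_params()].
#' @return list of class `synthetic_city`: `network`, `population`, `pois`,
#'   `candidates`, `hotspots` (with the densest flagged), `bbox`, `params`.
#' @export
generate_city <- function(params = city_params()) {
  stopifnot(inherits(params, "city_params"))
  if (params$grid_nx < 2 || params$grid_ny < 2) {
    stop("degenerate grid: need at least 2 x 2 intersections")
  }
  set.seed(params$seed)
  nx <- params$grid_nx; ny <- params$grid_ny; s <- params$spacing

  grid <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  n <- nrow(grid)
  jit <- params$edge_jitter * s
  nodes <- data.frame(
    id = seq_len(n),
    x = (grid$i - 1) * s + stats::runif(n, -jit, jit),
    y = (grid$j - 1) * s + stats::runif(n, -jit, jit)
  )
  right <- which(grid$i < nx)
  up <- which(grid$j < ny)
  edges <- rbind(
    data.frame(from = right, to = right + 1),
    data.frame(from = up, to = up + nx)
  )
  edges$length <- sqrt((nodes$x[edges$from] - nodes$x[edges$to])^2 +
                         (nodes$y[edges$from] - nodes$y[edges$to])^2)
  network <- road_network(nodes, edges)

  width <- (nx - 1) * s; height <- (ny - 1) * s
  margin <- s / 2
  bbox <- c(xmin = -margin, ymin = -margin,
            xmax = width + margin, ymax = height + margin)

  k <- params$pop_hotspots
  hotspots <- data.frame(
    x = stats::runif(k, 0.15 * width, 0.85 * width),
    y = stats::runif(k, 0.15 * height, 0.85 * height),
    sigma = stats::runif(k, 300, 600),
    weight = stats::runif(k, 0.5, 1.5)
  )
  # peak density of an isotropic Gaussian component
  hotspots$peak <- hotspots$weight / (2 * pi * hotspots$sigma^2)
  hotspots$densest <- seq_len(k) == which.max(hotspots$peak)

  ts <- params$tile_spacing
  tiles <- expand.grid(x = seq(bbox["xmin"] + ts / 2, bbox["xmax"], by = ts),
                       y = seq(bbox["ymin"] + ts / 2, bbox["ymax"], by = ts))
  w <- rep(0.02, nrow(tiles))
  for (h in seq_len(k)) {
    d2 <- (tiles$x - hotspots$x[h])^2 + (tiles$y - hotspots$y[h])^2
    w <- w + hotspots$weight[h] * exp(-d2 / (2 * hotspots$sigma[h]^2))
  }
  persons <- as.vector(stats::rmultinom(1, params$pop_total, w))
  population <- data.frame(
    x = tiles$x, y = tiles$y, persons = persons,
    persons_female = stats::rbinom(nrow(tiles), persons, 0.51),
    persons_65plus = stats::rbinom(nrow(tiles), persons, 0.21)
  )

  area_km2 <- (bbox["xmax"] - bbox["xmin"]) * (bbox["ymax"] - bbox["ymin"]) / 1e6
  poi_list <- lapply(names(params$poi_rates), function(cat) {
    m <- stats::rpois(1, params$poi_rates[[cat]] * area_km2)
    if (m == 0) return(NULL)
    near_hot <- stats::runif(m) < 0.6
    h <- sample.int(k, m, replace = TRUE, prob = hotspots$weight)
    x <- ifelse(near_hot,
                stats::rnorm(m, hotspots$x[h], hotspots$sigma[h]),
                stats::runif(m, bbox["xmin"], bbox["xmax"]))
    y <- ifelse(near_hot,
                stats::rnorm(m, hotspots$y[h], hotspots$sigma[h]),
                stats::runif(m, bbox["ymin"], bbox["ymax"]))
    data.frame(x = pmin(pmax(x, bbox["xmin"]), bbox["xmax"]),
               y = pmin(pmax(y, bbox["ymin"]), bbox["ymax"]),
               category = cat)
  })
  pois <- do.call(rbind, poi_list)
  if (is.null(pois)) pois <- empty_poi()

  structure(list(network = network, population = population, pois = pois,
                 candidates = extract_intersections(network),
                 hotspots = hotspots, bbox = bbox, params = params),
            class = "synthetic_city")
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat(sprintf("synthetic_city: %d nodes, %d candidates, %d residents, %d POIs\n",
              nrow(x$network$nodes), nrow(x$candidates),
              sum(x$population$persons), nrow(x$pois)))
  invisible(x)
}

#' Plant a per-candidate alert intensity
#'
#' The expected alerts-per-year rate of candidate i is
#' `lambda_i = c * softplus(w . z_i)` where `z_i` are the candidate's
#' z-scored features, `w` the configured weights (population-dominated), and
#' the scale `c` is chosen so the expected total alert count over the
#' observation window equals `expected_total`. Softplus keeps the intensity
#' non-negative while the scaling preserves the ranking. Deterministic.
#'
#' @param features candidate feature table (see [build_feature_table()]).
#' @param weights named feature weights.
#' @param expected_total expected total alert count over the window.
#' @param years observation-window span in years.
#' @return data.frame with `id`, `score` (linear predictor) and `lambda`
#'   (alerts/year).
#' @export
plant_intensity <- function(features, weights, expected_total, years) {
  miss <- setdiff(names(weights), names(features))
  if (length(miss) > 0) stop("weights name unknown features: ",
                             paste(miss, collapse = ", "))
  Z <- sapply(names(weights), function(f) {
    v <- features[[f]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  score <- as.vector(Z %*% weights)
  softplus <- ifelse(score > 30, score, log1p(exp(score)))
  lambda <- softplus * expected_total / (sum(softplus) * years)
  data.frame(id = features$id, score = score, lambda = lambda)
}

#' Sample alert records from a planted intensity
#'
#' Each candidate contributes `Poisson(lambda_i * years)` alerts, scattered
#' uniformly over its 3-minute isochrone extent (a reached node chosen
#' uniformly, plus a uniform offset within the snap tolerance) with
#' timestamps uniform over the observation window.
#'
#' @param intensity a [plant_intensity()] table.
#' @param network a [road_network()].
#' @param candidates candidate table matching `intensity$id`.
#' @param years window span in years.
#' @param seed RNG seed.
#' @param budget,speed,snap_tol isochrone extent parameters.
#' @param start window start date.
#' @return data.frame with `id`, `x`, `y`, `timestamp` (POSIXct, UTC).
#' @export
sample_alerts <- function(intensity, network, candidates, years, seed,
                          budget = 180, speed = 1.65, snap_tol = 50,
                          start = "2018-10-07") {
  stopifnot(nrow(intensity) == nrow(candidates),
            all(intensity$id == candidates$id))
  set.seed(seed)
  counts <- stats::rpois(nrow(intensity), intensity$lambda * years)
  total <- sum(counts)
  if (total == 0) {
    return(data.frame(id = integer(), x = numeric(), y = numeric(),
                      timestamp = as.POSIXct(character(), tz = "UTC")))
  }
  rc <- reached_coords(network, candidates, budget = budget, speed = speed)
  xs <- ys <- numeric(total)
  pos <- 0
  for (i in which(counts > 0)) {
    m <- counts[i]
    xy <- rc[[i]]
    pick <- sample.int(nrow(xy), m, replace = TRUE)
    theta <- stats::runif(m, 0, 2 * pi)
    r <- snap_tol * sqrt(stats::runif(m))
    xs[pos + seq_len(m)] <- xy[pick, 1] + r * cos(theta)
    ys[pos + seq_len(m)] <- xy[pick, 2] + r * sin(theta)
    pos <- pos + m
  }
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  data.frame(id = seq_len(total), x = xs, y = ys,
             timestamp = t0 + sort(stats::runif(total, 0, years * 365.25 * 86400)))
}

#' Place the clustered status-quo baseline AEDs
#'
#' Emulates an unplanned installed base: sites are sampled among candidates
#' with probability decaying with distance from the densest population
#' hotspot, producing a deliberately suboptimal clustered configuration. All
#' sites are flagged as available 24/7.
#'
#' @param candidates candidate table.
#' @param centre numeric `c(x, y)` of the densest hotspot.
#' @param count number of AEDs (`<= nrow(candidates)`).
#' @param seed RNG seed.
#' @param sigma clustering scale in metres (default 300).
#' @return AED data.frame (`id`, `x`, `y`, `node`, `always_available`).
#' @export
place_baseline_aeds <- function(candidates, centre, count, seed, sigma = 300) {
  stopifnot(count >= 0, count <= nrow(candidates), length(centre) == 2)
  if (count == 0) {
    return(data.frame(id = integer(), x = numeric(), y = numeric(),
                      node = integer(), always_available = logical()))
  }
  set.seed(seed)
  d2 <- (candidates$x - centre[1])^2 + (candidates$y - centre[2])^2
  prob <- exp(-d2 / (2 * sigma^2)) + 1e-6
  pick <- sample.int(nrow(candidates), count, prob = prob)
  data.frame(id = seq_len(count), x = candidates$x[pick],
             y = candidates$y[pick], node = candidates$node[pick],
             always_available = TRUE)
}

#' Run the full synthetic experiment
#'
#' Generates a city, plants the alert intensity, samples alerts and the
#' clustered baseline AED set, builds the feature table, screens features,
#' fits the regression-tree risk model, and runs the requested evaluation
#' scenarios. Sub-stages use seeds derived from `seed` by fixed offsets so
#' the whole run is reproducible from one integer.
#'
#' @param seed master seed.
#' @param params a [city_params()]; its `seed` is overridden by `seed`.
#' @param scenarios scenario ids to run (default all six).
#' @param mode coverage rule for evaluation.
#' @return list with `city`, `features` (table incl. alert counts and risk
#'   areas), `intensity`, `alerts`, `existing`, `retained` (screened
#'   features), `model`, `scenarios` (per-id [run_scenario()] results) and
#'   `table` (the [scenario_table()]).
#' @export
run_synthetic_experiment <- function(seed = 1, params = city_params(),
                                     scenarios = c("0", "1", "2", "A", "B", "C"),
                                     mode = "euclidean_300") {
  params$seed <- seed
  city <- generate_city(params)
  base <- build_feature_table(city$network, city$candidates,
                              city$population, city$pois,
                              snap_tol = params$snap_tol)
  intensity <- plant_intensity(base, params$intensity_weights,
                               params$expected_alerts, params$years)
  alerts <- sample_alerts(intensity, city$network, city$candidates,
                          params$years, seed + 1000003L,
                          snap_tol = params$snap_tol)
  features <- build_feature_table(city$network, city$candidates,
                                  city$population, city$pois,
                                  alerts = alerts, years = params$years,
                                  snap_tol = params$snap_tol)
  centre <- unlist(city$hotspots[city$hotspots$densest, c("x", "y")])
  existing <- place_baseline_aeds(city$candidates, centre,
                                  params$baseline_aeds, seed + 2000003L)
  retained <- screen_features(features)
  model <- fit_risk_tree(features, retained, seed = seed)
  results <- lapply(scenarios, function(id) {
    run_scenario(id, city$network, features, alerts, existing,
                 model = model, mode = mode)
  })
  names(results) <- scenarios
  list(city = city, features = features, intensity = intensity,
       alerts = alerts, existing = existing, retained = retained,
       model = model, scenarios = results,
       table = scenario_table(results))
}
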