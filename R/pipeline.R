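# Configuration and end-to-end pipeline orchestration.

# djb2-style 32-bit string hash (exact in doubles); used to stamp outputs
# with the configuration they came from.
hash32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  hash32(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                       digits = NA)))
}

#' Assemble a run configuration
#'
#' Either a synthetic run (default: the [city_params()] study conditions,
#' optionally overridden via `city`) or a real-data run with paths to the
#' five GeoJSON layers and an explicit observation window.
#'
#' @param synthetic generate inputs instead of reading them.
#' @param seed master seed.
#' @param city named list of [city_params()] overrides (synthetic runs).
#' @param paths named list with `network`, `population`, `pois`, `alerts`,
#'   `aeds` (real-data runs).
#' @param window list with `start` and `end` dates (real-data runs).
#' @param scenarios scenario ids to evaluate.
#' @param coverage_mode `"euclidean_300"` or `"network_297"`.
#' @param reduction_constant greedy risk-decay constant.
#' @param snap_tol isochrone membership tolerance (metres).
#' @param out_dir output directory, or `NULL` to skip writing artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(synthetic = TRUE, seed = 1, city = list(),
                       paths = NULL, window = NULL,
                       scenarios = c("0", "1", "2", "A", "B", "C"),
                       coverage_mode = "euclidean_300",
                       reduction_constant = 2, snap_tol = 50,
                       out_dir = NULL) {
  if (!synthetic) {
    need <- c("network", "population", "pois", "alerts", "aeds")
    if (is.null(paths) || !all(need %in% names(paths))) {
      stop("real-data runs need paths for: ", paste(need, collapse = ", "))
    }
    missing <- !vapply(paths[need], file.exists, logical(1))
    if (any(missing)) {
      stop("input file(s) not found: ",
           paste(unlist(paths[need][missing]), collapse = ", "))
    }
    if (is.null(window)) stop("real-data runs need an observation window")
  }
  structure(list(synthetic = synthetic, seed = seed, city = city,
                 paths = paths, window = window, scenarios = scenarios,
                 coverage_mode = coverage_mode,
                 reduction_constant = reduction_constant,
                 snap_tol = snap_tol, out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the full pipeline
#'
#' Chains all stages: input generation or loading, feature aggregation,
#' risk-area binning, feature screening, tree fitting, risk prediction and
#' scenario evaluation. When `config$out_dir` is set, writes the scenario
#' table (CSV), feature table (CSV), model summary (JSON), per-scenario
#' placements (GeoJSON) and a run log (JSON with seed, configuration hash
#' and per-stage timings).
#'
#' @param config a [run_config()] or a path to a YAML configuration.
#' @return invisibly, a list with `table` (scenario table), `model`,
#'   `features`, `scenarios`, `config_hash`, `timings`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(unclass(config))
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e))
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  if (config$synthetic) {
    overrides <- config$city
    if (!"snap_tol" %in% names(overrides)) {
      overrides$snap_tol <- config$snap_tol
    }
    params <- do.call(city_params, overrides)
    exp <- tick("synthetic_experiment",
                run_synthetic_experiment(config$seed, params,
                                         scenarios = config$scenarios,
                                         mode = config$coverage_mode))
    network <- exp$city$network
    features <- exp$features
    model <- exp$model
    results <- exp$scenarios
    alerts <- exp$alerts
  } else {
    network <- tick("read_network", read_layer(config$paths$network, "network"))
    pop <- tick("read_population",
                read_layer(config$paths$population, "population"))
    pois <- tick("read_pois", read_layer(config$paths$pois, "poi"))
    alerts <- tick("read_alerts", read_layer(config$paths$alerts, "alerts"))
    aeds <- tick("read_aeds", read_layer(config$paths$aeds, "aeds"))
    window <- observation_window(config$window$start, config$window$end)
    candidates <- tick("extract_intersections", extract_intersections(network))
    features <- tick("features",
                     build_feature_table(network, candidates, pop, pois,
                                         alerts = alerts,
                                         years = window$years,
                                         snap_tol = config$snap_tol))
    retained <- tick("screen", screen_features(features))
    model <- tick("fit", fit_risk_tree(features, retained, seed = config$seed))
    results <- tick("scenarios", {
      r <- lapply(config$scenarios, function(id) {
        run_scenario(id, network, features, alerts, aeds, model = model,
                     mode = config$coverage_mode,
                     reduction_constant = config$reduction_constant)
      })
      names(r) <- config$scenarios
      r
    })
  }
  table <- scenario_table(results)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table, file.path(config$out_dir, "scenario_table.csv"),
                     row.names = FALSE)
    utils::write.csv(features, file.path(config$out_dir, "features.csv"),
                     row.names = FALSE)
    write_risk_model_json(model, file.path(config$out_dir, "model.json"))
    for (id in names(results)) {
      if (!is.null(results[[id]]$placement)) {
        write_placement_geojson(
          results[[id]]$placement,
          file.path(config$out_dir, paste0("placement_", id, ".geojson")))
      }
    }
    jsonlite::write_json(
      list(seed = config$seed, config_hash = hash,
           r_version = as.character(getRversion()),
           n_alerts = nrow(alerts), timings_s = as.list(timings)),
      file.path(config$out_dir, "run_log.json"),
      auto_unbox = TRUE, digits = NA)
  }

  invisible(list(table = table, model = model, features = features,
                 scenarios = results, config_hash = hash,
                 timings = timings))
}
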