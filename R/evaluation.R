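# Coverage metric and the scenario engine.

.available_aeds <- function(aeds) {
  if (is.null(aeds)) return(NULL)
  if ("always_available" %in% names(aeds)) {
    aeds <- aeds[as.logical(aeds$always_available), , drop = FALSE]
  }
  aeds
}

# Logical matrix [alert, aed]: TRUE when the AED covers the alert.
.coverage_matrix <- function(alerts, aeds, network, mode,
                             radius_euclid = 300, radius_network = 297) {
  mode <- match.arg(mode, c("euclidean_300", "network_297"))
  n_a <- nrow(alerts)
  n_d <- if (is.null(aeds)) 0 else nrow(aeds)
  if (n_d == 0) return(matrix(FALSE, n_a, 0))
  if (mode == "euclidean_300") {
    M <- matrix(FALSE, n_a, n_d)
    for (j in seq_len(n_d)) {
      M[, j] <- sqrt((alerts$x - aeds$x[j])^2 + (alerts$y - aeds$y[j])^2) <=
        radius_euclid + 1e-9
    }
    return(M)
  }
  if (is.null(network)) stop("network_297 mode requires a road network")
  if (!"node" %in% names(aeds) || any(is.na(aeds$node))) {
    aeds$node <- snap_to_network(network, aeds$x, aeds$y)$node
  }
  alert_nodes <- snap_to_network(network, alerts$x, alerts$y)$node
  D <- igraph::distances(network$graph,
                         v = as.character(unique(alert_nodes)),
                         to = as.character(unique(aeds$node)))
  D[match(as.character(alert_nodes), rownames(D)),
    match(as.character(aeds$node), colnames(D)), drop = FALSE] <=
    radius_network + 1e-9
}

#' Is an alert covered by an AED?
#'
#' An alert counts as covered when an always-available AED lies within 300 m
#' straight-line distance (`"euclidean_300"`, the default validation rule)
#' or within 297 m network walking distance of the alert's nearest road
#' node (`"network_297"`, a three-minute walk at 1.65 m/s).
#'
#' @param alerts alert points (`x`, `y`); vectorized over rows.
#' @param aeds AED table (`x`, `y`, optional `node`, `always_available`).
#' @param network a [road_network()]; required for `"network_297"`.
#' @param mode `"euclidean_300"` or `"network_297"`.
#' @return logical vector, one element per alert.
#' @export
is_covered <- function(alerts, aeds, network = NULL,
                       mode = c("euclidean_300", "network_297")) {
  mode <- match.arg(mode)
  aeds <- .available_aeds(aeds)
  M <- .coverage_matrix(alerts, aeds, network, mode)
  if (ncol(M) == 0) return(rep(FALSE, nrow(alerts)))
  rowSums(M) > 0
}

#' Alert coverage report
#'
#' @inheritParams is_covered
#' @return object of class `coverage_report`: `n_alerts`, `n_covered` and
#'   `percent` (100 x covered / total, rounded to one decimal).
#' @examples
#' alerts <- data.frame(x = c(0, 1000), y = 0)
#' coverage(alerts, data.frame(x = 0, y = 0, always_available = TRUE))
#' @export
coverage <- function(alerts, aeds, network = NULL,
                     mode = c("euclidean_300", "network_297")) {
  if (is.null(alerts) || nrow(alerts) == 0) {
    stop("coverage is undefined for an empty alert set")
  }
  flags <- is_covered(alerts, aeds, network, mode)
  structure(list(n_alerts = nrow(alerts), n_covered = sum(flags),
                 percent = round(100 * sum(flags) / nrow(alerts), 1)),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("coverage: %d / %d alerts (%.1f%%)\n",
              x$n_covered, x$n_alerts, x$percent))
  invisible(x)
}

#' Scenario specification
#'
#' The six evaluation configurations. Scenario 0 is the status quo
#' (installed AEDs only). Scenarios 1 and 2 ignore the installed devices and
#' place the same number afresh, prioritized by the model-predicted (1) or
#' the historically observed (2) risk; their coverage counts only the newly
#' placed set, for a fair comparison with the status quo. Scenarios A, B and
#' C keep the installed devices (candidates are pre-processed against them)
#' and add model-prioritized AEDs: a 20% fleet increase (A), or placements
#' until risk area 5 (B) or 3 (C) is exhausted; coverage is evaluated on the
#' union.
#'
#' @param id one of `"0"`, `"1"`, `"2"`, `"A"`, `"B"`, `"C"`.
#' @return object of class `scenario_spec` with `id`, `consider_installed`,
#'   `termination` (`"n_installed"`, `"fleet_increase"`, a [termination()]
#'   or `NULL`) and `risk_source` (`"model"`, `"historical"` or `"none"`).
#' @export
scenario_spec <- function(id) {
  id <- as.character(id)
  spec <- switch(id,
    "0" = list(consider_installed = TRUE, termination = NULL,
               risk_source = "none"),
    "1" = list(consider_installed = FALSE, termination = "n_installed",
               risk_source = "model"),
    "2" = list(consider_installed = FALSE, termination = "n_installed",
               risk_source = "historical"),
    "A" = list(consider_installed = TRUE, termination = "fleet_increase",
               risk_source = "model"),
    "B" = list(consider_installed = TRUE,
               termination = termination("risk_threshold", min_risk = 5),
               risk_source = "model"),
    "C" = list(consider_installed = TRUE,
               termination = termination("risk_threshold", min_risk = 3),
               risk_source = "model"),
    stop("unknown scenario id: ", id)
  )
  structure(c(list(id = id), spec), class = "scenario_spec")
}

#' Run one evaluation scenario
#'
#' @param spec a [scenario_spec()] (or an id accepted by it).
#' @param network a [road_network()].
#' @param candidates feature table from [build_feature_table()] including
#'   the empirical `rate` column.
#' @param alerts historical alert points used for coverage validation.
#' @param existing installed AED table (only 24/7-available devices count).
#' @param model a fitted [fit_risk_tree()] model (required when the
#'   scenario's risk source is the model).
#' @param mode coverage rule, see [is_covered()].
#' @param reduction_constant risk-decay constant (default 2).
#' @param fleet_increase fractional fleet increase for scenario A
#'   (default 0.2).
#' @param n_override optional device count overriding the
#'   installed-fleet-derived count for scenarios 1/2/A.
#' @return list with `id`, `placement` (a `placement_result` or `NULL`),
#'   `coverage` (a `coverage_report`), `n_new` and `n_aeds` (devices whose
#'   coverage was evaluated).
#' @export
run_scenario <- function(spec, network, candidates, alerts, existing,
                         model = NULL, mode = "euclidean_300",
                         reduction_constant = 2, fleet_increase = 0.2,
                         n_override = NULL) {
  if (!inherits(spec, "scenario_spec")) spec <- scenario_spec(spec)
  existing <- .available_aeds(existing)
  n_installed <- if (is.null(existing)) 0L else nrow(existing)

  if (spec$risk_source == "none") {
    cov <- coverage(alerts, existing, network, mode)
    return(list(id = spec$id, placement = NULL, coverage = cov,
                n_new = 0L, n_aeds = n_installed))
  }

  cand <- candidates
  if (spec$risk_source == "model") {
    if (is.null(model)) stop("scenario ", spec$id, " requires a fitted model")
    cand$risk <- predict_risk(model, cand)
    cand$score <- predict_risk(model, cand, raw = TRUE)
  } else {
    if (!"rate" %in% names(cand)) {
      stop("historical risk source requires a 'rate' column")
    }
    cand$risk <- bin_risk_area(cand$rate)
    cand$score <- cand$rate
  }

  term <- spec$termination
  if (identical(term, "n_installed")) {
    n <- if (!is.null(n_override)) n_override else n_installed
    if (n < 1) stop("scenario ", spec$id, " needs at least one device to place")
    term <- termination("count", n = n)
  } else if (identical(term, "fleet_increase")) {
    n <- if (!is.null(n_override)) n_override
         else max(1L, round(fleet_increase * n_installed))
    term <- termination("count", n = n)
  }

  if (spec$consider_installed && n_installed > 0) {
    pre <- preprocess_existing(cand, existing, network,
                               reduction_constant = reduction_constant)
    cand <- pre$candidates
  }

  placement <- greedy_place(cand, network, term,
                            reduction_constant = reduction_constant)
  new_aeds <- placement_as_aeds(placement)
  eval_set <- if (spec$consider_installed && n_installed > 0) {
    rbind(existing[, c("x", "y", "always_available")],
          new_aeds[, c("x", "y", "always_available")])
  } else {
    new_aeds[, c("x", "y", "always_available")]
  }
  cov <- coverage(alerts, eval_set, network, mode)
  list(id = spec$id, placement = placement, coverage = cov,
       n_new = nrow(new_aeds), n_aeds = nrow(eval_set))
}

#' Tabulate scenario results
#'
#' @param results list of [run_scenario()] results.
#' @return data.frame with columns `scenario`, `n_aeds`, `n_covered`,
#'   `n_alerts`, `percent`.
#' @export
scenario_table <- function(results) {
  stopifnot(length(results) >= 1)
  do.call(rbind, lapply(results, function(r) {
    data.frame(scenario = r$id, n_aeds = r$n_aeds,
               n_covered = r$coverage$n_covered,
               n_alerts = r$coverage$n_alerts,
               percent = r$coverage$percent)
  }))
}
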