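# Greedy prioritization of AED placements with isochrone removal and decay.

#' Termination rule for greedy placement
#'
#' Exactly one criterion is active: stop after `n` devices (`"count"`), or
#' stop once no remaining candidate has a current risk level at or above
#' `min_risk` (`"risk_threshold"`).
#'
#' @param mode `"count"` or `"risk_threshold"`.
#' @param n device count (count mode).
#' @param min_risk minimum risk level 1..9 (risk-threshold mode).
#' @return object of class `termination`.
#' @export
termination <- function(mode = c("count", "risk_threshold"), n = NULL,
                        min_risk = NULL) {
  mode <- match.arg(mode)
  if (mode == "count") {
    if (is.null(n) || n < 1 || !is.null(min_risk)) {
      stop("count termination requires n >= 1 and no min_risk")
    }
  } else {
    if (is.null(min_risk) || !is.null(n) || min_risk < 1 || min_risk > 9) {
      stop("risk_threshold termination requires min_risk in 1..9 and no n")
    }
  }
  structure(list(mode = mode, n = n, min_risk = min_risk),
            class = "termination")
}

.require_risk <- function(candidates) {
  if (!"risk" %in% names(candidates) || any(is.na(candidates$risk))) {
    stop("every candidate must carry a risk level")
  }
  if (any(candidates$risk < 1 | candidates$risk > 9)) {
    stop("risk levels must lie in 1..9")
  }
}

#' Pre-process candidates against already-installed AEDs
#'
#' Candidates within the 3-minute isochrone (297 m network distance by
#' default) of any installed, 24/7-available AED are removed; remaining
#' candidates within the 5-minute isochrone (495 m) have their risk level
#' reduced by `reduction_constant`, floored at level 1. AEDs located off the
#' network are snapped to their nearest node (snap distances are logged).
#'
#' @param candidates candidate table with `id`, `node` and `risk` columns.
#' @param existing installed AED table (`x`, `y`, optional `node`,
#'   `always_available`); sites without 24/7 availability are ignored.
#' @param network a [road_network()].
#' @param reduction_constant integer risk decay (default 2).
#' @param radius_remove,radius_decay metres (defaults 297 and 495).
#' @return list with `candidates` (the surviving, possibly decayed table)
#'   and `log` (data.frame of removals/decays with distances).
#' @export
preprocess_existing <- function(candidates, existing, network,
                                reduction_constant = 2,
                                radius_remove = 297, radius_decay = 495) {
  .require_risk(candidates)
  existing <- .available_aeds(existing)
  if (is.null(existing) || nrow(existing) == 0) {
    return(list(candidates = candidates,
                log = data.frame(id = integer(), action = character(),
                                 before = integer(), after = integer(),
                                 dist = numeric())))
  }
  if (!"node" %in% names(existing) || any(is.na(existing$node))) {
    snap <- snap_to_network(network, existing$x, existing$y)
    existing$node <- snap$node
    existing$snap_dist <- snap$snap_dist
  }
  D <- igraph::distances(network$graph, v = as.character(candidates$node),
                         to = as.character(unique(existing$node)))
  dmin <- apply(D, 1, min)
  remove <- dmin <= radius_remove + 1e-9
  decay <- !remove & dmin <= radius_decay + 1e-9
  log <- rbind(
    if (any(remove)) data.frame(id = candidates$id[remove],
                                action = "removed",
                                before = candidates$risk[remove],
                                after = NA_integer_,
                                dist = dmin[remove]),
    if (any(decay)) data.frame(id = candidates$id[decay],
                               action = "decayed",
                               before = candidates$risk[decay],
                               after = pmax(1L, candidates$risk[decay] -
                                              as.integer(reduction_constant)),
                               dist = dmin[decay])
  )
  if (is.null(log)) {
    log <- data.frame(id = integer(), action = character(),
                      before = integer(), after = integer(), dist = numeric())
  }
  candidates$risk[decay] <- pmax(1L, candidates$risk[decay] -
                                   as.integer(reduction_constant))
  list(candidates = candidates[!remove, , drop = FALSE], log = log)
}

#' Greedy AED placement
#'
#' Iteratively selects the remaining candidate with the highest current risk
#' level (ties broken by the larger raw risk `score` when present, then by
#' the smallest candidate id), removes all remaining candidates within the
#' 3-minute isochrone of the selection (297 m network distance), and reduces
#' by `reduction_constant` (floored at level 1) the risk of those within the
#' 5-minute isochrone (495 m). Stops when the termination criterion is met
#' or no candidates remain. Deterministic.
#'
#' @param candidates candidate table with `id`, `node`, `x`, `y`, `risk`
#'   (integer 1..9) and optionally `score` (raw model output or empirical
#'   rate, used only for tie-breaking).
#' @param network a [road_network()].
#' @param termination a [termination()] rule.
#' @param reduction_constant integer risk decay per iteration (default 2).
#' @param radius_remove,radius_decay metres (defaults 297 = 180 s x 1.65 m/s
#'   and 495 = 300 s x 1.65 m/s).
#' @return object of class `placement_result`: `selected` (ordered
#'   data.frame with `iteration` and `risk_at_selection`), `log` (list of
#'   per-iteration records: chosen id, removed ids, decayed ids with
#'   before/after levels) and `reduction_constant`.
#' @export
greedy_place <- function(candidates, network, termination,
                         reduction_constant = 2,
                         radius_remove = 297, radius_decay = 495) {
  stopifnot(inherits(termination, "termination"), reduction_constant >= 0)
  .require_risk(candidates)
  k <- as.integer(reduction_constant)
  cand <- candidates
  cand$score <- if ("score" %in% names(cand)) cand$score else NA_real_
  D <- candidate_distances(network, cand)
  risk <- as.integer(cand$risk)
  alive <- rep(TRUE, nrow(cand))
  selected <- integer()
  risk_at_sel <- integer()
  log <- list()

  repeat {
    if (termination$mode == "count" && length(selected) >= termination$n) break
    if (!any(alive)) {
      if (termination$mode == "count" && length(selected) < termination$n) {
        warning("ran out of placeable candidates before reaching n = ",
                termination$n)
      }
      break
    }
    pool <- which(alive)
    if (termination$mode == "risk_threshold" &&
        max(risk[pool]) < termination$min_risk) break
    top <- pool[risk[pool] == max(risk[pool])]
    if (length(top) > 1) {
      sc <- cand$score[top]
      sc[is.na(sc)] <- -Inf
      top <- top[sc == max(sc)]
      if (length(top) > 1) top <- top[which.min(cand$id[top])]
    }
    i <- top[1]
    selected <- c(selected, i)
    risk_at_sel <- c(risk_at_sel, risk[i])
    alive[i] <- FALSE
    near <- D[i, ]
    removed <- which(alive & near <= radius_remove + 1e-9)
    alive[removed] <- FALSE
    decayed <- which(alive & near <= radius_decay + 1e-9)
    before <- risk[decayed]
    risk[decayed] <- pmax(1L, risk[decayed] - k)
    log[[length(log) + 1]] <- list(
      iteration = length(selected),
      chosen = cand$id[i],
      risk_at_selection = risk_at_sel[length(selected)],
      removed = cand$id[removed],
      decayed = data.frame(id = cand$id[decayed], before = before,
                           after = risk[decayed])
    )
  }

  sel <- cand[selected, setdiff(names(cand), "risk"), drop = FALSE]
  sel$iteration <- seq_along(selected)
  sel$risk_at_selection <- risk_at_sel
  rownames(sel) <- NULL
  structure(list(selected = sel, log = log,
                 reduction_constant = k,
                 termination = termination),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat("placement_result:", nrow(x$selected), "AED sites selected",
      sprintf("(reduction constant %d)\n", x$reduction_constant))
  invisible(x)
}

# Selected sites as an AED layer for coverage evaluation.
placement_as_aeds <- function(result) {
  stopifnot(inherits(result, "placement_result"))
  sel <- result$selected
  data.frame(id = sel$id, x = sel$x, y = sel$y, node = sel$node,
             always_available = TRUE)
}

#' Exhaustive-search placement oracle for small instances
#'
#' Enumerates all `n`-subsets of the candidates and returns one that covers
#' the most alerts (ties: lexicographically smallest id tuple). Intended as
#' a test oracle for the greedy heuristic, which can return local optima.
#'
#' @param candidates candidate table (`id`, `x`, `y`, `node`).
#' @param network a [road_network()] (needed for `"network_297"` mode).
#' @param alerts alert points.
#' @param n subset size; `choose(nrow(candidates), n)` must not exceed
#'   10,000.
#' @param mode coverage rule, see [is_covered()].
#' @return list with `ids` (sorted candidate ids), `n_covered`.
#' @export
brute_force_best <- function(candidates, network = NULL, alerts, n,
                             mode = "euclidean_300") {
  m <- nrow(candidates)
  stopifnot(n >= 1, n <= m)
  if (choose(m, n) > 10000) stop("instance too large for exhaustive search")
  ord <- order(candidates$id)
  cand <- candidates[ord, , drop = FALSE]
  covered <- .coverage_matrix(alerts, data.frame(
    id = cand$id, x = cand$x, y = cand$y,
    node = if ("node" %in% names(cand)) cand$node else NA,
    always_available = TRUE), network, mode)
  combos <- utils::combn(m, n)
  best <- NULL
  best_cov <- -1L
  for (j in seq_len(ncol(combos))) {
    cov <- sum(Reduce(`|`, lapply(combos[, j], function(c) covered[, c])))
    if (cov > best_cov) {
      best_cov <- cov
      best <- combos[, j]
    }
  }
  list(ids = sort(cand$id[best]), n_covered = as.integer(best_cov))
}

#' Sensitivity sweep over the risk-decay constant
#'
#' Reruns [greedy_place()] for each candidate reduction constant and
#' evaluates the resulting alert coverage; the constant with the largest
#' coverage is flagged (first maximum on ties).
#'
#' @param candidates,network,termination as in [greedy_place()].
#' @param alerts alert points for coverage evaluation.
#' @param constants non-empty vector of non-negative integers.
#' @param mode coverage rule, see [is_covered()].
#' @return data.frame with columns `constant`, `n_selected`, `n_covered`,
#'   `percent`, `best`.
#' @export
sensitivity_sweep <- function(candidates, network, alerts, termination,
                              constants = 0:4, mode = "euclidean_300") {
  stopifnot(length(constants) > 0, all(constants >= 0))
  rows <- lapply(constants, function(k) {
    res <- greedy_place(candidates, network, termination,
                        reduction_constant = k)
    cov <- coverage(alerts, placement_as_aeds(res), network = network,
                    mode = mode)
    data.frame(constant = k, n_selected = nrow(res$selected),
               n_covered = cov$n_covered, percent = cov$percent)
  })
  out <- do.call(rbind, rows)
  out$best <- seq_len(nrow(out)) == which.max(out$percent)
  out
}
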