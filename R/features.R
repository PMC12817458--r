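# Demographic/infrastructural layers and per-isochrone feature aggregation.

POI_CATEGORIES <- c("public_building", "residential", "industrial",
                    "sport", "transport", "parking")

#' Canonical feature names
#'
#' The per-candidate feature vector: residents inside the isochrone
#' (`population`), fraction female (`sex_ratio`), residents aged 65+
#' (`age_65_plus`, optional, see `include_age` in [build_feature_table()]),
#' point-of-interest counts per category and presence flags for
#' residential/industrial land use.
#'
#' @param include_age include the `age_65_plus` column.
#' @return character vector of feature column names.
#' @export
aed_feature_names <- function(include_age = FALSE) {
  base <- c("population", "sex_ratio",
            if (include_age) "age_65_plus",
            "n_public_buildings", "residential_flag", "industrial_flag",
            "n_sport_facilities", "n_transport_stations", "n_parking_spaces")
  base
}

#' Validate a population layer
#'
#' @param pop data.frame with columns `x`, `y`, `persons`, `persons_female`
#'   (and optionally `persons_65plus`); `persons >= persons_female >= 0`.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_population <- function(pop) {
  stopifnot(is.data.frame(pop),
            all(c("x", "y", "persons", "persons_female") %in% names(pop)))
  if (any(pop$persons_female < 0) || any(pop$persons < pop$persons_female)) {
    stop("population layer violates persons >= persons_female >= 0")
  }
  pop
}

#' Validate a point-of-interest layer
#'
#' @param poi data.frame with columns `x`, `y`, `category`; categories must
#'   come from the fixed enumeration (see `POI_CATEGORIES`).
#' @return the validated data.frame.
#' @export
validate_poi <- function(poi) {
  stopifnot(is.data.frame(poi), all(c("x", "y", "category") %in% names(poi)))
  bad <- which(!poi$category %in% POI_CATEGORIES)
  if (length(bad) > 0) {
    stop("unknown POI category '", poi$category[bad[1]],
         "' at feature index ", bad[1])
  }
  poi
}

empty_population <- function() {
  data.frame(x = numeric(), y = numeric(), persons = numeric(),
             persons_female = numeric())
}

empty_poi <- function() {
  data.frame(x = numeric(), y = numeric(), category = character())
}

.feature_row <- function(inside_pop, pop, inside_poi, poi, include_age = FALSE) {
  persons <- sum(pop$persons[inside_pop])
  female <- sum(pop$persons_female[inside_pop])
  cat_in <- poi$category[inside_poi]
  row <- data.frame(
    population = persons,
    sex_ratio = if (persons > 0) female / persons else 0,
    n_public_buildings = sum(cat_in == "public_building"),
    residential_flag = as.integer(any(cat_in == "residential")),
    industrial_flag = as.integer(any(cat_in == "industrial")),
    n_sport_facilities = sum(cat_in == "sport"),
    n_transport_stations = sum(cat_in == "transport"),
    n_parking_spaces = sum(cat_in == "parking")
  )
  if (include_age) {
    row$age_65_plus <- if ("persons_65plus" %in% names(pop)) {
      sum(pop$persons_65plus[inside_pop])
    } else 0
  }
  row[, aed_feature_names(include_age)]
}

#' Aggregate demographic and infrastructural features over an isochrone
#'
#' Sums the population tiles and counts the POIs whose points fall inside the
#' isochrone's spatial extent (see [extent_contains()]).
#'
#' @param candidate one-row candidate data.frame (from
#'   [extract_intersections()]); its `node` must equal `iso$origin`.
#' @param iso the candidate's [isochrone()].
#' @param pop population layer (see [validate_population()]); may be empty.
#' @param poi POI layer (see [validate_poi()]); may be empty.
#' @param mode,snap_tol extent membership rule, see [extent_contains()].
#' @param include_age include the `age_65_plus` feature.
#' @return one-row data.frame of features (see [aed_feature_names()]).
#' @export
aggregate_features <- function(candidate, iso, pop, poi,
                               mode = "snap", snap_tol = 50,
                               include_age = FALSE) {
  stopifnot(inherits(iso, "isochrone"))
  if (candidate$node != iso$origin) {
    stop("isochrone origin does not match candidate node")
  }
  pop <- validate_population(pop)
  poi <- validate_poi(poi)
  inside_pop <- extent_contains(iso, pop$x, pop$y, mode = mode,
                                snap_tol = snap_tol)
  inside_poi <- extent_contains(iso, poi$x, poi$y, mode = mode,
                                snap_tol = snap_tol)
  .feature_row(inside_pop, pop, inside_poi, poi, include_age)
}

#' Count historical alerts inside an isochrone
#'
#' @inheritParams aggregate_features
#' @param alerts data.frame with columns `x`, `y` (and usually `timestamp`).
#' @return integer count of alerts inside the extent.
#' @export
count_alerts <- function(candidate, iso, alerts, mode = "snap", snap_tol = 50) {
  stopifnot(inherits(iso, "isochrone"))
  if (candidate$node != iso$origin) {
    stop("isochrone origin does not match candidate node")
  }
  if (is.null(alerts) || nrow(alerts) == 0) return(0L)
  sum(extent_contains(iso, alerts$x, alerts$y, mode = mode,
                      snap_tol = snap_tol))
}

#' Build the per-candidate feature table
#'
#' Computes every candidate's 3-minute isochrone in one shortest-path sweep
#' and aggregates features (and, when alerts and an observation window are
#' supplied, the observed alert count, empirical alerts-per-year rate and the
#' binned risk area) per candidate.
#'
#' @param network a [road_network()].
#' @param candidates candidate table from [extract_intersections()].
#' @param pop,poi layers as in [aggregate_features()].
#' @param alerts optional alert points (`x`, `y`).
#' @param years optional observation-window length in years; required with
#'   `alerts` to compute `rate` and `risk_area`.
#' @param budget,speed isochrone parameters (default 180 s at 1.65 m/s).
#' @param mode,snap_tol extent membership rule.
#' @param include_age include the `age_65_plus` feature.
#' @return data.frame: candidate columns (`id`, `node`, `x`, `y`), feature
#'   columns, and when alerts are given `alerts_observed`, `rate`,
#'   `risk_area`.
#' @export
build_feature_table <- function(network, candidates, pop, poi,
                                alerts = NULL, years = NULL,
                                budget = 180, speed = 1.65,
                                mode = "snap", snap_tol = 50,
                                include_age = FALSE) {
  stopifnot(inherits(network, "road_network"))
  pop <- validate_population(pop)
  poi <- validate_poi(poi)
  if (nrow(candidates) == 0) stop("no candidate locations")
  rc <- reached_coords(network, candidates, budget = budget, speed = speed)
  mode <- match.arg(mode, c("snap", "disc"))
  radius <- budget * speed
  cand_xy <- cbind(candidates$x, candidates$y)

  member <- function(i, px, py) {
    if (mode == "disc") {
      sqrt((px - cand_xy[i, 1])^2 + (py - cand_xy[i, 2])^2) <= radius + 1e-9
    } else {
      points_near(rc[[i]], px, py, snap_tol)
    }
  }

  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    f <- .feature_row(member(i, pop$x, pop$y), pop,
                      member(i, poi$x, poi$y), poi, include_age)
    if (!is.null(alerts)) {
      f$alerts_observed <- if (nrow(alerts) > 0) {
        sum(member(i, alerts$x, alerts$y))
      } else 0L
    }
    f
  })
  out <- cbind(candidates[, c("id", "node", "x", "y")],
               do.call(rbind, rows))
  if (!is.null(alerts)) {
    if (is.null(years)) stop("'years' is required when alerts are supplied")
    out$rate <- alerts_per_year(out$alerts_observed, years)
    out$risk_area <- bin_risk_area(out$rate)
  }
  rownames(out) <- NULL
  out
}
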