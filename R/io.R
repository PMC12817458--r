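# GeoJSON readers/writers and the local planar projection.
#
# All core computations run in planar metres. Geographic inputs (lon/lat,
# detected by coordinate range) are projected once at read time with a local
# azimuthal equidistant projection about the layer centroid, which preserves
# metric distances from the centre to well within city-scale tolerances.

EARTH_RADIUS_M <- 6371008.8

#' Project lon/lat to a local azimuthal equidistant plane
#'
#' @param lon,lat coordinates in degrees.
#' @param lon0,lat0 projection centre in degrees.
#' @return matrix with columns `x`, `y` in metres.
#' @export
project_aeqd <- function(lon, lat, lon0, lat0) {
  to_rad <- pi / 180
  lam <- lon * to_rad; phi <- lat * to_rad
  lam0 <- lon0 * to_rad; phi0 <- lat0 * to_rad
  cos_c <- pmin(1, pmax(-1, sin(phi0) * sin(phi) +
                          cos(phi0) * cos(phi) * cos(lam - lam0)))
  c <- acos(cos_c)
  k <- ifelse(c < 1e-12, 1, c / sin(c))
  cbind(x = EARTH_RADIUS_M * k * cos(phi) * sin(lam - lam0),
        y = EARTH_RADIUS_M * k * (cos(phi0) * sin(phi) -
                                    sin(phi0) * cos(phi) * cos(lam - lam0)))
}

.is_geographic <- function(x, y) {
  length(x) > 0 && all(abs(x) <= 180) && all(abs(y) <= 90)
}

.project_if_geographic <- function(x, y) {
  if (!.is_geographic(x, y)) return(cbind(x = x, y = y))
  project_aeqd(x, y, mean(x), mean(y))
}

.read_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection: ", path)
  }
  gj$features
}

.feature_points <- function(features, kind) {
  n <- length(features)
  x <- y <- numeric(n)
  for (i in seq_len(n)) {
    geom <- features[[i]]$geometry
    if (is.null(geom) || !identical(geom$type, "Point")) {
      stop(kind, " feature ", i, ": geometry must be a Point")
    }
    x[i] <- as.numeric(geom$coordinates[[1]])
    y[i] <- as.numeric(geom$coordinates[[2]])
  }
  list(x = x, y = y)
}

.prop <- function(feature, name, i, kind, default = NULL) {
  v <- feature$properties[[name]]
  if (is.null(v)) {
    if (!is.null(default)) return(default)
    stop(kind, " feature ", i, ": missing property '", name, "'")
  }
  v
}

# Deduplicate coordinates within `tol` metres using a grid hash; returns node
# ids per input point plus the node table.
.dedup_nodes <- function(x, y, tol = 0.5) {
  n <- length(x)
  ids <- integer(n)
  nx <- numeric(0); ny <- numeric(0)
  cells <- new.env(parent = emptyenv())
  next_id <- 0L
  for (i in seq_len(n)) {
    ci <- floor(x[i] / tol); cj <- floor(y[i] / tol)
    found <- 0L
    for (di in -1:1) for (dj in -1:1) {
      key <- paste(ci + di, cj + dj)
      for (cand in cells[[key]]) {
        if ((x[i] - nx[cand])^2 + (y[i] - ny[cand])^2 <= tol^2) found <- cand
      }
    }
    if (found == 0L) {
      next_id <- next_id + 1L
      nx[next_id] <- x[i]; ny[next_id] <- y[i]
      key <- paste(ci, cj)
      cells[[key]] <- c(cells[[key]], next_id)
      found <- next_id
    }
    ids[i] <- found
  }
  list(ids = ids, nodes = data.frame(id = seq_len(next_id), x = nx, y = ny))
}

#' Read a typed GeoJSON layer
#'
#' Parses and validates one of the five input layers. Geographic
#' coordinates are detected by range and projected to a local planar frame
#' (azimuthal equidistant about the layer centroid); planar inputs pass
#' through unchanged. Road networks are LineString collections whose edge
#' lengths come from a `length_m` property or, when absent, from the
#' (projected) geometry; endpoints are deduplicated into nodes within
#' 0.5 m. Schema violations report the offending feature index and field.
#'
#' @param path GeoJSON file path.
#' @param kind one of `"network"`, `"population"`, `"poi"`, `"alerts"`,
#'   `"aeds"`.
#' @return a [road_network()] for `"network"`, otherwise the corresponding
#'   data.frame layer.
#' @export
read_layer <- function(path, kind = c("network", "population", "poi",
                                      "alerts", "aeds")) {
  kind <- match.arg(kind)
  features <- .read_geojson(path)

  if (kind == "network") {
    segs <- lapply(seq_along(features), function(i) {
      geom <- features[[i]]$geometry
      if (is.null(geom) || !identical(geom$type, "LineString")) {
        stop("network feature ", i, ": geometry must be a LineString")
      }
      coords <- do.call(rbind, lapply(geom$coordinates, function(p) {
        c(as.numeric(p[[1]]), as.numeric(p[[2]]))
      }))
      if (nrow(coords) < 2) stop("network feature ", i, ": needs >= 2 points")
      list(coords = coords,
           length_m = features[[i]]$properties$length_m)
    })
    all_xy <- do.call(rbind, lapply(segs, `[[`, "coords"))
    proj <- .project_if_geographic(all_xy[, 1], all_xy[, 2])
    pos <- 0
    for (i in seq_along(segs)) {
      m <- nrow(segs[[i]]$coords)
      segs[[i]]$coords <- proj[pos + seq_len(m), , drop = FALSE]
      pos <- pos + m
    }
    ends <- do.call(rbind, lapply(segs, function(s) {
      s$coords[c(1, nrow(s$coords)), , drop = FALSE]
    }))
    dd <- .dedup_nodes(ends[, 1], ends[, 2])
    edges <- do.call(rbind, lapply(seq_along(segs), function(i) {
      coords <- segs[[i]]$coords
      len <- segs[[i]]$length_m
      if (is.null(len)) {
        len <- sum(sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2))
      }
      data.frame(from = dd$ids[2 * i - 1], to = dd$ids[2 * i],
                 length = as.numeric(len))
    }))
    edges <- edges[edges$from != edges$to, , drop = FALSE]
    return(road_network(dd$nodes, edges))
  }

  pts <- .feature_points(features, kind)
  proj <- .project_if_geographic(pts$x, pts$y)
  n <- length(features)
  out <- switch(kind,
    population = {
      df <- data.frame(
        x = proj[, 1], y = proj[, 2],
        persons = vapply(seq_len(n), function(i)
          as.numeric(.prop(features[[i]], "persons", i, kind)), numeric(1)),
        persons_female = vapply(seq_len(n), function(i)
          as.numeric(.prop(features[[i]], "persons_female", i, kind)),
          numeric(1)))
      p65 <- lapply(seq_len(n), function(i)
        features[[i]]$properties$persons_65plus)
      if (!any(vapply(p65, is.null, logical(1)))) {
        df$persons_65plus <- as.numeric(unlist(p65))
      }
      validate_population(df)
    },
    poi = validate_poi(data.frame(
      x = proj[, 1], y = proj[, 2],
      category = vapply(seq_len(n), function(i)
        as.character(.prop(features[[i]], "category", i, kind)),
        character(1)))),
    alerts = data.frame(
      id = vapply(seq_len(n), function(i)
        as.integer(.prop(features[[i]], "id", i, kind, default = i)),
        integer(1)),
      x = proj[, 1], y = proj[, 2],
      timestamp = as.POSIXct(sub("Z$", "", vapply(seq_len(n), function(i)
        as.character(.prop(features[[i]], "timestamp", i, kind,
                           default = NA_character_)), character(1))),
        tz = "UTC",
        tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                       "%Y-%m-%d"))),
    aeds = data.frame(
      id = vapply(seq_len(n), function(i)
        as.integer(.prop(features[[i]], "id", i, kind, default = i)),
        integer(1)),
      x = proj[, 1], y = proj[, 2],
      always_available = vapply(seq_len(n), function(i)
        as.logical(.prop(features[[i]], "always_available", i, kind,
                         default = TRUE)), logical(1)))
  )
  out
}

.point_feature <- function(x, y, props) {
  list(type = "Feature",
       geometry = list(type = "Point", coordinates = c(x, y)),
       properties = props)
}

#' Write a typed layer as GeoJSON
#'
#' Inverse of [read_layer()] for planar layers (coordinates are written in
#' the local metric frame). Deterministic: identical input yields
#' byte-identical output.
#'
#' @param layer the layer object (a `road_network` or a layer data.frame).
#' @param path output path.
#' @param kind layer kind, see [read_layer()].
#' @return `path`, invisibly.
#' @export
write_layer <- function(layer, path, kind = c("network", "population", "poi",
                                              "alerts", "aeds")) {
  kind <- match.arg(kind)
  features <- if (kind == "network") {
    stopifnot(inherits(layer, "road_network"))
    nodes <- layer$nodes
    lapply(seq_len(nrow(layer$edges)), function(i) {
      e <- layer$edges[i, ]
      a <- match(e$from, nodes$id); b <- match(e$to, nodes$id)
      list(type = "Feature",
           geometry = list(type = "LineString",
                           coordinates = list(c(nodes$x[a], nodes$y[a]),
                                              c(nodes$x[b], nodes$y[b]))),
           properties = list(length_m = e$length))
    })
  } else {
    lapply(seq_len(nrow(layer)), function(i) {
      props <- switch(kind,
        population = {
          p <- list(persons = layer$persons[i],
                    persons_female = layer$persons_female[i])
          if ("persons_65plus" %in% names(layer)) {
            p$persons_65plus <- layer$persons_65plus[i]
          }
          p
        },
        poi = list(category = layer$category[i]),
        alerts = list(id = layer$id[i],
                      timestamp = format(layer$timestamp[i],
                                         "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
        aeds = list(id = layer$id[i],
                    always_available = layer$always_available[i])
      )
      .point_feature(layer$x[i], layer$y[i], props)
    })
  }
  gj <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 10), path)
  invisible(path)
}

#' Export a placement result as GeoJSON
#'
#' Selected sites as Point features carrying the iteration index and the
#' risk level at selection.
#'
#' @param result a `placement_result` from [greedy_place()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_placement_geojson <- function(result, path) {
  stopifnot(inherits(result, "placement_result"))
  sel <- result$selected
  features <- lapply(seq_len(nrow(sel)), function(i) {
    .point_feature(sel$x[i], sel$y[i],
                   list(id = sel$id[i], iteration = sel$iteration[i],
                        risk_at_selection = sel$risk_at_selection[i]))
  })
  gj <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 10), path)
  invisible(path)
}
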