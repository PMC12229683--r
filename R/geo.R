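# mean Earth radius, km (IUGG mean radius)
EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between two points (Haversine formula)
#'
#' `d = 2R asin( sqrt( sin^2(dphi/2) + cos(phi1) cos(phi2) sin^2(dlambda/2) ) )`
#' with R = 6371.0088 km.
#'
#' @param p1,p2 Numeric vectors `c(lat, lon)` in degrees.
#' @return Distance in km.
#' @export
haversine_km <- function(p1, p2) {
  check_coords(rbind(p1, p2))
  phi1 <- p1[1] * pi / 180
  phi2 <- p2[1] * pi / 180
  dphi <- (p2[1] - p1[1]) * pi / 180
  dlam <- (p2[2] - p1[2]) * pi / 180
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

check_coords <- function(m) {
  lat <- m[, 1]
  lon <- m[, 2]
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180)) {
    ysnpdb_abort("coordinates out of range (lat in [-90,90], lon in [-180,180])",
                 "ysnpdb_bad_coordinates")
  }
  invisible(m)
}

# all-pairs haversine between two lat/lon matrices; returns the minimum
min_cross_haversine <- function(a, b) {
  phi_a <- a[, 1] * pi / 180
  phi_b <- b[, 1] * pi / 180
  lam_a <- a[, 2] * pi / 180
  lam_b <- b[, 2] * pi / 180
  s_phi <- sin(outer(phi_a, phi_b, "-") / 2)^2
  s_lam <- sin(outer(lam_a, lam_b, "-") / 2)^2
  h <- s_phi + outer(cos(phi_a), cos(phi_b)) * s_lam
  2 * EARTH_RADIUS_KM * min(asin(pmin(1, sqrt(h))))
}

#' Construct a region geometry
#'
#' @param region_id Region name.
#' @param rings List of matrices with columns `lat`, `lon` (degrees), one per
#'   boundary ring; each ring needs at least 3 vertices.
#' @param parent Optional parent country id (for subregions).
#' @return An object of class `region_geometry`.
#' @export
region_geometry <- function(region_id, rings, parent = NA_character_) {
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    colnames(r) <- c("lat", "lon")
    if (nrow(r) < 3) {
      ysnpdb_abort(sprintf("degenerate ring in region '%s' (<3 vertices)", region_id),
                   "ysnpdb_degenerate_ring")
    }
    check_coords(r)
    r
  })
  structure(list(region_id = as.character(region_id), rings = rings,
                 parent = as.character(parent)),
            class = "region_geometry")
}

#' Read region geometries from GeoJSON
#'
#' Reads a FeatureCollection; `properties.name` becomes the region id and an
#' optional `properties.parent` the parent country. Polygon and MultiPolygon
#' geometries are supported. GeoJSON stores positions as (lon, lat); they are
#' converted to the package's (lat, lon) ring matrices.
#'
#' @param path Path to a GeoJSON file.
#' @return List of `region_geometry` objects.
#' @export
read_regions_geojson <- function(path) {
  if (!file.exists(path)) {
    ysnpdb_abort(sprintf("GeoJSON file not found: %s", path), "ysnpdb_missing_file")
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$features)) {
    ysnpdb_abort("GeoJSON is not a FeatureCollection", "ysnpdb_parse_error")
  }
  lapply(doc$features, function(f) {
    name <- f$properties$name
    if (is.null(name)) {
      ysnpdb_abort("GeoJSON feature lacks properties.name", "ysnpdb_parse_error")
    }
    ring_mat <- function(ring) {
      m <- do.call(rbind, lapply(ring, function(pt) c(pt[[2]], pt[[1]])))
      colnames(m) <- c("lat", "lon")
      m
    }
    rings <- switch(
      f$geometry$type,
      Polygon = lapply(f$geometry$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(f$geometry$coordinates,
                                   function(poly) lapply(poly, ring_mat)),
                            recursive = FALSE),
      ysnpdb_abort(sprintf("unsupported geometry type '%s'", f$geometry$type),
                   "ysnpdb_parse_error")
    )
    region_geometry(name, rings, parent = f$properties$parent %||% NA_character_)
  })
}

# insert vertices so consecutive ring points are at most max_spacing_km apart
densify_ring <- function(ring, max_spacing_km = 50) {
  out <- list()
  n <- nrow(ring)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p <- ring[i, ]
    q <- ring[j, ]
    out[[length(out) + 1L]] <- p
    d <- haversine_km(p, q)
    if (d > max_spacing_km) {
      k <- ceiling(d / max_spacing_km)
      t <- seq_len(k - 1) / k
      # linear interpolation in lat/lon: adequate at the <=50 km spacing used
      out[[length(out) + 1L]] <- cbind(p[1] + t * (q[1] - p[1]),
                                       p[2] + t * (q[2] - p[2]))
    }
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("lat", "lon")
  m
}

region_vertices <- function(geom, max_spacing_km = 50) {
  do.call(rbind, lapply(geom$rings, densify_ring, max_spacing_km = max_spacing_km))
}

#' Shortest spherical distance between two region borders
#'
#' Minimum Haversine distance over all pairs of boundary vertices after
#' densifying each ring to at most `max_spacing_km` between consecutive
#' vertices (an approximation to the exact segment-to-segment great-circle
#' distance with error below about half the spacing). Shared vertices give 0.
#'
#' @param a,b `region_geometry` objects.
#' @param max_spacing_km Densification spacing, km.
#' @return Distance in km.
#' @export
border_distance_km <- function(a, b, max_spacing_km = 50) {
  stopifnot(inherits(a, "region_geometry"), inherits(b, "region_geometry"))
  min_cross_haversine(region_vertices(a, max_spacing_km),
                      region_vertices(b, max_spacing_km))
}

#' Interpolation parameters
#'
#' Defaults follow the rule: a region qualifies as a neighbor when it holds
#' at least 50 informative individuals and its border lies within 1000 km;
#' interpolation proceeds only with at least three such neighbors, using
#' plain inverse distance (power 1) weights. Distances below `epsilon_km`
#' are floored so adjacent regions cannot receive unbounded weight.
#'
#' @param min_neighbor_n Minimum informative sample count of a neighbor.
#' @param max_km Maximum border distance of a neighbor, km.
#' @param min_neighbors Minimum number of qualifying neighbors.
#' @param power Inverse-distance exponent.
#' @param epsilon_km Distance floor, km.
#' @return List of class `interp_params`.
#' @export
interp_params <- function(min_neighbor_n = 50, max_km = 1000,
                          min_neighbors = 3, power = 1, epsilon_km = 1) {
  stopifnot(min_neighbor_n > 0, max_km > 0, min_neighbors > 0,
            power > 0, epsilon_km > 0)
  structure(list(min_neighbor_n = min_neighbor_n, max_km = max_km,
                 min_neighbors = min_neighbors, power = power,
                 epsilon_km = epsilon_km),
            class = "interp_params")
}

#' Interpolate the frequency of a region without data
#'
#' Inverse-distance weighted average of the frequencies of qualifying
#' neighboring regions: `f = sum(w_i f_i) / sum(w_i)` with
#' `w_i = 1 / max(d_i, epsilon_km)^power`, where `d_i` is the shortest
#' spherical distance between borders. Returns `NULL` when fewer than
#' `min_neighbors` regions qualify.
#'
#' @param target Region id lacking data in `table`.
#' @param table A `frequency_table` (absolute scale recommended).
#' @param geometries List of `region_geometry` covering target and neighbors.
#' @param params An [interp_params()] object.
#' @return An `interpolated_cell` (list with region_id, frequency, neighbors
#'   data.frame and `interpolated = TRUE`) or `NULL`.
#' @export
interpolate_region <- function(target, table, geometries, params = interp_params()) {
  stopifnot(inherits(table, "frequency_table"), inherits(params, "interp_params"))
  cells <- table$cells
  t_cell <- cells[cells$region_id == target, , drop = FALSE]
  if (nrow(t_cell) && t_cell$n_informative[1] > 0) {
    ysnpdb_abort(sprintf("region '%s' already has data; refusing to interpolate", target),
                 "ysnpdb_has_data")
  }
  geom_ids <- vapply(geometries, `[[`, character(1), "region_id")
  ti <- match(target, geom_ids)
  if (is.na(ti)) {
    ysnpdb_abort(sprintf("no geometry for region '%s'", target), "ysnpdb_unknown_region")
  }
  cand <- cells[cells$n_informative >= params$min_neighbor_n &
                  !is.na(cells$frequency) & cells$region_id != target, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  dist <- vapply(cand$region_id, function(r) {
    gi <- match(r, geom_ids)
    if (is.na(gi)) return(Inf)
    border_distance_km(geometries[[ti]], geometries[[gi]])
  }, numeric(1))
  keep <- is.finite(dist) & dist <= params$max_km
  if (sum(keep) < params$min_neighbors) return(NULL)
  cand <- cand[keep, , drop = FALSE]
  dist <- dist[keep]
  w <- 1 / pmax(dist, params$epsilon_km)^params$power
  w <- w / sum(w)
  structure(list(
    region_id = target,
    frequency = sum(w * cand$frequency),
    neighbors = data.frame(region_id = cand$region_id, distance_km = unname(dist),
                           weight = unname(w), stringsAsFactors = FALSE),
    interpolated = TRUE
  ), class = "interpolated_cell")
}

#' Fill every data-less region of a table by interpolation
#'
#' Applies [interpolate_region()] to each registered region with zero
#' informative samples (and to regions that have a geometry but no cell).
#' Regions with any empirical data, however few samples, are never
#' overwritten; regions whose neighborhood does not qualify stay empty.
#'
#' @inheritParams interpolate_region
#' @return The input `frequency_table` with interpolated cells filled in and
#'   flagged `interpolated = TRUE`.
#' @export
interpolate_all <- function(table, geometries, params = interp_params()) {
  stopifnot(inherits(table, "frequency_table"))
  geom_ids <- vapply(geometries, `[[`, character(1), "region_id")
  empty <- table$cells$region_id[table$cells$n_informative == 0]
  targets <- union(intersect(empty, geom_ids),
                   setdiff(geom_ids, table$cells$region_id))
  for (target in targets) {
    cell <- interpolate_region(target, table, geometries, params)
    if (is.null(cell)) next
    i <- match(target, table$cells$region_id)
    if (is.na(i)) {
      table$cells <- rbind(table$cells, data.frame(
        region_id = target, country_id = target, n_derived = 0L,
        n_informative = 0L, frequency = NA_real_, display_pct = NA_real_,
        interpolated = FALSE, stringsAsFactors = FALSE
      ))
      i <- nrow(table$cells)
    }
    table$cells$frequency[i] <- cell$frequency
    table$cells$display_pct[i] <- round_half_up(100 * cell$frequency)
    table$cells$interpolated[i] <- TRUE
  }
  table$cells <- table$cells[order(table$cells$region_id), , drop = FALSE]
  rownames(table$cells) <- NULL
  table
}

#' Write region geometries to GeoJSON
#'
#' @param geometries List of `region_geometry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_geojson <- function(geometries, path) {
  feats <- lapply(geometries, function(g) {
    rings <- lapply(g$rings, function(r) {
      lapply(seq_len(nrow(r)), function(k) c(r[k, "lon"], r[k, "lat"]))
    })
    props <- list(name = g$region_id)
    if (!is.na(g$parent)) props$parent <- g$parent
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
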