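## Minimal GeoJSON interchange for landscape layers.
##
## A landscape is a FeatureCollection in which each feature carries a
## "layer" property naming its role: roads | trails | powerline |
## road_polygon | boundary (the study-area polygon).  Coordinates are
## planar meters (the files are projected, not lon/lat).  The 5 m road
## buffer is derived on read via buffer_polygon() unless a road_buffer
## feature is supplied explicitly.

.coords_to_matrix <- function(coords) {
  do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
}

.geom_to_lines <- function(geom) {
  switch(geom$type,
    LineString = list(.coords_to_matrix(geom$coordinates)),
    MultiLineString = lapply(geom$coordinates, .coords_to_matrix),
    stop("unsupported line geometry: ", geom$type, call. = FALSE))
}

.geom_to_parts <- function(geom) {
  switch(geom$type,
    Polygon = list(lapply(geom$coordinates, .coords_to_matrix)),
    MultiPolygon = lapply(geom$coordinates, function(pp)
      lapply(pp, .coords_to_matrix)),
    stop("unsupported polygon geometry: ", geom$type, call. = FALSE))
}

#' Read a landscape from GeoJSON
#'
#' @param path GeoJSON FeatureCollection; each feature needs a "layer"
#'   property (roads, trails, powerline, road_polygon, boundary,
#'   optionally road_buffer).
#' @param buffer_distance roadside buffer distance (m) applied to the
#'   road_polygon when no road_buffer feature is present (default 5).
#' @return an `lc_landscape`.
#' @export
read_landscape <- function(path, buffer_distance = 5) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection", call. = FALSE)
  lines <- list(roads = list(), trails = list())
  polys <- list(powerline = list(), road_polygon = list(), boundary = list(),
                road_buffer = list())
  for (ft in gj$features) {
    layer <- ft$properties$layer
    if (is.null(layer)) next
    if (layer %in% names(lines)) {
      lines[[layer]] <- c(lines[[layer]], .geom_to_lines(ft$geometry))
    } else if (layer %in% names(polys)) {
      polys[[layer]] <- c(polys[[layer]], .geom_to_parts(ft$geometry))
    }
  }
  for (need in c("powerline", "boundary"))
    if (length(polys[[need]]) == 0L)
      stop("landscape GeoJSON missing layer: ", need, call. = FALSE)
  road_polygon <- if (length(polys$road_polygon))
    lc_polygon(parts = polys$road_polygon)
  road_buffer <- if (length(polys$road_buffer)) {
    lc_polygon(parts = polys$road_buffer)
  } else if (!is.null(road_polygon)) {
    buffer_polygon(road_polygon, buffer_distance)
  } else stop("landscape GeoJSON needs road_polygon or road_buffer", call. = FALSE)
  landscape(roads = lines$roads, trails = lines$trails,
            powerline = lc_polygon(parts = polys$powerline),
            road_buffer = road_buffer,
            study_area = lc_polygon(parts = polys$boundary),
            road_polygon = road_polygon)
}

.matrix_to_coords <- function(m) {
  lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
}

.line_feature <- function(m, layer) {
  list(type = "Feature", properties = list(layer = layer),
       geometry = list(type = "LineString",
                       coordinates = .matrix_to_coords(m)))
}

.poly_feature <- function(poly, layer) {
  parts <- poly$parts
  close_ring <- function(r) .matrix_to_coords(rbind(r, r[1, ]))
  if (length(parts) == 1L) {
    geom <- list(type = "Polygon", coordinates = lapply(parts[[1]], close_ring))
  } else {
    geom <- list(type = "MultiPolygon",
                 coordinates = lapply(parts, function(p) lapply(p, close_ring)))
  }
  list(type = "Feature", properties = list(layer = layer), geometry = geom)
}

#' Write a landscape to GeoJSON
#'
#' @param land an `lc_landscape`.
#' @param path output path.
#' @export
write_landscape <- function(land, path) {
  feats <- c(
    lapply(land$roads, .line_feature, layer = "roads"),
    lapply(land$trails, .line_feature, layer = "trails"),
    list(.poly_feature(land$powerline, "powerline"),
         .poly_feature(land$road_buffer, "road_buffer"),
         .poly_feature(land$study_area, "boundary")),
    if (!is.null(land$road_polygon))
      list(.poly_feature(land$road_polygon, "road_polygon")))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
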