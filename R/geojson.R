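# GeoJSON (RFC 7946 geometry types, planar coordinates) reader/writer for
# landscapes. One FeatureCollection holds all layers, distinguished by the
# `layer` property: "patch", "study_boundary", "city_boundary",
# "development". Grid and habitat-class metadata travel as foreign members
# ("grid", "classes") of the collection. Coordinates are assumed already
# projected; no CRS handling is performed.

#' @noRd
close_ring <- function(xy) rbind(xy, xy[1, , drop = FALSE])

#' @noRd
ring_to_coords <- function(xy) {
  xy <- close_ring(xy)
  lapply(seq_len(nrow(xy)), function(i) as.numeric(xy[i, ]))
}

#' @noRd
coords_to_ring <- function(cc) {
  m <- do.call(rbind, lapply(cc, as.numeric))
  if (nrow(m) >= 2 && all(abs(m[1, ] - m[nrow(m), ]) < 1e-12))
    m <- m[-nrow(m), , drop = FALSE]
  ring_ccw(m)
}

#' @noRd
geom_to_json <- function(parts) {
  if (length(parts) == 1) {
    list(type = "Polygon", coordinates = list(ring_to_coords(parts[[1]])))
  } else {
    list(type = "MultiPolygon",
         coordinates = lapply(parts, function(r) list(ring_to_coords(r))))
  }
}

#' @noRd
json_to_geom <- function(g, idx) {
  if (is.null(g$type))
    abort(sprintf("feature %d has no geometry type", idx))
  if (g$type == "Polygon") {
    list(coords_to_ring(g$coordinates[[1]]))
  } else if (g$type == "MultiPolygon") {
    lapply(g$coordinates, function(poly) coords_to_ring(poly[[1]]))
  } else {
    abort(sprintf("feature %d has non-polygon geometry type '%s'", idx, g$type))
  }
}

#' Write a landscape to GeoJSON
#'
#' Writes all layers of a landscape as one GeoJSON FeatureCollection. Patch
#' features carry `layer = "patch"`, `patch_id` and `habitat_class`
#' properties; boundary and development features carry only `layer`. The
#' grid specification and habitat class table are stored as foreign members
#' so that [read_landscape()] restores a complete object.
#'
#' @param landscape A `landscape`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  p <- landscape$patches
  feats <- lapply(seq_len(nrow(p)), function(i) {
    list(type = "Feature",
         properties = list(layer = "patch", patch_id = p$patch_id[i],
                           habitat_class = p$habitat_class[i]),
         geometry = geom_to_json(p$geometry[[i]]))
  })
  bfeat <- function(ring, layer) {
    list(type = "Feature", properties = list(layer = layer),
         geometry = geom_to_json(list(ring)))
  }
  feats <- c(feats, list(bfeat(landscape$study_boundary, "study_boundary"),
                         bfeat(landscape$city_boundary, "city_boundary")))
  for (d in landscape$developments) feats <- c(feats, list(bfeat(d, "development")))
  g <- landscape$grid
  fc <- list(type = "FeatureCollection",
             grid = list(origin = g$origin, cell_size = g$cell_size,
                         n_cols = g$n_cols, n_rows = g$n_rows),
             classes = lapply(seq_len(nrow(landscape$classes)), function(i)
               as.list(landscape$classes[i, ])),
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a landscape from GeoJSON
#'
#' Reads a FeatureCollection written by [write_landscape()] (or assembled by
#' hand to the same schema). Patch areas and centroids are recomputed from
#' the geometry on read, so write-read round trips are identity up to
#' coordinate serialisation round-off.
#'
#' @param path Path to a GeoJSON file.
#' @return A `landscape`.
#' @export
read_landscape <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    abort("file is not a GeoJSON FeatureCollection")
  geoms <- list(); cls <- integer(0); ids <- integer(0)
  study <- NULL; city <- NULL; devs <- list()
  for (i in seq_along(fc$features)) {
    f <- fc$features[[i]]
    layer <- f$properties$layer
    if (is.null(layer)) layer <- "patch"
    g <- json_to_geom(f$geometry, i)
    if (layer == "patch") {
      if (is.null(f$properties$patch_id))
        abort(sprintf("feature %d is missing required property 'patch_id'", i))
      if (is.null(f$properties$habitat_class))
        abort(sprintf("feature %d is missing required property 'habitat_class'", i))
      geoms <- c(geoms, list(g))
      ids <- c(ids, as.integer(f$properties$patch_id))
      cls <- c(cls, as.integer(f$properties$habitat_class))
    } else if (layer == "study_boundary") {
      study <- g[[1]]
    } else if (layer == "city_boundary") {
      city <- g[[1]]
    } else if (layer == "development") {
      devs <- c(devs, list(g[[1]]))
    } else {
      abort(sprintf("feature %d has unknown layer '%s'", i, layer))
    }
  }
  if (is.null(study) || is.null(city))
    abort("file is missing study_boundary and/or city_boundary features")
  if (is.null(fc$grid))
    abort("file is missing the 'grid' member")
  grid <- grid_spec(origin = unlist(fc$grid$origin),
                    cell_size = fc$grid$cell_size,
                    n_cols = fc$grid$n_cols, n_rows = fc$grid$n_rows)
  classes <- if (!is.null(fc$classes)) {
    dplyr::bind_rows(lapply(fc$classes, tibble::as_tibble))
  } else habitat_classes()
  landscape(patch_tbl(geoms, cls, patch_id = ids), study, city, devs, grid,
            classes = classes)
}
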