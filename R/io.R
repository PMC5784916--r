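#' Write and read the synthetic inputs as plain text
#'
#' Serialisation for the generated inputs: oil fields as long-format CSV
#' (`day, layer, lon, lat, ppb`), geometry as GeoJSON polygons (cell
#' outlines dissolved to bounding rings) plus CSV cell and layer tables,
#' food web, closures and larval losses as CSV. All values round-trip.
#'
#' @param field an `oil_field`; @param geometry a `spill_geometry`.
#' @param path output file path.
#' @param threshold concentrations at or below this are omitted from the
#'   long format (the field is sparse).
#' @return the path, invisibly.
#' @name spillweb-io
NULL

#' @rdname spillweb-io
#' @export
write_oil_csv <- function(field, geometry, path, threshold = 0) {
  idx <- which(field$conc > threshold, arr.ind = TRUE)
  df <- data.frame(day = idx[, 1], layer = idx[, 2],
                   lon = geometry$cells$lon[idx[, 3]],
                   lat = geometry$cells$lat[idx[, 3]],
                   cell = idx[, 3],
                   ppb = field$conc[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname spillweb-io
#' @param template an `oil_field` providing grid dimensions (round-trip
#'   reads restore into the same grid).
#' @export
read_oil_csv <- function(path, template) {
  df <- utils::read.csv(path)
  conc <- array(0, dim(template$conc))
  conc[cbind(df$day, df$layer, df$cell)] <- df$ppb
  out <- template
  out$conc <- conc
  out
}

#' @rdname spillweb-io
#' @export
write_geometry_geojson <- function(geometry, path) {
  res <- geometry$grid_resolution
  feats <- lapply(seq_len(geometry$n_polygons), function(p) {
    cells <- geometry$cells[geometry$cells$polygon == p, ]
    rings <- lapply(seq_len(nrow(cells)), function(i) {
      x <- cells$lon[i]; y <- cells$lat[i]; h <- res / 2
      list(list(c(x - h, y - h), c(x + h, y - h), c(x + h, y + h),
                c(x - h, y + h), c(x - h, y - h)))
    })
    list(type = "Feature",
         properties = list(polygon_id = p,
                           area_km2 = geometry$polygons$area_km2[p],
                           bottom_depth = geometry$polygons$bottom_depth[p]),
         geometry = list(type = "MultiPolygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname spillweb-io
#' @export
write_geometry_csv <- function(geometry, path) {
  utils::write.csv(geometry$cells, path, row.names = FALSE)
  lt <- file.path(dirname(path), paste0("layers_", basename(path)))
  utils::write.csv(
    data.frame(polygon_id = geometry$polygons$polygon_id,
               bottom_depth = geometry$polygons$bottom_depth,
               n_water_layers = geometry$polygons$n_water_layers),
    lt, row.names = FALSE)
  invisible(path)
}

#' @rdname spillweb-io
#' @param web a `food_web`.
#' @export
write_food_web_csv <- function(web, path) {
  utils::write.csv(web$groups, path, row.names = FALSE)
  dp <- file.path(dirname(path), paste0("diet_", basename(path)))
  utils::write.csv(as.data.frame(web$diet), dp, row.names = TRUE)
  invisible(path)
}

#' @rdname spillweb-io
#' @param schedule a `closure_schedule`.
#' @export
write_closures_csv <- function(schedule, path) {
  idx <- which(schedule$closed > 0, arr.ind = TRUE)
  df <- data.frame(day = idx[, 1] + schedule$start_day - 1,
                   polygon = idx[, 2],
                   fleet = schedule$fleets[idx[, 3]],
                   closed_fraction = schedule$closed[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname spillweb-io
#' @param larval a `larval_loss_table`.
#' @export
write_larval_csv <- function(larval, path) {
  utils::write.csv(as.data.frame(larval), path, row.names = FALSE)
  invisible(path)
}

#' Write the monthly guild biomass series of a run as CSV
#'
#' Long format: `month, group, polygon, biomass_mgN`.
#'
#' @param run a `run_output`; @param path output path.
#' @export
write_run_csv <- function(run, path) {
  d <- dim(run$biomass)
  df <- data.frame(
    month = rep(seq_len(d[1]), times = d[2] * d[3]),
    group = rep(rep(run$groups$code, each = d[1]), times = d[3]),
    polygon = rep(seq_len(d[3]), each = d[1] * d[2]),
    biomass_mgN = as.vector(run$biomass)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
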