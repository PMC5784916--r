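#' Generate a reduced polygon model geometry
#'
#' Tiles a rectangular lon/lat domain of grid cells into `n_polygons`
#' contiguous polygons (a Voronoi partition around seeded centres), assigns
#' each polygon a bottom depth from a north-to-south shelf-to-basin gradient,
#' and partitions the water column at the supplied depth cuts. Each polygon
#' occupies the water layers above its bottom depth plus one sediment layer.
#' With the default cuts (10, 20, 50, 200, 2000 m) a full-depth polygon has
#' 6 water layers.
#'
#' @param n_polygons number of polygons (>= 2, or 1 for a single-region case).
#' @param depth_cuts strictly increasing depths (m) partitioning water layers.
#' @param grid_resolution cell size in degrees.
#' @param seed integer seed; the same seed reproduces the geometry exactly.
#' @param lon_range,lat_range domain extent (degrees).
#' @param shelf_depth,basin_depth bottom depth (m) at the northern and
#'   southern domain edges.
#' @return A `spill_geometry`: cell table with polygon membership and area
#'   weights, polygon table (area, bottom depth, number of water layers),
#'   layer thickness matrix, adjacency pairs, and grid descriptors.
#' @export
gen_geometry <- function(n_polygons = 16,
                         depth_cuts = c(10, 20, 50, 200, 2000),
                         grid_resolution = 0.25, seed = 1,
                         lon_range = c(-90, -86), lat_range = c(26, 30),
                         shelf_depth = 35, basin_depth = 2500) {
  if (n_polygons < 1) stop("n_polygons must be >= 1")
  if (length(depth_cuts) == 0 || any(diff(depth_cuts) <= 0) || any(depth_cuts <= 0))
    stop("depth_cuts must be nonempty and strictly increasing")
  set.seed(seed)
  nx <- round(diff(lon_range) / grid_resolution)
  ny <- round(diff(lat_range) / grid_resolution)
  lon <- lon_range[1] + (seq_len(nx) - 0.5) * grid_resolution
  lat <- lat_range[1] + (seq_len(ny) - 0.5) * grid_resolution
  cells <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  cells$lon <- lon[cells$ix]
  cells$lat <- lat[cells$iy]
  cells$cell <- seq_len(nrow(cells))
  # contiguous partition: nearest seeded centre (ties broken by centre index)
  if (n_polygons == 1) {
    cells$polygon <- 1L
  } else {
    cx <- stats::runif(n_polygons, lon_range[1], lon_range[2])
    cy <- stats::runif(n_polygons, lat_range[1], lat_range[2])
    d2 <- outer(cells$lon, cx, "-")^2 + outer(cells$lat, cy, "-")^2
    cells$polygon <- max.col(-d2, ties.method = "first")
    # guard against empty polygons: reassign nearest unclaimed cells
    for (p in seq_len(n_polygons)) {
      if (!any(cells$polygon == p)) {
        free <- which(tabulate(cells$polygon, n_polygons)[cells$polygon] > 1)
        take <- free[which.min(d2[free, p])]
        cells$polygon[take] <- p
      }
    }
  }
  cell_area <- grid_resolution * 111.32 *
    grid_resolution * 111.32 * cos(mean(lat_range) * pi / 180)
  npc <- tabulate(cells$polygon, n_polygons)
  cells$weight <- 1 / npc[cells$polygon]
  # bottom depth: north (shallow shelf) to south (deep basin), mild noise
  tfrac <- (lat_range[2] - cells$lat) / diff(lat_range)
  cell_depth <- exp(log(shelf_depth) + tfrac * (log(basin_depth) - log(shelf_depth)))
  cell_depth <- cell_depth * exp(stats::rnorm(nrow(cells), 0, 0.08))
  bottom <- as.vector(tapply(cell_depth, cells$polygon, mean))
  nl <- length(depth_cuts) + 1
  edges <- c(0, depth_cuts, Inf)
  thick <- matrix(0, n_polygons, nl)
  for (p in seq_len(n_polygons)) {
    lo <- pmin(edges[seq_len(nl)], bottom[p])
    hi <- pmin(edges[seq_len(nl) + 1], bottom[p])
    thick[p, ] <- pmax(hi - lo, 0)
  }
  polygons <- data.frame(
    polygon_id = seq_len(n_polygons),
    area_km2 = npc * cell_area,
    bottom_depth = bottom,
    n_water_layers = rowSums(thick > 0)
  )
  # adjacency: polygons sharing a cell edge
  grid <- matrix(cells$polygon, nx, ny)
  pairs <- rbind(
    cbind(as.vector(grid[-nx, ]), as.vector(grid[-1, ])),
    cbind(as.vector(grid[, -ny]), as.vector(grid[, -1]))
  )
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- unique(t(apply(pairs, 1, sort)))
  structure(list(n_polygons = n_polygons, cells = cells, polygons = polygons,
                 depth_cuts = depth_cuts, n_layers = nl,
                 layer_thickness = thick, adjacency = pairs,
                 nx = nx, ny = ny, lon = lon, lat = lat,
                 lon_range = lon_range, lat_range = lat_range,
                 grid_resolution = grid_resolution,
                 cell_area_km2 = cell_area, seed = seed),
            class = "spill_geometry")
}

# Polygon containing a lon/lat point.
polygon_at <- function(geometry, lon, lat) {
  d2 <- (geometry$cells$lon - lon)^2 + (geometry$cells$lat - lat)^2
  geometry$cells$polygon[which.min(d2)]
}

# Water layer index containing a given depth (m).
layer_at_depth <- function(geometry, depth) {
  findInterval(depth, c(0, geometry$depth_cuts), rightmost.closed = FALSE)
}
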