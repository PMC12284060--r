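#' Construct a model grid
#'
#' Bundles the horizontal cell geometry of a structured ocean-model grid:
#' cell-center coordinates, bathymetry, land mask and cell areas. All other
#' objects in the package (fields, masks, boundaries) are defined on a
#' `model_grid`.
#'
#' @param lat,lon Numeric matrices (ny x nx) of cell-center latitude
#'   (degrees north, within \[-90, 90\]) and longitude (degrees east).
#' @param bottom_depth Numeric matrix (ny x nx) of bathymetry in meters,
#'   positive down. Must be >= 0 on water cells; values on land cells are
#'   ignored.
#' @param land_mask Logical matrix (ny x nx), `TRUE` on land cells.
#' @param cell_area Optional numeric matrix (ny x nx) of cell areas in km2,
#'   strictly positive on water cells. If `NULL`, areas are estimated from
#'   the local grid spacing on a sphere (requires ny, nx >= 2).
#'
#' @return An object of class `model_grid`.
#' @export
model_grid <- function(lat, lon, bottom_depth, land_mask, cell_area = NULL) {
  dims <- dim(lat)
  if (is.null(dims) || length(dims) != 2L)
    stop("lat must be a 2-D matrix of cell-center latitudes")
  for (nm in c("lon", "bottom_depth", "land_mask")) {
    m <- get(nm)
    if (!identical(dim(m), dims))
      stop(sprintf("%s must have the same dimensions as lat", nm))
  }
  if (any(lat < -90 | lat > 90)) stop("latitudes must lie within [-90, 90]")
  land_mask <- land_mask & TRUE  # coerce to logical
  if (any(bottom_depth[!land_mask] < 0, na.rm = TRUE))
    stop("bottom_depth must be >= 0 (meters, positive down) on water cells")
  if (is.null(cell_area)) cell_area <- .cell_area_from_spacing(lat, lon)
  if (!identical(dim(cell_area), dims))
    stop("cell_area must have the same dimensions as lat")
  if (any(cell_area[!land_mask] <= 0, na.rm = TRUE))
    stop("cell_area must be > 0 (km2) on water cells")
  structure(
    list(lat = lat, lon = lon, bottom_depth = bottom_depth,
         land_mask = land_mask, cell_area = cell_area),
    class = "model_grid")
}

# Spherical cell-area estimate from cell-center spacing: R^2 dlat dlon cos(lat).
.cell_area_from_spacing <- function(lat, lon) {
  if (nrow(lat) < 2L || ncol(lat) < 2L)
    stop("cell_area cannot be estimated from a grid smaller than 2 x 2; ",
         "supply it explicitly")
  km_per_deg <- pi / 180 * 6371
  dlat <- apply(lat, 2, function(v) .center_diff(v))
  dlon <- t(apply(lon, 1, function(v) .center_diff(v)))
  abs(dlat) * abs(dlon) * km_per_deg^2 * cos(lat * pi / 180)
}

.center_diff <- function(v) {
  n <- length(v)
  d <- numeric(n)
  d[1] <- v[2] - v[1]
  d[n] <- v[n] - v[n - 1]
  if (n > 2) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
  d
}

#' @export
print.model_grid <- function(x, ...) {
  d <- dim(x$lat)
  cat(sprintf("<model_grid> %d x %d cells (%d land, %d water)\n",
              d[1], d[2], sum(x$land_mask), sum(!x$land_mask)))
  cat(sprintf("  lat %.2f..%.2f, lon %.2f..%.2f, max depth %.0f m\n",
              min(x$lat), max(x$lat), min(x$lon), max(x$lon),
              max(x$bottom_depth[!x$land_mask], 0)))
  invisible(x)
}

#' Great-circle distance from each water cell to the nearest land cell
#'
#' Offshore distance is the haversine great-circle distance (km, Earth radius
#' 6371 km) from each water cell center to the nearest land cell center. Land
#' cells are assigned distance 0.
#'
#' @param grid A [model_grid()].
#' @return Numeric matrix (ny x nx) of distances in km.
#' @export
distance_offshore <- function(grid) {
  stopifnot(inherits(grid, "model_grid"))
  if (!any(grid$land_mask))
    stop("grid has no land cells: a coastline is required to measure ",
         "offshore distance")
  out <- matrix(0, nrow(grid$lat), ncol(grid$lat))
  wet <- !grid$land_mask
  land_pts <- cbind(grid$lon[grid$land_mask], grid$lat[grid$land_mask])
  wet_pts <- cbind(grid$lon[wet], grid$lat[wet])
  d_m <- geosphere::distm(wet_pts, land_pts,
                          fun = function(p1, p2)
                            geosphere::distHaversine(p1, p2, r = 6371000))
  out[wet] <- apply(d_m, 1, min) / 1000
  out
}

#' Parameters of the analysis-domain mask
#'
#' Defaults follow the study-domain definition for the central California
#' Current: cells deeper than the 400 m isobath, within 200 km of the coast,
#' between Point Conception (34.5 N) and Cape Mendocino (40 N).
#'
#' @param min_bottom_depth_m Minimum bathymetry in meters (inclusive).
#' @param max_offshore_km Maximum distance from the coast in km (inclusive).
#' @param lat_min_deg,lat_max_deg Latitude bounds in degrees north (inclusive).
#' @return A list of class `domain_mask_params`.
#' @export
domain_mask_params <- function(min_bottom_depth_m = 400,
                               max_offshore_km = 200,
                               lat_min_deg = 34.5, lat_max_deg = 40.0) {
  stopifnot(min_bottom_depth_m > 0, max_offshore_km > 0,
            lat_min_deg < lat_max_deg)
  structure(list(min_bottom_depth_m = min_bottom_depth_m,
                 max_offshore_km = max_offshore_km,
                 lat_min_deg = lat_min_deg, lat_max_deg = lat_max_deg),
            class = "domain_mask_params")
}

#' Build the analysis-domain mask
#'
#' A cell belongs to the analysis domain iff it is water, its bottom depth is
#' at least `min_bottom_depth_m`, it lies no farther than `max_offshore_km`
#' from the nearest land cell, and its latitude falls within the configured
#' bounds. All bounds are inclusive.
#'
#' @param grid A [model_grid()].
#' @param params A [domain_mask_params()].
#' @param offshore_km Optional precomputed [distance_offshore()] matrix.
#' @return Logical matrix (ny x nx), `TRUE` inside the analysis domain.
#' @export
build_domain_mask <- function(grid, params = domain_mask_params(),
                              offshore_km = NULL) {
  stopifnot(inherits(grid, "model_grid"), inherits(params, "domain_mask_params"))
  if (is.null(offshore_km)) offshore_km <- distance_offshore(grid)
  mask <- !grid$land_mask &
    grid$bottom_depth >= params$min_bottom_depth_m &
    offshore_km <= params$max_offshore_km &
    grid$lat >= params$lat_min_deg & grid$lat <= params$lat_max_deg
  if (!any(mask)) message("domain mask is empty under the given parameters")
  mask
}

#' Total area of a domain mask
#'
#' @param grid A [model_grid()].
#' @param mask Logical matrix matching the grid.
#' @return Total area in km2 (>= 0).
#' @export
domain_area <- function(grid, mask) {
  stopifnot(inherits(grid, "model_grid"), identical(dim(mask), dim(grid$lat)))
  sum(grid$cell_area[mask])
}
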