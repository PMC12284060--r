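# Shared fixtures: tiny grids and single-column fields built in code.

# Regular lat/lon grid; equal_area = TRUE gives uniform 9 km2 cells so that
# weighted and unweighted spatial means coincide in tests that need that.
make_test_grid <- function(nx = 6, ny = 5, depth = 600, lat0 = 36,
                           dlat = 0.05, lon0 = -124, dlon = 0.05,
                           n_land_cols = 1, equal_area = FALSE) {
  lat <- matrix(lat0 + dlat * (seq_len(ny) - 1), ny, nx)
  lon <- matrix(lon0 + dlon * (seq_len(nx) - 1), ny, nx, byrow = TRUE)
  land <- matrix(FALSE, ny, nx)
  land[, nx - seq_len(n_land_cols) + 1] <- TRUE
  bd <- matrix(depth, ny, nx)
  bd[land] <- 0
  area <- if (equal_area) matrix(9, ny, nx) else NULL
  model_grid(lat, lon, bd, land, cell_area = area)
}

# One vertical profile replicated over a (ny, nx, nt) grid.
make_profile_field <- function(profile, depth_levels, variable = "var",
                               units = "u", ny = 1, nx = 1, nt = 1,
                               time_stamps = NULL) {
  if (is.null(time_stamps))
    time_stamps <- seq(as.Date("2000-01-15"), by = "month", length.out = nt)
  v <- array(rep(profile, each = ny * nx), dim = c(ny, nx, length(profile), nt))
  field4d(v, variable, units, depth_levels, time_stamps)
}

# Independent haversine (hand formula, R = 6371 km) for distance oracles.
haversine_ref <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

# Monthly Date axis for a span of years.
monthly_dates <- function(years) {
  as.Date(sprintf("%d-%02d-15", rep(years, each = 12), 1:12))
}
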