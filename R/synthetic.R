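#' Default vertical levels of the synthetic grid
#'
#' 10 m spacing through the upper 400 m (where both habitat boundaries
#' live), coarser below. Meters, positive down.
#' @return Numeric vector of level depths.
#' @export
default_depth_levels <- function() {
  c(seq(5, 95, by = 10), seq(105, 395, by = 10), seq(420, 580, by = 40))
}

#' Scenario parameters for one synthetic ensemble member
#'
#' Encodes the century-scale structure a downscaled projection member is
#' emulated with: a warming rate at 150 m, a signed dissolved-oxygen trend
#' at 300 m (negative for deoxygenating members, positive for a member in
#' which subsurface oxygen increases), a fractional chlorophyll trend,
#' initial boundary depths, AR(1) interannual noise, and optional marine-
#' heatwave years in which chlorophyll is suppressed and temperature bumped.
#'
#' @param member Member id string.
#' @param surface_warming_rate Warming at 150 m, degC/century.
#' @param oxygen_trend_at_300m Signed DO trend at 300 m, mmol/m3/century.
#' @param chl_trend Fractional chlorophyll trend per century (e.g. -0.3 for
#'   a 30% decline).
#' @param initial_hypoxic_depth Mean depth (m) of the 63 mmol/m3 isopleth at
#'   the start of the century.
#' @param initial_upper_light_depth Mean depth (m) of the light-threshold
#'   boundary at the start of the century; calibrates the phytoplankton
#'   magnitude through the attenuation model.
#' @param do_gradient Vertical DO gradient (mmol/m3 per m, magnitude) at the
#'   initial hypoxic isopleth; together with the oxygen trend it sets the
#'   isopleth shoaling rate (trend / gradient).
#' @param interannual_sd Named list of yearly anomaly SDs:
#'   `temperature` (degC), `oxygen` (mmol/m3), `chl_frac` (fractional).
#' @param ar1_rho Lag-1 autocorrelation of the yearly anomalies.
#' @param heatwave_years Integer years flagged as marine heatwaves.
#' @param chl_suppression_fraction Fractional chlorophyll suppression in
#'   heatwave years.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A list of class `scenario_params`.
#' @export
scenario_params <- function(member = "member",
                            surface_warming_rate = 1.8,
                            oxygen_trend_at_300m = -29,
                            chl_trend = -0.30,
                            initial_hypoxic_depth = 290,
                            initial_upper_light_depth = 187,
                            do_gradient = 0.23,
                            interannual_sd = list(temperature = 0.15,
                                                  oxygen = 2,
                                                  chl_frac = 0.05),
                            ar1_rho = 0.5,
                            heatwave_years = integer(),
                            chl_suppression_fraction = 0.3,
                            seed = 1L) {
  stopifnot(is.finite(surface_warming_rate), is.finite(oxygen_trend_at_300m),
            is.finite(chl_trend), initial_hypoxic_depth > 0,
            initial_upper_light_depth > 0, do_gradient > 0,
            ar1_rho >= 0, ar1_rho < 1,
            chl_suppression_fraction >= 0, chl_suppression_fraction < 1)
  structure(as.list(environment()), class = "scenario_params")
}

#' The three default scenarios
#'
#' A low-warming and a moderate-warming member with declining subsurface
#' oxygen, and a high-warming member with increasing subsurface oxygen —
#' the qualitative ensemble structure of the projections emulated (ensemble-
#' mean DO trend at 300 m of -14.3 mmol/m3/century, which with the default
#' isopleth gradient imposes ~0.62 m/yr of hypoxic-boundary shoaling).
#'
#' @param seed Base seed; member seeds are derived as seed, seed+1, seed+2.
#' @return Named list of three [scenario_params()].
#' @export
default_scenarios <- function(seed = 1L) {
  list(
    gfdl = scenario_params(member = "gfdl", surface_warming_rate = 1.2,
                           oxygen_trend_at_300m = -24, seed = seed),
    ipsl = scenario_params(member = "ipsl", surface_warming_rate = 1.8,
                           oxygen_trend_at_300m = -29, seed = seed + 1L),
    hadl = scenario_params(member = "hadl", surface_warming_rate = 2.6,
                           oxygen_trend_at_300m = 10, seed = seed + 2L))
}

#' Generate a synthetic coastal model grid
#'
#' A rectangular grid with a meridional coastline on the east edge and
#' bottom depth increasing monotonically offshore following a tanh shelf-
#' slope profile. Cell areas follow spherical geometry (so they vary with
#' the cosine of latitude).
#'
#' @param nx,ny Grid size (>= 4 each). Columns run west to east.
#' @param shelf_width_cells e-folding width of the shelf-slope tanh, in
#'   cells.
#' @param max_depth_m Offshore maximum depth, m.
#' @param lat_range,lon_range Length-2 vectors of cell-center coordinate
#'   ranges, degrees.
#' @param n_land_cols Number of land columns at the east edge.
#' @return A [model_grid()].
#' @export
generate_grid <- function(nx = 40, ny = 60, shelf_width_cells = 6,
                          max_depth_m = 600,
                          lat_range = c(34, 40.5),
                          lon_range = c(-126.5, -121.5),
                          n_land_cols = 1L) {
  stopifnot(nx >= 4, ny >= 4, n_land_cols >= 1, n_land_cols < nx)
  lat <- matrix(seq(lat_range[1], lat_range[2], length.out = ny), ny, nx)
  lon <- matrix(seq(lon_range[1], lon_range[2], length.out = nx), ny, nx,
                byrow = TRUE)
  land <- matrix(FALSE, ny, nx)
  land[, (nx - n_land_cols + 1L):nx] <- TRUE
  coast_col <- nx - n_land_cols + 1L  # westernmost land column
  cells_off <- matrix(rep(pmax(coast_col - seq_len(nx), 0), each = ny), ny, nx)
  depth <- max_depth_m * tanh(cells_off / shelf_width_cells)
  depth[land] <- 0
  model_grid(lat = lat, lon = lon, bottom_depth = depth, land_mask = land)
}

# Analytic tanh DO base profile through (z0, threshold) with gradient g there.
# DO(z) = do_deep + (do_surf - do_deep)/2 * (1 - tanh((z - zm)/w))
.do_profile_params <- function(z0, g, threshold = 63,
                               do_surf = 250, do_deep = 20) {
  f <- (threshold - do_deep) / (do_surf - do_deep)
  stopifnot(f > 0, f < 1)
  u <- atanh(1 - 2 * f)
  w <- (do_surf - do_deep) * (1 - (1 - 2 * f)^2) / (2 * g)
  list(zm = z0 - u * w, w = w, do_surf = do_surf, do_deep = do_deep)
}

.do_base <- function(z, pp) {
  pp$do_deep + (pp$do_surf - pp$do_deep) / 2 * (1 - tanh((z - pp$zm) / pp$w))
}

# AR(1) yearly anomaly series with stationary SD `sd`.
.ar1 <- function(n, rho, sd) {
  x <- numeric(n)
  if (n == 0L || sd == 0) return(x)
  x[1] <- stats::rnorm(1, sd = sd)
  if (n > 1) for (i in 2:n)
    x[i] <- rho * x[i - 1] + stats::rnorm(1, sd = sd * sqrt(1 - rho^2))
  x
}

#' Generate one synthetic ensemble member
#'
#' Produces monthly fields of temperature, dissolved oxygen, phytoplankton
#' nitrogen biomass (all 4-D) and surface shortwave (2-D + time) with the
#' statistical structure the habitat analysis assumes:
#'
#' * temperature: surface-intensified mean profile anchored near 8.8 degC at
#'   150 m, seasonal cycle decaying with depth, surface-intensified linear
#'   century warming scaled to `surface_warming_rate` at 150 m, AR(1) yearly
#'   anomalies;
#' * oxygen: monotone tanh profile passing through the hypoxic threshold at
#'   `initial_hypoxic_depth` with gradient `do_gradient`, a spatial pattern
#'   deepening the isopleth offshore, a linear trend at depth scaled to
#'   `oxygen_trend_at_300m` (tapering to zero at the surface), and AR(1)
#'   yearly anomalies; values are clipped at zero with a logged count;
#' * phytoplankton: exponential biomass profile whose magnitude is
#'   calibrated so that the derived bulk attenuation puts the light-
#'   threshold boundary near `initial_upper_light_depth` under the annual-
#'   mean shortwave; seasonal cycle, fractional century trend, heatwave
#'   suppression, AR(1) fractional anomalies;
#' * shortwave: sinusoidal seasonal climatology (annual mean 200 W/m2).
#'
#' Generation is fully deterministic for a fixed seed.
#'
#' @param grid A [model_grid()], typically from [generate_grid()].
#' @param params A [scenario_params()].
#' @param years Integer vector of simulated calendar years.
#' @param depth_levels Level depths, m.
#' @param optics An [optics_params()] used for the biomass calibration.
#' @param thresholds A [habitat_thresholds()] (light threshold used in the
#'   calibration).
#' @return A list of class `synthetic_member`: `grid`, `params`,
#'   `temperature`, `oxygen`, `phyto` ([field4d()]s), `shortwave`
#'   (array ny x nx x nt), `time_stamps`.
#' @export
generate_member <- function(grid, params = scenario_params(),
                            years = 2000:2100,
                            depth_levels = default_depth_levels(),
                            optics = optics_params(),
                            thresholds = habitat_thresholds()) {
  stopifnot(inherits(grid, "model_grid"), inherits(params, "scenario_params"))
  set.seed(params$seed)
  ny <- nrow(grid$lat); nx <- ncol(grid$lat)
  nz <- length(depth_levels); z <- depth_levels
  nyr <- length(years)
  nt <- 12L * nyr
  time_stamps <- as.Date(sprintf("%d-%02d-15", rep(years, each = 12L), 1:12))
  month <- rep(1:12, times = nyr)
  t_century <- (rep(years, each = 12L) + (month - 0.5) / 12 - years[1]) / 100

  # yearly AR(1) anomalies, replicated to months
  a_T <- rep(.ar1(nyr, params$ar1_rho, params$interannual_sd$temperature),
             each = 12L)
  a_O <- rep(.ar1(nyr, params$ar1_rho, params$interannual_sd$oxygen),
             each = 12L)
  a_C <- rep(.ar1(nyr, params$ar1_rho, params$interannual_sd$chl_frac),
             each = 12L)

  # --- shortwave: seasonal climatology, annual mean 200 W/m2
  sw_month <- 200 * (1 + 0.45 * cos(2 * pi * (month - 6.5) / 12))
  shortwave <- array(rep(sw_month, each = ny * nx), dim = c(ny, nx, nt))

  # --- temperature
  t_base <- 5 + 12 * exp(-z / 130)                     # 8.78 degC at 150 m
  seas_amp <- 3 * exp(-z / 40)
  warm_prof <- exp(-z / 217) / exp(-150 / 217)         # = 1 at 150 m
  lat_grad <- -0.15 * (grid$lat - mean(grid$lat))      # cooler poleward
  Tarr <- array(NA_real_, dim = c(ny, nx, nz, nt))
  for (j in seq_len(nz)) {
    prof_t <- t_base[j] + seas_amp[j] * cos(2 * pi * (month - 8.5) / 12) +
      params$surface_warming_rate * warm_prof[j] * t_century +
      a_T * exp(-z[j] / 200)
    Tarr[, , j, ] <- rep(lat_grad, times = nt) +
      rep(prof_t, each = ny * nx)
  }

  # --- dissolved oxygen
  pp <- .do_profile_params(params$initial_hypoxic_depth, params$do_gradient,
                           thresholds$oxygen_threshold)
  offshore <- distance_offshore(grid)
  off_norm <- offshore / max(offshore)
  lat_norm <- (grid$lat - min(grid$lat)) / max(diff(range(grid$lat)), 1e-9)
  # isopleth deepens offshore, gentle along-shore wiggle
  z0_shift <- 60 * (off_norm - 0.3) + 8 * sin(2 * pi * lat_norm)
  z0_shift[grid$land_mask] <- 0
  taper <- pmin(z / 150, 1)                            # trend vanishes at surface
  Oarr <- array(NA_real_, dim = c(ny, nx, nz, nt))
  zm_cell <- pp$zm + z0_shift                          # (ny, nx)
  for (j in seq_len(nz)) {
    base_j <- pp$do_deep + (pp$do_surf - pp$do_deep) / 2 *
      (1 - tanh((z[j] - zm_cell) / pp$w))              # (ny, nx)
    trend_j <- (params$oxygen_trend_at_300m * t_century + a_O) * taper[j]
    Oarr[, , j, ] <- rep(base_j, times = nt) + rep(trend_j, each = ny * nx)
  }
  nclip <- sum(Oarr < 0, na.rm = TRUE)
  if (nclip > 0) {
    Oarr[Oarr < 0] <- 0
    message(nclip, " oxygen value(s) clipped at 0")
  }

  # --- phytoplankton biomass, calibrated to the target light boundary
  sw_mean <- mean(sw_month)
  i0_par <- optics$par_fraction_of_shortwave * sw_mean
  k_target <- log(i0_par / thresholds$light_threshold) /
    params$initial_upper_light_depth
  if (k_target <= optics$k_chl_a)
    stop("initial_upper_light_depth is unreachable: required attenuation is ",
         "below the pure-water term")
  chl_avg_target <- ((k_target - optics$k_chl_a) / optics$k_chl_b) ^
    (1 / optics$k_chl_c)
  shape <- exp(-z / 60)
  # 0-100 m depth average of the shape, by the same trapezoid rule the
  # pipeline integrates with (surface-extended)
  zi <- c(0, z[z < 100], 100)
  si <- exp(-zi / 60); si[1] <- si[2]
  shape_avg <- sum((si[-1] + si[-length(si)]) / 2 * diff(zi)) / 100
  b0 <- chl_avg_target / (phyto_to_chl(1, optics) * shape_avg)
  hw <- rep(years, each = 12L) %in% params$heatwave_years
  scale_t <- pmax(1 + params$chl_trend * t_century, 0.05) * (1 + a_C) *
    ifelse(hw, 1 - params$chl_suppression_fraction, 1)
  seas_p <- 1 + 0.3 * cos(2 * pi * (month - 4.5) / 12)  # spring maximum
  Parr <- array(NA_real_, dim = c(ny, nx, nz, nt))
  for (j in seq_len(nz)) {
    prof_p <- b0 * shape[j] * scale_t * seas_p
    Parr[, , j, ] <- rep(prof_p, each = ny * nx)
  }
  Parr[Parr < 0] <- 0

  member <- list(
    grid = grid, params = params, time_stamps = time_stamps,
    temperature = mask_below_bottom(
      field4d(Tarr, "temperature", "degC", z, time_stamps), grid),
    oxygen = mask_below_bottom(
      field4d(Oarr, "oxygen", "mmol/m3", z, time_stamps), grid),
    phyto = mask_below_bottom(
      field4d(Parr, "phyto", "mmolN/m3", z, time_stamps), grid),
    shortwave = shortwave)
  class(member) <- "synthetic_member"
  member
}

#' @export
print.synthetic_member <- function(x, ...) {
  cat(sprintf("<synthetic_member> %s: %d x %d cells, %d levels, %s..%s\n",
              x$params$member, nrow(x$grid$lat), ncol(x$grid$lat),
              length(x$temperature$depth_levels),
              format(min(x$time_stamps)), format(max(x$time_stamps))))
  cat(sprintf("  warming %.1f degC/century @150m, DO trend %+.0f mmol/m3/century @300m, chl trend %+.0f%%/century\n",
              x$params$surface_warming_rate, x$params$oxygen_trend_at_300m,
              100 * x$params$chl_trend))
  invisible(x)
}

#' Generate a synthetic ensemble
#'
#' @param grid A [model_grid()].
#' @param scenarios List of [scenario_params()] (default
#'   [default_scenarios()]).
#' @param ... Passed to [generate_member()].
#' @return Named list of `synthetic_member` objects.
#' @export
generate_ensemble <- function(grid, scenarios = default_scenarios(), ...) {
  lapply(scenarios, function(p) generate_member(grid, p, ...))
}

#' Draw pseudo-observations from a synthetic member
#'
#' Samples random water cells, wet depths and months from a member's fields
#' and adds Gaussian noise — input for the model-evaluation stage. Values
#' are taken by linear interpolation in depth at the sampled cell and month
#' (the same scheme [cosample()] uses), so with zero noise co-sampling
#' recovers them exactly.
#'
#' @param member A `synthetic_member`.
#' @param n_per_year Records per variable per year, >= 1.
#' @param noise_sd Named list of observation-noise SDs per variable (units
#'   of the variable), e.g. `list(temperature = 0.1, oxygen = 1)`.
#' @param variables Which member fields to sample.
#' @param seed Integer seed.
#' @return A [tibble::tibble()] with columns `lat`, `lon`, `depth`, `time`,
#'   `variable`, `value`, `units`.
#' @export
generate_observations <- function(member, n_per_year = 50,
                                  noise_sd = list(temperature = 0.1,
                                                  oxygen = 1),
                                  variables = c("temperature", "oxygen"),
                                  seed = 1L) {
  stopifnot(inherits(member, "synthetic_member"), n_per_year >= 1)
  set.seed(seed)
  grid <- member$grid
  yrs <- unique(as.integer(format(member$time_stamps, "%Y")))
  n <- n_per_year * length(yrs)
  wet <- which(!grid$land_mask & grid$bottom_depth >=
                 min(member$temperature$depth_levels) * 2)
  out <- list()
  for (v in variables) {
    f <- member[[v]]
    zl <- f$depth_levels
    cell <- sample(wet, n, replace = TRUE)
    bd <- grid$bottom_depth[cell]
    depth <- stats::runif(n, min(zl), pmin(bd, max(zl)))
    ti <- sample(length(member$time_stamps), n, replace = TRUE)
    jz <- findInterval(depth, zl, all.inside = TRUE)
    ci <- arrayInd(cell, dim(grid$lat))
    v_lo <- f$values[cbind(ci, jz, ti)]
    v_hi <- f$values[cbind(ci, jz + 1L, ti)]
    w <- (depth - zl[jz]) / (zl[jz + 1L] - zl[jz])
    val <- (1 - w) * v_lo + w * v_hi
    sdv <- if (!is.null(noise_sd[[v]])) noise_sd[[v]] else 0
    val <- val + stats::rnorm(n, sd = sdv)
    ok <- !is.na(val)
    out[[v]] <- tibble::tibble(
      lat = grid$lat[cell][ok], lon = grid$lon[cell][ok],
      depth = depth[ok], time = member$time_stamps[ti][ok],
      variable = v, value = val[ok], units = f$units)
  }
  do.call(rbind, out)
}
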