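#' Co-sample a model field at observation locations and times
#'
#' For each observation record, takes the model value at the nearest water
#' grid cell (great-circle distance), linearly interpolated in depth between
#' the bracketing levels, at the nearest model month. No horizontal
#' interpolation is performed: at km-scale grids the positioning error of
#' shipboard observations dominates the cell-to-cell gradient. Records
#' outside the model's space-time-depth bounds (or hitting a dry cell/level)
#' are dropped with a logged count.
#'
#' @param field A [field4d()] for one variable.
#' @param grid A [model_grid()].
#' @param obs A data frame with columns `lat`, `lon`, `depth` (m), `time`
#'   (`Date`), `value`; extra columns are carried through.
#' @return `obs` restricted to matchable records, with a `model_value`
#'   column appended.
#' @export
cosample <- function(field, grid, obs) {
  stopifnot(inherits(field, "field4d"), inherits(grid, "model_grid"))
  need <- c("lat", "lon", "depth", "time", "value")
  if (!all(need %in% names(obs)))
    stop("obs must have columns: ", paste(need, collapse = ", "))
  n0 <- nrow(obs)
  zl <- field$depth_levels
  in_depth <- obs$depth >= min(zl) & obs$depth <= max(zl)
  tnum <- as.numeric(as.Date(obs$time))
  mt <- as.numeric(field$time_stamps)
  half <- stats::median(diff(mt)) / 2 + 1
  in_time <- tnum >= min(mt) - half & tnum <= max(mt) + half
  obs <- obs[in_depth & in_time, , drop = FALSE]
  if (nrow(obs) == 0L) stop("no observations fall inside the model bounds")
  wet <- which(!grid$land_mask)
  wet_pts <- cbind(grid$lon[wet], grid$lat[wet])
  d <- geosphere::distm(cbind(obs$lon, obs$lat), wet_pts,
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2, r = 6371000))
  cell <- wet[apply(d, 1, which.min)]
  ti <- vapply(as.numeric(as.Date(obs$time)),
               function(x) which.min(abs(mt - x)), integer(1))
  jz <- findInterval(obs$depth, zl, all.inside = TRUE)
  ny <- dim(field$values)[1]; nx <- dim(field$values)[2]
  nz <- length(zl)
  ci <- arrayInd(cell, c(ny, nx))
  idx_lo <- cbind(ci, jz, ti)
  idx_hi <- cbind(ci, pmin(jz + 1L, nz), ti)
  v_lo <- field$values[idx_lo]
  v_hi <- field$values[idx_hi]
  w <- ifelse(zl[pmin(jz + 1L, nz)] > zl[jz],
              (obs$depth - zl[jz]) / (zl[pmin(jz + 1L, nz)] - zl[jz]), 0)
  w[obs$depth <= zl[jz]] <- 0
  mv <- (1 - w) * v_lo + w * v_hi
  keep <- !is.na(mv)
  dropped <- n0 - sum(keep)
  if (dropped > 0)
    message(dropped, " observation(s) dropped (outside bounds or dry cells)")
  obs <- obs[keep, , drop = FALSE]
  obs$model_value <- mv[keep]
  tibble::as_tibble(obs)
}

#' Evaluate co-sampled projections against observations
#'
#' Aggregates paired (observed, simulated) values to annual means, then
#' reports means, bias (simulated minus observed, also as a percentage of
#' the observed mean), OLS trends of both annual series, and the trends
#' recomputed on a restricted sub-period (emulating a trend-sensitivity
#' re-analysis that excludes anomalous late years). When pairs from several
#' ensemble members are supplied (via a `member` column), the simulated
#' annual series is the ensemble mean and the per-year ensemble spread of
#' the simulated annual values is summarized as its time mean.
#'
#' @param pairs Output of [cosample()] (optionally with a `member` column);
#'   needs >= 3 distinct years.
#' @param sub_period Inclusive year range for the sub-period trend
#'   (default `c(2000, 2013)`).
#' @return A one-row [tibble::tibble()] with `observed_mean`,
#'   `simulated_mean`, `bias`, `bias_pct`, `observed_trend`,
#'   `simulated_trend`, `observed_trend_sub`, `simulated_trend_sub`,
#'   `ensemble_spread_mean`, `n_years`; attribute `annual` holds the annual
#'   paired series.
#' @export
evaluate_projections <- function(pairs, sub_period = c(2000, 2013)) {
  yr <- as.integer(format(as.Date(pairs$time), "%Y"))
  obs_ann <- tapply(pairs$value, yr, mean)
  years <- as.integer(names(obs_ann))
  if (length(years) < 3L) stop("need at least 3 years of paired values")
  if ("member" %in% names(pairs) && length(unique(pairs$member)) > 1L) {
    per_member <- tapply(pairs$model_value,
                         list(yr, pairs$member), mean)
    sim_ann <- rowMeans(per_member, na.rm = TRUE)
    spread <- apply(per_member, 1, stats::sd, na.rm = TRUE)
  } else {
    sim_ann <- tapply(pairs$model_value, yr, mean)
    spread <- rep(NA_real_, length(years))
  }
  annual <- tibble::tibble(year = years,
                           observed = as.numeric(obs_ann),
                           simulated = as.numeric(sim_ann),
                           ensemble_spread = as.numeric(spread))
  trend_of <- function(value, yrs) {
    if (length(yrs) < 3L) return(NA_real_)
    linear_trend(tibble::tibble(year = yrs, value = value))$slope
  }
  sub <- annual$year >= sub_period[1] & annual$year <= sub_period[2]
  obs_mean <- mean(annual$observed)
  bias <- mean(annual$simulated) - obs_mean
  out <- tibble::tibble(
    observed_mean = obs_mean,
    simulated_mean = mean(annual$simulated),
    bias = bias,
    bias_pct = if (obs_mean != 0) 100 * bias / abs(obs_mean) else NA_real_,
    observed_trend = trend_of(annual$observed, annual$year),
    simulated_trend = trend_of(annual$simulated, annual$year),
    observed_trend_sub = trend_of(annual$observed[sub], annual$year[sub]),
    simulated_trend_sub = trend_of(annual$simulated[sub], annual$year[sub]),
    ensemble_spread_mean = mean(annual$ensemble_spread),
    n_years = length(years))
  attr(out, "annual") <- annual
  out
}
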