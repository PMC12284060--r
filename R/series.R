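#' Annual domain-averaged series of a 2-D + time metric
#'
#' Spatial mean over the masked, defined cells of each monthly slab
#' (area-weighted by default, with weights renormalized over the defined
#' cells), followed by the calendar-year mean of the monthly values. Years
#' with missing months are flagged in the `complete` column; months with no
#' defined cell yield `NA` and are logged.
#'
#' @param values Array (ny, nx, nt) of a per-cell metric.
#' @param time_stamps `Date` vector of length nt (monthly or finer).
#' @param grid A [model_grid()].
#' @param mask Non-empty logical domain mask.
#' @param weighting `"area"` (cell-area weights) or `"none"` (plain mean).
#' @param metric,member Optional provenance strings stored as columns.
#' @return A [tibble::tibble()] (class `annual_series`) with columns `year`,
#'   `value`, `n_months`, `complete`, and the provenance columns; attribute
#'   `area_weighted` records the weighting mode.
#' @export
annual_spatial_mean <- function(values, time_stamps, grid, mask,
                                weighting = c("area", "none"),
                                metric = NA_character_,
                                member = NA_character_) {
  weighting <- match.arg(weighting)
  stopifnot(length(dim(values)) == 3L, dim(values)[3] == length(time_stamps))
  if (!any(mask)) stop("mask is empty")
  w <- if (weighting == "area") grid$cell_area[mask] else rep(1, sum(mask))
  nt <- length(time_stamps)
  monthly <- vapply(seq_len(nt), function(t) {
    v <- values[, , t][mask]
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * w[ok]) / sum(w[ok])
  }, numeric(1))
  if (anyNA(monthly))
    message(sum(is.na(monthly)), " time step(s) with zero defined cells")
  yr <- as.integer(format(as.Date(time_stamps), "%Y"))
  years <- sort(unique(yr))
  value <- tapply(monthly, yr, mean, na.rm = TRUE)[as.character(years)]
  value[is.nan(value)] <- NA_real_
  n_months <- tapply(!is.na(monthly), yr, sum)[as.character(years)]
  out <- tibble::tibble(year = years, value = as.numeric(value),
                        n_months = as.integer(n_months),
                        complete = as.integer(n_months) == 12L,
                        metric = metric, member = member)
  attr(out, "area_weighted") <- weighting == "area"
  class(out) <- c("annual_series", class(out))
  out
}

#' Ordinary least-squares linear trend of an annual series
#'
#' Fits value ~ year by OLS and reports the slope (units/yr), intercept,
#' coefficient of determination and the two-sided p-value of the slope. A
#' constant series returns slope 0 and R-squared 0.
#'
#' @param series An `annual_series` (or any data frame with `year` and
#'   `value` columns); at least 3 non-missing years.
#' @return A one-row [tibble::tibble()]: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`.
#' @export
linear_trend <- function(series) {
  df <- series[!is.na(series$value), c("year", "value")]
  if (nrow(df) < 3L) stop("need at least 3 non-missing years")
  if (stats::sd(df$value) == 0)
    return(tibble::tibble(slope = 0, intercept = df$value[1], r_squared = 0,
                          p_value = NA_real_, n = nrow(df)))
  fit <- stats::lm(value ~ year, data = df)
  sm <- summary(fit)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2, 4]),
                 n = nrow(df))
}

#' Epoch means and Welch t-test
#'
#' Compares the annual values of two non-overlapping, inclusive year windows
#' (default 2000-2030 vs 2070-2100) with a two-sided Welch (unequal-variance)
#' two-sample t-test. The reported difference is `mean2 - mean1`.
#'
#' @param series An `annual_series` (or data frame with `year`, `value`).
#' @param window1,window2 Length-2 integer vectors of inclusive year ranges;
#'   each must contain at least 3 non-missing years.
#' @return A one-row [tibble::tibble()]: window bounds, `mean1`, `mean2`,
#'   `difference`, `t_statistic`, `p_value`.
#' @export
epoch_means_ttest <- function(series, window1 = c(2000, 2030),
                              window2 = c(2070, 2100)) {
  if (max(window1[1], window2[1]) <= min(window1[2], window2[2]))
    stop("epoch windows must not overlap")
  v1 <- series$value[series$year >= window1[1] & series$year <= window1[2]]
  v2 <- series$value[series$year >= window2[1] & series$year <= window2[2]]
  v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
  if (length(v1) < 3L || length(v2) < 3L)
    stop("each window needs at least 3 non-missing years")
  if (stats::var(v1) + stats::var(v2) > 0) {
    tt <- stats::t.test(v2, v1, var.equal = FALSE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    # degenerate windows with zero variance: the test statistic is undefined;
    # identical means are reported as p = 1, distinct means as p = 0
    t_stat <- NA_real_
    p <- as.numeric(mean(v2) == mean(v1))
  }
  tibble::tibble(window1_start = window1[1], window1_end = window1[2],
                 window2_start = window2[1], window2_end = window2[2],
                 mean1 = mean(v1), mean2 = mean(v2),
                 difference = mean(v2) - mean(v1),
                 t_statistic = t_stat,
                 p_value = p)
}

#' Ensemble mean and spread of member series
#'
#' Per-year mean across the ensemble members and per-year spread, defined as
#' the standard deviation of the members relative to the ensemble mean
#' (sample SD, divisor n-1, by default).
#'
#' @param member_series A list of `annual_series` objects on identical year
#'   axes (typically one per projection member).
#' @param spread `"sample"` (divisor n-1, default) or `"population"`
#'   (divisor n).
#' @return A [tibble::tibble()] with `year`, `ensemble_mean`,
#'   `ensemble_spread`.
#' @export
ensemble_mean_spread <- function(member_series,
                                 spread = c("sample", "population")) {
  spread <- match.arg(spread)
  stopifnot(length(member_series) >= 2L)
  years <- member_series[[1]]$year
  for (s in member_series[-1])
    if (!identical(s$year, years)) stop("member series have mismatched years")
  vals <- vapply(member_series, function(s) s$value, numeric(length(years)))
  m <- rowMeans(vals)
  sdv <- apply(vals, 1, stats::sd)
  if (spread == "population")
    sdv <- sdv * sqrt((ncol(vals) - 1) / ncol(vals))
  tibble::tibble(year = years, ensemble_mean = m, ensemble_spread = sdv)
}

#' Per-cell epoch-difference map
#'
#' For each cell, the mean over time steps falling in `window2` minus the
#' mean over `window1` (negative values are losses when the input is a
#' habitat metric). Cells undefined throughout either window are `NA`.
#'
#' @param values Array (ny, nx, nt).
#' @param time_stamps `Date` vector of length nt.
#' @param window1,window2 Inclusive year ranges.
#' @return Matrix (ny, nx) of differences.
#' @export
epoch_map_difference <- function(values, time_stamps,
                                 window1 = c(2000, 2030),
                                 window2 = c(2070, 2100)) {
  yr <- as.integer(format(as.Date(time_stamps), "%Y"))
  in1 <- yr >= window1[1] & yr <= window1[2]
  in2 <- yr >= window2[1] & yr <= window2[2]
  if (!any(in1) || !any(in2)) stop("both windows must contain time steps")
  m1 <- apply(values[, , in1, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
  m2 <- apply(values[, , in2, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
  out <- m2 - m1
  out[is.nan(m1) | is.nan(m2)] <- NA_real_
  out
}
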