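test_that("annual spatial means weight by area and average months within years", {
  g <- make_test_grid(nx = 3, ny = 1, depth = 500, n_land_cols = 1,
                      equal_area = TRUE)
  g$cell_area[1, 1:2] <- c(1, 3)
  mask <- !g$land_mask
  ts <- monthly_dates(2000:2001)
  v <- array(NA_real_, dim = c(1, 3, 24))
  v[1, 1, ] <- 4; v[1, 2, ] <- 0
  s_area <- annual_spatial_mean(v, ts, g, mask, weighting = "area")
  s_none <- annual_spatial_mean(v, ts, g, mask, weighting = "none")
  expect_equal(s_area$value, c(1, 1))      # (4*1 + 0*3) / 4
  expect_equal(s_none$value, c(2, 2))
  expect_true(all(s_area$complete))
  # spatially uniform field: series is the constant, either weighting
  v[1, 1:2, ] <- 7.5
  expect_equal(annual_spatial_mean(v, ts, g, mask)$value, c(7.5, 7.5))
})

test_that("incomplete years are flagged and empty slabs are logged", {
  g <- make_test_grid(nx = 3, ny = 1, depth = 500, equal_area = TRUE)
  mask <- !g$land_mask
  ts <- monthly_dates(2000)[1:10]          # ten months only
  v <- array(1, dim = c(1, 3, 10))
  v[, , 4] <- NA                           # one month with no defined cell
  expect_message(s <- annual_spatial_mean(v, ts, g, mask), "zero defined")
  expect_false(s$complete[1])
  expect_equal(s$n_months[1], 9L)
  expect_equal(s$value[1], 1)
})

test_that("linear trends recover exact and constant series", {
  yrs <- 2000:2020
  exact <- tibble::tibble(year = yrs, value = 2 * yrs + 5)
  tr <- suppressWarnings(linear_trend(exact))  # "perfect fit" notice
  expect_equal(tr$slope, 2, tolerance = 1e-10)
  expect_equal(tr$r_squared, 1)
  flat <- tibble::tibble(year = yrs, value = rep(3.3, length(yrs)))
  tr0 <- linear_trend(flat)
  expect_equal(tr0$slope, 0)
  expect_equal(tr0$r_squared, 0)
})

test_that("OLS slope estimation is unbiased within Monte-Carlo error", {
  set.seed(31)
  beta <- 0.05
  slopes <- replicate(500, {
    yrs <- 2000:2099
    linear_trend(tibble::tibble(year = yrs,
                                value = beta * yrs + rnorm(100)))$slope
  })
  se_mean <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - beta), 2 * se_mean)
})

test_that("epoch comparison reports window means and rejects overlap", {
  yrs <- 2000:2100
  s <- tibble::tibble(year = yrs, value = ifelse(yrs <= 2030, 5, 8))
  ec <- epoch_means_ttest(s)
  expect_equal(ec$mean1, 5)
  expect_equal(ec$mean2, 8)
  expect_equal(ec$difference, 3)
  expect_error(epoch_means_ttest(s, c(2000, 2050), c(2040, 2100)), "overlap")
  same <- tibble::tibble(year = yrs, value = rep(c(1, 2, 3), length.out = 101))
  expect_equal(epoch_means_ttest(same)$difference, 0, tolerance = 0.2)
})

test_that("the Welch t statistic matches the hand formula on random samples", {
  set.seed(41)
  for (i in 1:1000) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    x1 <- rnorm(n1, sd = runif(1, 0.5, 3)); x2 <- rnorm(n2, 1, runif(1, 0.5, 3))
    s <- tibble::tibble(year = c(2000:(1999 + n1), 2070:(2069 + n2)),
                        value = c(x1, x2))
    ec <- epoch_means_ttest(s, c(2000, 1999 + n1), c(2070, 2069 + n2))
    t_ref <- (mean(x2) - mean(x1)) / sqrt(var(x1) / n1 + var(x2) / n2)
    expect_equal(ec$t_statistic, t_ref, tolerance = 1e-10)
  }
})

test_that("trend and epoch summaries are consistent on noise-free linear input", {
  yrs <- 2000:2100
  s <- tibble::tibble(year = yrs, value = -0.61 * yrs)
  slope <- suppressWarnings(linear_trend(s))$slope
  ec <- epoch_means_ttest(s)
  # epoch midpoints are 70 years apart, so slope x 70 is the epoch difference
  expect_equal(slope * 70, ec$difference, tolerance = 1e-8)
})

test_that("ensemble spread is the member SD, zero for identical members, permutation invariant", {
  yrs <- 2000:2004
  mk <- function(v) tibble::tibble(year = yrs, value = v)
  m1 <- mk(rep(1, 5)); m2 <- mk(rep(2, 5)); m3 <- mk(rep(3, 5))
  es <- ensemble_mean_spread(list(m1, m2, m3))
  expect_equal(es$ensemble_mean, rep(2, 5))
  expect_equal(es$ensemble_spread, rep(1, 5))   # sample SD of {1,2,3}
  expect_equal(ensemble_mean_spread(list(m1, m1, m1))$ensemble_spread, rep(0, 5))
  perm <- ensemble_mean_spread(list(m3, m1, m2))
  expect_equal(perm$ensemble_spread, es$ensemble_spread)
  # adding a constant shifts the mean, not the spread
  shift <- ensemble_mean_spread(list(mk(rep(1, 5) + 10), mk(rep(2, 5) + 10),
                                     mk(rep(3, 5) + 10)))
  expect_equal(shift$ensemble_mean, es$ensemble_mean + 10)
  expect_equal(shift$ensemble_spread, es$ensemble_spread)
  expect_equal(ensemble_mean_spread(list(m1, m2, m3),
                                    spread = "population")$ensemble_spread,
               rep(sqrt(2 / 3), 5))
  expect_error(ensemble_mean_spread(list(m1, mk(rep(1, 5))[1:4, ])),
               "mismatched")
})

test_that("epoch-difference maps recover drift and preserve the loss sign convention", {
  ts <- monthly_dates(2000:2100)
  nt <- length(ts)
  yrfrac <- as.numeric(format(ts, "%Y")) |> as.integer()
  v <- array(rep(0.1 * (yrfrac - 2000), each = 4), dim = c(2, 2, nt))
  d <- epoch_map_difference(v, ts)
  expect_equal(d, matrix(7, 2, 2), tolerance = 1e-9)  # +1/decade over 70 years
  stationary <- array(5, dim = c(2, 2, nt))
  expect_equal(epoch_map_difference(stationary, ts), matrix(0, 2, 2))
  # a shrinking habitat metric yields negative differences
  shrink <- array(rep(100 - 0.3 * (yrfrac - 2000), each = 4), dim = c(2, 2, nt))
  expect_true(all(epoch_map_difference(shrink, ts) < 0))
  # cells undefined in one window are undefined in the map
  v[1, 1, yrfrac >= 2070] <- NA
  expect_true(is.na(epoch_map_difference(v, ts)[1, 1]))
})
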