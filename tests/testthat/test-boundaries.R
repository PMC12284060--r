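test_that("the light boundary matches the closed-form crossing on analytic columns", {
  z <- seq(2.5, 397.5, by = 5)
  thr <- habitat_thresholds()
  for (k in c(0.035, 0.0443, 0.06)) {
    i0_sw <- 200
    light <- make_profile_field(light_profile(i0_sw, k, z), z,
                                variable = "light", units = "W/m2")
    ub <- upper_boundary(light, thr)
    closed_form <- log(0.43 * i0_sw / thr$light_threshold) / k
    expect_lt(abs(ub$depth[1, 1, 1] - closed_form), 0.5)
  }
})

test_that("a surface already darker than the threshold leaves the upper boundary undefined", {
  z <- seq(5, 95, by = 10)
  light <- make_profile_field(light_profile(0.04, 0.05, z), z)  # PAR 0.0172 at z=0
  ub <- upper_boundary(light)
  expect_true(is.na(ub$depth[1, 1, 1]))
  expect_true(ub$surface_below[1, 1, 1])
})

test_that("stronger attenuation shoals the light boundary", {
  z <- seq(2.5, 397.5, by = 5)
  d <- sapply(c(0.04, 0.05, 0.06), function(k) {
    ub <- upper_boundary(make_profile_field(light_profile(200, k, z), z))
    ub$depth[1, 1, 1]
  })
  expect_true(all(diff(d) < 0))
})

test_that("a light profile increasing with depth is rejected by name", {
  z <- c(10, 20, 30)
  bad <- make_profile_field(c(1, 0.5, 0.7), z)
  expect_error(upper_boundary(bad), "y=1, x=1, t=1")
})

test_that("the hypoxic boundary interpolates, falls back to the bottom and flags hypoxic tops", {
  z <- c(200, 400)
  g <- make_test_grid(nx = 2, ny = 1, depth = 1000, n_land_cols = 1,
                      equal_area = TRUE)
  oxy <- make_profile_field(c(100, 40), z, ny = 1, nx = 2,
                            variable = "oxygen", units = "mmol/m3")
  lb <- lower_boundary(oxy, g)
  expect_equal(lb$depth[1, 1, 1], 200 + 200 * (100 - 63) / 60, tolerance = 1e-9)
  expect_false(lb$bottom_fallback[1, 1, 1])

  well_ox <- make_profile_field(c(120, 80), z, ny = 1, nx = 2)
  lb2 <- lower_boundary(well_ox, g)
  expect_equal(lb2$depth[1, 1, 1], 1000)   # bottom depth stands in
  expect_true(lb2$bottom_fallback[1, 1, 1])

  hypoxic_top <- make_profile_field(c(50, 30), z, ny = 1, nx = 2)
  lb3 <- lower_boundary(hypoxic_top, g)
  expect_equal(lb3$depth[1, 1, 1], 200)
  expect_true(lb3$hypoxic_at_top[1, 1, 1])

  at_level <- make_profile_field(c(63, 30), z, ny = 1, nx = 2)
  expect_equal(lower_boundary(at_level, g)$depth[1, 1, 1], 200)
})

test_that("vertical extent subtracts boundaries, zeroes compressed columns and honors omission", {
  d <- c(1, 1, 4)  # four time steps on one cell
  mk <- function(up, lo, fallback = rep(FALSE, 4)) {
    ub <- structure(list(depth = array(up, d),
                         surface_below = array(FALSE, d),
                         not_reached = array(is.na(up), d)),
                    class = "boundary_field")
    lb <- structure(list(depth = array(lo, d),
                         bottom_fallback = array(fallback, d),
                         hypoxic_at_top = array(FALSE, d)),
                    class = "boundary_field")
    habitat_boundaries(ub, lb)
  }
  hb <- vertical_extent(mk(c(188, 250, 100, NA), c(293, 240, 600, 300),
                           fallback = c(FALSE, FALSE, TRUE, FALSE)))
  expect_equal(hb$extent[1, 1, ], c(105, 0, 500, NA))
  expect_equal(hb$fully_compressed[1, 1, ], c(FALSE, TRUE, FALSE, FALSE))

  strict <- vertical_extent(mk(c(188, 250, 100, NA), c(293, 240, 600, 300),
                               fallback = c(FALSE, FALSE, TRUE, FALSE)),
                            omit_fallback = TRUE)
  expect_true(is.na(strict$extent[1, 1, 3]))      # fallback column omitted
  expect_equal(strict$extent[1, 1, 1], 105)       # others unchanged
})

test_that("extent bookkeeping conserves cells and respects its defining identity", {
  set.seed(5)
  g <- make_test_grid(nx = 6, ny = 5, depth = 700, n_land_cols = 1)
  mask <- !g$land_mask
  z <- seq(5, 595, by = 10)
  nt <- 3
  i0 <- array(runif(5 * 6 * nt, 150, 250), dim = c(5, 6, nt))
  k <- array(runif(5 * 6 * nt, 0.035, 0.06), dim = c(5, 6, nt))
  light <- mask_below_bottom(
    light_field(i0, k, z, monthly_dates(2000)[seq_len(nt)]), g)
  oxy_prof <- 250 - 0.45 * z
  oxy <- mask_below_bottom(
    make_profile_field(pmax(oxy_prof, 0), z, ny = 5, nx = 6, nt = nt,
                       variable = "oxygen", units = "mmol/m3"), g)
  hb <- vertical_extent(habitat_boundaries(upper_boundary(light),
                                           lower_boundary(oxy, g)))
  for (t in seq_len(nt)) {
    ext <- hb$extent[, , t][mask]
    expect_equal(sum(!is.na(ext)) + sum(is.na(ext)), sum(mask))
    ok <- !is.na(ext) & !hb$fully_compressed[, , t][mask]
    expect_equal(ext[ok],
                 (hb$lower_depth[, , t][mask] - hb$upper_depth[, , t][mask])[ok])
  }
})

test_that("lowering oxygen everywhere never deepens the boundary nor grows habitat area", {
  g <- make_test_grid(nx = 5, ny = 4, depth = 700, n_land_cols = 1)
  mask <- !g$land_mask
  z <- seq(5, 595, by = 10)
  base_prof <- 200 - 0.35 * z
  oxy1 <- mask_below_bottom(make_profile_field(pmax(base_prof, 0), z,
                                               ny = 4, nx = 5), g)
  oxy2 <- oxy1; oxy2$values <- pmax(oxy1$values - 15, 0)
  lb1 <- lower_boundary(oxy1, g); lb2 <- lower_boundary(oxy2, g)
  expect_true(all(lb2$depth <= lb1$depth + 1e-9, na.rm = TRUE))
  a1 <- habitat_area_at_depth(oxy1, g, mask)$area_km2
  a2 <- habitat_area_at_depth(oxy2, g, mask)$area_km2
  expect_true(all(a2 <= a1))
})

test_that("habitat area counts cell areas above the oxygen threshold at the reference depth", {
  g <- make_test_grid(nx = 5, ny = 2, depth = 700, n_land_cols = 1,
                      equal_area = TRUE)
  mask <- !g$land_mask   # 8 water cells of 9 km2
  z <- c(250, 350)
  v <- array(100, dim = c(2, 5, 2, 1))      # everyone oxygenated at 300 m
  oxy <- field4d(v, "oxygen", "mmol/m3", z, as.Date("2000-01-15"))
  expect_equal(habitat_area_at_depth(oxy, g, mask)$area_km2, 72)
  v[, , , ] <- 10                            # nobody above threshold
  oxy$values <- v
  expect_equal(habitat_area_at_depth(oxy, g, mask)$area_km2, 0)
  v[, 1:2, , ] <- 100                        # exactly half the water cells
  oxy$values <- v
  expect_equal(habitat_area_at_depth(oxy, g, mask)$area_km2, 36)
})
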