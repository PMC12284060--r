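#' Hydrographic parameters
#'
#' @param gravity Gravitational acceleration, m/s2.
#' @param reference_density Reference seawater density, kg/m3.
#' @param n2_search_depth_m Depth limit (m) of the search for the
#'   stratification maximum; 100 m targets the main thermocline.
#' @return A list of class `hydro_params`.
#' @export
hydro_params <- function(gravity = 9.81, reference_density = 1025,
                         n2_search_depth_m = 100) {
  stopifnot(gravity > 0, reference_density > 0, n2_search_depth_m > 0)
  structure(list(gravity = gravity, reference_density = reference_density,
                 n2_search_depth_m = n2_search_depth_m),
            class = "hydro_params")
}

#' Seawater density from a linear equation of state
#'
#' rho = rho0 * (1 - alpha (T - T0) + beta (S - S0)). A linear fallback for
#' computing stratification when only temperature (and optionally salinity)
#' is carried; adequate for N2 maxima, not a replacement for a full equation
#' of state.
#'
#' @param temperature Potential temperature, degC.
#' @param salinity Salinity, psu (default constant 35).
#' @param rho0 Reference density, kg/m3.
#' @param alpha Thermal expansion coefficient, 1/degC.
#' @param beta Haline contraction coefficient, 1/psu.
#' @param t0,s0 Reference temperature and salinity.
#' @return Density in kg/m3, same shape as `temperature`.
#' @export
density_from_temperature <- function(temperature, salinity = 35,
                                     rho0 = 1025, alpha = 2.0e-4,
                                     beta = 7.6e-4, t0 = 10, s0 = 35) {
  rho0 * (1 - alpha * (temperature - t0) + beta * (salinity - s0))
}

#' Maximum buoyancy frequency in the upper water column
#'
#' N2 = (g / rho0) * d(rho)/dz evaluated by centered differences on level
#' midpoints (z positive down, so stable stratification gives positive N2).
#' Returns the maximum over midpoints shallower than `n2_search_depth_m`
#' together with the depth at which it occurs.
#'
#' @param density Density profile(s) in kg/m3: a vector (one profile) or a
#'   matrix with one profile per row.
#' @param depth_levels Level depths in m, positive down, strictly increasing;
#'   at least 3 levels must lie within the search depth.
#' @param params A [hydro_params()].
#' @return A list with `n2_max` (1/s2), `depth` (m, midpoint of the maximum)
#'   and `unstable` (logical: `TRUE` where every midpoint N2 is negative, in
#'   which case the — negative — maximum is still returned, with a warning).
#'   Each element is a vector with one entry per profile.
#' @export
buoyancy_frequency_max <- function(density, depth_levels,
                                   params = hydro_params()) {
  if (is.null(dim(density))) density <- matrix(density, nrow = 1L)
  nz <- length(depth_levels)
  stopifnot(ncol(density) == nz, all(diff(depth_levels) > 0))
  if (sum(depth_levels <= params$n2_search_depth_m) < 3L)
    stop("need at least 3 levels within the N2 search depth")
  dz <- diff(depth_levels)
  mid <- (depth_levels[-1] + depth_levels[-nz]) / 2
  keep <- mid <= params$n2_search_depth_m
  n2 <- (density[, -1, drop = FALSE] - density[, -nz, drop = FALSE]) /
    rep(dz, each = nrow(density)) * (params$gravity / params$reference_density)
  n2 <- n2[, keep, drop = FALSE]
  midk <- mid[keep]
  j <- max.col(replace(n2, is.na(n2), -Inf), ties.method = "first")
  n2_max <- n2[cbind(seq_len(nrow(n2)), j)]
  unstable <- apply(n2 < 0, 1, all)
  unstable[is.na(unstable)] <- FALSE
  if (any(unstable))
    warning(sum(unstable), " unstable column(s): all-negative N2")
  list(n2_max = n2_max, depth = midk[j], unstable = unstable)
}
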