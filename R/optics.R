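#' Optical and stoichiometric parameters
#'
#' Constants used to derive chlorophyll from phytoplankton biomass and light
#' at depth from surface shortwave radiation.
#'
#' * `photons_per_joule`: PAR quantum-to-energy conversion, umol photons per
#'   joule (default 4.6; 0.1 umol/m2/s / 4.6 = 0.0217 W/m2).
#' * `chl_to_c`: chlorophyll-to-carbon mass ratio, g Chl per g C (0.03,
#'   representative of bulk phytoplankton community properties).
#' * `redfield_c_n`: Redfield carbon-to-nitrogen molar ratio (106/16).
#' * `carbon_molar_mass`: g C per mol (12.011).
#' * `par_fraction_of_shortwave`: fraction of downwelling shortwave that is
#'   PAR (0.43).
#' * `k_chl_a`, `k_chl_b`, `k_chl_c`: coefficients of the bulk attenuation
#'   relationship k = a + b * Chl^c (1/m, with Chl the 0-100 m depth-averaged
#'   chlorophyll in mg/m3). The defaults are implementer defaults documented
#'   in the methods vignette; the empirical relationship they stand in for
#'   was published without coefficients usable here.
#'
#' @param photons_per_joule umol photons per J of PAR, > 0.
#' @param chl_to_c g Chl per g C, > 0.
#' @param redfield_c_n mol C per mol N, > 0.
#' @param carbon_molar_mass g/mol, > 0.
#' @param par_fraction_of_shortwave dimensionless in (0, 1].
#' @param k_chl_a,k_chl_b,k_chl_c attenuation coefficients; `k_chl_c` must lie
#'   in (0, 1.5].
#' @return A list of class `optics_params`.
#' @export
optics_params <- function(photons_per_joule = 4.6,
                          chl_to_c = 0.03,
                          redfield_c_n = 106 / 16,
                          carbon_molar_mass = 12.011,
                          par_fraction_of_shortwave = 0.43,
                          k_chl_a = 0.0384, k_chl_b = 0.0518,
                          k_chl_c = 0.428) {
  vals <- c(photons_per_joule, chl_to_c, redfield_c_n, carbon_molar_mass,
            par_fraction_of_shortwave, k_chl_a, k_chl_b, k_chl_c)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all optics parameters must be strictly positive")
  if (k_chl_c > 1.5) stop("k_chl_c must lie in (0, 1.5]")
  structure(list(photons_per_joule = photons_per_joule, chl_to_c = chl_to_c,
                 redfield_c_n = redfield_c_n,
                 carbon_molar_mass = carbon_molar_mass,
                 par_fraction_of_shortwave = par_fraction_of_shortwave,
                 k_chl_a = k_chl_a, k_chl_b = k_chl_b, k_chl_c = k_chl_c),
            class = "optics_params")
}

#' Convert PAR photon flux to irradiance
#'
#' Divides a photon flux by the PAR quantum-to-energy factor (default 4.6
#' umol photons per joule), so 0.1 umol/m2/s maps to 0.0217 W/m2 — the light
#' threshold used for the upper mesopelagic boundary.
#'
#' @param q Photon flux in umol photons/m2/s, >= 0.
#' @param params An [optics_params()].
#' @return Irradiance in W/m2.
#' @seealso [irradiance_to_photon_flux()] for the exact inverse.
#' @export
photon_flux_to_irradiance <- function(q, params = optics_params()) {
  if (any(q < 0, na.rm = TRUE)) stop("photon flux must be non-negative")
  q / params$photons_per_joule
}

#' Convert irradiance to PAR photon flux
#'
#' @param e Irradiance in W/m2, >= 0.
#' @param params An [optics_params()].
#' @return Photon flux in umol photons/m2/s.
#' @export
irradiance_to_photon_flux <- function(e, params = optics_params()) {
  if (any(e < 0, na.rm = TRUE)) stop("irradiance must be non-negative")
  e * params$photons_per_joule
}

#' Chlorophyll from phytoplankton nitrogen biomass
#'
#' Converts phytoplankton biomass (mmol N/m3) to chlorophyll (mg/m3) using a
#' constant Redfield C:N of 106/16 and a fixed Chl:C of 0.03:
#' Chl = P * (C:N) * M_C * (Chl:C). Linear in the biomass.
#'
#' @param p Phytoplankton nitrogen biomass in mmol N/m3, >= 0.
#' @param params An [optics_params()].
#' @return Chlorophyll concentration in mg/m3.
#' @export
phyto_to_chl <- function(p, params = optics_params()) {
  if (any(p < 0, na.rm = TRUE)) stop("phytoplankton biomass must be non-negative")
  p * params$redfield_c_n * params$carbon_molar_mass * params$chl_to_c
}

#' Bulk light attenuation coefficient from upper-ocean chlorophyll
#'
#' Evaluates k = a + b * Chl^c with the configured coefficients. `chl` is the
#' 0-100 m depth-averaged chlorophyll concentration (mg/m3, i.e. the 0-100 m
#' depth integral divided by 100 m). k is strictly positive and non-decreasing
#' in chlorophyll; at Chl = 0 it reduces to the pure-water term `a`.
#'
#' @param chl Chlorophyll in mg/m3, >= 0.
#' @param params An [optics_params()].
#' @return Attenuation coefficient in 1/m.
#' @export
attenuation_coefficient <- function(chl, params = optics_params()) {
  if (any(chl < 0, na.rm = TRUE)) stop("chlorophyll must be non-negative")
  params$k_chl_a + params$k_chl_b * chl^params$k_chl_c
}

#' Exponential light profile from surface shortwave
#'
#' I(z) = f_PAR * SW * exp(-k z): the PAR fraction of the surface shortwave
#' attenuated exponentially with a single column-bulk coefficient. Strictly
#' decreasing in depth for k > 0.
#'
#' @param surface_shortwave Surface downwelling shortwave in W/m2, >= 0
#'   (scalar or vector).
#' @param k Bulk attenuation coefficient in 1/m, > 0 (scalar or vector
#'   matching `surface_shortwave`).
#' @param depth_levels Depths in m, positive down.
#' @param params An [optics_params()].
#' @return If `surface_shortwave` and `k` are scalars, a vector of irradiance
#'   (W/m2) per level; otherwise a matrix (length(surface_shortwave) x
#'   length(depth_levels)).
#' @export
light_profile <- function(surface_shortwave, k, depth_levels,
                          params = optics_params()) {
  if (any(surface_shortwave < 0, na.rm = TRUE))
    stop("surface shortwave must be non-negative")
  if (any(k <= 0, na.rm = TRUE)) stop("attenuation coefficient must be > 0")
  i0 <- params$par_fraction_of_shortwave * surface_shortwave
  if (length(i0) == 1L && length(k) == 1L)
    return(i0 * exp(-k * depth_levels))
  n <- max(length(i0), length(k))
  i0 <- rep_len(i0, n); k <- rep_len(k, n)
  i0 * exp(-outer(k, depth_levels))
}

#' Euphotic-zone depth
#'
#' Depth where light reaches 1% of its surface value under exponential
#' attenuation: z_eu = ln(100) / k. Independent of surface irradiance, so it
#' is a direct summary of upper-ocean light attenuation.
#'
#' @param k Bulk attenuation coefficient in 1/m, > 0.
#' @return Euphotic depth in m.
#' @export
euphotic_depth <- function(k) {
  if (any(k <= 0, na.rm = TRUE) || any(is.nan(k) | is.infinite(k)))
    stop("euphotic depth is undefined for k <= 0")
  log(100) / k
}

#' Build a 4-D light field from surface shortwave and bulk attenuation
#'
#' Expands per-cell, per-time surface shortwave and attenuation into a
#' [field4d()] of irradiance at the given depth levels using
#' [light_profile()]'s exponential model.
#'
#' @param shortwave Array (ny, nx, nt) of surface shortwave, W/m2.
#' @param k Array (ny, nx, nt) of bulk attenuation, 1/m.
#' @param depth_levels Depths in m.
#' @param time_stamps `Date` vector of length nt.
#' @param params An [optics_params()].
#' @return A [field4d()] of irradiance (W/m2).
#' @export
light_field <- function(shortwave, k, depth_levels, time_stamps,
                        params = optics_params()) {
  stopifnot(identical(dim(shortwave), dim(k)), length(dim(shortwave)) == 3L)
  d <- dim(shortwave)
  i0 <- params$par_fraction_of_shortwave * shortwave
  out <- array(NA_real_, dim = c(d[1], d[2], length(depth_levels), d[3]))
  for (j in seq_along(depth_levels))
    out[, , j, ] <- i0 * exp(-k * depth_levels[j])
  field4d(out, variable = "light", units = "W/m2",
          depth_levels = depth_levels, time_stamps = time_stamps)
}
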