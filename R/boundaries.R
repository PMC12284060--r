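#' Habitat threshold parameters
#'
#' The two physiological thresholds that delimit mesopelagic habitat, plus
#' the reference depth for horizontal habitat-area accounting.
#'
#' @param light_threshold Irradiance threshold for the upper boundary, W/m2
#'   (default 0.0217, i.e. 0.1 umol photons/m2/s at 4.6 umol/J).
#' @param oxygen_threshold Hypoxic threshold for the lower boundary, mmol/m3
#'   (default 63, ~2.0 mg O2/L).
#' @param reference_depth_for_area Depth (m) at which horizontal habitat
#'   area is evaluated (default 300, near the historical mean hypoxic-
#'   boundary depth).
#' @return A list of class `habitat_thresholds`.
#' @export
habitat_thresholds <- function(light_threshold = 0.0217,
                               oxygen_threshold = 63,
                               reference_depth_for_area = 300) {
  stopifnot(light_threshold > 0, oxygen_threshold > 0,
            reference_depth_for_area > 0)
  structure(list(light_threshold = light_threshold,
                 oxygen_threshold = oxygen_threshold,
                 reference_depth_for_area = reference_depth_for_area),
            class = "habitat_thresholds")
}

#' Upper (light-limited) mesopelagic boundary
#'
#' The depth at which downwelling irradiance falls to the light threshold,
#' found by downward scanning with linear interpolation. Columns whose
#' surface irradiance is already below the threshold are undefined and
#' flagged; columns where the threshold is not reached above the bottom are
#' undefined. Light must decrease monotonically with depth (the exponential
#' optics model guarantees it); a non-monotone column is an error naming the
#' offending cell.
#'
#' @param light A [field4d()] of irradiance (W/m2).
#' @param thresholds A [habitat_thresholds()].
#' @return A list of class `boundary_field` with arrays (ny, nx, nt):
#'   `depth` (m, `NA` where undefined), `surface_below` (surface light below
#'   threshold) and `not_reached`.
#' @export
upper_boundary <- function(light, thresholds = habitat_thresholds()) {
  stopifnot(inherits(light, "field4d"))
  M <- .profiles(light)
  inc <- M[, -1, drop = FALSE] > M[, -ncol(M), drop = FALSE] * (1 + 1e-12)
  bad <- which(rowSums(inc, na.rm = TRUE) > 0L)
  if (length(bad)) {
    d <- dim(light$values)[c(1, 2, 4)]
    idx <- arrayInd(bad[1], d)
    stop(sprintf(paste0("light profile increases with depth at cell ",
                        "(y=%d, x=%d, t=%d): violates the exponential ",
                        "optics model"), idx[1], idx[2], idx[3]))
  }
  res <- .crossing_matrix(M, light$depth_levels, thresholds$light_threshold,
                          "decreasing")
  depth <- res$depth
  depth[res$at_top] <- NA_real_               # no habitat ceiling: too dark at surface
  structure(list(
    depth = .from_profile_vector(depth, light),
    surface_below = .from_profile_vector(res$at_top, light),
    not_reached = .from_profile_vector(!res$reached, light)),
    class = "boundary_field", boundary = "upper")
}

#' Lower (hypoxia-limited) mesopelagic boundary
#'
#' The depth of the first downward crossing of dissolved oxygen below the
#' hypoxic threshold, linearly interpolated. Columns whose oxygen never
#' drops below the threshold take the local bottom depth instead, with
#' `bottom_fallback = TRUE`. Columns already below the threshold at the
#' shallowest wet level return that level's depth with
#' `hypoxic_at_top = TRUE`.
#'
#' @param oxygen A [field4d()] of dissolved oxygen (mmol/m3), non-negative.
#' @param grid A [model_grid()] supplying the bottom depth for the fallback.
#' @param thresholds A [habitat_thresholds()].
#' @return A list of class `boundary_field` with arrays (ny, nx, nt):
#'   `depth` (m), `bottom_fallback` and `hypoxic_at_top`.
#' @export
lower_boundary <- function(oxygen, grid, thresholds = habitat_thresholds()) {
  stopifnot(inherits(oxygen, "field4d"), inherits(grid, "model_grid"))
  if (any(oxygen$values < 0, na.rm = TRUE))
    stop("oxygen must be non-negative")
  M <- .profiles(oxygen)
  res <- .crossing_matrix(M, oxygen$depth_levels, thresholds$oxygen_threshold,
                          "decreasing")
  d <- dim(oxygen$values)[c(1, 2, 4)]
  depth <- res$depth
  fallback <- !res$reached
  depth[fallback] <- rep(c(grid$bottom_depth), times = d[3])[fallback]
  land <- rep(c(grid$land_mask), times = d[3])
  depth[land] <- NA_real_
  fallback[land] <- FALSE
  structure(list(
    depth = array(depth, d),
    bottom_fallback = array(fallback, d),
    hypoxic_at_top = array(res$at_top & !land, d)),
    class = "boundary_field", boundary = "lower")
}

#' Combine upper and lower boundaries into a habitat-boundaries object
#'
#' @param upper A `boundary_field` from [upper_boundary()].
#' @param lower A `boundary_field` from [lower_boundary()].
#' @return An object of class `habitat_boundaries` holding both depth arrays
#'   and their flags; extent fields are filled in by [vertical_extent()].
#' @export
habitat_boundaries <- function(upper, lower) {
  stopifnot(inherits(upper, "boundary_field"),
            inherits(lower, "boundary_field"),
            identical(dim(upper$depth), dim(lower$depth)))
  structure(list(
    upper_depth = upper$depth, surface_below = upper$surface_below,
    upper_not_reached = upper$not_reached,
    lower_depth = lower$depth, lower_is_bottom_fallback = lower$bottom_fallback,
    hypoxic_at_top = lower$hypoxic_at_top,
    extent = NULL, fully_compressed = NULL, omit_fallback = NA),
    class = "habitat_boundaries")
}

#' @export
print.habitat_boundaries <- function(x, ...) {
  d <- dim(x$upper_depth)
  cat(sprintf("<habitat_boundaries> %d x %d cells, %d times\n", d[1], d[2], d[3]))
  cat(sprintf("  upper defined: %d | lower fallback: %d | hypoxic at top: %d\n",
              sum(!is.na(x$upper_depth)), sum(x$lower_is_bottom_fallback),
              sum(x$hypoxic_at_top)))
  if (!is.null(x$extent))
    cat(sprintf("  extent defined: %d (fully compressed: %d, omit_fallback=%s)\n",
                sum(!is.na(x$extent)), sum(x$fully_compressed, na.rm = TRUE),
                x$omit_fallback))
  invisible(x)
}

#' Vertical extent of mesopelagic habitat
#'
#' extent = lower - upper wherever both boundaries are defined. Cells where
#' the hypoxic boundary sits above the light boundary get extent 0 and
#' `fully_compressed = TRUE` (habitat lost, not omitted). Cells where either
#' boundary is undefined are `NA` and thus omitted from downstream means;
#' with `omit_fallback = TRUE`, cells whose lower boundary is a bottom-depth
#' fallback are omitted as well (the strict reading in which extent is only
#' evaluated where both thresholds are actually reached).
#'
#' @param boundaries A [habitat_boundaries()].
#' @param omit_fallback Logical; drop bottom-fallback columns from the
#'   extent (default `FALSE`: fallback columns are included, with the bottom
#'   standing in for the hypoxic depth).
#' @return The [habitat_boundaries()] with `extent` (m) and
#'   `fully_compressed` arrays filled in.
#' @export
vertical_extent <- function(boundaries, omit_fallback = FALSE) {
  stopifnot(inherits(boundaries, "habitat_boundaries"))
  up <- boundaries$upper_depth
  lo <- boundaries$lower_depth
  extent <- lo - up
  compressed <- !is.na(extent) & extent < 0
  extent[compressed] <- 0
  if (omit_fallback) extent[boundaries$lower_is_bottom_fallback] <- NA_real_
  boundaries$extent <- extent
  boundaries$fully_compressed <- compressed & !is.na(extent)
  boundaries$omit_fallback <- omit_fallback
  boundaries
}

#' Horizontal habitat area at a reference depth
#'
#' For each time step, sums the cell areas of analysis-domain cells whose
#' interpolated dissolved oxygen at the reference depth exceeds the hypoxic
#' threshold. Cells with bottom shallower than the reference depth are
#' excluded. The result lies between 0 and [domain_area()].
#'
#' @param oxygen A [field4d()] of dissolved oxygen, mmol/m3.
#' @param grid A [model_grid()].
#' @param mask Logical domain mask from [build_domain_mask()].
#' @param thresholds A [habitat_thresholds()].
#' @return A [tibble::tibble()] with columns `time` and `area_km2`.
#' @export
habitat_area_at_depth <- function(oxygen, grid, mask,
                                  thresholds = habitat_thresholds()) {
  stopifnot(inherits(oxygen, "field4d"), inherits(grid, "model_grid"))
  do_ref <- extract_at_depth(oxygen, thresholds$reference_depth_for_area, grid)
  nt <- dim(do_ref)[3]
  eligible <- mask & grid$bottom_depth >= thresholds$reference_depth_for_area
  area <- vapply(seq_len(nt), function(t) {
    slab <- do_ref[, , t]
    sum(grid$cell_area[eligible & !is.na(slab) &
                         slab > thresholds$oxygen_threshold])
  }, numeric(1))
  tibble::tibble(time = oxygen$time_stamps, area_km2 = area)
}
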