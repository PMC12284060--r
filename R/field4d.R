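#' Construct a 4-D gridded field
#'
#' Carrier for one physical variable on a (y, x, depth, time) grid. Depth
#' levels are in meters, positive down, strictly increasing; cells below the
#' local bottom depth are `NA`. Time stamps are monthly calendar dates.
#'
#' @param values Numeric array with dim (ny, nx, nz, nt).
#' @param variable Variable name, e.g. `"oxygen"`.
#' @param units Units string, non-empty, e.g. `"mmol/m3"`.
#' @param depth_levels Numeric vector of nz level depths (m, positive down),
#'   strictly increasing.
#' @param time_stamps `Date` vector of length nt (monthly convention: one
#'   stamp per month).
#'
#' @return An object of class `field4d`.
#' @export
field4d <- function(values, variable, units, depth_levels, time_stamps) {
  d <- dim(values)
  if (is.null(d) || length(d) != 4L)
    stop("values must be a 4-D array (y, x, depth, time)")
  if (length(depth_levels) != d[3])
    stop("length(depth_levels) must match dim(values)[3]")
  if (any(diff(depth_levels) <= 0))
    stop("depth_levels must be strictly increasing (meters, positive down)")
  if (length(time_stamps) != d[4])
    stop("length(time_stamps) must match dim(values)[4]")
  if (!nzchar(units)) stop("units must be non-empty")
  structure(list(values = values, variable = variable, units = units,
                 depth_levels = as.numeric(depth_levels),
                 time_stamps = as.Date(time_stamps)),
            class = "field4d")
}

#' @export
print.field4d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<field4d> %s [%s]: %d x %d cells, %d levels (%.1f..%.1f m), %d times (%s..%s)\n",
              x$variable, x$units, d[1], d[2], d[3],
              min(x$depth_levels), max(x$depth_levels), d[4],
              format(min(x$time_stamps)), format(max(x$time_stamps))))
  invisible(x)
}

# Reshape a field4d to a profile matrix (ny*nx*nt rows, nz columns) and back.
# Row order is (y, x, t) with y fastest, matching array(.) on dim (ny,nx,nt).
.profiles <- function(field) {
  v <- aperm(field$values, c(1, 2, 4, 3))
  dim(v) <- c(prod(dim(field$values)[c(1, 2, 4)]), dim(field$values)[3])
  v
}

.from_profile_vector <- function(x, field) {
  array(x, dim = dim(field$values)[c(1, 2, 4)])
}

#' Mask a field below the bottom depth
#'
#' Sets to `NA` every sample at a level deeper than the local bathymetry.
#'
#' @param field A [field4d()].
#' @param grid A [model_grid()] on the same horizontal grid.
#' @return The masked [field4d()].
#' @export
mask_below_bottom <- function(field, grid) {
  stopifnot(inherits(field, "field4d"), inherits(grid, "model_grid"))
  d <- dim(field$values)
  deep <- outer(c(grid$bottom_depth), field$depth_levels, `<`) # (cells, nz)
  deep <- array(deep, dim = c(d[1], d[2], d[3]))
  for (t in seq_len(d[4])) {
    slab <- field$values[, , , t]
    slab[deep] <- NA_real_
    field$values[, , , t] <- slab
  }
  land <- array(grid$land_mask, dim = d[1:3])
  for (t in seq_len(d[4])) {
    slab <- field$values[, , , t]
    slab[land] <- NA_real_
    field$values[, , , t] <- slab
  }
  field
}
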