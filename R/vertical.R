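#' Integrate or average a field over the upper water column
#'
#' Trapezoidal integral (units x m) or depth average (units) of a [field4d()]
#' over \[0, `z_max`\]. The shallowest level's value is extended to the
#' surface, and the profile is linearly interpolated at `z_max` when it falls
#' between levels. Columns whose bottom is shallower than `z_max` are
#' integrated to the deepest wet level instead (logged via `message`).
#'
#' @param field A [field4d()] (bottom-masked values `NA`).
#' @param z_max Lower limit of integration, m; must not exceed the deepest
#'   level, and at least 2 levels must lie at or above it.
#' @param mode `"integral"` or `"average"`.
#' @return Array (ny, nx, nt) of integrals or averages.
#' @export
integrate_upper <- function(field, z_max, mode = c("integral", "average")) {
  mode <- match.arg(mode)
  stopifnot(inherits(field, "field4d"))
  z <- field$depth_levels
  if (z_max > max(z)) stop("z_max exceeds the deepest level")
  if (sum(z <= z_max) < 2L) stop("need at least 2 levels above z_max")
  v <- .profiles(field)                      # (nprof, nz)
  # augmented coordinate: surface + levels above z_max + interpolated z_max
  keep <- which(z < z_max)
  jb <- max(keep) + 1L                       # bracketing level at/below z_max
  if (z[jb] == z_max) { keep <- c(keep, jb); vmax <- v[, jb]; jb <- NA_integer_ }
  else {
    w <- (z_max - z[jb - 1L]) / (z[jb] - z[jb - 1L])
    vmax <- (1 - w) * v[, jb - 1L] + w * v[, jb]
  }
  zz <- c(0, z[keep], z_max)
  vv <- cbind(v[, keep[1]], v[, keep, drop = FALSE], vmax)
  bad <- rowSums(is.na(vv)) > 0L
  dz <- diff(zz)
  integ <- as.vector((vv[, -1, drop = FALSE] + vv[, -ncol(vv), drop = FALSE]) %*%
                       (dz / 2))
  depth_used <- rep(z_max, nrow(vv))
  if (any(bad)) {
    shallow <- bad & !is.na(vv[, 2])         # wet at the top but truncated
    if (any(shallow)) {
      message(sum(shallow), " column(s) shallower than z_max; ",
              "integrated to the deepest wet level")
      for (i in which(shallow)) {
        wet <- which(!is.na(vv[i, ]))
        zi <- zz[wet]; vi <- vv[i, wet]
        integ[i] <- sum((vi[-1] + vi[-length(vi)]) / 2 * diff(zi))
        depth_used[i] <- max(zi)
      }
    }
    integ[bad & is.na(vv[, 2])] <- NA_real_
  }
  out <- if (mode == "integral") integ else integ / depth_used
  .from_profile_vector(out, field)
}

#' Extract a field at a fixed depth
#'
#' Linear interpolation between the two levels bracketing `z`; exact when `z`
#' coincides with a level. Where the local bottom depth is shallower than `z`
#' (or either bracketing value is missing) the result is `NA`.
#'
#' @param field A [field4d()].
#' @param z Target depth in m; must lie within the level range.
#' @param grid Optional [model_grid()]; if given, cells with
#'   `bottom_depth < z` are masked.
#' @return Array (ny, nx, nt).
#' @export
extract_at_depth <- function(field, z, grid = NULL) {
  stopifnot(inherits(field, "field4d"))
  zl <- field$depth_levels
  if (z < min(zl) || z > max(zl))
    stop(sprintf("depth %g m is outside the level range [%g, %g]",
                 z, min(zl), max(zl)))
  j <- findInterval(z, zl)
  if (zl[j] == z) out <- field$values[, , j, ]
  else {
    w <- (z - zl[j]) / (zl[j + 1] - zl[j])
    out <- (1 - w) * field$values[, , j, ] + w * field$values[, , j + 1, ]
  }
  out <- array(out, dim = dim(field$values)[c(1, 2, 4)])
  if (!is.null(grid)) {
    shallow <- grid$bottom_depth < z | grid$land_mask
    out[array(shallow, dim = dim(out))] <- NA_real_
  }
  out
}

# Vectorized first-crossing search on a profile matrix.
# M: (nprof, nz) with NA below bottom (contiguous from the bottom up);
# direction "decreasing": first level where M <= thr, scanned downward.
# Returns depth (NA if never crossed), at_top (beyond threshold already at the
# shallowest wet level), reached, too_few (fewer than 2 wet levels).
.crossing_matrix <- function(M, depth_levels, threshold,
                             direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  n <- nrow(M); nz <- ncol(M)
  stopifnot(length(depth_levels) == nz)
  hit <- if (direction == "decreasing") M <= threshold else M >= threshold
  strict <- if (direction == "decreasing") M < threshold else M > threshold
  hit[is.na(hit)] <- FALSE
  strict[is.na(strict)] <- FALSE
  nwet <- rowSums(!is.na(M))
  j <- max.col(hit, ties.method = "first")
  found <- hit[cbind(seq_len(n), j)]
  too_few <- nwet < 2L
  reached <- found & !too_few
  depth <- rep(NA_real_, n)
  at_top <- reached & j == 1L & strict[, 1]
  # exact tie at the shallowest level, or flagged top-exceedance: level depth
  depth[reached & j == 1L] <- depth_levels[1]
  ii <- which(reached & j > 1L)
  if (length(ii)) {
    jj <- j[ii]
    v1 <- M[cbind(ii, jj - 1L)]
    v2 <- M[cbind(ii, jj)]
    frac <- (v1 - threshold) / (v1 - v2)     # in (0, 1]; exact tie gives 1
    depth[ii] <- depth_levels[jj - 1L] +
      frac * (depth_levels[jj] - depth_levels[jj - 1L])
  }
  list(depth = depth, at_top = at_top, reached = reached, too_few = too_few)
}

#' Depth at which a profile crosses a threshold
#'
#' Scans a vertical profile downward and returns the shallowest depth at
#' which it crosses `threshold` in the stated direction, linearly
#' interpolating between the bracketing levels. Exact equality at a level
#' returns that level's depth. Profiles that never cross return `NA` with
#' status `"not_reached"`; profiles already beyond the threshold at the
#' shallowest wet level return that level's depth with status `"at_top"`;
#' profiles with fewer than 2 wet levels return `NA` with a warning.
#'
#' @param profile_values Numeric vector, one value per level (`NA` below the
#'   bottom).
#' @param depth_levels Strictly increasing depths, m.
#' @param threshold Threshold value, in the profile's units.
#' @param direction `"decreasing"` (crossing from above to below the
#'   threshold) or `"increasing"`.
#' @return A single depth in m (`NA` if not reached) with attribute `status`
#'   in `c("crossed", "at_top", "not_reached", "too_few_levels")`.
#' @export
threshold_crossing_depth <- function(profile_values, depth_levels, threshold,
                                     direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  if (any(diff(depth_levels) <= 0)) stop("depth_levels must be strictly increasing")
  res <- .crossing_matrix(matrix(profile_values, nrow = 1L), depth_levels,
                          threshold, direction)
  status <- if (res$too_few) {
    warning("fewer than 2 wet levels: crossing not evaluated")
    "too_few_levels"
  } else if (res$at_top) "at_top"
  else if (res$reached) "crossed"
  else "not_reached"
  structure(res$depth, status = status)
}
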