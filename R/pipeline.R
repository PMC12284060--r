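#' Pipeline configuration
#'
#' Consolidates every tunable of the analysis chain, with defaults matching
#' the printed study constants where one exists (400 m isobath, 200 km
#' offshore, 34.5-40 N, 0.0217 W/m2 light threshold, 63 mmol/m3 hypoxic
#' threshold, 300 m area reference depth, 150 m temperature/light depth,
#' 100 m integration depth, epochs 2000-2030 and 2070-2100).
#'
#' @param grid_nx,grid_ny Synthetic grid size (demonstration scale).
#' @param grid_args Extra arguments for [generate_grid()] (e.g. a narrower
#'   `lon_range` for coarse grids so the isobath stays inside the offshore
#'   limit).
#' @param years Simulated calendar years.
#' @param scenarios List of [scenario_params()]; `NULL` for
#'   [default_scenarios()] seeded from `seed`.
#' @param mask_params A [domain_mask_params()].
#' @param optics An [optics_params()].
#' @param hydro A [hydro_params()].
#' @param thresholds A [habitat_thresholds()].
#' @param epoch1,epoch2 Inclusive epoch-year windows.
#' @param weighting Spatial-mean weighting, `"area"` or `"none"`.
#' @param omit_fallback Drop bottom-fallback columns from the extent.
#' @param metric_depth_t,metric_depth_light Fixed depths (m) for the
#'   temperature and light metrics.
#' @param integration_depth Upper-ocean integration depth (m) for
#'   chlorophyll and the attenuation input.
#' @param with_evaluation Run the pseudo-observation evaluation stage.
#' @param obs_per_year Pseudo-observations per variable per year.
#' @param seed Integer seed for every random stage.
#' @param output_dir Directory for CSV/report output (`NULL`: no files).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(grid_nx = 16, grid_ny = 20,
                            grid_args = list(),
                            years = 2000:2100,
                            scenarios = NULL,
                            mask_params = domain_mask_params(),
                            optics = optics_params(),
                            hydro = hydro_params(),
                            thresholds = habitat_thresholds(),
                            epoch1 = c(2000, 2030), epoch2 = c(2070, 2100),
                            weighting = c("area", "none"),
                            omit_fallback = FALSE,
                            metric_depth_t = 150, metric_depth_light = 150,
                            integration_depth = 100,
                            with_evaluation = TRUE,
                            obs_per_year = 40,
                            seed = 1L,
                            output_dir = NULL) {
  weighting <- match.arg(weighting)
  if (is.null(scenarios)) scenarios <- default_scenarios(seed)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Scalar parameters round-trip through YAML; parameter-group objects are
#' rebuilt through their constructors so invariants are re-validated on
#' read.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- lapply(config, function(x) if (is.list(x)) lapply(x, unclass) else x)
  plain$scenarios <- lapply(config$scenarios, unclass)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$years <- raw$years[1]:raw$years[length(raw$years)]
  raw$scenarios <- lapply(raw$scenarios, function(s) do.call(scenario_params, s))
  for (nm in c("mask_params", "optics", "hydro", "thresholds")) {
    ctor <- switch(nm, mask_params = domain_mask_params,
                   optics = optics_params, hydro = hydro_params,
                   thresholds = habitat_thresholds)
    raw[[nm]] <- do.call(ctor, raw[[nm]])
  }
  do.call(pipeline_config, raw[setdiff(names(raw), "")])
}

#' Per-member habitat and ocean metrics
#'
#' Runs the derived-field and boundary stages for one member and returns the
#' 2-D + time metric arrays the series statistics consume: both habitat
#' boundaries and the vertical extent, temperature and light at their fixed
#' metric depths, dissolved oxygen at the area reference depth, 0-100 m
#' depth-integrated chlorophyll, euphotic depth, peak upper-ocean N2, and
#' the horizontal habitat-area series.
#'
#' @param member A `synthetic_member` (or any list with the same fields).
#' @param mask Logical analysis-domain mask.
#' @param config A [pipeline_config()].
#' @return A list: `metrics` (named list of ny x nx x nt arrays),
#'   `area` (tibble from [habitat_area_at_depth()]), `boundaries`
#'   (a [habitat_boundaries()]), `time_stamps`.
#' @export
compute_member_metrics <- function(member, mask, config = pipeline_config()) {
  grid <- member$grid
  opt <- config$optics
  thr <- config$thresholds
  z <- member$temperature$depth_levels
  ts <- member$time_stamps

  chl_field <- member$phyto
  chl_field$values <- phyto_to_chl(chl_field$values, opt)
  chl_field$variable <- "chl"; chl_field$units <- "mg/m3"
  chl_int <- integrate_upper(chl_field, config$integration_depth, "integral")
  chl_avg <- chl_int / config$integration_depth
  k <- attenuation_coefficient(chl_avg, opt)
  light <- light_field(member$shortwave, k, z, ts, opt)
  light <- mask_below_bottom(light, grid)

  ub <- upper_boundary(light, thr)
  lb <- lower_boundary(member$oxygen, grid, thr)
  hb <- vertical_extent(habitat_boundaries(ub, lb), config$omit_fallback)

  dens <- density_from_temperature(member$temperature$values)
  nprof <- prod(dim(dens)[c(1, 2, 4)])
  dmat <- aperm(dens, c(1, 2, 4, 3)); dim(dmat) <- c(nprof, length(z))
  n2 <- suppressWarnings(
    buoyancy_frequency_max(dmat, z, config$hydro))
  n2max <- array(n2$n2_max, dim = dim(dens)[c(1, 2, 4)])

  metrics <- list(
    upper_boundary_m = hb$upper_depth,
    lower_boundary_m = hb$lower_depth,
    extent_m = hb$extent,
    t_at_150m_C = extract_at_depth(member$temperature, config$metric_depth_t, grid),
    do_at_300m = extract_at_depth(member$oxygen, thr$reference_depth_for_area, grid),
    chl_int_0_100 = chl_int,
    light_at_150m = extract_at_depth(light, config$metric_depth_light, grid),
    euphotic_depth_m = euphotic_depth(k),
    n2_max = n2max)
  area <- habitat_area_at_depth(member$oxygen, grid, mask, thr)
  list(metrics = metrics, area = area, boundaries = hb, time_stamps = ts)
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a synthetic ensemble, builds the analysis-domain
#' mask, computes per-member habitat boundaries and ocean metrics, reduces
#' them to annual area-weighted series, fits linear trends, performs epoch
#' Welch t-tests, summarizes the ensemble mean and spread per metric, and —
#' optionally — evaluates the ensemble against pseudo-observations drawn
#' from the first member. With `output_dir` set, writes `series.csv`,
#' `trends.csv`, `epochs.csv`, `ensemble.csv`, `area.csv`,
#' `evaluation.csv`, a `config.yaml` echo, and `report.txt` echoing the
#' headline metrics; every file records the package version and the config
#' hash, so equal-hash runs are byte-comparable.
#'
#' @param config A [pipeline_config()].
#' @param members Optional pre-generated list of `synthetic_member`s (then
#'   the generation stage is skipped).
#' @return A list: `series` (tibble of all member/metric annual series),
#'   `trends`, `epochs`, `ensemble`, `area`, `evaluation` (tibbles),
#'   `mask`, `grid`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), members = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(members)) {
    grid <- do.call(generate_grid, c(list(nx = config$grid_nx,
                                          ny = config$grid_ny),
                                     config$grid_args))
    members <- generate_ensemble(grid, config$scenarios,
                                 years = config$years,
                                 optics = config$optics,
                                 thresholds = config$thresholds)
  } else grid <- members[[1]]$grid
  if (length(members) < 2L)
    warning("fewer than 2 members: ensemble summaries skipped")
  offshore <- distance_offshore(grid)
  mask <- build_domain_mask(grid, config$mask_params, offshore)

  series <- list(); area_tbl <- list(); eval_pairs <- list()
  for (nm in names(members)) {
    mm <- compute_member_metrics(members[[nm]], mask, config)
    for (metric in names(mm$metrics)) {
      series[[paste(nm, metric)]] <- annual_spatial_mean(
        mm$metrics[[metric]], mm$time_stamps, grid, mask,
        weighting = config$weighting, metric = metric, member = nm)
    }
    a <- mm$area
    a$member <- nm
    area_tbl[[nm]] <- a
    rm(mm)
  }
  series_tbl <- do.call(rbind, unname(series))
  area_tbl <- do.call(rbind, unname(area_tbl))

  trends <- do.call(rbind, lapply(split(series_tbl,
                                        series_tbl[c("member", "metric")]),
                                  function(s) {
    cbind(tibble::tibble(member = s$member[1], metric = s$metric[1]),
          linear_trend(s))
  }))
  epochs <- do.call(rbind, lapply(split(series_tbl,
                                        series_tbl[c("member", "metric")]),
                                  function(s) {
    cbind(tibble::tibble(member = s$member[1], metric = s$metric[1]),
          epoch_means_ttest(s, config$epoch1, config$epoch2))
  }))
  rownames(trends) <- rownames(epochs) <- NULL

  ens <- NULL
  if (length(members) >= 2L) {
    ens <- do.call(rbind, lapply(unique(series_tbl$metric), function(metric) {
      ml <- lapply(names(members), function(nm)
        series_tbl[series_tbl$member == nm & series_tbl$metric == metric, ])
      out <- ensemble_mean_spread(ml)
      out$metric <- metric
      out
    }))
  }

  evaluation <- NULL
  if (isTRUE(config$with_evaluation)) {
    obs <- generate_observations(members[[1]], n_per_year = config$obs_per_year,
                                 seed = config$seed + 1000L)
    evaluation <- do.call(rbind, lapply(unique(obs$variable), function(v) {
      ov <- obs[obs$variable == v, ]
      pairs <- do.call(rbind, lapply(names(members), function(nm) {
        p <- cosample(members[[nm]][[v]], grid, ov)
        p$member <- nm
        p
      }))
      cbind(tibble::tibble(variable = v), evaluate_projections(pairs))
    }))
  }

  result <- list(series = series_tbl, trends = trends, epochs = epochs,
                 ensemble = ens, area = area_tbl, evaluation = evaluation,
                 mask = mask, grid = grid, config = config)
  result$config_hash <- .config_hash(config)
  if (!is.null(config$output_dir)) .write_outputs(result, config)
  result
}

.config_hash <- function(config) {
  config$output_dir <- NULL   # hash the scientific configuration only
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_pipeline_config(config, tmp)
  unname(tools::md5sum(tmp))
}

.write_outputs <- function(result, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# mesohab %s | config %s",
                   as.character(utils::packageVersion("mesohab")),
                   result$config_hash)
  wcsv <- function(df, name) {
    path <- file.path(config$output_dir, name)
    writeLines(stamp, path)
    suppressWarnings(utils::write.table(df, path, append = TRUE, sep = ",",
                                        row.names = FALSE, qmethod = "double"))
  }
  wcsv(result$series, "series.csv")
  wcsv(result$trends, "trends.csv")
  wcsv(result$epochs, "epochs.csv")
  if (!is.null(result$ensemble)) wcsv(result$ensemble, "ensemble.csv")
  wcsv(result$area, "area.csv")
  if (!is.null(result$evaluation)) wcsv(result$evaluation, "evaluation.csv")
  write_pipeline_config(config, file.path(config$output_dir, "config.yaml"))
  writeLines(.format_report(result), file.path(config$output_dir, "report.txt"))
}

.format_report <- function(result) {
  ep <- result$epochs
  line <- function(metric, fmt, scale = 1) {
    e <- ep[ep$metric == metric, ]
    if (!nrow(e)) return(character())
    sprintf(paste0("  %-18s ", fmt, " -> ", fmt, "  (ensemble epoch means)"),
            metric, mean(e$mean1) * scale, mean(e$mean2) * scale)
  }
  yr <- as.integer(format(result$area$time, "%Y"))
  a1 <- mean(result$area$area_km2[yr >= result$config$epoch1[1] &
                                    yr <= result$config$epoch1[2]])
  a2 <- mean(result$area$area_km2[yr >= result$config$epoch2[1] &
                                    yr <= result$config$epoch2[2]])
  c(sprintf("mesohab pipeline report (config %s)", result$config_hash),
    sprintf("domain: %d cells, %.0f km2", sum(result$mask),
            domain_area(result$grid, result$mask)),
    "epoch means (all members pooled):",
    line("upper_boundary_m", "%7.1f m"),
    line("lower_boundary_m", "%7.1f m"),
    line("extent_m", "%7.1f m"),
    sprintf("  habitat area @ref depth: %.0f -> %.0f km2 (%+.1f%%)",
            a1, a2, 100 * (a2 - a1) / a1))
}
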