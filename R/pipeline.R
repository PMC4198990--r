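# End-to-end orchestration: local dispersion at per-home receptor grids,
# kriged-and-scaled background, hybrid combination and windowed metrics.

#' Per-home exposure metrics for a scenario
#'
#' For every home: builds the anonymizing mini-grid against the nearest
#' major road (or a five-point grid when none qualifies), runs the local
#' dispersion solvers at the grid receptors, reduces the grid to an hourly
#' home series (row interpolation at the true home distance, or the
#' five-point average), estimates the background by space-time kriging of
#' the monitor observations scaled by the regional fraction, combines the
#' source categories into the hybrid total, and windows the result.
#'
#' @param scenario [make_scenario()] output (or a compatible list).
#' @param home_ids Homes to process (default: all in `scenario$homes`).
#' @param params [stok_params()] for the background stage.
#' @param windows [exposure_windows()].
#' @param options [dispersion_options()].
#' @param keep_hourly Return the hourly hybrid series as well.
#' @return List with `metrics` (windowed [window_metrics()] rows for all
#'   homes) and, if requested, `hourly` (long per-home hybrid series).
#' @export
home_exposure <- function(scenario, home_ids = NULL, params = stok_params(),
                          windows = exposure_windows(),
                          options = dispersion_options(
                            wind_floor = scenario$config$wind_floor),
                          keep_hourly = FALSE) {
  homes <- scenario$homes
  if (!is.null(home_ids)) homes <- homes[homes$id %in% home_ids, , drop = FALSE]
  metrics <- list()
  hourly <- list()
  for (i in seq_len(nrow(homes))) {
    home <- homes[i, ]
    grid <- tryCatch(
      build_minigrid(home, scenario$roads,
                     receptor_height = options$receptor_height),
      hx_no_major_road = function(e)
        five_point_grid(home, receptor_height = options$receptor_height))
    local <- simulate_hourly(scenario$roads, scenario$point_sources,
                             scenario$area_sources, scenario$ef_table,
                             scenario$profile, grid$receptors, scenario$met,
                             scenario$config$pollutants, options)
    home_local <- if (inherits(grid, "hx_minigrid")) {
      minigrid_home_series(grid, local,
                           home$distance_to_nearest_major_road %||%
                             grid$home_distance)
    } else {
      five_point_series(grid, local)
    }
    bg <- background_series(
      data.frame(id = home$id, x = home$x, y = home$y),
      scenario$met$time, scenario$config$pollutants,
      scenario$observations, scenario$ratio_field, params)
    key <- function(d) paste(format_time(d$time), d$pollutant)
    mob <- home_local[home_local$category == "mobile", , drop = FALSE]
    sta <- home_local[home_local$category == "stationary", , drop = FALSE]
    sta <- sta[match(key(mob), key(sta)), , drop = FALSE]
    bgm <- bg[match(key(mob), key(bg)), , drop = FALSE]
    comp <- combine_hybrid(mob$value, sta$value, bgm$value)
    series <- rbind(
      data.frame(time = mob$time, pollutant = mob$pollutant,
                 category = "mobile", value = comp$mobile),
      data.frame(time = mob$time, pollutant = mob$pollutant,
                 category = "stationary", value = comp$stationary),
      data.frame(time = mob$time, pollutant = mob$pollutant,
                 category = "background", value = comp$background),
      data.frame(time = mob$time, pollutant = mob$pollutant,
                 category = "total", value = comp$total))
    metrics[[home$id]] <- window_metrics(series, windows, home_id = home$id)
    if (keep_hourly) {
      hourly[[home$id]] <- cbind(home_id = home$id, series)
    }
  }
  out <- list(metrics = do.call(rbind, c(metrics, list(make.row.names = FALSE))))
  if (keep_hourly) {
    out$hourly <- do.call(rbind, c(hourly, list(make.row.names = FALSE)))
  }
  out
}

#' Model-to-monitor evaluation for a scenario
#'
#' Reconstructs the hybrid model series at each monitor site (local truth
#' categories plus a background kriged from the *other* sites when
#' `leave_one_out` is TRUE) and compares it with the synthetic observations.
#'
#' @param scenario [make_scenario()] output.
#' @param params [stok_params()].
#' @param leave_one_out Hold each site out of its own background kriging.
#' @return [evaluation_table()] rows per site x pollutant.
#' @export
evaluate_scenario <- function(scenario, params = stok_params(),
                              leave_one_out = TRUE) {
  mon <- scenario$monitors
  truth <- scenario$truth
  key <- function(d) paste(d$receptor_id, format_time(d$time), d$pollutant)
  mob <- truth[truth$category == "mobile", , drop = FALSE]
  sta <- truth[truth$category == "stationary", , drop = FALSE]
  sta <- sta[match(key(mob), key(sta)), , drop = FALSE]
  model <- list()
  for (i in seq_len(nrow(mon))) {
    s <- mon$site[i]
    bg <- background_series(
      data.frame(id = s, x = mon$x[i], y = mon$y[i]),
      scenario$met$time, scenario$config$pollutants,
      scenario$observations, scenario$ratio_field, params,
      exclude_site = if (leave_one_out) s else NULL)
    m <- mob[mob$receptor_id == s, , drop = FALSE]
    st <- sta[sta$receptor_id == s, , drop = FALSE]
    bgm <- bg[match(paste(format_time(m$time), m$pollutant),
                    paste(format_time(bg$time), bg$pollutant)), , drop = FALSE]
    model[[s]] <- data.frame(receptor_id = s, time = m$time,
                             pollutant = m$pollutant, category = "total",
                             value = m$value + st$value + bgm$value,
                             stringsAsFactors = FALSE)
  }
  model <- do.call(rbind, c(model, list(make.row.names = FALSE)))
  evaluation_table(model, scenario$observations)
}
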