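# From hourly receptor concentrations to per-home, per-window,
# source-apportioned exposure metrics: anonymizing mini-grids near major
# roads, row interpolation to the true home distance, 5-point grids
# elsewhere, hybrid combination, windowing with a completeness rule, and the
# HD/LD/LT exposure-group classifier.

#' Exposure time windows
#'
#' The daily window and the five sub-windows that partition the 24
#' hour-ending hours: a.m. off-peak 1-6, a.m. peak 7-8, mid-day 9-14,
#' p.m. peak 15-17, p.m. off-peak 18-24.
#'
#' @return Named list of integer hour vectors.
#' @export
exposure_windows <- function() {
  list(daily = 1:24,
       am_offpeak = 1:6,
       am_peak = 7:8,
       midday = 9:14,
       pm_peak = 15:17,
       pm_offpeak = 18:24)
}

#' Exposure-group road-proximity criteria
#'
#' Thresholds defining the three recruitment groups: high diesel (HD) - a
#' road within 150 m exceeding 6000 commercial vehicles/day (CAADT) and
#' 90,000 total vehicles/day (AADT); low diesel (LD) - a road within 150 m
#' exceeding 90,000 AADT with CAADT below 4500; low traffic (LT) - at least
#' 300 m from any road with over 25,000 AADT.
#'
#' @param hd_max_distance,hd_min_caadt,hd_min_aadt HD thresholds.
#' @param ld_max_distance,ld_min_aadt,ld_max_caadt LD thresholds.
#' @param lt_min_distance,lt_aadt_threshold LT thresholds.
#' @return List of class `hx_group_criteria`.
#' @export
group_criteria <- function(hd_max_distance = 150, hd_min_caadt = 6000,
                           hd_min_aadt = 90000,
                           ld_max_distance = 150, ld_min_aadt = 90000,
                           ld_max_caadt = 4500,
                           lt_min_distance = 300, lt_aadt_threshold = 25000) {
  stopifnot(hd_max_distance > 0, hd_min_caadt > 0, hd_min_aadt > 0,
            ld_max_distance > 0, ld_min_aadt > 0, ld_max_caadt > 0,
            lt_min_distance > 0, lt_aadt_threshold > 0,
            hd_min_caadt > ld_max_caadt)
  out <- list(hd = list(max_distance = hd_max_distance,
                        min_caadt = hd_min_caadt, min_aadt = hd_min_aadt),
              ld = list(max_distance = ld_max_distance,
                        min_aadt = ld_min_aadt, max_caadt = ld_max_caadt),
              lt = list(min_distance = lt_min_distance,
                        aadt_threshold = lt_aadt_threshold))
  class(out) <- "hx_group_criteria"
  out
}

#' Classify a home into a traffic exposure group
#'
#' Applies the HD / LD / LT road-proximity rules with precedence
#' HD > LD > LT; a home matching none of the three definitions (e.g. near a
#' road in the unassigned 4500-6000 CAADT band, or between 150 and 300 m of
#' a busy road) is `"unclassified"`.
#'
#' @param home List or one-row data frame with `x`, `y`.
#' @param roads Road-link data frame with `geometry` list-column, `aadt`,
#'   `caadt`.
#' @param criteria [group_criteria()].
#' @return One of `"HD"`, `"LD"`, `"LT"`, `"unclassified"`.
#' @export
classify_exposure_group <- function(home, roads, criteria = group_criteria()) {
  if (is.data.frame(home)) home <- as.list(home[1, , drop = FALSE])
  d <- vapply(roads$geometry, distance_to_polyline, numeric(1),
              px = home$x, py = home$y)
  hd <- any(d <= criteria$hd$max_distance &
              roads$caadt > criteria$hd$min_caadt &
              roads$aadt > criteria$hd$min_aadt)
  if (hd) return("HD")
  ld <- any(d <= criteria$ld$max_distance &
              roads$aadt > criteria$ld$min_aadt &
              roads$caadt < criteria$ld$max_caadt)
  if (ld) return("LD")
  busy <- roads$aadt > criteria$lt$aadt_threshold
  if (!any(busy) || all(d[busy] >= criteria$lt$min_distance)) return("LT")
  "unclassified"
}

.no_major_road <- function(msg) {
  stop(structure(class = c("hx_no_major_road", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Build an anonymizing near-road receptor mini-grid
#'
#' A rectangular lattice of receptors on 50 m centers tied to a home and its
#' nearest major road: rows parallel to the road at fixed perpendicular
#' distances (first row 10 m from the centerline by default, then 50 m
#' increments), columns centered on the perpendicular foot of the home. No
#' receptor is placed on the home itself, which anonymizes the location
#' while resolving the near-road gradient; the home-row value is recovered
#' later by distance interpolation between rows.
#'
#' @param home List or one-row data frame with `id`, `x`, `y`.
#' @param roads Road-link data frame.
#' @param rows,cols Grid shape (default 4 x 6 = 24 receptors).
#' @param spacing Row/column spacing, m.
#' @param first_row_offset Distance of the first row from the road
#'   centerline, m.
#' @param max_distance Maximum home-to-road distance, m; beyond it an error
#'   of class `hx_no_major_road` directs the caller to [five_point_grid()].
#' @param major_aadt AADT above which a road counts as major.
#' @param receptor_height Receptor height, m.
#' @return List of class `hx_minigrid` with the `receptors` data frame
#'   (`id, x, y, z, row, col, row_distance`), the road reference, bearing,
#'   and `row_distances`.
#' @export
build_minigrid <- function(home, roads, rows = 4L, cols = 6L, spacing = 50,
                           first_row_offset = 10, max_distance = 300,
                           major_aadt = 25000, receptor_height = 1.5) {
  if (is.data.frame(home)) home <- as.list(home[1, , drop = FALSE])
  majors <- roads[roads$aadt > major_aadt, , drop = FALSE]
  if (nrow(majors) == 0) {
    .no_major_road("no major road in the network; use a five-point grid")
  }
  near <- lapply(majors$geometry, nearest_on_polyline, px = home$x, py = home$y)
  di <- which.min(vapply(near, `[[`, numeric(1), "distance"))
  np <- near[[di]]
  if (np$distance > max_distance) {
    .no_major_road(sprintf(
      "no major road within %g m of home %s; use a five-point grid",
      max_distance, home$id %||% "?"))
  }
  th <- np$bearing * pi / 180
  along <- c(sin(th), cos(th))                  # unit vector along the road
  if (np$distance > 1e-9) {
    normal <- c(home$x - np$x, home$y - np$y) / np$distance
  } else {
    normal <- c(along[2], -along[1])            # home on the centerline
  }
  row_distances <- first_row_offset + spacing * (seq_len(rows) - 1)
  col_offsets <- (seq_len(cols) - (cols + 1) / 2) * spacing
  rec <- expand.grid(row = seq_len(rows), col = seq_len(cols),
                     KEEP.OUT.ATTRS = FALSE)
  rec$row_distance <- row_distances[rec$row]
  rec$x <- np$x + rec$row_distance * normal[1] + col_offsets[rec$col] * along[1]
  rec$y <- np$y + rec$row_distance * normal[2] + col_offsets[rec$col] * along[2]
  rec$z <- receptor_height
  rec$id <- sprintf("%s_r%dc%d", home$id %||% "home", rec$row, rec$col)
  out <- list(home_id = home$id %||% "home", road_id = majors$id[di],
              home_distance = np$distance, bearing = np$bearing,
              origin = c(np$x, np$y), rows = rows, cols = cols,
              spacing = spacing, row_distances = row_distances,
              receptors = rec[, c("id", "x", "y", "z", "row", "col",
                                  "row_distance")])
  class(out) <- "hx_minigrid"
  out
}

#' Five-point receptor grid around a home
#'
#' One receptor on the home and four at +/- `offset` on each axis; used for
#' homes without a qualifying major road nearby. The hourly home value is
#' the mean of the five receptors.
#'
#' @param home List or one-row data frame with `id`, `x`, `y`.
#' @param offset Receptor offset, m (default 50).
#' @param receptor_height Receptor height, m.
#' @return List of class `hx_fivepoint` with a 5-row `receptors` data frame.
#' @export
five_point_grid <- function(home, offset = 50, receptor_height = 1.5) {
  if (is.data.frame(home)) home <- as.list(home[1, , drop = FALSE])
  dx <- c(0, offset, -offset, 0, 0)
  dy <- c(0, 0, 0, offset, -offset)
  rec <- data.frame(id = sprintf("%s_p%d", home$id %||% "home", 1:5),
                    x = home$x + dx, y = home$y + dy, z = receptor_height,
                    stringsAsFactors = FALSE)
  out <- list(home_id = home$id %||% "home", offset = offset, receptors = rec)
  class(out) <- "hx_fivepoint"
  out
}

#' Interpolate mini-grid row values to the home distance
#'
#' Linear interpolation in perpendicular distance between the two bracketing
#' row means, clamped to the nearest row outside the row range.
#'
#' @param row_values Row-mean concentrations, one per grid row.
#' @param row_distances Strictly increasing row distances, m.
#' @param home_distance Actual home-to-road distance, m.
#' @return Interpolated concentration (NA if any bracketing value is NA).
#' @export
interpolate_home <- function(row_values, row_distances, home_distance) {
  if (length(row_values) != length(row_distances)) {
    stop("row_values and row_distances must have the same length")
  }
  if (any(diff(row_distances) <= 0)) {
    stop("row distances must be strictly increasing")
  }
  if (anyNA(row_values)) return(NA_real_)
  stats::approx(row_distances, row_values, xout = home_distance,
                rule = 2)$y
}

#' Five-point average
#'
#' Arithmetic mean of the available (non-missing) receptor values; missing
#' when all five are missing.
#'
#' @param values Numeric vector of exactly 5 concentrations (NAs allowed).
#' @return Mean concentration or NA.
#' @export
five_point_average <- function(values) {
  if (length(values) != 5L) stop("five_point_average expects 5 values")
  if (all(is.na(values))) return(NA_real_)
  mean(values, na.rm = TRUE)
}

#' Combine local and background series into the hybrid total
#'
#' Total = mobile + stationary + background hour by hour; an hour missing in
#' any component is missing in the total.
#'
#' @param local_mobile,local_stationary,background Aligned numeric series.
#' @return Data frame with columns `mobile`, `stationary`, `background`,
#'   `total`.
#' @export
combine_hybrid <- function(local_mobile, local_stationary, background) {
  n <- length(local_mobile)
  if (length(local_stationary) != n || length(background) != n) {
    stop("component series must be aligned (equal length)")
  }
  data.frame(mobile = local_mobile, stationary = local_stationary,
             background = background,
             total = local_mobile + local_stationary + background)
}

# Reduce a concentration series at mini-grid receptors to an hourly home
# series: unweighted mean of each row's receptors, then row interpolation at
# the home distance.
minigrid_home_series <- function(grid, conc, home_distance = grid$home_distance) {
  stopifnot(inherits(grid, "hx_minigrid"))
  rec <- grid$receptors
  conc <- conc[conc$receptor_id %in% rec$id, , drop = FALSE]
  conc$row <- rec$row[match(conc$receptor_id, rec$id)]
  rm <- stats::aggregate(value ~ time + pollutant + category + row,
                         data = conc, FUN = mean, na.action = stats::na.pass)
  rm <- rm[order(rm$pollutant, rm$category, rm$time, rm$row), , drop = FALSE]
  groups <- split(rm, list(rm$pollutant, rm$category, format_time(rm$time)),
                  drop = TRUE)
  out <- lapply(groups, function(g) {
    g <- g[order(g$row), , drop = FALSE]
    data.frame(time = g$time[1], pollutant = g$pollutant[1],
               category = g$category[1],
               value = interpolate_home(g$value, grid$row_distances[g$row],
                                        home_distance),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$pollutant, out$category, out$time), , drop = FALSE]
}

# Reduce a concentration series at five-point receptors to the home series.
five_point_series <- function(grid, conc) {
  stopifnot(inherits(grid, "hx_fivepoint"))
  conc <- conc[conc$receptor_id %in% grid$receptors$id, , drop = FALSE]
  agg <- stats::aggregate(value ~ time + pollutant + category, data = conc,
                          FUN = function(v) {
                            if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
                          }, na.action = stats::na.pass)
  agg[order(agg$pollutant, agg$category, agg$time), , drop = FALSE]
}

#' Windowed exposure metrics from an hourly series
#'
#' Per date, window, pollutant and source category: the mean of the
#' available hours, subject to a 70% completeness criterion on the window's
#' hours (a metric below the threshold is emitted as incomplete with a
#' missing value). All six windows are emitted for every date in the series'
#' span.
#'
#' @param series Hourly data frame `time, pollutant, category, value` (NA
#'   values and absent hours both count as missing).
#' @param windows Named list of hour vectors, see [exposure_windows()].
#' @param min_completeness Completeness threshold as a fraction of window
#'   hours (default 0.70).
#' @param home_id Optional id prepended as a column.
#' @return Data frame `home_id?, date, window, pollutant, category, value,
#'   n_hours, complete`.
#' @export
window_metrics <- function(series, windows = exposure_windows(),
                           min_completeness = 0.70, home_id = NULL) {
  stopifnot(nrow(series) > 0)
  series$date <- metric_date(series$time)
  series$hour <- hour_ending(series$time)
  dates <- seq(min(series$date), max(series$date), by = "day")
  polls <- unique(series$pollutant)
  cats <- unique(series$category)
  out <- list()
  for (w in names(windows)) {
    hrs <- windows[[w]]
    sub <- series[series$hour %in% hrs, , drop = FALSE]
    grid <- expand.grid(date = dates, pollutant = polls, category = cats,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    if (nrow(sub) > 0) {
      n_av <- stats::aggregate(value ~ date + pollutant + category, data = sub,
                               FUN = function(v) sum(!is.na(v)),
                               na.action = stats::na.pass)
      names(n_av)[4] <- "n_hours"
      mv <- stats::aggregate(value ~ date + pollutant + category, data = sub,
                             FUN = function(v) {
                               if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
                             }, na.action = stats::na.pass)
      grid <- merge(grid, n_av, all.x = TRUE)
      grid <- merge(grid, mv, all.x = TRUE)
    } else {
      grid$n_hours <- 0L
      grid$value <- NA_real_
    }
    grid$n_hours[is.na(grid$n_hours)] <- 0L
    grid$window <- w
    grid$complete <- grid$n_hours / length(hrs) >= min_completeness
    grid$value[!grid$complete] <- NA_real_
    out[[w]] <- grid
  }
  out <- do.call(rbind, out)
  out <- out[, c("date", "window", "pollutant", "category", "value",
                 "n_hours", "complete")]
  if (!is.null(home_id)) out <- cbind(home_id = home_id, out)
  out <- out[order(out$date, match(out$window, names(windows)),
                   out$pollutant, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
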