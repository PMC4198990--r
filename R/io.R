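# Readers and writers for the pipeline's plain-text interchange formats:
# roads as GeoJSON or CSV+WKT, tabular CSV for meteorology, monitors, homes,
# sources and metrics, and long-format gridded CSV for ratio fields and
# concentration series. Every reader validates type invariants with messages
# naming the offending record; every writer/reader pair is lossless for
# in-range data.

.wkt_coords <- function(body) {
  parts <- strsplit(trimws(strsplit(body, ",")[[1]]), "[[:space:]]+")
  m <- do.call(rbind, lapply(parts, function(p) as.numeric(p[1:2])))
  colnames(m) <- c("x", "y")
  m
}

parse_wkt_linestring <- function(s) {
  body <- sub("^\\s*LINESTRING\\s*\\(", "", s, ignore.case = TRUE)
  body <- sub("\\)\\s*$", "", body)
  .wkt_coords(body)
}

parse_wkt_polygon <- function(s) {
  body <- sub("^\\s*POLYGON\\s*\\(\\s*\\(", "", s, ignore.case = TRUE)
  body <- sub("\\)\\s*\\)\\s*$", "", body)
  m <- .wkt_coords(body)
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

format_wkt_linestring <- function(coords) {
  sprintf("LINESTRING (%s)",
          paste(sprintf("%.6f %.6f", coords[, 1], coords[, 2]),
                collapse = ", "))
}

format_wkt_polygon <- function(coords) {
  ring <- rbind(coords, coords[1, , drop = FALSE])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.6f %.6f", ring[, 1], ring[, 2]), collapse = ", "))
}

.validate_roads <- function(roads) {
  for (i in seq_len(nrow(roads))) {
    if (is.na(roads$aadt[i]) || roads$aadt[i] < 0) {
      stop("road link '", roads$id[i], "': AADT must be >= 0")
    }
    if (is.na(roads$caadt[i]) || roads$caadt[i] < 0 ||
        roads$caadt[i] > roads$aadt[i]) {
      stop("road link '", roads$id[i],
           "': CAADT must satisfy 0 <= CAADT <= AADT")
    }
  }
  roads$length <- vapply(roads$geometry, polyline_length, numeric(1))
  roads$diesel_fraction <- ifelse(roads$aadt > 0, roads$caadt / roads$aadt, 0)
  roads
}

#' Read a road network
#'
#' Accepts GeoJSON (`LineString` features with `id`, `aadt`, `caadt` and
#' optional `road_class` properties) or CSV with a `wkt` LINESTRING column.
#' Link lengths are recomputed from the geometry; AADT/CAADT invariants are
#' validated with errors naming the offending link.
#'
#' @param path File path (`.geojson`/`.json` or `.csv`).
#' @return Road-link data frame with a `geometry` list-column.
#' @export
read_roads <- function(path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    feats <- gj$features
    rows <- lapply(feats, function(f) {
      coords <- do.call(rbind, lapply(f$geometry$coordinates, function(c2)
        as.numeric(unlist(c2))))
      pr <- f$properties
      data.frame(id = as.character(pr$id),
                 aadt = as.numeric(pr$aadt),
                 caadt = as.numeric(pr$caadt),
                 road_class = as.character(pr$road_class %||% "unknown"),
                 geometry = I(list(coords)), stringsAsFactors = FALSE)
    })
    roads <- do.call(rbind, rows)
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    roads <- data.frame(id = as.character(d$id), aadt = d$aadt,
                        caadt = d$caadt,
                        road_class = if (!is.null(d$road_class)) d$road_class
                        else "unknown",
                        geometry = I(lapply(d$wkt, parse_wkt_linestring)),
                        stringsAsFactors = FALSE)
  }
  .validate_roads(roads)
}

#' Write a road network
#'
#' @param roads Road-link data frame.
#' @param path Output path; GeoJSON for `.geojson`/`.json`, else CSV+WKT.
#' @export
write_roads <- function(roads, path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    feats <- lapply(seq_len(nrow(roads)), function(i) {
      coords <- roads$geometry[[i]]
      list(type = "Feature",
           properties = list(id = roads$id[i], aadt = roads$aadt[i],
                             caadt = roads$caadt[i],
                             road_class = roads$road_class[i]),
           geometry = list(type = "LineString",
                           coordinates = lapply(seq_len(nrow(coords)),
                                                function(j) c(coords[j, 1],
                                                              coords[j, 2]))))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    d <- data.frame(id = roads$id, aadt = roads$aadt, caadt = roads$caadt,
                    road_class = roads$road_class,
                    wkt = vapply(roads$geometry, format_wkt_linestring,
                                 character(1)),
                    stringsAsFactors = FALSE)
    utils::write.csv(d, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read hourly meteorology
#'
#' CSV with ISO-8601 local-standard-time hour-ending timestamps. Duplicate
#' timestamps are an error; wind directions are normalized into [0, 360);
#' gaps are left as absent records, never filled.
#'
#' @param path CSV path with columns `time, wind_speed, wind_direction,
#'   stability_class, temperature` (optional `mixing_height`).
#' @return Meteorology data frame.
#' @export
read_met <- function(path) {
  # stability class "F" must not type-convert to logical FALSE
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(stability_class = "character"))
  d$time <- parse_time(d$time)
  if (anyDuplicated(d$time)) {
    stop("duplicate timestamps in meteorology file: ",
         format_time(d$time[duplicated(d$time)][1]))
  }
  if (any(d$wind_speed < 0)) stop("wind_speed must be >= 0")
  d$wind_direction <- d$wind_direction %% 360
  bad <- !d$stability_class %in% stability_classes()
  if (any(bad)) {
    stop("unknown stability class '", d$stability_class[bad][1], "'")
  }
  d[order(d$time), , drop = FALSE]
}

#' Write hourly meteorology
#' @param met Meteorology data frame.
#' @param path Output CSV path.
#' @export
write_met <- function(met, path) {
  d <- met
  d$time <- format_time(d$time)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write windowed exposure metrics
#'
#' Fixed schema `home_id, date, window, pollutant, category, value, n_hours,
#' complete`; incomplete metrics serialize with an empty value. Column order
#' is stable across runs.
#'
#' @param metrics Data frame from [window_metrics()] / [home_exposure()].
#' @param path Output CSV path.
#' @export
write_metrics <- function(metrics, path) {
  cols <- c("home_id", "date", "window", "pollutant", "category", "value",
            "n_hours", "complete")
  if (is.null(metrics$home_id)) metrics$home_id <- ""
  d <- metrics[, cols]
  d$date <- format(d$date, "%Y-%m-%d")
  d$complete <- tolower(as.character(d$complete))
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read windowed exposure metrics
#' @param path CSV path written by [write_metrics()].
#' @return Metrics data frame.
#' @export
read_metrics <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(home_id = "character",
                                      window = "character",
                                      pollutant = "character",
                                      category = "character"))
  d$date <- as.Date(d$date)
  d$value <- as.numeric(d$value)
  d$n_hours <- as.integer(d$n_hours)
  d$complete <- d$complete == "true"
  d
}

#' Write monitor observations
#' @param obs Long data frame `site, x, y, time, pollutant, value`.
#' @param path Output CSV path.
#' @export
write_monitors <- function(obs, path) {
  d <- obs
  d$time <- format_time(d$time)
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read monitor observations
#' @param path CSV path.
#' @return Long observation data frame; negative values are an error.
#' @export
read_monitors <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(site = "character",
                                      pollutant = "character"))
  d$time <- parse_time(d$time)
  if (any(d$value < 0, na.rm = TRUE)) {
    bad <- d[which(d$value < 0)[1], ]
    stop("negative observation at site '", bad$site, "'")
  }
  key <- paste(d$site, d$pollutant)
  for (k in unique(key)) {
    tt <- d$time[key == k]
    if (anyDuplicated(tt)) {
      stop("duplicate timestamps for site/pollutant '", k, "'")
    }
  }
  d
}

#' Write a ratio field as long-format gridded CSV
#' @param field [ratio_field()].
#' @param path Output CSV path.
#' @export
write_ratio_field <- function(field, path) {
  grid <- expand.grid(x = field$x, y = field$y,
                      pollutant = field$pollutants,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$value <- as.vector(field$values)
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' Read a ratio field from long-format gridded CSV
#' @param path CSV path with columns `x, y, pollutant, value`.
#' @return [ratio_field()].
#' @export
read_ratio_field <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  xs <- sort(unique(d$x))
  ys <- sort(unique(d$y))
  polls <- unique(d$pollutant)
  vals <- array(NA_real_, c(length(xs), length(ys), length(polls)))
  ix <- match(d$x, xs)
  iy <- match(d$y, ys)
  ip <- match(d$pollutant, polls)
  vals[cbind(ix, iy, ip)] <- d$value
  if (anyNA(vals)) stop("ratio-field CSV does not cover a full lattice")
  ratio_field(xs, ys, vals, polls)
}

#' Write home locations
#' @param homes Homes data frame.
#' @param path Output CSV path.
#' @export
write_homes <- function(homes, path) {
  utils::write.csv(homes, path, row.names = FALSE)
  invisible(path)
}

#' Read home locations
#' @param path CSV with at least `id, x, y`.
#' @return Homes data frame.
#' @export
read_homes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(id = "character"))
  stopifnot(all(c("id", "x", "y") %in% names(d)))
  d
}

#' Write stationary sources (points and areas) to one CSV
#' @param point_sources,area_sources Source data frames (either may be NULL).
#' @param path Output CSV path.
#' @export
write_sources <- function(point_sources, area_sources, path) {
  polls <- unique(c(
    if (!is.null(point_sources)) names(point_sources$rates[[1]]),
    if (!is.null(area_sources)) names(area_sources$rates[[1]])))
  row_of <- function(src, type) {
    d <- data.frame(id = src$id, type = type,
                    x = src$x %||% NA, y = src$y %||% NA,
                    stack_height = src$stack_height %||% NA,
                    stack_diameter = src$stack_diameter %||% NA,
                    exit_velocity = src$exit_velocity %||% NA,
                    exit_temperature = src$exit_temperature %||% NA,
                    release_height = src$release_height %||% NA,
                    polygon_wkt = if (!is.null(src$polygon))
                      vapply(src$polygon, format_wkt_polygon, character(1))
                    else NA_character_,
                    stringsAsFactors = FALSE)
    for (p in polls) {
      d[[paste0("rate_", p)]] <- vapply(src$rates, function(r)
        if (p %in% names(r)) r[[p]] else NA_real_, numeric(1))
    }
    d
  }
  out <- rbind(
    if (!is.null(point_sources) && nrow(point_sources))
      row_of(point_sources, "point"),
    if (!is.null(area_sources) && nrow(area_sources))
      row_of(area_sources, "area"))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read stationary sources
#' @param path CSV written by [write_sources()].
#' @return List with `point_sources` and `area_sources` data frames.
#' @export
read_sources <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(id = "character", type = "character"))
  rate_cols <- grep("^rate_", names(d), value = TRUE)
  polls <- sub("^rate_", "", rate_cols)
  rates <- lapply(seq_len(nrow(d)), function(i)
    stats::setNames(as.numeric(d[i, rate_cols]), polls))
  pts <- d[d$type == "point", , drop = FALSE]
  ars <- d[d$type == "area", , drop = FALSE]
  point_sources <- if (nrow(pts)) {
    if (any(pts$stack_height < 0, na.rm = TRUE)) {
      stop("point source '", pts$id[which(pts$stack_height < 0)[1]],
           "': stack_height must be >= 0")
    }
    data.frame(id = pts$id, x = pts$x, y = pts$y,
               stack_height = pts$stack_height,
               stack_diameter = pts$stack_diameter,
               exit_velocity = pts$exit_velocity,
               exit_temperature = pts$exit_temperature,
               rates = I(rates[d$type == "point"]), stringsAsFactors = FALSE)
  }
  area_sources <- if (nrow(ars)) {
    data.frame(id = ars$id, release_height = ars$release_height,
               polygon = I(lapply(ars$polygon_wkt, parse_wkt_polygon)),
               rates = I(rates[d$type == "area"]), stringsAsFactors = FALSE)
  }
  list(point_sources = point_sources, area_sources = area_sources)
}

#' Write a long concentration series
#' @param conc Long data frame `receptor_id, time, pollutant, category,
#'   value`.
#' @param path Output CSV path.
#' @export
write_concentrations <- function(conc, path) {
  d <- conc
  d$time <- format_time(d$time)
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a long concentration series
#' @param path CSV path.
#' @return Long concentration data frame.
#' @export
read_concentrations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(receptor_id = "character",
                                      pollutant = "character",
                                      category = "character"))
  d$time <- parse_time(d$time)
  d
}

#' Read a pipeline configuration file
#'
#' YAML file with optional keys for the scenario generator (`n_hours`,
#' `homes_per_group`, `n_monitors`, `pollutants`, `obs_noise_frac`, `seed`),
#' kriging (`stok: {sill, spatial_range, temporal_range, nugget}`) and
#' dispersion options; missing keys take package defaults.
#'
#' @param path YAML path.
#' @return List with `scenario` ([scenario_config()]), `stok`
#'   ([stok_params()]), `options` ([dispersion_options()]) and `seed`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path) %||% list()
  sc_args <- cfg[intersect(names(cfg),
                           names(formals(scenario_config)))]
  if (!is.null(sc_args$start)) sc_args$start <- parse_time(sc_args$start)
  stok_args <- cfg$stok %||% list()
  opt_args <- cfg$dispersion %||% list()
  list(scenario = do.call(scenario_config, sc_args),
       stok = do.call(stok_params, stok_args),
       options = do.call(dispersion_options, opt_args),
       seed = cfg$seed %||% 1L)
}
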