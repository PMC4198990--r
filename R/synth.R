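# Synthetic study scenarios with known ground truth. The generator emulates
# the study design this pipeline targets: a 30 x 40 km planar source domain
# with a high-diesel and a low-diesel highway, stationary point and area
# sources, sparse multi-pollutant monitors sited away from the highways, a
# smooth regional background with a mild diurnal cycle, a regional-fraction
# lattice consistent with that background, and homes recruited into the
# HD / LD / LT road-proximity groups.

#' Scenario generator configuration
#'
#' @param n_hours Hours of meteorology and truth to generate (>= 24).
#' @param start First hour-ending timestamp (local standard time).
#' @param homes_per_group Homes generated in each of HD, LD, LT.
#' @param n_monitors Monitor sites (>= 1; the background stage is untestable
#'   without monitors).
#' @param pollutants Inert primary tracers to model.
#' @param obs_noise_frac Observation noise SD as a fraction of each series'
#'   mean (additive Gaussian truncated at zero).
#' @param ratio_nx,ratio_ny Ratio-field lattice size.
#' @param ratio_hour_stride Hour subsampling stride used when computing the
#'   time-mean local concentrations behind the ratio field.
#' @param wind_floor Wind-speed floor, m/s.
#' @param domain `c(xmin, ymin, xmax, ymax)` in meters.
#' @param monitor_clearance Minimum monitor distance from a highway, m.
#' @return List of class `hx_scenario_config`.
#' @export
scenario_config <- function(n_hours = 72L,
                            start = as.POSIXct("2010-09-01 01:00:00",
                                               tz = "UTC"),
                            homes_per_group = 3L,
                            n_monitors = 6L,
                            pollutants = c("CO", "NOx", "PM2.5", "EC", "OC",
                                           "benzene"),
                            obs_noise_frac = 0.05,
                            ratio_nx = 6L, ratio_ny = 8L,
                            ratio_hour_stride = 4L,
                            wind_floor = 0.5,
                            domain = c(0, 0, 30000, 40000),
                            monitor_clearance = 2000) {
  stopifnot(n_hours >= 24, homes_per_group >= 1, obs_noise_frac >= 0,
            ratio_nx >= 2, ratio_ny >= 2, ratio_hour_stride >= 1)
  if (n_monitors < 1) {
    stop("at least one monitor is required (background stage untestable)")
  }
  out <- list(n_hours = as.integer(n_hours), start = start,
              homes_per_group = as.integer(homes_per_group),
              n_monitors = as.integer(n_monitors),
              pollutants = pollutants, obs_noise_frac = obs_noise_frac,
              ratio_nx = as.integer(ratio_nx), ratio_ny = as.integer(ratio_ny),
              ratio_hour_stride = as.integer(ratio_hour_stride),
              wind_floor = wind_floor, domain = domain,
              monitor_clearance = monitor_clearance)
  class(out) <- "hx_scenario_config"
  out
}

# Regional background truth parameters: base levels (ug/m3) in the regimes
# seen in urban hybrid studies (background-dominated PM2.5 and carbon,
# background-lean NOx), a mild shared diurnal cycle, and a small planar
# spatial gradient (urban backgrounds are nearly uniform at this scale).
.background_defaults <- function(pollutants) {
  base <- c(CO = 300, NOx = 8, "PM2.5" = 10, EC = 0.6, OC = 2.5,
            benzene = 0.5)
  missing_p <- setdiff(pollutants, names(base))
  if (length(missing_p)) {
    base[missing_p] <- 1
  }
  list(base = base[pollutants], diurnal_amp = 0.2, diurnal_phase = 9,
       spatial_amp = 0.05)
}

# Closure evaluating the true regional background at (x, y, time, pollutant).
background_truth_fun <- function(config) {
  p <- .background_defaults(config$pollutants)
  d <- config$domain
  cx <- (d[1] + d[3]) / 2
  cy <- (d[2] + d[4]) / 2
  wx <- (d[3] - d[1]) / 2
  wy <- (d[4] - d[2]) / 2
  function(x, y, time, pollutant) {
    h <- hour_ending(time)
    diurnal <- 1 + p$diurnal_amp * sin(2 * pi * (h - p$diurnal_phase) / 24)
    spatial <- 1 + p$spatial_amp * (0.6 * (x - cx) / wx + 0.4 * (y - cy) / wy)
    unname(p$base[pollutant]) * diurnal * spatial
  }
}

# Fixed synthetic road network: an east-west high-diesel highway in the
# south, a low-diesel highway in the north, and low-volume local roads.
.synth_roads <- function(domain) {
  xmin <- domain[1]; xmax <- domain[3]
  road <- function(id, coords, aadt, caadt, class) {
    data.frame(id = id, aadt = aadt, caadt = caadt,
               diesel_fraction = ifelse(aadt > 0, caadt / aadt, 0),
               road_class = class, length = polyline_length(coords),
               geometry = I(list(coords)), stringsAsFactors = FALSE)
  }
  rbind(
    road("hwy_hd", cbind(c(xmin, xmax), c(10000, 10000)), 120000, 9600,
         "highway"),
    road("hwy_ld", cbind(c(xmin, xmax), c(28000, 28000)), 100000, 3000,
         "highway"),
    road("collector", cbind(c(15000, 15000), c(domain[2], domain[4])),
         20000, 800, "arterial"),
    road("local_1", cbind(c(xmin + 2000, xmax - 2000), c(19500, 20500)),
         6000, 150, "local")
  )
}

.synth_point_sources <- function(pollutants) {
  rate1 <- c(CO = 5, NOx = 3, "PM2.5" = 1.5, EC = 0.15, OC = 0.4,
             benzene = 0.05)
  rate1 <- rate1[intersect(names(rate1), pollutants)]
  extra <- setdiff(pollutants, names(rate1))
  if (length(extra)) rate1[extra] <- 0.1
  data.frame(id = c("stack_1", "stack_2"),
             x = c(20000, 7000), y = c(22000, 7000),
             stack_height = c(35, 20), stack_diameter = c(2, 1.2),
             exit_velocity = c(12, 8), exit_temperature = c(420, 390),
             rates = I(list(rate1[pollutants], rate1[pollutants] * 0.5)),
             stringsAsFactors = FALSE)
}

.synth_area_sources <- function(pollutants) {
  rate <- c(CO = 2, NOx = 1, "PM2.5" = 0.8, EC = 0.08, OC = 0.25,
            benzene = 0.03)
  rate <- rate[intersect(names(rate), pollutants)]
  extra <- setdiff(pollutants, names(rate))
  if (length(extra)) rate[extra] <- 0.05
  poly <- cbind(c(23000, 25000, 25000, 23000), c(32000, 32000, 33500, 33500))
  data.frame(id = "airport", release_height = 3,
             polygon = I(list(poly)), rates = I(list(rate[pollutants])),
             stringsAsFactors = FALSE)
}

#' Generate synthetic hourly surface meteorology
#'
#' Emulates an hourly airport surface record: lognormal wind speeds clamped
#' at a floor, slowly wandering wind direction, a day/night stability cycle
#' (classes A-D by day, D-F by night) and a diurnal temperature cycle.
#'
#' @param seed Integer RNG seed; the series is bit-identical under a fixed
#'   seed.
#' @param n_hours Number of hours (>= 24).
#' @param start First hour-ending timestamp.
#' @param wind_floor Wind-speed floor, m/s.
#' @return Data frame `time, wind_speed, wind_direction, stability_class,
#'   temperature, mixing_height` with strictly increasing timestamps.
#' @export
generate_met <- function(seed, n_hours, start = as.POSIXct(
  "2010-09-01 01:00:00", tz = "UTC"), wind_floor = 0.5) {
  if (n_hours < 24) stop("n_hours must be >= 24")
  set.seed(seed)
  n <- as.integer(n_hours)
  time <- start + 3600 * (0:(n - 1L))
  h <- hour_ending(time)
  day <- h >= 7 & h <= 18
  midday <- h >= 10 & h <= 15
  stab <- character(n)
  for (i in seq_len(n)) {
    stab[i] <- if (day[i]) {
      probs <- if (midday[i]) c(0.15, 0.30, 0.30, 0.25) else
        c(0.05, 0.20, 0.35, 0.40)
      sample(c("A", "B", "C", "D"), 1L, prob = probs)
    } else {
      sample(c("D", "E", "F"), 1L, prob = c(0.40, 0.35, 0.25))
    }
  }
  ws <- pmin(pmax(stats::rlnorm(n, log(3), 0.45), wind_floor), 15)
  wd <- (stats::runif(1, 0, 360) + cumsum(stats::rnorm(n, 0, 18))) %% 360
  temp <- 285 + 6 * sin(2 * pi * (h - 15) / 24) + stats::rnorm(n, 0, 0.5)
  mix <- ifelse(day, 1000, 300) + stats::runif(n, -50, 50)
  data.frame(time = time, wind_speed = ws, wind_direction = wd,
             stability_class = stab, temperature = temp,
             mixing_height = mix, stringsAsFactors = FALSE)
}

#' Synthesize monitor observations from a truth series
#'
#' Observation = truth + independent zero-mean Gaussian noise, truncated at
#' zero. Missing truth hours stay missing.
#'
#' @param truth_series Numeric truth series, ug/m3.
#' @param noise_sd Noise standard deviation, ug/m3 (>= 0).
#' @param seed Integer RNG seed.
#' @return Observation series of the same length, all values >= 0 (or NA).
#' @export
generate_observations <- function(truth_series, noise_sd, seed) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  obs <- truth_series + stats::rnorm(length(truth_series), 0, noise_sd)
  pmax(obs, 0)
}

#' Generate a complete synthetic scenario with known ground truth
#'
#' Builds the road network, stationary sources, meteorology, homes in the
#' three exposure groups, monitor sites, the per-category truth series at
#' the monitors (local concentrations from the package's own dispersion
#' solvers plus the regional background truth), the regional-fraction
#' lattice consistent with that decomposition, and noisy monitor
#' observations. Identical `(seed, config)` inputs reproduce the scenario
#' bit for bit; with zero observation noise the monitor series equal the
#' hybrid truth exactly.
#'
#' @param seed Integer RNG seed.
#' @param config [scenario_config()].
#' @return List of class `hx_scenario`: `roads`, `point_sources`,
#'   `area_sources`, `ef_table`, `profile`, `met`, `homes`, `monitors`
#'   (site table), `observations` (long), `truth` (long, categories
#'   mobile/stationary/background/total at monitor sites), `ratio_field`,
#'   `background_truth` (function), `config`, `seed`.
#' @export
make_scenario <- function(seed, config = scenario_config()) {
  stopifnot(inherits(config, "hx_scenario_config"))
  set.seed(seed)
  domain <- config$domain
  roads <- .synth_roads(domain)
  point_sources <- .synth_point_sources(config$pollutants)
  area_sources <- .synth_area_sources(config$pollutants)
  ef_table <- default_emission_factors()
  profile <- temporal_profile(
    diurnal_weekday = .default_diurnal(),
    diurnal_weekend = rep(1 / 24, 24))

  n <- config$homes_per_group
  hd_road <- roads$geometry[[match("hwy_hd", roads$id)]]
  ld_road <- roads$geometry[[match("hwy_ld", roads$id)]]
  mk_near <- function(prefix, road_y, k) {
    x <- stats::runif(k, 6000, 24000)
    d <- stats::runif(k, 25, 140)
    side <- sample(c(-1, 1), k, replace = TRUE)
    data.frame(id = sprintf("%s_%02d", prefix, seq_len(k)), x = x,
               y = road_y + side * d, stringsAsFactors = FALSE)
  }
  homes <- rbind(
    cbind(mk_near("hd", 10000, n), assigned_group = "HD"),
    cbind(mk_near("ld", 28000, n), assigned_group = "LD"),
    data.frame(id = sprintf("lt_%02d", seq_len(n)),
               x = stats::runif(n, 4000, 26000),
               y = stats::runif(n, 17000, 22500),
               assigned_group = "LT", stringsAsFactors = FALSE)
  )
  majors <- roads[roads$aadt > 25000, , drop = FALSE]
  near <- lapply(seq_len(nrow(homes)), function(i) {
    nn <- lapply(majors$geometry, nearest_on_polyline,
                 px = homes$x[i], py = homes$y[i])
    di <- which.min(vapply(nn, `[[`, numeric(1), "distance"))
    list(road = majors$id[di], distance = nn[[di]]$distance)
  })
  homes$nearest_major_road <- vapply(near, `[[`, character(1), "road")
  homes$distance_to_nearest_major_road <-
    vapply(near, `[[`, numeric(1), "distance")

  monitors <- .synth_monitors(config, roads)
  met <- generate_met(seed + 1L, config$n_hours, config$start,
                      config$wind_floor)
  bg_fun <- background_truth_fun(config)
  opts <- dispersion_options(wind_floor = config$wind_floor)

  # truth at monitor sites: local categories from the dispersion solvers
  mon_rec <- data.frame(id = monitors$site, x = monitors$x, y = monitors$y)
  local <- simulate_hourly(roads, point_sources, area_sources, ef_table,
                           profile, mon_rec, met, config$pollutants, opts)
  truth <- .add_background_truth(local, mon_rec, bg_fun)

  rfield <- .synth_ratio_field(config, roads, point_sources, area_sources,
                               ef_table, profile, met, bg_fun, opts)

  total <- truth[truth$category == "total", , drop = FALSE]
  obs <- total
  names(obs)[names(obs) == "receptor_id"] <- "site"
  obs$x <- monitors$x[match(obs$site, monitors$site)]
  obs$y <- monitors$y[match(obs$site, monitors$site)]
  obs$category <- NULL
  i <- 0L
  for (s in monitors$site) {
    for (p in config$pollutants) {
      i <- i + 1L
      idx <- which(obs$site == s & obs$pollutant == p)
      truth_v <- obs$value[idx]
      sd_p <- config$obs_noise_frac * mean(truth_v, na.rm = TRUE)
      if (!is.finite(sd_p)) sd_p <- 0
      obs$value[idx] <- generate_observations(truth_v, sd_p, seed + 1000L + i)
    }
  }
  obs <- obs[, c("site", "x", "y", "time", "pollutant", "value")]

  out <- list(domain = domain, roads = roads, point_sources = point_sources,
              area_sources = area_sources, ef_table = ef_table,
              profile = profile, met = met, homes = homes,
              monitors = monitors, observations = obs, truth = truth,
              ratio_field = rfield, background_truth = bg_fun,
              config = config, seed = seed)
  class(out) <- "hx_scenario"
  out
}

# Weekday diurnal traffic shape with morning and evening rush peaks.
.default_diurnal <- function() {
  h <- 1:24
  w <- 0.35 + exp(-((h - 8)^2) / 8) + 0.9 * exp(-((h - 17)^2) / 10)
  w / sum(w)
}

# Monitor sites: spread across the domain, away from the highways so the
# local contribution at monitors stays small relative to the background.
.synth_monitors <- function(config, roads) {
  base <- cbind(x = c(5000, 25000, 4000, 26000, 9000, 21000, 14000, 16000),
                y = c(4000, 5500, 20000, 21000, 34500, 33500, 16500, 24500))
  k <- config$n_monitors
  if (k <= nrow(base)) {
    pos <- base[seq_len(k), , drop = FALSE]
  } else {
    hw <- roads[roads$road_class == "highway", , drop = FALSE]
    extra <- matrix(NA_real_, k - nrow(base), 2)
    got <- 0L
    while (got < nrow(extra)) {
      cand <- c(stats::runif(1, config$domain[1] + 1000, config$domain[3] - 1000),
                stats::runif(1, config$domain[2] + 1000, config$domain[4] - 1000))
      dmin <- min(vapply(hw$geometry, distance_to_polyline, numeric(1),
                         px = cand[1], py = cand[2]))
      if (dmin >= config$monitor_clearance) {
        got <- got + 1L
        extra[got, ] <- cand
      }
    }
    pos <- rbind(base, extra)
  }
  jit <- matrix(stats::runif(2 * k, -400, 400), ncol = 2)
  data.frame(site = sprintf("mon_%02d", seq_len(k)),
             x = pos[, 1] + jit[, 1], y = pos[, 2] + jit[, 2],
             stringsAsFactors = FALSE)
}

# Append background and total categories (background truth evaluated at the
# receptor coordinates) to a local mobile/stationary series.
.add_background_truth <- function(local, receptors, bg_fun) {
  mob <- local[local$category == "mobile", , drop = FALSE]
  sta <- local[local$category == "stationary", , drop = FALSE]
  key <- function(d) paste(d$receptor_id, format_time(d$time), d$pollutant)
  sta <- sta[match(key(mob), key(sta)), , drop = FALSE]
  bg <- mob
  bg$category <- "background"
  xs <- receptors$x[match(bg$receptor_id, receptors$id)]
  ys <- receptors$y[match(bg$receptor_id, receptors$id)]
  bg$value <- vapply(seq_len(nrow(bg)), function(i) {
    bg_fun(xs[i], ys[i], bg$time[i], bg$pollutant[i])
  }, numeric(1))
  tot <- mob
  tot$category <- "total"
  tot$value <- mob$value + sta$value + bg$value
  out <- rbind(local, bg, tot)
  rownames(out) <- NULL
  out
}

# Regional-fraction lattice consistent with the generated decomposition:
# r = Bbar / (Bbar + Lbar) at each node from subsampled-hour time means,
# clamped to [0.2, 0.95].
.synth_ratio_field <- function(config, roads, point_sources, area_sources,
                               ef_table, profile, met, bg_fun, opts) {
  d <- config$domain
  xs <- seq(d[1], d[3], length.out = config$ratio_nx)
  ys <- seq(d[2], d[4], length.out = config$ratio_ny)
  nodes <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  nodes$id <- sprintf("node_%03d", seq_len(nrow(nodes)))
  sub_met <- met[seq(1, nrow(met), by = config$ratio_hour_stride), ,
                 drop = FALSE]
  local <- simulate_hourly(roads, point_sources, area_sources, ef_table,
                           profile, nodes[, c("id", "x", "y")], sub_met,
                           config$pollutants, opts)
  vals <- array(NA_real_, c(length(xs), length(ys), length(config$pollutants)))
  for (pi in seq_along(config$pollutants)) {
    p <- config$pollutants[pi]
    sub <- local[local$pollutant == p, , drop = FALSE]
    lsum <- tapply(sub$value, sub$receptor_id,
                   function(v) mean(v, na.rm = TRUE) * 2)  # mobile+stationary
    lbar <- as.numeric(lsum[nodes$id])
    bbar <- vapply(seq_len(nrow(nodes)), function(i) {
      mean(vapply(sub_met$time, function(t)
        bg_fun(nodes$x[i], nodes$y[i], t, p), numeric(1)))
    }, numeric(1))
    r <- bbar / (bbar + lbar)
    vals[, , pi] <- matrix(pmin(0.95, pmax(0.2, r)), length(xs), length(ys))
  }
  ratio_field(xs, ys, vals, config$pollutants)
}
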