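# Link-based mobile emissions and temporally allocated stationary emissions.
# All allocation is mass-conserving: temporal profiles redistribute an annual
# mean rate over months / day types / hours, spatial surrogates redistribute
# a regional total over grid cells.

#' Emission factor table
#'
#' Per-pollutant emission factors (g per vehicle-kilometer) for a two-class
#' fleet: light duty and heavy duty (diesel commercial). The two-class split
#' is the minimal structure expressing the high-diesel / low-diesel contrast
#' in near-road studies.
#'
#' @param pollutant Character vector of pollutant names.
#' @param light_duty,heavy_duty Non-negative factors, g/veh-km.
#' @return Data frame of class `hx_ef_table`.
#' @export
emission_factor_table <- function(pollutant, light_duty, heavy_duty) {
  stopifnot(length(pollutant) == length(light_duty),
            length(pollutant) == length(heavy_duty))
  if (any(light_duty < 0) || any(heavy_duty < 0)) {
    stop("emission factors must be >= 0")
  }
  out <- data.frame(pollutant = as.character(pollutant),
                    light_duty = as.numeric(light_duty),
                    heavy_duty = as.numeric(heavy_duty),
                    stringsAsFactors = FALSE)
  class(out) <- c("hx_ef_table", "data.frame")
  out
}

#' Default emission factor table
#'
#' Fleet-average factors of the expected magnitude for a mid-2000s US urban
#' fleet: heavy-duty diesel dominates NOx and carbonaceous PM per kilometer,
#' light-duty gasoline dominates CO and benzene.
#'
#' @return An [emission_factor_table()].
#' @export
default_emission_factors <- function() {
  emission_factor_table(
    pollutant  = c("CO", "NOx", "PM2.5", "EC",   "OC",  "benzene"),
    light_duty = c(4.0,  0.5,   0.020,   0.005,  0.010, 0.020),
    heavy_duty = c(8.0,  9.0,   0.300,   0.150,  0.080, 0.010)
  )
}

# Fleet-weighted factor per pollutant for one link:
# (1 - CAADT/AADT) * EF_ld + (CAADT/AADT) * EF_hd.
fleet_weighted_ef <- function(link, ef, pollutants = NULL) {
  if (is.data.frame(link)) link <- as.list(link[1, , drop = FALSE])
  if (is.null(pollutants)) pollutants <- ef$pollutant
  missing_p <- setdiff(pollutants, ef$pollutant)
  if (length(missing_p)) {
    stop("no emission factor for pollutant(s): ",
         paste(missing_p, collapse = ", "))
  }
  frac <- if (link$aadt > 0) link$caadt / link$aadt else 0
  i <- match(pollutants, ef$pollutant)
  stats::setNames((1 - frac) * ef$light_duty[i] + frac * ef$heavy_duty[i],
                  pollutants)
}

.check_fractions <- function(x, n, what) {
  if (length(x) != n) stop(what, " must have length ", n)
  if (any(x < 0)) stop(what, " must be non-negative")
  if (abs(sum(x) - 1) > 1e-9) stop(what, " must sum to 1")
  as.numeric(x)
}

#' Temporal allocation profile
#'
#' Monthly, day-type (weekday/Saturday/Sunday) and diurnal fraction vectors,
#' each non-negative and summing to one. The flat profile reproduces the
#' annual-average rate in every hour.
#'
#' @param monthly 12 fractions.
#' @param day_type 3 fractions (weekday, saturday, sunday); the flat value is
#'   the natural share (5/7, 1/7, 1/7).
#' @param diurnal_weekday,diurnal_weekend 24 fractions each.
#' @return List of class `hx_temporal_profile`.
#' @export
temporal_profile <- function(monthly = rep(1 / 12, 12),
                             day_type = c(weekday = 5 / 7, saturday = 1 / 7,
                                          sunday = 1 / 7),
                             diurnal_weekday = rep(1 / 24, 24),
                             diurnal_weekend = rep(1 / 24, 24)) {
  out <- list(
    monthly = .check_fractions(monthly, 12L, "monthly profile"),
    day_type = stats::setNames(.check_fractions(day_type, 3L, "day-type profile"),
                               c("weekday", "saturday", "sunday")),
    diurnal_weekday = .check_fractions(diurnal_weekday, 24L, "weekday diurnal profile"),
    diurnal_weekend = .check_fractions(diurnal_weekend, 24L, "weekend diurnal profile")
  )
  class(out) <- "hx_temporal_profile"
  out
}

#' Flat temporal profile
#' @return A [temporal_profile()] that is the identity for temporal allocation.
#' @export
flat_profile <- function() temporal_profile()

# Natural (calendar) share of each day type within a week.
.natural_day_share <- c(weekday = 5 / 7, saturday = 1 / 7, sunday = 1 / 7)

# Resolve a timestamp against a profile: multiplicative month and day-type
# factors (1 under flat profiles) and the raw diurnal fraction of its hour.
profile_factors <- function(profile, time) {
  if (!inherits(profile, "hx_temporal_profile")) {
    stop("profile must be created with temporal_profile()")
  }
  m <- month_of(time)
  d <- day_type_of(time)
  h <- hour_ending(time)
  diur <- if (d == "weekday") profile$diurnal_weekday else profile$diurnal_weekend
  list(month_factor = 12 * profile$monthly[m],
       day_factor = profile$day_type[[d]] / .natural_day_share[[d]],
       diurnal_fraction = diur[h],
       hour = h)
}

#' Hourly line-source emission strength of a road link
#'
#' Total hourly link emissions are emission factors multiplied by traffic
#' activity: AADT scaled by the profile's month/day-type factors and the
#' diurnal fraction of the hour, times the fleet-weighted emission factor,
#' expressed as a uniform per-meter line strength for the line solver.
#'
#' @param link Road link (row with `aadt`, `caadt`).
#' @param ef Emission factor table.
#' @param profile Temporal profile.
#' @param time Hour-ending timestamp.
#' @param pollutants Pollutants to return (default: all in `ef`); a pollutant
#'   absent from `ef` is an error naming it.
#' @return Named numeric vector of strengths, g/s per meter.
#' @examples
#' link <- list(aadt = 90000, caadt = 0)
#' ef <- emission_factor_table("NOx", 0.3, 0.3)
#' prof <- temporal_profile(diurnal_weekday = c(rep(0.06, 8), rep(0.52 / 16, 16)))
#' # hour 1, fraction 0.06: 90000 * 0.06 * 0.3 g/km over the hour = 4.5e-4 g/s/m
#' @export
link_hourly_emission <- function(link, ef, profile, time, pollutants = NULL) {
  if (is.data.frame(link)) link <- as.list(link[1, , drop = FALSE])
  if (link$caadt > link$aadt) stop("link has CAADT > AADT")
  efw <- fleet_weighted_ef(link, ef, pollutants)
  f <- profile_factors(profile, time)
  veh_per_h <- link$aadt * f$month_factor * f$day_factor * f$diurnal_fraction
  efw * veh_per_h * 1e-3 / 3600
}

#' Temporal allocation of an annual-average rate
#'
#' Hourly rate = annual rate x 12 monthly[m] x k day_type[d] x 24 diurnal[h],
#' with k normalizing the day-type fractions by their natural calendar shares.
#' Flat profiles return the annual rate unchanged for every hour.
#'
#' @param annual_rate Annual-average emission rate, g/s.
#' @param profile Temporal profile.
#' @param time Hour-ending timestamp.
#' @return Emission rate for that hour, g/s (>= 0).
#' @export
temporal_allocate <- function(annual_rate, profile, time) {
  if (annual_rate < 0) stop("annual rate must be >= 0")
  f <- profile_factors(profile, time)
  annual_rate * f$month_factor * f$day_factor * 24 * f$diurnal_fraction
}

#' Spatial allocation of a regional total to grid cells
#'
#' Distributes a regional emission total over cells proportionally to
#' non-negative surrogate weights; the cell rates sum to the total exactly.
#'
#' @param regional_total Total rate to distribute, g/s.
#' @param weights Non-negative per-cell surrogate weights, at least one
#'   positive.
#' @param cells Optional data frame of cell attributes (one row per weight),
#'   returned with a `rate` column appended.
#' @return If `cells` is NULL, the numeric vector of per-cell rates;
#'   otherwise `cells` with the `rate` column.
#' @export
grid_area_emissions <- function(regional_total, weights, cells = NULL) {
  if (regional_total < 0) stop("regional total must be >= 0")
  if (any(weights < 0)) stop("surrogate weights must be >= 0")
  total_w <- sum(weights)
  if (total_w <= 0) stop("all surrogate weights are zero; cannot allocate")
  rates <- regional_total * weights / total_w
  if (is.null(cells)) return(rates)
  if (nrow(cells) != length(weights)) {
    stop("cells must have one row per weight")
  }
  cells$rate <- rates
  cells
}
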