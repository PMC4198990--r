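# Shared fixtures, built in code. Scenarios are memoized so the suite pays
# for each one once per session.

met_hour <- function(u = 3, wd = 0, stab = "D", temp = 288) {
  list(wind_speed = u, wind_direction = wd, stability_class = stab,
       temperature = temp)
}

ts0 <- function(hour = 1, date = "2010-09-01") {
  as.POSIXct(sprintf("%s 00:00:00", date), tz = "UTC") + 3600 * hour
}

# hourly series covering full days
hour_seq <- function(n, date = "2010-09-01") ts0(1, date) + 3600 * (0:(n - 1))

tiny_config <- function(...) {
  scenario_config(n_hours = 24, homes_per_group = 1, n_monitors = 5,
                  ratio_nx = 4, ratio_ny = 5, ratio_hour_stride = 6, ...)
}

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# Noiseless study scenario at the generator's default domain/network with
# three homes per exposure group: the workhorse for recovery and
# cross-module consistency checks.
noiseless_scenario <- function() {
  memo("noiseless", make_scenario(101, scenario_config(
    n_hours = 48, homes_per_group = 3, obs_noise_frac = 0)))
}

# A single east-west road with one-row "homes" on a perpendicular transect.
single_road <- function(aadt = 110000, caadt = 8000) {
  data.frame(id = "hwy", aadt = aadt, caadt = caadt,
             diesel_fraction = caadt / aadt, road_class = "highway",
             length = 30000,
             geometry = I(list(cbind(c(0, 30000), c(10000, 10000)))),
             stringsAsFactors = FALSE)
}
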