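# Timestamps are POSIXct in local standard time (stored with tz = "UTC" as a
# fixed-offset clock; no daylight saving is ever applied). The hour-ending
# convention is used throughout: hour 1 covers 00:01-01:00, so the timestamp
# "01:00" labels hour 1 and "00:00" labels hour 24 of the *previous* date.

#' Hour-ending index of timestamps
#'
#' Maps a vector of hour-ending timestamps to the 1..24 hour labels used by
#' the exposure windows (hour 1 = 00:01-01:00 local standard time).
#'
#' @param time POSIXct vector of hour-ending timestamps.
#' @return Integer vector in 1..24.
#' @export
hour_ending <- function(time) {
  h <- as.integer(format(time, "%H", tz = "UTC"))
  ifelse(h == 0L, 24L, h)
}

#' Date a metric hour belongs to
#'
#' Under the hour-ending convention the timestamp "00:00" is hour 24 of the
#' previous calendar date; this returns the date each hour is accounted to.
#'
#' @param time POSIXct vector of hour-ending timestamps.
#' @return Date vector.
#' @export
metric_date <- function(time) {
  as.Date(time - 1, tz = "UTC")
}

# weekday / saturday / sunday day-type of the metric date of a timestamp
day_type_of <- function(time) {
  wd <- as.integer(format(metric_date(time), "%u"))
  c(rep("weekday", 5), "saturday", "sunday")[wd]
}

month_of <- function(time) {
  as.integer(format(metric_date(time), "%m"))
}

parse_time <- function(x) {
  t <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  bad <- is.na(t) & !is.na(x)
  if (any(bad)) {
    t2 <- as.POSIXct(x[bad], tz = "UTC")
    t[bad] <- t2
  }
  t
}

format_time <- function(time) format(time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
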