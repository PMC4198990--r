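.ew_road <- function(aadt = 100000, caadt = 7000) {
  data.frame(id = "ew", aadt = aadt, caadt = caadt,
             diesel_fraction = caadt / aadt, road_class = "highway",
             length = 20000,
             geometry = I(list(cbind(c(-10000, 10000), c(0, 0)))),
             stringsAsFactors = FALSE)
}

test_that("the mini-grid lattice sits on 50 m centers with rows parallel to the road", {
  home <- list(id = "h1", x = 1234, y = 120)   # 120 m north of an E-W road
  g <- build_minigrid(home, .ew_road())
  rec <- g$receptors
  expect_equal(nrow(rec), 24)
  expect_equal(sort(unique(round(rec$y, 6))), c(10, 60, 110, 160))
  expect_equal(g$row_distances, c(10, 60, 110, 160))
  expect_equal(sort(unique(round(rec$x - 1234, 6))),
               c(-125, -75, -25, 25, 75, 125))
  # perpendicular distances to the road take exactly 4 distinct values
  d <- vapply(seq_len(nrow(rec)), function(i)
    hybridex:::distance_to_polyline(g <- .ew_road()$geometry[[1]],
                                    rec$x[i], rec$y[i]), numeric(1))
  expect_equal(sort(unique(round(d, 6))), c(10, 60, 110, 160))
  # the home itself never coincides with a receptor (anonymity)
  expect_true(all((rec$x - home$x)^2 + (rec$y - home$y)^2 > 1))
})

test_that("mini-grid construction is rigid-motion equivariant", {
  home <- list(id = "h1", x = 1234, y = 120)
  g0 <- build_minigrid(home, .ew_road())
  ang <- 37
  ctr <- c(500, 500)
  roads_r <- .ew_road()
  roads_r$geometry <- I(list(rotate_xy(roads_r$geometry[[1]], ang, ctr)))
  home_xy <- rotate_xy(rbind(c(home$x, home$y)), ang, ctr)
  g1 <- build_minigrid(list(id = "h1", x = home_xy[1], y = home_xy[2]), roads_r)
  rec0 <- rotate_xy(as.matrix(g0$receptors[, c("x", "y")]), ang, ctr)
  expect_equal(as.matrix(g1$receptors[, c("x", "y")]), rec0,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("homes without a qualifying major road are directed to five-point grids", {
  far_home <- list(id = "h2", x = 0, y = 5000)
  expect_error(build_minigrid(far_home, .ew_road()),
               class = "hx_no_major_road")
  minor <- .ew_road(aadt = 20000, caadt = 500)
  expect_error(build_minigrid(list(id = "h3", x = 0, y = 50), minor),
               class = "hx_no_major_road")
  g <- five_point_grid(far_home)
  expect_equal(nrow(g$receptors), 5)
  expect_equal(g$receptors$x[1], 0)
  expect_equal(g$receptors$y[1], 5000)
  expect_equal(sort(g$receptors$x - 0), c(-50, 0, 0, 0, 50))
})

test_that("row interpolation hits nodes exactly, interpolates linearly, and clamps", {
  rows <- c(10, 60, 110, 160)
  vals <- c(9, 8, 4, 3)
  expect_equal(interpolate_home(vals, rows, 60), 8)
  expect_equal(interpolate_home(c(NA, 8, 4, 3), rows, 60), NA_real_)
  expect_equal(interpolate_home(vals, rows, 85), 6)     # midpoint of 8 and 4
  expect_equal(interpolate_home(vals, rows, 5), 9)      # clamp below
  expect_equal(interpolate_home(vals, rows, 400), 3)    # clamp above
  expect_error(interpolate_home(vals, c(10, 60, 60, 160), 85),
               "strictly increasing")
})

test_that("five-point averaging uses available receptors only", {
  expect_equal(five_point_average(c(1, 2, 3, 4, 5)), 3)
  expect_equal(five_point_average(rep(2.5, 5)), 2.5)
  expect_equal(five_point_average(c(2, 4, NA, NA, NA)), 3)
  expect_identical(five_point_average(rep(NA_real_, 5)), NA_real_)
  expect_error(five_point_average(1:4), "5 values")
})

test_that("hybrid combination adds categories hour by hour and propagates gaps", {
  h <- combine_hybrid(c(0, 0, 0), c(0, 0, 0), c(3, 4, 5))
  expect_equal(h$total, c(3, 4, 5))
  set.seed(8)
  m <- runif(50); s <- runif(50); b <- runif(50)
  m[7] <- NA
  h2 <- combine_hybrid(m, s, b)
  brute <- vapply(1:50, function(i) m[i] + s[i] + b[i], numeric(1))
  expect_equal(h2$total, brute)
  expect_true(is.na(h2$total[7]))
  ok <- !is.na(h2$total) & h2$total > 0
  frac <- (h2$mobile + h2$stationary + h2$background)[ok] / h2$total[ok]
  expect_equal(frac, rep(1, sum(ok)), tolerance = 1e-12)
})

.const_series <- function(hours, value = 5, drop_hours = integer()) {
  t <- hour_seq(24)[setdiff(seq_len(24), drop_hours)]
  data.frame(time = t, pollutant = "NOx", category = "total", value = value)
}

test_that("windowed metrics honor the 70% completeness criterion at its boundaries", {
  # 16 of 24 hours: 0.667 < 0.70, incomplete; 17 of 24: 0.708, complete
  m16 <- window_metrics(.const_series(drop_hours = 1:8))
  d16 <- m16[m16$window == "daily", ]
  expect_false(d16$complete)
  expect_true(is.na(d16$value))
  expect_equal(d16$n_hours, 16L)

  m17 <- window_metrics(.const_series(drop_hours = 1:7))
  d17 <- m17[m17$window == "daily", ]
  expect_true(d17$complete)
  expect_equal(d17$value, 5)

  # a 3-hour window needs all 3 hours: 2/3 < 0.70
  m_pk <- window_metrics(.const_series(drop_hours = 15))
  pk <- m_pk[m_pk$window == "pm_peak", ]
  expect_false(pk$complete)
  expect_equal(pk$n_hours, 2L)
})

test_that("the five sub-windows partition the day and reproduce the daily mean", {
  w <- exposure_windows()
  sub <- w[setdiff(names(w), "daily")]
  expect_equal(sort(unlist(sub)), 1:24, ignore_attr = TRUE)
  expect_equal(unname(lengths(sub)), c(6L, 2L, 6L, 3L, 7L))

  set.seed(9)
  series <- data.frame(time = hour_seq(24), pollutant = "PM2.5",
                       category = "total", value = runif(24, 2, 20))
  m <- window_metrics(series)
  expect_true(all(m$complete))
  daily <- m$value[m$window == "daily"]
  sizes <- lengths(sub)
  weighted <- sum(m$value[match(names(sub), m$window)] * sizes) / 24
  expect_equal(daily, weighted, tolerance = 1e-12)

  m_const <- window_metrics(.const_series(value = 3.3))
  expect_equal(unique(m_const$value), 3.3)
  expect_equal(sort(unique(m_const$window)), sort(names(w)))
})

test_that("the HD/LD/LT classifier applies the recruitment thresholds with precedence", {
  mk_roads <- function(...) do.call(rbind, list(...))
  road_at <- function(id, y, aadt, caadt) {
    data.frame(id = id, aadt = aadt, caadt = caadt,
               diesel_fraction = caadt / aadt, road_class = "x",
               length = 20000,
               geometry = I(list(cbind(c(-10000, 10000), c(y, y)))),
               stringsAsFactors = FALSE)
  }
  home <- list(x = 0, y = 0)
  # 100 m from AADT 95,000 / CAADT 7,000
  expect_equal(classify_exposure_group(home, road_at("r", 100, 95000, 7000)), "HD")
  # 100 m from AADT 95,000 / CAADT 4,000
  expect_equal(classify_exposure_group(home, road_at("r", 100, 95000, 4000)), "LD")
  # 400 m from every road above 25,000 AADT
  expect_equal(classify_exposure_group(home, road_at("r", 400, 95000, 7000)), "LT")
  # 200 m from a 95,000/7,000 road and 250 m from a 30,000-AADT road: none apply
  roads <- mk_roads(road_at("a", 200, 95000, 7000), road_at("b", -250, 30000, 100))
  expect_equal(classify_exposure_group(home, roads), "unclassified")
  # CAADT in the unassigned 4500..6000 band
  expect_equal(classify_exposure_group(home, road_at("r", 100, 95000, 5000)),
               "unclassified")
  # HD precedence over LD when both match
  both <- mk_roads(road_at("hd", 100, 95000, 7000), road_at("ld", 120, 95000, 1000))
  expect_equal(classify_exposure_group(home, both), "HD")
})

test_that("interpolated mobile exposure decays with home distance on a single road", {
  roads <- single_road()
  met <- generate_met(77, 24)
  ef <- default_emission_factors()
  prof <- flat_profile()
  vals <- vapply(c(20, 60, 100, 140), function(d) {
    home <- list(id = sprintf("d%d", d), x = 15000, y = 10000 + d)
    g <- build_minigrid(home, roads)
    conc <- simulate_hourly(roads, NULL, NULL, ef, prof, g$receptors, met,
                            "NOx")
    series <- hybridex:::minigrid_home_series(g, conc, d)
    mob <- series[series$category == "mobile", ]
    mean(mob$value, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(vals) <= 0))
})
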