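test_that("generated meteorology respects count, ordering, clamps and the diurnal stability cycle", {
  met <- generate_met(42, 24)
  expect_equal(nrow(met), 24)
  expect_true(all(diff(as.numeric(met$time)) == 3600))
  expect_true(all(met$wind_direction >= 0 & met$wind_direction < 360))
  expect_true(all(met$stability_class %in% c("A", "B", "C", "D", "E", "F")))

  long <- generate_met(42, 10000, wind_floor = 0.5)
  expect_gte(min(long$wind_speed), 0.5)
  h <- hour_ending(long$time)
  day <- h >= 7 & h <= 18
  expect_true(all(long$stability_class[day] %in% c("A", "B", "C", "D")))
  expect_true(all(long$stability_class[!day] %in% c("D", "E", "F")))

  expect_identical(generate_met(42, 48), generate_met(42, 48))
  expect_error(generate_met(42, 12), ">= 24")
})

test_that("synthetic observations follow the truncated additive noise model", {
  truth <- c(3, 0, 7, NA, 2)
  expect_identical(generate_observations(truth, 0, 1), truth)
  expect_error(generate_observations(truth, -1, 1), ">= 0")

  zeros <- generate_observations(rep(0, 500), 3, 2)
  expect_true(all(zeros >= 0))

  big <- generate_observations(rep(1000, 10000), 2, 3)
  noise_sd <- sd(big - 1000)
  expect_lt(abs(noise_sd - 2) / 2, 0.05)
})

test_that("scenario generation is bit-identical under a fixed seed and config", {
  a <- make_scenario(7, tiny_config())
  b <- make_scenario(7, tiny_config())
  expect_identical(a$roads, b$roads)
  expect_identical(a$homes, b$homes)
  expect_identical(a$met, b$met)
  expect_identical(a$monitors, b$monitors)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
  expect_identical(a$ratio_field$values, b$ratio_field$values)
  c <- make_scenario(8, tiny_config())
  expect_false(identical(a$observations$value, c$observations$value))
})

test_that("zero monitors are rejected; zero noise makes observations equal the hybrid truth", {
  expect_error(scenario_config(n_monitors = 0), "monitor")
  sc <- noiseless_scenario()
  tot <- sc$truth[sc$truth$category == "total", ]
  key <- function(d, id) paste(id, format(d$time), d$pollutant)
  m <- match(key(sc$observations, sc$observations$site),
             key(tot, tot$receptor_id))
  expect_identical(sc$observations$value, tot$value[m])
})

test_that("scenario geometry, truth decomposition and labels satisfy the invariants", {
  sc <- noiseless_scenario()
  d <- sc$domain
  expect_true(all(sc$homes$x >= d[1] & sc$homes$x <= d[3]))
  expect_true(all(sc$homes$y >= d[2] & sc$homes$y <= d[4]))
  expect_true(all(sc$monitors$x >= d[1] & sc$monitors$x <= d[3]))

  # stored home distances equal recomputed perpendicular distances within 1 m
  majors <- sc$roads[sc$roads$aadt > 25000, ]
  for (i in seq_len(nrow(sc$homes))) {
    dmin <- min(vapply(majors$geometry, hybridex:::distance_to_polyline,
                       numeric(1), px = sc$homes$x[i], py = sc$homes$y[i]))
    expect_lt(abs(dmin - sc$homes$distance_to_nearest_major_road[i]), 1)
  }

  # truth categories sum to the total used to synthesize observations
  w <- sc$truth
  piv <- function(cat) {
    s <- w[w$category == cat, ]
    s[order(s$receptor_id, s$time, s$pollutant), "value"]
  }
  expect_equal(piv("total"),
               piv("mobile") + piv("stationary") + piv("background"))

  # the exposure classifier reproduces every generated group label
  got <- vapply(seq_len(nrow(sc$homes)), function(i)
    classify_exposure_group(sc$homes[i, ], sc$roads), character(1))
  expect_equal(got, sc$homes$assigned_group)
  expect_equal(sort(unique(got)), c("HD", "LD", "LT"))

  expect_true(all(sc$ratio_field$values >= 0.2 & sc$ratio_field$values <= 0.95))
})
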