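test_that("the space-time covariance has the stated separable exponential form", {
  p <- stok_params(sill = 4, spatial_range = 10000, temporal_range = 12,
                   nugget = 0.5)
  expect_equal(st_covariance(0, 0, p), 4.5)
  p0 <- stok_params(4, 10000, 12, 0)
  expect_equal(st_covariance(10000, 0, p0), 4 * exp(-1), tolerance = 1e-12)
  expect_equal(st_covariance(10000, 12, p0), 4 * exp(-2), tolerance = 1e-12)
  h <- seq(0, 50000, by = 5000)
  cv <- st_covariance(h, 3, p0)
  expect_true(all(diff(cv) < 0))
  expect_true(all(cv > 0))
  expect_error(st_covariance(-1, 0, p0), ">= 0")
})

.obs3 <- function() {
  data.frame(x = c(0, 8000, 3000), y = c(0, 1000, 7000),
             time = rep(ts0(5), 3), value = c(10, 14, 9))
}

test_that("ordinary kriging interpolates exactly with zero nugget and weights sum to one", {
  p <- stok_params(sill = 4, spatial_range = 10000, temporal_range = 12,
                   nugget = 0)
  obs <- .obs3()
  at_data <- krige(obs, list(x = 8000, y = 1000, time = ts0(5)), p)
  expect_equal(at_data$estimate, 14, tolerance = 1e-8)
  expect_equal(at_data$weights[2], 1, tolerance = 1e-8)
  expect_equal(at_data$weights[c(1, 3)], c(0, 0), tolerance = 1e-8)

  between <- krige(obs, list(x = 4000, y = 2500, time = ts0(5)), p)
  expect_equal(sum(between$weights), 1, tolerance = 1e-9)

  # all observations equal: the estimate is that constant anywhere
  obs_c <- obs; obs_c$value <- 7.5
  anywhere <- krige(obs_c, list(x = -2000, y = 9000, time = ts0(7)), p)
  expect_equal(anywhere$estimate, 7.5, tolerance = 1e-9)
})

test_that("kriging weights match an independent dense solve of the OK system", {
  p <- stok_params(sill = 2.5, spatial_range = 12000, temporal_range = 8,
                   nugget = 0.3)
  obs <- data.frame(x = c(0, 8000, 3000), y = c(0, 1000, 7000),
                    time = ts0(5) + 3600 * c(0, 2, -3),
                    value = c(10, 14, 9))
  target <- list(x = 4000, y = 2000, time = ts0(6))
  k <- krige(obs, target, p)
  # independent construction and solve of the same OK system
  C <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    h <- sqrt((obs$x[i] - obs$x[j])^2 + (obs$y[i] - obs$y[j])^2)
    tau <- abs(as.numeric(difftime(obs$time[i], obs$time[j], units = "hours")))
    C[i, j] <- 2.5 * exp(-h / 12000 - tau / 8) + 0.3 * (i == j)
  }
  c0 <- sapply(1:3, function(i) {
    h <- sqrt((obs$x[i] - target$x)^2 + (obs$y[i] - target$y)^2)
    tau <- abs(as.numeric(difftime(obs$time[i], target$time, units = "hours")))
    2.5 * exp(-h / 12000 - tau / 8)
  })
  A <- rbind(cbind(C, 1), c(1, 1, 1, 0))
  sol <- solve(A, c(c0, 1))
  expect_equal(k$weights, sol[1:3], tolerance = 1e-8)
  expect_equal(k$estimate, max(0, sum(sol[1:3] * obs$value)), tolerance = 1e-8)
})

test_that("kriging requires a populated neighborhood and survives duplicate points", {
  p <- stok_params(1, 10000, 12, 0)
  obs <- .obs3()
  expect_error(krige(obs[1, ], list(x = 0, y = 0, time = ts0(5)), p),
               "at least 2")
  expect_error(krige(obs, list(x = 0, y = 0, time = ts0(5) + 200 * 3600), p),
               "at least 2")
  # coincident points with zero nugget: jitter-and-retry keeps the solve alive
  dup <- rbind(obs, obs[1, ])
  k <- krige(dup, list(x = 4000, y = 2500, time = ts0(5)), p)
  expect_equal(sum(k$weights), 1, tolerance = 1e-6)
})

test_that("the background is the kriged observation scaled by the interpolated ratio", {
  p <- stok_params(1, 10000, 12, 0)
  mon <- data.frame(site = c("a", "b", "c"),
                    x = c(0, 8000, 3000), y = c(0, 1000, 7000),
                    time = rep(ts0(5), 3), pollutant = "PM2.5",
                    value = c(10, 14, 9))
  fld1 <- ratio_field(c(-1000, 9000), c(-1000, 8000),
                      matrix(1, 2, 2), "PM2.5")
  tgt <- list(x = 0, y = 0, time = ts0(5))
  b1 <- background_at(tgt, "PM2.5", mon, fld1, p)
  expect_equal(as.numeric(b1), 10, tolerance = 1e-8)   # r = 1: kriged value

  fld0 <- ratio_field(c(-1000, 9000), c(-1000, 8000), matrix(0, 2, 2), "PM2.5")
  expect_equal(as.numeric(background_at(tgt, "PM2.5", mon, fld0, p)), 0)

  fld6 <- ratio_field(c(-1000, 9000), c(-1000, 8000), matrix(0.6, 2, 2), "PM2.5")
  b6 <- background_at(tgt, "PM2.5", mon, fld6, p)
  expect_equal(as.numeric(b6), 6, tolerance = 1e-8)    # kriged 10 x r 0.6
  expect_equal(attr(b6, "ratio"), 0.6)
})

test_that("ratio-field interpolation is bilinear and rejects out-of-lattice targets", {
  vals <- array(c(0.2, 0.4, 0.6, 0.8), c(2, 2, 1))
  fld <- ratio_field(c(0, 1000), c(0, 2000), vals, "NOx")
  expect_equal(ratio_at(fld, 0, 0, "NOx"), 0.2)
  expect_equal(ratio_at(fld, 1000, 2000, "NOx"), 0.8)
  expect_equal(ratio_at(fld, 500, 1000, "NOx"), mean(c(0.2, 0.4, 0.6, 0.8)))
  expect_equal(ratio_at(fld, 250, 500, "NOx"),
               0.2 * 0.75 * 0.75 + 0.4 * 0.25 * 0.75 +
                 0.6 * 0.75 * 0.25 + 0.8 * 0.25 * 0.25)
  expect_error(ratio_at(fld, -10, 0, "NOx"), "outside")
  expect_error(ratio_at(fld, 0, 0, "CO"), "no pollutant")
  expect_error(ratio_field(c(0, 1000), c(0, 2000), vals * 2, "NOx"), "\\[0, 1\\]")
})

test_that("variogram moment matching recovers the scale of synthetic parameters", {
  set.seed(21)
  true_p <- stok_params(sill = 4, spatial_range = 8000, temporal_range = 10,
                        nugget = 0)
  sites <- data.frame(site = sprintf("s%d", 1:8),
                      x = runif(8, 0, 30000), y = runif(8, 0, 30000))
  times <- ts0(1) + 3600 * (0:47)
  # Gaussian process draw under the separable exponential covariance
  grid <- expand.grid(i = 1:8, t = seq_along(times))
  H <- as.matrix(dist(sites[grid$i, c("x", "y")]))
  Tau <- abs(outer(grid$t, grid$t, `-`))
  C <- 4 * exp(-H / 8000 - Tau / 10)
  L <- chol(C + diag(1e-8, nrow(C)))
  v <- 20 + as.vector(t(L) %*% rnorm(nrow(C)))
  obs <- data.frame(site = sites$site[grid$i], x = sites$x[grid$i],
                    y = sites$y[grid$i], time = times[grid$t], value = v)
  fit <- fit_stok_params(obs)
  expect_gt(fit$sill, 1)
  expect_gt(fit$spatial_range, 1500)
  expect_lt(fit$spatial_range, 40000)
  expect_gt(fit$temporal_range, 2)
  expect_lt(fit$temporal_range, 50)
})
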