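# Regional background by space-time ordinary kriging (STOK) of monitor
# observations, scaled by a regional-fraction field derived from paired
# chemical-transport runs (with / without local anthropogenic emissions).
# The transport model itself is out of scope; the ratio field is an input.

#' Space-time kriging parameters
#'
#' Parameters of the separable exponential space-time covariance
#' \eqn{C(h, \tau) = \sigma^2 e^{-h/a_s} e^{-\tau/a_t} + nugget\,1[h=0,\tau=0]}.
#'
#' @param sill Partial sill \eqn{\sigma^2}, (ug/m3)^2; must be > 0.
#' @param spatial_range Spatial e-folding range \eqn{a_s}, m.
#' @param temporal_range Temporal e-folding range \eqn{a_t}, hours.
#' @param nugget Nugget variance, (ug/m3)^2.
#' @return List of class `hx_stok_params`.
#' @export
stok_params <- function(sill = 1, spatial_range = 15000,
                        temporal_range = 12, nugget = 0.01) {
  stopifnot(sill > 0, spatial_range >= 0, temporal_range >= 0, nugget >= 0)
  out <- list(sill = sill, spatial_range = spatial_range,
              temporal_range = temporal_range, nugget = nugget)
  class(out) <- "hx_stok_params"
  out
}

#' Separable exponential space-time covariance
#'
#' @param h Spatial lag(s), m (>= 0).
#' @param tau Temporal lag(s), hours (>= 0).
#' @param params [stok_params()].
#' @return Covariance value(s); positive and non-increasing in each lag.
#' @examples
#' st_covariance(10000, 0, stok_params(4, 10000, 12, 0))  # 4 * exp(-1)
#' @export
st_covariance <- function(h, tau, params) {
  if (any(h < 0) || any(tau < 0)) stop("lags must be >= 0")
  hs <- if (params$spatial_range > 0) h / params$spatial_range else
    ifelse(h > 0, Inf, 0)
  ht <- if (params$temporal_range > 0) tau / params$temporal_range else
    ifelse(tau > 0, Inf, 0)
  params$sill * exp(-hs - ht) + params$nugget * as.numeric(h == 0 & tau == 0)
}

.hours_between <- function(t1, t2) {
  abs(as.numeric(difftime(t1, t2, units = "hours")))
}

#' Space-time ordinary kriging prediction
#'
#' Solves the ordinary kriging system (unbiasedness enforced by a Lagrange
#' multiplier, weights summing to one) over a space-time neighborhood of the
#' target: observations within `time_window` hours, capped at `max_points`
#' nearest in scaled space-time distance \eqn{h/a_s + \tau/a_t}. The nugget
#' sits on the data-data covariance diagonal only, so with zero nugget the
#' predictor interpolates the data exactly. Negative estimates are clamped to
#' zero.
#'
#' @param obs Data frame with columns `x`, `y` (m), `time` (POSIXct), `value`.
#' @param target List or one-row data frame with `x`, `y`, `time`.
#' @param params [stok_params()].
#' @param max_points Neighborhood cap (default 500).
#' @param time_window Temporal half-window, hours (default 24).
#' @return List with `estimate` (>= 0), `variance` (kriging variance),
#'   `weights`, and `used` (row indices of `obs` in the neighborhood).
#' @export
krige <- function(obs, target, params, max_points = 500L, time_window = 24) {
  if (is.data.frame(target)) target <- as.list(target[1, , drop = FALSE])
  obs <- obs[!is.na(obs$value), , drop = FALSE]
  tau0 <- .hours_between(obs$time, target$time)
  sel <- which(tau0 <= time_window)
  if (length(sel) < 2L) {
    stop("kriging needs at least 2 observations in the space-time neighborhood")
  }
  h0 <- sqrt((obs$x[sel] - target$x)^2 + (obs$y[sel] - target$y)^2)
  a_s <- max(params$spatial_range, .Machine$double.eps)
  a_t <- max(params$temporal_range, .Machine$double.eps)
  scaled <- h0 / a_s + tau0[sel] / a_t
  if (length(sel) > max_points) {
    keep <- order(scaled)[seq_len(max_points)]
    sel <- sel[keep]
    h0 <- h0[keep]
  }
  n <- length(sel)
  dx <- outer(obs$x[sel], obs$x[sel], `-`)
  dy <- outer(obs$y[sel], obs$y[sel], `-`)
  H <- sqrt(dx^2 + dy^2)
  tt <- as.numeric(obs$time[sel])
  Tau <- abs(outer(tt, tt, `-`)) / 3600
  C <- params$sill * exp(-H / a_s - Tau / a_t)
  diag(C) <- params$sill + params$nugget
  # exact duplicate points off the diagonal also carry the nugget
  dup <- H == 0 & Tau == 0
  diag(dup) <- FALSE
  C[dup] <- C[dup] + params$nugget
  tau_t <- .hours_between(obs$time[sel], target$time)
  c0 <- params$sill * exp(-h0 / a_s - tau_t / a_t)
  A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  b <- c(c0, 1)
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(sol)) {
    diag(A)[seq_len(n)] <- diag(A)[seq_len(n)] + 1e-8 * params$sill
    sol <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(sol)) {
      stop("singular kriging system (duplicate points with zero nugget?)")
    }
  }
  w <- sol[seq_len(n)]
  mu <- sol[n + 1L]
  est <- max(0, sum(w * obs$value[sel]))
  kvar <- params$sill + params$nugget - sum(w * c0) - mu
  list(estimate = est, variance = max(kvar, 0), weights = w, used = sel)
}

#' Regional-fraction (ratio) field
#'
#' A rectangular lattice of regional-fraction values r(x, y) in [0, 1] per
#' pollutant: the fraction of the monitored concentration attributable to
#' sources outside the local domain.
#'
#' @param x,y Strictly increasing lattice node coordinates, m.
#' @param values Array `[length(x), length(y), n_pollutants]` (a matrix is
#'   accepted for a single pollutant), values in [0, 1].
#' @param pollutants Pollutant names, one per slice of `values`.
#' @return List of class `hx_ratio_field`.
#' @export
ratio_field <- function(x, y, values, pollutants) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(all(diff(x) > 0), all(diff(y) > 0),
            dim(values)[1] == length(x), dim(values)[2] == length(y),
            dim(values)[3] == length(pollutants))
  if (any(values < 0 | values > 1, na.rm = TRUE)) {
    stop("ratio values must lie in [0, 1]")
  }
  dimnames(values) <- list(NULL, NULL, pollutants)
  out <- list(x = x, y = y, values = values, pollutants = pollutants)
  class(out) <- "hx_ratio_field"
  out
}

#' Bilinear interpolation of a ratio field
#'
#' @param field [ratio_field()].
#' @param x,y Query coordinates, m (vectorised); must lie on the lattice.
#' @param pollutant Single pollutant name.
#' @return Interpolated ratio(s) in [0, 1].
#' @export
ratio_at <- function(field, x, y, pollutant) {
  stopifnot(inherits(field, "hx_ratio_field"))
  if (!pollutant %in% field$pollutants) {
    stop("ratio field has no pollutant '", pollutant, "'")
  }
  if (any(x < field$x[1] | x > field$x[length(field$x)] |
          y < field$y[1] | y > field$y[length(field$y)])) {
    stop("target outside the ratio-field lattice")
  }
  v <- field$values[, , pollutant]
  ix <- pmin(pmax(findInterval(x, field$x), 1L), length(field$x) - 1L)
  iy <- pmin(pmax(findInterval(y, field$y), 1L), length(field$y) - 1L)
  x1 <- field$x[ix]; x2 <- field$x[ix + 1L]
  y1 <- field$y[iy]; y2 <- field$y[iy + 1L]
  tx <- (x - x1) / (x2 - x1)
  ty <- (y - y1) / (y2 - y1)
  v[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
    v[cbind(ix + 1L, iy)] * tx * (1 - ty) +
    v[cbind(ix, iy + 1L)] * (1 - tx) * ty +
    v[cbind(ix + 1L, iy + 1L)] * tx * ty
}

#' Background concentration at a space-time point
#'
#' Kriges the total observed concentration to the target and multiplies by
#' the bilinearly interpolated regional fraction, stripping the local signal
#' embedded in the monitor observations.
#'
#' @param target List with `x`, `y`, `time`.
#' @param pollutant Pollutant name.
#' @param monitors Long observation data frame: `site`, `x`, `y`, `time`,
#'   `pollutant`, `value`.
#' @param ratio_field [ratio_field()] covering the target.
#' @param params [stok_params()].
#' @param ... Passed to [krige()] (`max_points`, `time_window`).
#' @return Background concentration, ug/m3 (>= 0), with attributes `kriged`
#'   and `ratio`.
#' @export
background_at <- function(target, pollutant, monitors, ratio_field, params,
                          ...) {
  obs <- monitors[monitors$pollutant == pollutant, , drop = FALSE]
  k <- krige(obs, target, params, ...)
  r <- ratio_at(ratio_field, target$x, target$y, pollutant)
  out <- max(0, k$estimate * r)
  attr(out, "kriged") <- k$estimate
  attr(out, "ratio") <- r
  out
}

#' Background series at fixed locations
#'
#' Kriges the monitor observations to each (location, hour) and applies the
#' regional fraction, for every requested pollutant. When every pollutant is
#' observed at the same site-hours (the usual co-located multi-pollutant
#' network), the kriging weights are shared across pollutants and each
#' system is solved once per location-hour.
#'
#' @param targets Data frame with `id`, `x`, `y`.
#' @param times POSIXct vector of hours.
#' @param pollutants Character vector.
#' @param monitors Long observation data frame (see [background_at()]).
#' @param field [ratio_field()].
#' @param params [stok_params()] shared across pollutants.
#' @param max_points,time_window See [krige()].
#' @param exclude_site Optional site id(s) to hold out of the kriging.
#' @return Long data frame `receptor_id, time, pollutant, category, value`
#'   with category `"background"`.
#' @export
background_series <- function(targets, times, pollutants, monitors, field,
                              params = stok_params(), max_points = 500L,
                              time_window = 24, exclude_site = NULL) {
  if (!is.null(exclude_site)) {
    monitors <- monitors[!monitors$site %in% exclude_site, , drop = FALSE]
  }
  monitors <- monitors[monitors$pollutant %in% pollutants &
                         !is.na(monitors$value), , drop = FALSE]
  if (nrow(monitors) == 0) stop("no usable monitor observations")
  key <- paste(monitors$site, format_time(monitors$time))
  shared <- all(table(key) == length(pollutants)) &&
    length(unique(monitors$pollutant)) == length(pollutants)
  out <- vector("list", nrow(targets))
  if (shared) {
    # one solve per (target, hour); apply the weight vector to each pollutant
    wide_key <- unique(data.frame(site = monitors$site, x = monitors$x,
                                  y = monitors$y, time = monitors$time,
                                  stringsAsFactors = FALSE))
    wide_key <- wide_key[order(wide_key$site, wide_key$time), , drop = FALSE]
    V <- matrix(NA_real_, nrow(wide_key), length(pollutants),
                dimnames = list(NULL, pollutants))
    row_of <- stats::setNames(seq_len(nrow(wide_key)),
                              paste(wide_key$site, format_time(wide_key$time)))
    for (p in pollutants) {
      sub <- monitors[monitors$pollutant == p, , drop = FALSE]
      V[row_of[paste(sub$site, format_time(sub$time))], p] <- sub$value
    }
    geo <- data.frame(x = wide_key$x, y = wide_key$y, time = wide_key$time,
                      value = 0)
    for (gi in seq_len(nrow(targets))) {
      rs <- vapply(pollutants, function(p)
        ratio_at(field, targets$x[gi], targets$y[gi], p), numeric(1))
      res <- vector("list", length(times))
      for (ti in seq_along(times)) {
        tgt <- list(x = targets$x[gi], y = targets$y[gi], time = times[ti])
        k <- krige(geo, tgt, params, max_points, time_window)
        est <- as.vector(crossprod(k$weights, V[k$used, , drop = FALSE]))
        res[[ti]] <- pmax(0, est) * rs
      }
      vals <- do.call(rbind, res)
      out[[gi]] <- data.frame(
        receptor_id = targets$id[gi],
        time = rep(times, times = length(pollutants)),
        pollutant = rep(pollutants, each = length(times)),
        category = "background",
        value = as.vector(vals),
        stringsAsFactors = FALSE)
    }
  } else {
    for (gi in seq_len(nrow(targets))) {
      rows <- expand.grid(time = times, pollutant = pollutants,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      rows$value <- NA_real_
      for (ri in seq_len(nrow(rows))) {
        tgt <- list(x = targets$x[gi], y = targets$y[gi], time = rows$time[ri])
        rows$value[ri] <- as.numeric(background_at(
          tgt, rows$pollutant[ri], monitors, field, params,
          max_points = max_points, time_window = time_window))
      }
      out[[gi]] <- data.frame(receptor_id = targets$id[gi], time = rows$time,
                              pollutant = rows$pollutant,
                              category = "background", value = rows$value,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Fit kriging parameters by variogram moment matching
#'
#' Quick empirical fit of the separable exponential model: the sill is the
#' sample variance; the spatial range is matched to the binned same-hour
#' semivariogram and the temporal range to the binned same-site
#' semivariogram by least squares over the e-folding scale; the nugget is
#' the intercept of the spatial fit (floored at 0).
#'
#' @param obs Data frame `x`, `y`, `time`, `value` (single pollutant).
#' @param n_bins Number of lag bins for each empirical variogram.
#' @return [stok_params()].
#' @export
fit_stok_params <- function(obs, n_bins = 12L) {
  obs <- obs[!is.na(obs$value), , drop = FALSE]
  sill <- stats::var(obs$value)
  if (!is.finite(sill) || sill <= 0) {
    stop("cannot fit kriging parameters: zero variance")
  }
  gamma_fit <- function(lag, gamma, default_range) {
    ok <- is.finite(gamma) & lag > 0
    if (sum(ok) < 3) return(c(range = default_range, nugget = 0))
    f <- function(par) {
      a <- par[1]; c0 <- par[2]
      sum((pmax(0, c0) + (sill - pmax(0, c0)) * (1 - exp(-lag[ok] / a)) -
             gamma[ok])^2)
    }
    fit <- stats::optim(c(default_range, 0), f,
                        lower = c(default_range / 100, 0),
                        upper = c(default_range * 100, sill),
                        method = "L-BFGS-B")
    c(range = fit$par[1], nugget = max(0, fit$par[2]))
  }
  # spatial: pairs observed at the same hour
  sp <- split(seq_len(nrow(obs)), format_time(obs$time))
  hh <- c(); gg <- c()
  for (idx in sp) {
    if (length(idx) < 2) next
    d <- as.matrix(stats::dist(obs[idx, c("x", "y")]))
    dv <- outer(obs$value[idx], obs$value[idx], `-`)^2 / 2
    up <- upper.tri(d)
    hh <- c(hh, d[up]); gg <- c(gg, dv[up])
  }
  sp_fit <- c(range = 15000, nugget = 0)
  if (length(hh) > 0) {
    bins <- cut(hh, n_bins)
    sp_fit <- gamma_fit(tapply(hh, bins, mean), tapply(gg, bins, mean), 15000)
  }
  # temporal: pairs at the same site
  st <- split(seq_len(nrow(obs)), obs$site %||% interaction(obs$x, obs$y))
  tt <- c(); gt <- c()
  for (idx in st) {
    if (length(idx) < 2) next
    d <- abs(outer(as.numeric(obs$time[idx]), as.numeric(obs$time[idx]), `-`)) / 3600
    dv <- outer(obs$value[idx], obs$value[idx], `-`)^2 / 2
    up <- upper.tri(d)
    tt <- c(tt, d[up]); gt <- c(gt, dv[up])
  }
  t_fit <- c(range = 12, nugget = 0)
  if (length(tt) > 0) {
    bins <- cut(tt, n_bins)
    t_fit <- gamma_fit(tapply(tt, bins, mean), tapply(gt, bins, mean), 12)
  }
  stok_params(sill = sill, spatial_range = unname(sp_fit["range"]),
              temporal_range = unname(t_fit["range"]),
              nugget = unname(sp_fit["nugget"]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
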