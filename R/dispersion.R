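# Steady-state Gaussian concentration solvers for point, line (road) and area
# sources under hourly meteorology. All solvers are linear in the emission
# rate and superpose across sources; concentrations are in ug/m3 for rates in
# g/s (point/area) or g/s per meter (line).

#' Dispersion solver options
#'
#' @param sigma_min Lower clamp on dispersion coefficients, m.
#' @param wind_floor Effective wind-speed floor, m/s. Hours with reported
#'   speed below the floor are treated as calm and produce missing values.
#' @param receptor_height Default receptor height (breathing height), m.
#' @param line_tol Relative convergence tolerance of the adaptive line
#'   integration.
#' @param line_max_points Hard cap on line integration points (2^14).
#' @param area_tol Relative convergence tolerance of the adaptive area
#'   integration.
#' @param area_max_side Hard cap on sub-points per polygon bounding-box axis.
#' @param road_release_height Effective release height of road links, m
#'   (vehicle wake mixing zone).
#' @return List of options for [simulate_hourly()] and friends.
#' @export
dispersion_options <- function(sigma_min = 1, wind_floor = 0.5,
                               receptor_height = 1.5,
                               line_tol = 1e-3, line_max_points = 16384L,
                               area_tol = 1e-3, area_max_side = 128L,
                               road_release_height = 1) {
  stopifnot(sigma_min > 0, wind_floor >= 0, line_tol > 0, area_tol > 0)
  list(sigma_min = sigma_min, wind_floor = wind_floor,
       receptor_height = receptor_height,
       line_tol = line_tol, line_max_points = as.integer(line_max_points),
       area_tol = area_tol, area_max_side = as.integer(area_max_side),
       road_release_height = road_release_height)
}

# Unit vector of the transport (downwind) direction for a meteorological
# wind direction (degrees the wind blows FROM, clockwise from north).
wind_unit_vector <- function(wind_direction) {
  th <- wind_direction * pi / 180
  c(-sin(th), -cos(th))
}

.met_fields <- function(met) {
  if (is.data.frame(met)) met <- as.list(met[1, , drop = FALSE])
  list(u = as.numeric(met$wind_speed),
       wd = as.numeric(met$wind_direction),
       stab = as.character(met$stability_class),
       temperature = if (!is.null(met$temperature)) as.numeric(met$temperature) else 288.15)
}

# Core Gaussian kernel with ground reflection, vectorised over source-receptor
# offsets. dxe/dyn are receptor-minus-source offsets (east, north); z receptor
# height; h effective release height. Returns s/m3 per unit emission rate.
.plume_kernel <- function(dxe, dyn, z, h, u, wd, stab,
                          sigma_min = 1, wind_floor = 0.5) {
  u_eff <- max(u, wind_floor)
  w <- wind_unit_vector(wd)
  xd <- dxe * w[1] + dyn * w[2]          # downwind offset
  yc <- -dxe * w[2] + dyn * w[1]         # crosswind offset
  out <- numeric(length(xd))
  ok <- xd > 0
  if (any(ok)) {
    s <- sigma_yz(xd[ok], stab, sigma_min)
    zz <- rep_len(z, length(xd))[ok]
    hh <- rep_len(h, length(xd))[ok]
    vert <- exp(-(zz - hh)^2 / (2 * s$sigma_z^2)) +
      exp(-(zz + hh)^2 / (2 * s$sigma_z^2))
    out[ok] <- exp(-yc[ok]^2 / (2 * s$sigma_y^2)) * vert /
      (2 * pi * u_eff * s$sigma_y * s$sigma_z)
  }
  out
}

#' Gaussian point-source kernel
#'
#' Concentration per unit emission rate (s/m3) of a steady Gaussian plume
#' with full ground reflection, in a frame rotated so transport is along the
#' wind vector. Receptors at or upwind of the source see zero.
#'
#' @param source Numeric `c(x, y)` source location, m.
#' @param effective_height Effective release height, m (stack + plume rise).
#' @param receptor Numeric `c(x, y, z)`; `z` defaults to 1.5 m if omitted.
#' @param met One meteorological hour: list or one-row data frame with
#'   `wind_speed` (m/s), `wind_direction` (degrees FROM), `stability_class`.
#' @param sigma_min,wind_floor See [dispersion_options()].
#' @return Concentration per unit rate, s/m3. Multiply by a rate in g/s and
#'   by 1e6 to obtain ug/m3.
#' @export
point_kernel <- function(source, effective_height, receptor, met,
                         sigma_min = 1, wind_floor = 0.5) {
  m <- .met_fields(met)
  z <- if (length(receptor) >= 3) receptor[3] else 1.5
  .plume_kernel(receptor[1] - source[1], receptor[2] - source[2],
                z, effective_height, m$u, m$wd, m$stab,
                sigma_min, wind_floor)
}

#' Briggs final plume rise of a buoyant stack
#'
#' Effective release height = stack height + final buoyant rise
#' \eqn{\Delta h = 1.6 F^{1/3} (3.5 x^*)^{2/3} / u}, with buoyancy flux
#' \eqn{F = g v_s d^2 (T_s - T_a) / (4 T_s)} and
#' \eqn{x^* = 14 F^{5/8}} for F < 55, \eqn{34 F^{2/5}} otherwise. A
#' non-positive flux (exit at or below ambient temperature) adds no rise.
#'
#' @param source List or one-row data frame with `stack_height` (m),
#'   `stack_diameter` (m), `exit_velocity` (m/s), `exit_temperature` (K).
#' @param met Meteorological hour with `wind_speed` and (ambient)
#'   `temperature` in K.
#' @param wind_floor Wind-speed floor used for the rise, m/s.
#' @return Effective release height, m.
#' @export
plume_rise <- function(source, met, wind_floor = 0.5) {
  if (is.data.frame(source)) source <- as.list(source[1, , drop = FALSE])
  m <- .met_fields(met)
  hs <- as.numeric(source$stack_height)
  vs <- as.numeric(source$exit_velocity)
  d <- as.numeric(source$stack_diameter)
  ts <- as.numeric(source$exit_temperature)
  stopifnot(hs >= 0, vs >= 0, d >= 0)
  Fb <- 9.80665 * vs * d^2 * (ts - m$temperature) / (4 * ts)
  if (!is.finite(Fb) || Fb <= 0) return(hs)
  u_eff <- max(m$u, wind_floor)
  xstar <- if (Fb < 55) 14 * Fb^(5 / 8) else 34 * Fb^(2 / 5)
  hs + 1.6 * Fb^(1 / 3) * (3.5 * xstar)^(2 / 3) / u_eff
}

# Unit-strength line integral of the plume kernel along a polyline by
# composite trapezoid with doubling refinement. Returns the integral in s/m2
# with attribute "converged".
.line_unit_integral <- function(coords, rx, ry, rz, met_u, met_wd, met_stab,
                                release_height = 1, tol = 1e-3,
                                n_start = 16L, max_points = 16384L,
                                sigma_min = 1, wind_floor = 0.5) {
  L <- polyline_length(coords)
  if (L <= 0) {
    out <- 0
    attr(out, "converged") <- TRUE
    return(out)
  }
  n <- as.integer(n_start)
  prev <- NA_real_
  cur <- 0
  converged <- FALSE
  repeat {
    s <- seq(0, L, length.out = n + 1L)
    p <- polyline_point_at(coords, s)
    k <- .plume_kernel(rx - p[, 1], ry - p[, 2], rz, release_height,
                       met_u, met_wd, met_stab, sigma_min, wind_floor)
    w <- rep(L / n, n + 1L)
    w[c(1L, n + 1L)] <- L / (2 * n)
    cur <- sum(w * k)
    if (!is.na(prev) && abs(cur - prev) <= tol * max(abs(cur), 1e-300)) {
      converged <- TRUE
      break
    }
    if (n >= max_points) break
    prev <- cur
    n <- n * 2L
  }
  attr(cur, "converged") <- converged
  cur
}

#' Concentration from a road link (line source)
#'
#' Numerically integrates the Gaussian point kernel along the link polyline,
#' doubling the number of integration points until the relative change falls
#' below `tol` or the hard cap is reached (then the result carries
#' `attr(, "converged") = FALSE` and a warning is raised).
#'
#' @param link Road link (list with a `geometry` coordinate matrix) or a bare
#'   two-column coordinate matrix.
#' @param strength Uniform line emission strength, g/s per meter.
#' @param receptor Numeric `c(x, y, z)`; z defaults to 1.5 m.
#' @param met Meteorological hour (see [point_kernel()]).
#' @param release_height Effective release height of the roadway, m.
#' @param tol,max_points,sigma_min,wind_floor See [dispersion_options()].
#' @return Concentration in ug/m3 (>= 0) with attribute `converged`.
#' @export
line_concentration <- function(link, strength, receptor, met,
                               release_height = 1, tol = 1e-3,
                               max_points = 16384L,
                               sigma_min = 1, wind_floor = 0.5) {
  if (strength < 0) stop("line strength must be >= 0")
  coords <- if (is.list(link) && !is.null(link$geometry)) link$geometry else link
  m <- .met_fields(met)
  z <- if (length(receptor) >= 3) receptor[3] else 1.5
  u <- .line_unit_integral(coords, receptor[1], receptor[2], z,
                           m$u, m$wd, m$stab, release_height, tol,
                           16L, max_points, sigma_min, wind_floor)
  out <- 1e6 * strength * as.numeric(u)
  if (!attr(u, "converged")) {
    warning("line integration hit the point cap before converging")
  }
  attr(out, "converged") <- attr(u, "converged")
  out
}

# Unit-rate area integral: mean kernel over sub-points inside the polygon,
# refined by doubling lattice resolution. Returns s/m3 per unit total rate
# with attributes "converged" and "receptor_inside".
.area_unit_integral <- function(poly, rx, ry, rz, met_u, met_wd, met_stab,
                                release_height = 0, tol = 1e-3,
                                n_start = 8L, max_side = 128L,
                                sigma_min = 1, wind_floor = 0.5) {
  poly <- as_coord_matrix(poly)
  if (polygon_area(poly) <= 0) stop("area source polygon has zero area")
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  aspect <- (yr[2] - yr[1]) / max(xr[2] - xr[1], .Machine$double.eps)
  rec_inside <- isTRUE(point_in_polygon(rx, ry, poly))
  n <- as.integer(n_start)
  prev <- NA_real_
  cur <- 0
  converged <- FALSE
  repeat {
    nx <- n
    ny <- max(2L, as.integer(round(n * aspect)))
    xs <- xr[1] + (seq_len(nx) - 0.5) * (xr[2] - xr[1]) / nx
    ys <- yr[1] + (seq_len(ny) - 0.5) * (yr[2] - yr[1]) / ny
    gx <- rep(xs, times = ny)
    gy <- rep(ys, each = nx)
    inside <- point_in_polygon(gx, gy, poly)
    if (rec_inside) {
      d2 <- (gx - rx)^2 + (gy - ry)^2
      inside <- inside & d2 > sigma_min^2
    }
    if (any(inside)) {
      k <- .plume_kernel(rx - gx[inside], ry - gy[inside], rz, release_height,
                         met_u, met_wd, met_stab, sigma_min, wind_floor)
      cur <- mean(k)
      if (!is.na(prev) && abs(cur - prev) <= tol * max(abs(cur), 1e-300)) {
        converged <- TRUE
        break
      }
      prev <- cur
    }
    if (n >= max_side) break
    n <- n * 2L
  }
  attr(cur, "converged") <- converged
  attr(cur, "receptor_inside") <- rec_inside
  cur
}

#' Concentration from a polygonal area source
#'
#' Integrates the Gaussian point kernel over the polygon by subdividing it
#' into a lattice of sub-points (equal rate split), doubling the resolution
#' until the relative change falls below `tol`. A receptor inside the polygon
#' is handled by excluding sub-points within `sigma_min` of it; the result is
#' then flagged with `attr(, "receptor_inside")`.
#'
#' @param area Area source (list with `polygon` matrix and optionally
#'   `release_height`) or a bare polygon vertex matrix.
#' @param rate Total emission rate of the polygon, g/s.
#' @param receptor Numeric `c(x, y, z)`.
#' @param met Meteorological hour.
#' @param release_height Release height, m (overridden by `area$release_height`).
#' @param tol,max_side,sigma_min,wind_floor See [dispersion_options()].
#' @return Concentration in ug/m3 with attributes `converged`,
#'   `receptor_inside`.
#' @export
area_concentration <- function(area, rate, receptor, met, release_height = 0,
                               tol = 1e-3, max_side = 128L,
                               sigma_min = 1, wind_floor = 0.5) {
  if (rate < 0) stop("area source rate must be >= 0")
  poly <- area
  if (is.list(area) && !is.null(area$polygon)) {
    poly <- area$polygon
    if (!is.null(area$release_height)) release_height <- area$release_height
  }
  m <- .met_fields(met)
  z <- if (length(receptor) >= 3) receptor[3] else 1.5
  u <- .area_unit_integral(poly, receptor[1], receptor[2], z,
                           m$u, m$wd, m$stab, release_height, tol,
                           8L, max_side, sigma_min, wind_floor)
  out <- 1e6 * rate * as.numeric(u)
  attributes(out) <- attributes(u)[c("converged", "receptor_inside")]
  out
}

.as_receptors <- function(receptors, default_z = 1.5) {
  receptors <- as.data.frame(receptors)
  if (is.null(receptors$id)) receptors$id <- as.character(seq_len(nrow(receptors)))
  if (is.null(receptors$z)) receptors$z <- default_z
  if (any(receptors$z < 0)) stop("receptor heights must be >= 0")
  receptors
}

#' Hourly local-scale concentrations from all sources
#'
#' Runs the line solver over every road link and the point/area solvers over
#' every stationary source for every receptor and meteorological hour,
#' summing within the `mobile` (roads) and `stationary` (points + areas)
#' source categories. Emission rates are resolved per hour from the emission
#' factor table and temporal profile. Superposition and linearity in the
#' rates hold exactly. Hours with wind speed below the calm floor yield
#' missing values (not zeros); hours absent from `met` are absent from the
#' output.
#'
#' @param roads Road-link data frame (see [read_roads()]) or NULL.
#' @param point_sources Point-source data frame with stack parameters and a
#'   `rates` list-column of named g/s vectors, or NULL.
#' @param area_sources Area-source data frame with a `polygon` list-column,
#'   `release_height`, and a `rates` list-column, or NULL.
#' @param ef Emission factor table, see [emission_factor_table()].
#' @param profile Temporal profile, see [temporal_profile()].
#' @param receptors Data frame with `id`, `x`, `y` and optional `z`.
#' @param met Meteorology data frame (one row per hour).
#' @param pollutants Character vector of pollutants to model.
#' @param options See [dispersion_options()].
#' @return Long data frame `receptor_id, time, pollutant, category, value`
#'   with categories `mobile` and `stationary`, values in ug/m3.
#' @export
simulate_hourly <- function(roads = NULL, point_sources = NULL,
                            area_sources = NULL, ef, profile,
                            receptors, met, pollutants,
                            options = dispersion_options()) {
  receptors <- .as_receptors(receptors, options$receptor_height)
  nr <- nrow(receptors)
  nt <- nrow(met)
  np <- length(pollutants)
  mobile <- array(0, c(nr, nt, np))
  stationary <- array(0, c(nr, nt, np))
  n_links <- if (is.null(roads)) 0L else nrow(roads)
  n_pts <- if (is.null(point_sources)) 0L else nrow(point_sources)
  n_areas <- if (is.null(area_sources)) 0L else nrow(area_sources)

  for (ti in seq_len(nt)) {
    m <- met[ti, ]
    if (m$wind_speed < options$wind_floor) {   # calm hour: missing, not zero
      mobile[, ti, ] <- NA_real_
      stationary[, ti, ] <- NA_real_
      next
    }
    mf <- .met_fields(m)
    if (n_links > 0) {
      for (li in seq_len(n_links)) {
        link <- roads[li, ]
        strengths <- link_hourly_emission(link, ef, profile, m$time,
                                          pollutants = pollutants)
        if (all(strengths == 0)) next
        unit <- vapply(seq_len(nr), function(ri) {
          as.numeric(.line_unit_integral(
            link$geometry[[1]], receptors$x[ri], receptors$y[ri],
            receptors$z[ri], mf$u, mf$wd, mf$stab,
            options$road_release_height, options$line_tol, 16L,
            options$line_max_points, options$sigma_min, options$wind_floor))
        }, numeric(1))
        for (pi in seq_len(np)) {
          if (strengths[pi] > 0) {
            mobile[, ti, pi] <- mobile[, ti, pi] + 1e6 * strengths[pi] * unit
          }
        }
      }
    }
    if (n_pts > 0) {
      for (si in seq_len(n_pts)) {
        src <- point_sources[si, ]
        heff <- plume_rise(src, m, options$wind_floor)
        k <- .plume_kernel(receptors$x - src$x, receptors$y - src$y,
                           receptors$z, heff, mf$u, mf$wd, mf$stab,
                           options$sigma_min, options$wind_floor)
        rates <- src$rates[[1]]
        for (pi in seq_len(np)) {
          r0 <- rates[[pollutants[pi]]]
          if (!is.null(r0) && !is.na(r0) && r0 > 0) {
            rate <- temporal_allocate(r0, profile, m$time)
            stationary[, ti, pi] <- stationary[, ti, pi] + 1e6 * rate * k
          }
        }
      }
    }
    if (n_areas > 0) {
      for (ai in seq_len(n_areas)) {
        src <- area_sources[ai, ]
        unit <- vapply(seq_len(nr), function(ri) {
          as.numeric(.area_unit_integral(
            src$polygon[[1]], receptors$x[ri], receptors$y[ri],
            receptors$z[ri], mf$u, mf$wd, mf$stab,
            src$release_height, options$area_tol, 8L,
            options$area_max_side, options$sigma_min, options$wind_floor))
        }, numeric(1))
        rates <- src$rates[[1]]
        for (pi in seq_len(np)) {
          r0 <- rates[[pollutants[pi]]]
          if (!is.null(r0) && !is.na(r0) && r0 > 0) {
            rate <- temporal_allocate(r0, profile, m$time)
            stationary[, ti, pi] <- stationary[, ti, pi] + 1e6 * rate * unit
          }
        }
      }
    }
  }

  grid <- expand.grid(receptor_id = receptors$id, time = met$time,
                      pollutant = pollutants,
                      category = c("mobile", "stationary"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$value <- c(as.vector(mobile), as.vector(stationary))
  grid[order(grid$receptor_id, grid$time, grid$pollutant, grid$category), ,
       drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
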