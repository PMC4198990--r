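# Planar geometry on projected coordinates (meters). Study domains are a few
# tens of km across, so projection distortion is negligible and no geodesy is
# performed anywhere downstream of ingest.

as_coord_matrix <- function(coords) {
  m <- as.matrix(coords)
  if (ncol(m) != 2L) stop("coordinates must be a two-column (x, y) matrix")
  storage.mode(m) <- "double"
  m
}

#' Arc length of a polyline
#'
#' @param coords Two-column matrix of (x, y) vertices in meters.
#' @return Length in meters.
#' @export
polyline_length <- function(coords) {
  coords <- as_coord_matrix(coords)
  if (nrow(coords) < 2L) return(0)
  d <- diff(coords)
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

# Points at arc-length positions `s` along a polyline (clamped to [0, L]).
polyline_point_at <- function(coords, s) {
  coords <- as_coord_matrix(coords)
  if (nrow(coords) < 2L) {
    return(cbind(x = rep(coords[1, 1], length(s)), y = rep(coords[1, 2], length(s))))
  }
  seg <- diff(coords)
  len <- sqrt(seg[, 1]^2 + seg[, 2]^2)
  cum <- c(0, cumsum(len))
  s <- pmin(pmax(s, 0), cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(seg))
  t <- (s - cum[i]) / pmax(len[i], .Machine$double.eps)
  cbind(x = coords[i, 1] + t * seg[i, 1], y = coords[i, 2] + t * seg[i, 2])
}

#' Nearest point on a polyline
#'
#' Perpendicular foot of a query point on a polyline, with the compass bearing
#' (degrees clockwise from north) of the segment carrying the foot.
#'
#' @param coords Two-column vertex matrix.
#' @param px,py Query point, meters.
#' @return List with `distance`, foot `x`, `y`, segment `bearing` (degrees),
#'   and the `segment` index.
#' @export
nearest_on_polyline <- function(coords, px, py) {
  coords <- as_coord_matrix(coords)
  if (nrow(coords) < 2L) stop("polyline needs at least two vertices")
  ax <- coords[-nrow(coords), 1]; ay <- coords[-nrow(coords), 2]
  bx <- coords[-1, 1]; by <- coords[-1, 2]
  dx <- bx - ax; dy <- by - ay
  L2 <- pmax(dx^2 + dy^2, .Machine$double.eps)
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / L2))
  fx <- ax + t * dx; fy <- ay + t * dy
  d2 <- (px - fx)^2 + (py - fy)^2
  i <- which.min(d2)
  list(distance = sqrt(d2[i]), x = fx[i], y = fy[i],
       bearing = (atan2(dx[i], dy[i]) * 180 / pi) %% 360, segment = i)
}

distance_to_polyline <- function(coords, px, py) {
  nearest_on_polyline(coords, px, py)$distance
}

polygon_area <- function(poly) {
  poly <- as_coord_matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Even-odd ray casting, vectorised over query points.
point_in_polygon <- function(px, py, poly) {
  poly <- as_coord_matrix(poly)
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if (yi != yj) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

#' Rotate planar points
#'
#' Counter-clockwise rotation about a center, used e.g. to check rigid-motion
#' equivariance of receptor constructions.
#'
#' @param xy Two-column coordinate matrix.
#' @param angle_deg Rotation angle, degrees counter-clockwise.
#' @param center Rotation center, default the origin.
#' @return Rotated coordinate matrix.
#' @export
rotate_xy <- function(xy, angle_deg, center = c(0, 0)) {
  xy <- as_coord_matrix(xy)
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out <- sweep(sweep(xy, 2, center) %*% t(R), 2, center, `+`)
  colnames(out) <- c("x", "y")
  out
}
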