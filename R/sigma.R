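# Briggs open-country dispersion curves keyed to Pasquill stability classes.
# sigma = a * x * (1 + b * x)^c with x the downwind distance in meters. This
# class-based scheme replaces similarity-theory profiles: it keeps the solver
# fully specified from the met record alone (class, speed, direction).

.briggs <- list(
  A = list(y = c(0.22, 1e-4, -0.5), z = c(0.20, 0,      0)),
  B = list(y = c(0.16, 1e-4, -0.5), z = c(0.12, 0,      0)),
  C = list(y = c(0.11, 1e-4, -0.5), z = c(0.08, 2e-4,  -0.5)),
  D = list(y = c(0.08, 1e-4, -0.5), z = c(0.06, 1.5e-3, -0.5)),
  E = list(y = c(0.06, 1e-4, -0.5), z = c(0.03, 3e-4,  -1)),
  F = list(y = c(0.04, 1e-4, -0.5), z = c(0.016, 3e-4, -1))
)

stability_classes <- function() names(.briggs)

.briggs_eval <- function(x, p) {
  if (p[2] == 0) p[1] * x else p[1] * x * (1 + p[2] * x)^p[3]
}

#' Gaussian plume dispersion coefficients
#'
#' Horizontal and vertical plume spreads from the Briggs open-country curves,
#' clamped below by `sigma_min` so the point kernel stays finite arbitrarily
#' close to a source.
#'
#' @param distance Downwind distance(s), meters; must be >= 0.
#' @param stability_class Single Pasquill class, one of `"A"`..`"F"`.
#' @param sigma_min Lower clamp on both coefficients, meters (default 1).
#' @return List with numeric vectors `sigma_y` and `sigma_z`, meters;
#'   both non-decreasing in distance.
#' @examples
#' sigma_yz(1000, "D")  # sigma_y ~ 76.3 m, sigma_z ~ 37.9 m
#' @export
sigma_yz <- function(distance, stability_class, sigma_min = 1) {
  if (any(distance < 0)) stop("downwind distance must be >= 0")
  p <- .briggs[[as.character(stability_class)]]
  if (is.null(p)) {
    stop("unknown stability class '", stability_class,
         "' (expected one of A-F)")
  }
  list(sigma_y = pmax(.briggs_eval(distance, p$y), sigma_min),
       sigma_z = pmax(.briggs_eval(distance, p$z), sigma_min))
}
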