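# Model-to-monitor comparison statistics and distributional summaries.

#' Model evaluation statistics for paired series
#'
#' Pairs model and observed series hour by hour, drops (never imputes) pairs
#' with a missing member, and computes the standard evaluation set: mean
#' bias MB = mean(model - obs), mean (absolute) error ME, Pearson R, and
#' FAC2, the fraction of pairs whose model/obs ratio lies within a factor of
#' two (bounds inclusive; a pair with obs = 0 counts as within only when the
#' model is also 0).
#'
#' @param model,obs Aligned numeric series (equal length).
#' @return One-row data frame of class `hx_eval_stats`: `obs_mean`,
#'   `model_mean`, `mean_bias`, `mean_error`, `r`, `fac2`, `n_pairs`. `r` is
#'   NA with fewer than 2 pairs or zero variance in either series.
#' @examples
#' eval_pairs(model = c(5, 40), obs = c(10, 20))  # MB 7.5, ME 12.5, FAC2 1
#' @export
eval_pairs <- function(model, obs) {
  if (length(model) != length(obs)) {
    stop("model and obs series must be aligned (equal length)")
  }
  ok <- !is.na(model) & !is.na(obs)
  model <- model[ok]
  obs <- obs[ok]
  n <- length(model)
  if (n == 0L) stop("no complete model-observation pairs")
  r <- NA_real_
  if (n >= 2L && stats::sd(model) > 0 && stats::sd(obs) > 0) {
    r <- stats::cor(model, obs)
  }
  within <- (obs == 0 & model == 0) |
    (obs > 0 & model / obs >= 0.5 & model / obs <= 2)
  out <- data.frame(obs_mean = mean(obs), model_mean = mean(model),
                    mean_bias = mean(model - obs),
                    mean_error = mean(abs(model - obs)),
                    r = r, fac2 = mean(within), n_pairs = n)
  class(out) <- c("hx_eval_stats", "data.frame")
  out
}

#' Distribution summary of a concentration series
#'
#' Minimum, 5th/25th/50th/75th/95th percentiles and maximum under the
#' standard linear-interpolation percentile rule.
#'
#' @param series Numeric series (NAs dropped).
#' @return Named non-decreasing numeric vector.
#' @export
distribution_summary <- function(series) {
  series <- series[!is.na(series)]
  if (length(series) == 0L) stop("empty series")
  q <- stats::quantile(series, probs = c(0, 0.05, 0.25, 0.5, 0.75, 0.95, 1),
                       type = 7, names = FALSE)
  stats::setNames(q, c("min", "p5", "p25", "p50", "p75", "p95", "max"))
}

#' Table of evaluation statistics per site and pollutant
#'
#' @param model Long model data frame `receptor_id, time, pollutant, value`
#'   (or with `category`, filtered to `"total"`).
#' @param obs Long observation data frame `site, time, pollutant, value`.
#' @return Data frame with one [eval_pairs()] row per site x pollutant.
#' @export
evaluation_table <- function(model, obs) {
  if (!is.null(model$category)) {
    model <- model[model$category == "total", , drop = FALSE]
  }
  key_m <- paste(model$receptor_id, format_time(model$time), model$pollutant)
  out <- list()
  for (s in unique(obs$site)) {
    for (p in unique(obs$pollutant[obs$site == s])) {
      o <- obs[obs$site == s & obs$pollutant == p, , drop = FALSE]
      m <- model$value[match(paste(s, format_time(o$time), p), key_m)]
      if (all(is.na(m) | is.na(o$value))) next
      st <- eval_pairs(m, o$value)
      out[[paste(s, p)]] <- cbind(site = s, pollutant = p, st)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
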