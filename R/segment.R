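#' Depth-binned, smoothed temperature profile
#'
#' Builds the vertical temperature structure sampled by a deployment: ambient
#' temperature is grouped into 1-m depth bins, per-bin means are computed,
#' empty interior bins are filled by linear interpolation between neighbouring
#' bin means (the animal does not occupy all depths uniformly), and the bin
#' means are smoothed with a centered moving average spanning
#' `smooth_half_width` metres either side (the window is truncated at the
#' profile edges).
#'
#' @param series A `tag_series` at 1-min step (resample upstream).
#' @param bin_width Depth bin width (m), default 1.
#' @param smooth_half_width Half-width of the centered smoothing window (m),
#'   default 10 (a 20-m span).
#' @return A data frame of class `thermal_profile` with columns `bin_center`
#'   (m), `mean_ta`, `smoothed_ta` (degC) and `occupancy` (samples per bin);
#'   attribute `n_filled` counts interpolated interior bins.
#' @export
build_profile <- function(series, bin_width = 1, smooth_half_width = 10) {
  stopifnot(inherits(series, "tag_series"))
  step <- series_step(series)
  if (abs(step - 1) > 1e-6)
    stop("profile requires a 1-min series; resample first")
  if (diff(range(series$depth_m)) < 30)
    stop("profile too shallow to smooth: < 30 m of depth coverage")

  bin <- floor(series$depth_m / bin_width)
  grid <- seq(min(bin), max(bin))
  occupancy <- as.integer(table(factor(bin, levels = grid)))
  mean_ta <- rep(NA_real_, length(grid))
  obs <- tapply(series$ta_c, factor(bin, levels = grid), mean)
  mean_ta[] <- as.vector(obs)
  centers <- (grid + 0.5) * bin_width

  n_filled <- sum(is.na(mean_ta))
  if (n_filled > 0) {
    filled <- approx(centers[!is.na(mean_ta)], mean_ta[!is.na(mean_ta)],
                     xout = centers, rule = 1)$y
    mean_ta <- filled
    message(sprintf("filled %d empty interior depth bin(s) by interpolation",
                    n_filled))
  }

  width <- 2L * as.integer(round(smooth_half_width / bin_width)) + 1L
  smoothed <- zoo::rollapply(mean_ta, width = width, FUN = mean,
                             partial = TRUE, align = "center")

  df <- data.frame(bin_center = centers, mean_ta = mean_ta,
                   smoothed_ta = as.numeric(smoothed), occupancy = occupancy)
  attr(df, "n_filled") <- n_filled
  attr(df, "bin_width") <- bin_width
  class(df) <- c("thermal_profile", "data.frame")
  df
}

#' Detect the thermocline
#'
#' The thermocline is the depth of the steepest vertical temperature gradient
#' of the smoothed profile, estimated by first differences of adjacent
#' smoothed bins. Smoothing turns a sharp interface into a ramp of equally
#' steep bin pairs, so exact ties are resolved by taking the shallowest
#' maximal-gradient run and returning its central depth (for a sharp step
#' this is the interface itself; a single steepest pair returns its
#' midpoint).
#'
#' @param profile A `thermal_profile` with at least 21 smoothed bins.
#' @return Thermocline depth (m).
#' @export
detect_thermocline <- function(profile) {
  stopifnot(inherits(profile, "thermal_profile"))
  if (nrow(profile) < 21) stop("profile needs >= 21 smoothed bins")
  grad <- diff(profile$smoothed_ta) / diff(profile$bin_center)
  g <- abs(grad)
  mx <- max(g)
  if (mx < 1e-12) stop("no gradient: profile is constant")
  mids <- (profile$bin_center[-nrow(profile)] + profile$bin_center[-1]) / 2
  cand <- which(g >= mx * (1 - 1e-8))
  runs <- split(cand, cumsum(c(1L, diff(cand) != 1L)))
  run <- runs[[1]]  # shallowest maximal run
  (mids[min(run)] + mids[max(run)]) / 2
}

#' Extract below-thermocline dives
#'
#' A dive is a maximal run of samples with depth strictly below (deeper than)
#' the thermocline; separate runs are never merged, so a brief return above
#' the thermocline splits a dive. Runs lasting `min_duration` or less are
#' excluded (the inclusive cutoff drops very short excursions). A run of
#' consecutive samples contributes its full sampled duration
#' (`n_samples * step`).
#'
#' @param series A `tag_series` with uniform step.
#' @param thermocline Thermocline depth (m), within the observed depth range.
#' @param min_duration Exclusion cutoff (min); runs with duration
#'   `<= min_duration` are dropped. Default 10.
#' @return A data frame of class `dive_events` with columns `start_min`,
#'   `end_min`, `duration_min`, `max_depth_m`, `min_ta_c`, ordered by start
#'   time (possibly zero rows).
#' @export
extract_dives <- function(series, thermocline, min_duration = 10) {
  stopifnot(inherits(series, "tag_series"), is.numeric(thermocline))
  step <- series_step(series)
  rng <- range(series$depth_m)
  if (thermocline < rng[1] || thermocline > rng[2])
    stop("`thermocline` outside the observed depth range")
  below <- series$depth_m > thermocline
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- data.frame(start_min = numeric(0), end_min = numeric(0),
                    duration_min = numeric(0), max_depth_m = numeric(0),
                    min_ta_c = numeric(0))
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    dur <- (i1 - i0 + 1) * step
    if (dur <= min_duration) next
    out <- rbind(out, data.frame(
      start_min = series$time_min[i0],
      end_min = series$time_min[i0] + dur,
      duration_min = dur,
      max_depth_m = max(series$depth_m[i0:i1]),
      min_ta_c = min(series$ta_c[i0:i1])))
  }
  class(out) <- c("dive_events", "data.frame")
  out
}

#' Dive statistics
#'
#' Arithmetic mean and range of dive duration and maximum depth.
#'
#' @param dives A non-empty `dive_events` table.
#' @return A list with elements `duration` and `max_depth`, each
#'   `c(mean, min, max)`, plus `n_dives`.
#' @export
dive_statistics <- function(dives) {
  stopifnot(inherits(dives, "dive_events"))
  if (nrow(dives) == 0) stop("no dives to summarise")
  mmr <- function(x) c(mean = mean(x), min = min(x), max = max(x))
  list(duration = mmr(dives$duration_min),
       max_depth = mmr(dives$max_depth_m),
       n_dives = nrow(dives))
}
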