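#' Tag time series
#'
#' Container for an animal-borne tag record: time since deployment (min),
#' depth (m), ambient water temperature and muscle temperature (degC). Time
#' must be strictly increasing; the modal sampling step is recorded as an
#' attribute. Operations that require a uniform step (resampling, profile
#' binning, model fitting) verify it themselves, so a series with isolated
#' dropped records can still be carried.
#'
#' @param time Time since deployment (min), strictly increasing.
#' @param depth Depth (m), >= 0.
#' @param ta Ambient temperature (degC), finite, within (-5, 45).
#' @param tb Muscle temperature (degC), finite, within (-5, 45).
#' @return A data frame of class `tag_series` with columns `time_min`,
#'   `depth_m`, `ta_c`, `tb_c` and attribute `step_min`.
#' @export
tag_series <- function(time, depth, ta, tb) {
  n <- length(time)
  if (!(length(depth) == n && length(ta) == n && length(tb) == n))
    stop("all channels must have equal length")
  if (n < 2) stop("a tag series needs at least 2 samples")
  if (any(!is.finite(time)) || any(diff(time) <= 0))
    stop("`time` must be finite and strictly increasing")
  if (any(depth < 0, na.rm = TRUE)) stop("`depth` must be >= 0")
  for (ch in list(ta = ta, tb = tb)) {
    if (any(!is.finite(ch)) || any(ch <= -5 | ch >= 45))
      stop("temperatures must be finite and within (-5, 45) degC")
  }
  df <- data.frame(time_min = time, depth_m = depth, ta_c = ta, tb_c = tb)
  attr(df, "step_min") <- unname(median(diff(time)))
  class(df) <- c("tag_series", "data.frame")
  df
}

# step of a series; error if not uniform (within tol)
series_step <- function(series, tol = 1e-9) {
  dt <- diff(series$time_min)
  if (any(abs(dt - dt[1]) > tol))
    stop("tag series does not have a uniform time step")
  dt[1]
}

#' Write a tag series to CSV
#'
#' Header `time_min,depth_m,ta_c,tb_c`, the dialect produced by the
#' synthetic-data generator and read back by [read_tag_series()].
#'
#' @param series A `tag_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tag_series <- function(series, path) {
  stopifnot(inherits(series, "tag_series"))
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Read a tag series from CSV
#'
#' Expects columns `time_min,depth_m,ta_c,tb_c`. Rows with any non-finite
#' field are dropped with a warning giving the count. Non-monotone time is an
#' error (e.g. shuffled rows).
#'
#' @param path CSV file path.
#' @return A `tag_series`.
#' @export
read_tag_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path)
  need <- c("time_min", "depth_m", "ta_c", "tb_c")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  ok <- Reduce(`&`, lapply(df[need], is.finite))
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    warning(sprintf("dropped %d row(s) with non-finite values", n_bad))
    df <- df[ok, , drop = FALSE]
  }
  if (any(diff(df$time_min) <= 0))
    stop("`time_min` is not strictly increasing")
  tag_series(df$time_min, df$depth_m, df$ta_c, df$tb_c)
}

#' Trim the post-capture period
#'
#' Drops the first `hours` of record to remove capture and handling effects;
#' the analysis window starts once behaviour has settled. By default the time
#' axis is re-zeroed at the new start.
#'
#' @param series A `tag_series`.
#' @param hours Hours to drop from the start (default 6).
#' @param rezero Re-zero the time axis after trimming (default `TRUE`).
#' @return The trimmed `tag_series`.
#' @export
trim_capture_effect <- function(series, hours = 6, rezero = TRUE) {
  stopifnot(inherits(series, "tag_series"), hours >= 0)
  cut <- series$time_min[1] + hours * 60
  keep <- series$time_min >= cut
  if (!any(keep)) stop("series lies entirely within the trim window")
  out <- series[keep, , drop = FALSE]
  time <- if (rezero) out$time_min - out$time_min[1] else out$time_min
  tag_series(time, out$depth_m, out$ta_c, out$tb_c)
}

#' Resample a tag series to a coarser step
#'
#' `mode = "subsample"` keeps the first sample of each interval (the
#' convention used upstream of model fitting); `mode = "average"` takes block
#' means per interval (the convention used for depth-temperature profiles).
#' The target interval must be an integer multiple of the native step. A
#' trailing incomplete block is dropped.
#'
#' @param series A `tag_series` with uniform step.
#' @param interval Target step (min), >= the native step.
#' @param mode `"subsample"` or `"average"`.
#' @return A `tag_series` at step `interval`.
#' @export
resample <- function(series, interval = 1, mode = c("subsample", "average")) {
  stopifnot(inherits(series, "tag_series"))
  mode <- match.arg(mode)
  step <- series_step(series)
  if (interval < step - 1e-9) stop("`interval` must be >= the native step")
  ratio <- interval / step
  if (abs(ratio - round(ratio)) > 1e-6)
    stop("`interval` must be an integer multiple of the native step")
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(series)
  n_blocks <- nrow(series) %/% ratio
  if (n_blocks < 2) stop("series too short for this interval")
  idx <- seq_len(n_blocks * ratio)
  block <- rep(seq_len(n_blocks), each = ratio)
  agg <- function(x) {
    x <- x[idx]
    if (mode == "subsample") x[seq(1, length(x), by = ratio)]
    else as.vector(tapply(x, block, mean))
  }
  t0 <- series$time_min[seq(1, n_blocks * ratio, by = ratio)]
  tag_series(t0, agg(series$depth_m), agg(series$ta_c), agg(series$tb_c))
}

#' Thermal summary of a deployment
#'
#' Descriptive statistics of depth, ambient and muscle temperature, their
#' difference (muscle minus ambient; positive means elevated muscle
#' temperature), and the fraction of time the muscle is strictly warmer than
#' the water.
#'
#' @param series A non-empty `tag_series`.
#' @return A list of class `thermal_summary` with elements `depth`, `ta`,
#'   `tb` (each `c(mean, min, max)`), `diff` (`c(mean, min, max)` of
#'   `tb - ta`) and `frac_tb_above` in `[0, 1]`.
#' @export
thermal_summary <- function(series) {
  if (!inherits(series, "tag_series") || nrow(series) == 0)
    stop("non-empty `tag_series` required")
  mmr <- function(x) c(mean = mean(x), min = min(x), max = max(x))
  d <- series$tb_c - series$ta_c
  structure(list(depth = mmr(series$depth_m), ta = mmr(series$ta_c),
                 tb = mmr(series$tb_c), diff = mmr(d),
                 frac_tb_above = mean(d > 0), n = nrow(series)),
            class = "thermal_summary")
}

#' @export
print.thermal_summary <- function(x, ...) {
  fmt <- function(v) sprintf("%.1f (%.1f-%.1f)", v["mean"], v["min"], v["max"])
  cat("Thermal summary (", x$n, " samples)\n", sep = "")
  cat("  depth (m):        ", fmt(x$depth), "\n")
  cat("  ambient (degC):   ", fmt(x$ta), "\n")
  cat("  muscle (degC):    ", fmt(x$tb), "\n")
  cat("  tb - ta (degC):   ", fmt(x$diff), "\n")
  cat(sprintf("  time tb > ta:      %.0f%%\n", 100 * x$frac_tb_above))
  invisible(x)
}

#' @export
as.data.frame.thermal_summary <- function(x, ...) {
  data.frame(depth_mean = x$depth["mean"], depth_min = x$depth["min"],
             depth_max = x$depth["max"], ta_mean = x$ta["mean"],
             ta_min = x$ta["min"], ta_max = x$ta["max"],
             tb_mean = x$tb["mean"], tb_min = x$tb["min"],
             tb_max = x$tb["max"], diff_mean = x$diff["mean"],
             diff_min = x$diff["min"], diff_max = x$diff["max"],
             frac_tb_above = x$frac_tb_above, n = x$n, row.names = NULL)
}
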