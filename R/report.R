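#' Deployment summary row
#'
#' One-row table combining the thermal summary and dive statistics of a
#' deployment, in the layout used to describe tagged individuals (depth,
#' ambient and muscle temperature means and ranges, muscle-ambient
#' difference, fraction of time warmer than the water, dive duration and
#' depth).
#'
#' @param series A processed (trimmed, 1-min) `tag_series`.
#' @param dives A `dive_events` table for the same deployment.
#' @param id Deployment identifier.
#' @return A one-row data frame.
#' @export
deployment_summary <- function(series, dives, id = "tag") {
  ts <- as.data.frame(thermal_summary(series))
  ds <- if (nrow(dives) > 0) dive_statistics(dives) else NULL
  cbind(data.frame(id = id),
        ts,
        data.frame(
          n_dives = if (is.null(ds)) 0L else ds$n_dives,
          dive_duration_mean = if (is.null(ds)) NA_real_ else ds$duration["mean"],
          dive_duration_min = if (is.null(ds)) NA_real_ else ds$duration["min"],
          dive_duration_max = if (is.null(ds)) NA_real_ else ds$duration["max"],
          dive_depth_mean = if (is.null(ds)) NA_real_ else ds$max_depth["mean"],
          dive_depth_min = if (is.null(ds)) NA_real_ else ds$max_depth["min"],
          dive_depth_max = if (is.null(ds)) NA_real_ else ds$max_depth["max"],
          row.names = NULL))
}

#' Heat-model comparison table
#'
#' Two-row table (constant vs variable model) of fitted parameters, MAE and
#' AIC for one deployment, with the selection decision attached as an
#' attribute.
#'
#' @param fit_const,fit_var `heat_fit` results on the same series.
#' @param selection Result of [select_heat_model()] on the two fits.
#' @param id Deployment identifier.
#' @return A two-row data frame with attribute `selection`.
#' @export
heat_model_table <- function(fit_const, fit_var, selection, id = "tag") {
  row <- function(f) {
    pp <- f$params
    data.frame(id = id, model = f$kind,
               k = if (f$kind == "constant") pp$k else NA_real_,
               k_warm = if (f$kind == "variable") pp$k_warm else NA_real_,
               k_cool = if (f$kind == "variable") pp$k_cool else NA_real_,
               ratio = if (f$kind == "variable") f$ratio else 1.0,
               tm_dot = pp$tm_dot, mae = f$mae, aic = as.numeric(f$aic),
               selected = f$kind == selection$selected)
  }
  out <- rbind(row(fit_const), row(fit_var))
  attr(out, "selection") <- selection
  out
}

#' Serialise a heat-model fit to JSON
#'
#' @param fit A `heat_fit`.
#' @param path Output path; if `NULL`, the JSON string is returned.
#' @param selection Optional [select_heat_model()] result to embed.
#' @return `path` (invisibly) or the JSON string.
#' @export
heat_fit_json <- function(fit, path = NULL, selection = NULL) {
  obj <- list(kind = fit$kind, scheme = fit$scheme,
              params = fit$params[setdiff(names(fit$params), "kind")],
              rss = fit$rss, mae = fit$mae, aic = as.numeric(fit$aic),
              n = fit$n, p = fit$p, ratio = fit$ratio)
  if (!is.null(selection))
    obj$selection <- selection[c("selected", "mae_improvement",
                                 "mae_guard", "guard_applied", "rationale")]
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
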