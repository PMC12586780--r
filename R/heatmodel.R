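#' Heat-exchange model parameters
#'
#' Parameters of the whole-body Newtonian heat-exchange model
#' `dTb/dt = k (Ta - Tb) + Tm_dot`. The `constant` kind uses a single heat
#' transfer coefficient `k`; the `variable` kind switches between `k_warm`
#' (warming phase, `Ta >= Tb`) and `k_cool` (cooling phase, `Ta < Tb`).
#' All rates are in 1/min (`k` is degC/min per degC of body-ambient
#' difference); `tm_dot`, the metabolic heat production rate, is in degC/min.
#' All parameters must lie within the fitting bounds `[0, 1]`.
#'
#' @param k Constant heat transfer coefficient (omit for the variable kind).
#' @param k_warm,k_cool Warming/cooling coefficients (omit for constant kind).
#' @param tm_dot Internal heat production rate (degC/min).
#' @return An object of class `heat_params` with a `kind` field.
#' @examples
#' heat_params(k_warm = 0.052, k_cool = 0.0036, tm_dot = 0.0062)
#' @export
heat_params <- function(k = NULL, k_warm = NULL, k_cool = NULL, tm_dot) {
  if (!is.null(k) && (is.null(k_warm) && is.null(k_cool))) {
    kind <- "constant"
    vals <- c(k = k, tm_dot = tm_dot)
  } else if (is.null(k) && !is.null(k_warm) && !is.null(k_cool)) {
    kind <- "variable"
    vals <- c(k_warm = k_warm, k_cool = k_cool, tm_dot = tm_dot)
  } else {
    stop("supply either `k` (constant kind) or both `k_warm` and `k_cool`")
  }
  if (any(vals < 0 | vals > 1))
    stop("all parameters must lie within [0, 1]")
  structure(c(as.list(vals), list(kind = kind)), class = "heat_params")
}

# (k_warm, k_cool) pair for either kind
.k_pair <- function(params) {
  if (params$kind == "constant") c(params$k, params$k)
  else c(params$k_warm, params$k_cool)
}

#' Ratio of warming to cooling coefficient
#'
#' `k_warm / k_cool` for variable-kind parameters; 1 for the constant kind.
#'
#' @param params A `heat_params` object.
#' @return Dimensionless ratio.
#' @export
k_ratio <- function(params) {
  stopifnot(inherits(params, "heat_params"))
  kp <- .k_pair(params)
  kp[1] / kp[2]
}

#' Forward-simulate the muscle temperature trace
#'
#' Closed forward simulation of the heat-exchange model from a single initial
#' value: at each step the active coefficient is chosen by comparing the
#' ambient temperature against the *simulated* muscle temperature (so the
#' prediction never peeks at the data; pass `tb_observed` to key the regime
#' to the measured trace instead, for sensitivity checks).
#'
#' Schemes: `"euler"` is the forward Euler update
#' `tb[t+1] = tb[t] + dt * (k (ta[t] - tb[t]) + tm_dot)`; `"exact_step"`
#' integrates the ODE exactly over each step holding `ta` constant,
#' `tb[t+1] = ta[t] + tm_dot/k + (tb[t] - ta[t] - tm_dot/k) exp(-k dt)`
#' (with the `k = 0` limit `tb[t] + tm_dot * dt`).
#'
#' @param ta Ambient temperature series (degC) at uniform step `dt`.
#' @param params A [heat_params()] object.
#' @param tb0 Initial muscle temperature (degC).
#' @param dt Time step (min), > 0.
#' @param scheme `"euler"` (default) or `"exact_step"`. Euler requires
#'   `k * dt < 1` and errors otherwise.
#' @param tb_observed Optional observed muscle trace (same length as `ta`)
#'   used only for the regime switch.
#' @return Predicted muscle temperature series, same length as `ta`.
#' @export
predict_muscle_temperature <- function(ta, params, tb0, dt = 1,
                                       scheme = c("euler", "exact_step"),
                                       tb_observed = NULL) {
  stopifnot(inherits(params, "heat_params"), dt > 0, is.finite(tb0))
  scheme <- match.arg(scheme)
  kp <- .k_pair(params)
  if (scheme == "euler" && max(kp) * dt >= 1)
    stop("euler scheme unstable: k * dt >= 1; use scheme = \"exact_step\"")
  ref <- if (is.null(tb_observed)) numeric(0) else as.numeric(tb_observed)
  if (length(ref) && length(ref) != length(ta))
    stop("`tb_observed` must match the length of `ta`")
  predict_tb_cpp(as.numeric(ta), dt, kp[1], kp[2], params$tm_dot, tb0,
                 if (scheme == "euler") 0L else 1L, ref)
}

#' Goodness of fit of a predicted trace
#'
#' Residual sum of squares, mean absolute error, and the Gaussian
#' least-squares AIC `n log(rss/n) + 2 (p + 1)` (the error variance counts as
#' a parameter; only AIC differences are meaningful). A perfect fit
#' (`rss = 0`) returns `aic = -Inf` with attribute `flagged = TRUE`.
#'
#' @param tb_obs,tb_pred Observed and predicted series of equal length
#'   `n >= p + 2`.
#' @param p Number of fitted mean parameters (2 constant / 3 variable).
#' @return A list with `rss` (degC^2), `mae` (degC), `aic`, `n`, `p`.
#' @export
goodness_of_fit <- function(tb_obs, tb_pred, p) {
  n <- length(tb_obs)
  if (length(tb_pred) != n) stop("observed and predicted lengths differ")
  if (n < p + 2) stop("need n >= p + 2 samples")
  e <- tb_obs - tb_pred
  rss <- sum(e^2)
  mae <- sum(abs(e)) / n
  if (rss == 0) {
    aic <- structure(-Inf, flagged = TRUE)
  } else {
    aic <- n * log(rss / n) + 2 * (p + 1)
  }
  list(rss = rss, mae = mae, aic = aic, n = n, p = p)
}

#' Fit the heat-exchange model to a tag series
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) minimising the squared error between the observed muscle
#' trace and the closed forward simulation. The initial simulated temperature
#' is the first observed value; all parameters start at `init` (default 0.01)
#' within `bounds` (default `[0, 1]`). Under the euler scheme the upper bound
#' on the coefficients is capped just below `1/dt` to keep the recursion
#' stable. On non-convergence, five rescaled starting points are tried before
#' giving up.
#'
#' @param series A `tag_series` with uniform step and >= 60 samples.
#' @param kind `"variable"` (two-regime) or `"constant"`.
#' @param scheme Integration scheme, see [predict_muscle_temperature()].
#' @param init Common starting value for all parameters.
#' @param bounds Length-2 lower/upper parameter bounds.
#' @param regime Key the warming/cooling switch to the `"predicted"` (default)
#'   or `"observed"` muscle temperature.
#' @return A list of class `heat_fit`: `params` ([heat_params()]), `tb_pred`,
#'   `rss`, `mae`, `aic`, `n`, `p`, `ratio` (`k_warm/k_cool`, variable kind
#'   only), `kind`, `scheme`, `convergence`.
#' @export
fit_heat_model <- function(series, kind = c("variable", "constant"),
                           scheme = c("euler", "exact_step"),
                           init = 0.01, bounds = c(0, 1),
                           regime = c("predicted", "observed")) {
  stopifnot(inherits(series, "tag_series"))
  kind <- match.arg(kind)
  scheme <- match.arg(scheme)
  regime <- match.arg(regime)
  dt <- series_step(series)
  n <- nrow(series)
  if (n < 60) stop("need >= 60 samples to fit")
  ta <- series$ta_c
  tb <- series$tb_c
  if (max(abs(ta - tb)) < 1e-6)
    stop("degenerate series: ta and tb coincide, k is unidentifiable")
  tb0 <- tb[1]
  tb_ref <- if (regime == "observed") tb else NULL

  par0 <- if (kind == "constant") c(k = init, tm_dot = init)
          else c(k_warm = init, k_cool = init, tm_dot = init)
  lower <- rep(bounds[1], length(par0))
  upper <- rep(bounds[2], length(par0))
  if (scheme == "euler") {
    k_idx <- seq_len(length(par0) - 1L)
    upper[k_idx] <- pmin(upper[k_idx], (1 - 1e-6) / dt)
  }

  as_params <- function(p) {
    if (kind == "constant") heat_params(k = p[["k"]], tm_dot = p[["tm_dot"]])
    else heat_params(k_warm = p[["k_warm"]], k_cool = p[["k_cool"]],
                     tm_dot = p[["tm_dot"]])
  }
  resid_fn <- function(p) {
    tb - predict_muscle_temperature(ta, as_params(p), tb0, dt = dt,
                                    scheme = scheme, tb_observed = tb_ref)
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-13,
                                     ptol = 1e-13)
  run <- function(start) {
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fn, control = ctrl)
  }
  fit <- run(par0)
  if (!(fit$info %in% 1:3)) {
    for (fac in c(0.2, 0.5, 2, 5, 10)) {   # deterministic multistart fallback
      cand <- run(pmin(pmax(par0 * fac, lower + 1e-8), upper - 1e-8))
      if (cand$info %in% 1:3) { fit <- cand; break }
      if (cand$deviance < fit$deviance) fit <- cand
    }
    if (!(fit$info %in% 1:3))
      stop(sprintf("optimizer did not converge (info = %d: %s)",
                   fit$info, fit$message))
  }

  params <- as_params(coef(fit))
  pred <- predict_muscle_temperature(ta, params, tb0, dt = dt,
                                     scheme = scheme, tb_observed = tb_ref)
  p <- if (kind == "constant") 2L else 3L
  gof <- goodness_of_fit(tb, pred, p)
  structure(list(params = params, tb_pred = pred, rss = gof$rss,
                 mae = gof$mae, aic = gof$aic, n = gof$n, p = p,
                 ratio = if (kind == "variable") k_ratio(params) else NA_real_,
                 kind = kind, scheme = scheme, regime = regime,
                 convergence = list(info = fit$info, message = fit$message,
                                    niter = fit$niter)),
            class = "heat_fit")
}

#' @export
print.heat_fit <- function(x, ...) {
  cat(sprintf("Heat-exchange model fit (%s k, %s scheme, n = %d)\n",
              x$kind, x$scheme, x$n))
  pp <- x$params
  if (x$kind == "constant") {
    cat(sprintf("  k = %.4g  tm_dot = %.4g\n", pp$k, pp$tm_dot))
  } else {
    cat(sprintf("  k_warm = %.4g  k_cool = %.4g  ratio = %.3g  tm_dot = %.4g\n",
                pp$k_warm, pp$k_cool, x$ratio, pp$tm_dot))
  }
  cat(sprintf("  MAE = %.4g degC  RSS = %.4g  AIC = %.4g\n",
              x$mae, x$rss, as.numeric(x$aic)))
  invisible(x)
}

#' Select between the constant and variable heat models
#'
#' The lower-AIC model wins unless the variable model's relative MAE
#' improvement over the constant model, `(mae_const - mae_var) / mae_const`,
#' falls below `mae_guard`: near-identical fitting errors indicate the extra
#' coefficient is overfitting, and the constant model is kept (the guard is
#' recorded in the rationale). Ties go to the constant model by parsimony.
#'
#' @param fit_const,fit_var `heat_fit` results (or lists with `mae`, `aic`,
#'   `n`) fitted to the same data.
#' @param mae_guard Minimum relative MAE improvement required to accept the
#'   variable model (default 0.10).
#' @return A list with `selected` (`"constant"` or `"variable"`), `fit` (the
#'   winning fit), `mae_improvement`, `mae_guard`, `guard_applied`, and a
#'   human-readable `rationale`.
#' @export
select_heat_model <- function(fit_const, fit_var, mae_guard = 0.10) {
  if (!is.null(fit_const$n) && !is.null(fit_var$n) &&
      fit_const$n != fit_var$n)
    stop("fits are not on identical data (different n)")
  impr <- (fit_const$mae - fit_var$mae) / fit_const$mae
  aic_c <- as.numeric(fit_const$aic)
  aic_v <- as.numeric(fit_var$aic)
  if (isTRUE(all.equal(fit_const$mae, fit_var$mae)) && aic_c == aic_v) {
    sel <- "constant"; guard <- FALSE
    why <- "identical fits; constant model kept by parsimony"
  } else if (aic_v < aic_c) {
    if (is.finite(impr) && impr < mae_guard) {
      sel <- "constant"; guard <- TRUE
      why <- sprintf(paste0("overfit guard: variable model improves MAE by ",
                            "only %.1f%% (< %.0f%%); constant model kept"),
                     100 * impr, 100 * mae_guard)
    } else {
      sel <- "variable"; guard <- FALSE
      why <- sprintf("variable model: lower AIC and %.1f%% MAE improvement",
                     100 * impr)
    }
  } else {
    sel <- "constant"; guard <- FALSE
    why <- "constant model has the lower AIC"
  }
  list(selected = sel,
       fit = if (sel == "constant") fit_const else fit_var,
       mae_improvement = impr, mae_guard = mae_guard,
       guard_applied = guard, rationale = why)
}
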