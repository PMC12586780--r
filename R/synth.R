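#' Sigmoid (logistic) water column
#'
#' A thermally stratified water column with a warm mixed layer over cold deep
#' water, joined by a logistic transition. The steepest vertical temperature
#' gradient of this profile sits exactly at `thermocline_depth`, which gives
#' downstream thermocline-detection code an analytic truth to recover.
#'
#' @param surface_temp Mixed-layer temperature (degC). Must exceed `deep_temp`.
#' @param deep_temp Deep-water asymptote (degC).
#' @param thermocline_depth Depth of the logistic midpoint (m), > 0.
#' @param transition_scale Logistic half-width (m), > 0. Smaller values give a
#'   sharper thermocline.
#' @return An object of class `water_column`.
#' @examples
#' wc <- water_column(25, 14, 100, 10)
#' ambient_at(wc, 100)  # midpoint: (25 + 14) / 2
#' @export
water_column <- function(surface_temp = 25, deep_temp = 14,
                         thermocline_depth = 100, transition_scale = 10) {
  stopifnot(is.numeric(surface_temp), is.numeric(deep_temp),
            length(surface_temp) == 1L, length(deep_temp) == 1L)
  if (!(surface_temp > deep_temp))
    stop("`surface_temp` must exceed `deep_temp`")
  if (!(thermocline_depth > 0)) stop("`thermocline_depth` must be > 0")
  if (!(transition_scale > 0)) stop("`transition_scale` must be > 0")
  structure(list(surface_temp = surface_temp, deep_temp = deep_temp,
                 thermocline_depth = thermocline_depth,
                 transition_scale = transition_scale),
            class = "water_column")
}

#' Ambient temperature at depth
#'
#' Evaluates the logistic depth-temperature profile of a [water_column()].
#' Monotone non-increasing in depth and bounded by
#' `[deep_temp, surface_temp]`.
#'
#' @param column A `water_column`.
#' @param depth Depth (m), vectorised; all values must be >= 0.
#' @return Ambient temperature (degC), same length as `depth`.
#' @export
ambient_at <- function(column, depth) {
  stopifnot(inherits(column, "water_column"), is.numeric(depth))
  if (any(depth < 0)) stop("`depth` must be non-negative")
  column$deep_temp + (column$surface_temp - column$deep_temp) /
    (1 + exp((depth - column$thermocline_depth) / column$transition_scale))
}

#' Simulation configuration for a tag deployment
#'
#' Describes the dive schedule and sampling of a synthetic deployment:
#' alternating surface intervals and trapezoidal dives (constant-rate descent,
#' flat bottom phase, constant-rate ascent).
#'
#' @param duration Total record length (min).
#' @param step Sampling step (min).
#' @param dive_depths Bottom depths of successive dives (m).
#' @param dive_durations Bottom-phase durations (min); same length as
#'   `dive_depths`.
#' @param surface_intervals Surface time preceding each dive (min); same
#'   length as `dive_depths`.
#' @param descent_rate Vertical speed during descent and ascent (m/min).
#' @param noise_sd Gaussian measurement noise on the muscle channel (degC).
#' @param seed Integer seed driving all random draws.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration = 1320, step = 1,
                       dive_depths = c(200, 250, 180),
                       dive_durations = c(60, 90, 45),
                       surface_intervals = c(60, 120, 90),
                       descent_rate = 50, noise_sd = 0.1, seed = 1L) {
  if (!(step > 0)) stop("`step` must be > 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (length(dive_depths) != length(dive_durations) ||
      length(dive_depths) != length(surface_intervals))
    stop("dive schedule lists must have the same length")
  if (length(dive_durations) && any(dive_durations <= 0))
    stop("all `dive_durations` must be > 0")
  if (length(surface_intervals) && any(surface_intervals <= 0))
    stop("all `surface_intervals` must be > 0")
  if (!(duration > 0)) stop("`duration` must be > 0")
  if (!(descent_rate > 0)) stop("`descent_rate` must be > 0")
  structure(list(duration = duration, step = step,
                 dive_depths = dive_depths, dive_durations = dive_durations,
                 surface_intervals = surface_intervals,
                 descent_rate = descent_rate, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a trapezoidal dive track
#'
#' Builds the depth trajectory of a deployment from a [sim_config()]: for each
#' dive, a surface interval at 0 m, a descent at `descent_rate`, a flat bottom
#' phase at the dive depth, and an ascent back to the surface. Time remaining
#' after the last dive is spent at the surface.
#'
#' @param cfg A `sim_config`.
#' @return Numeric vector of depths (m), one per sampling step
#'   (`duration / step` samples at times `0, step, 2*step, ...`).
#' @export
simulate_dive_track <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- floor(cfg$duration / cfg$step)
  times <- (seq_len(n) - 1) * cfg$step
  if (length(cfg$dive_depths) == 0L) return(rep(0, n))

  # piecewise-linear knots: (time, depth)
  kt <- 0
  kd <- 0
  t_cur <- 0
  for (i in seq_along(cfg$dive_depths)) {
    d <- cfg$dive_depths[i]
    travel <- d / cfg$descent_rate
    t_cur <- t_cur + cfg$surface_intervals[i]
    kt <- c(kt, t_cur); kd <- c(kd, 0)           # end of surface interval
    t_cur <- t_cur + travel
    kt <- c(kt, t_cur); kd <- c(kd, d)           # reached bottom
    t_cur <- t_cur + cfg$dive_durations[i]
    kt <- c(kt, t_cur); kd <- c(kd, d)           # leaving bottom
    t_cur <- t_cur + travel
    kt <- c(kt, t_cur); kd <- c(kd, 0)           # back at surface
  }
  if (t_cur > cfg$duration)
    stop(sprintf(
      "dive schedule (%.1f min) exceeds deployment duration (%.1f min)",
      t_cur, cfg$duration))
  kt <- c(kt, cfg$duration); kd <- c(kd, 0)
  approx(kt, kd, xout = times, method = "linear", ties = "ordered")$y
}

#' Simulate a full tag deployment
#'
#' Generates a [tag_series()] from a depth track: the ambient channel is the
#' water column evaluated along the track (treated as exact), and the muscle
#' channel is the forward-simulated two-regime heat-exchange model plus i.i.d.
#' Gaussian measurement noise.
#'
#' Random stream: `set.seed(seed)` followed by a single `rnorm(n, 0, noise_sd)`
#' draw for the muscle channel, so identical seeds give identical series.
#'
#' @param track Depth series (m) at uniform step `step`.
#' @param column A `water_column`.
#' @param params A [heat_params()] object (all rates within `[0, 1]`).
#' @param tb0 Initial muscle temperature (degC).
#' @param noise_sd Muscle measurement noise SD (degC), >= 0.
#' @param seed Integer seed.
#' @param step Sampling step of `track` (min).
#' @param scheme Integration scheme passed to [predict_muscle_temperature()].
#' @return A `tag_series`.
#' @export
simulate_tag_deployment <- function(track, column, params, tb0,
                                    noise_sd = 0.1, seed = 1L, step = 1,
                                    scheme = c("euler", "exact_step")) {
  stopifnot(inherits(column, "water_column"), inherits(params, "heat_params"),
            is.finite(tb0))
  scheme <- match.arg(scheme)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  n <- length(track)
  ta <- ambient_at(column, track)
  tb_true <- predict_muscle_temperature(ta, params, tb0, dt = step,
                                        scheme = scheme)
  set.seed(as.integer(seed))
  tb <- tb_true + rnorm(n, 0, noise_sd)
  tag_series(time = (seq_len(n) - 1) * step, depth = track, ta = ta, tb = tb)
}

#' Simulate a comparative heat-transfer dataset over a phylogeny
#'
#' Generates per-individual warming and cooling heat transfer coefficients
#' with the structure the comparative regression assumes: log-log allometry
#' with endothermy-specific intercepts and slopes, a Brownian phylogenetic
#' species effect, an i.i.d. species effect, and individual residual noise,
#' all on the log10 scale. Body masses are drawn log-uniformly over
#' `mass_range` (default 0.01-1600 kg, the span of published estimates).
#'
#' Random stream: `set.seed(seed)`, then (in order) masses, phylogenetic
#' effects / species effects / residuals for the warming coefficient, then the
#' same three blocks for the cooling coefficient.
#'
#' @param tree A rooted phylogeny (`phylo`) with >= 3 uniquely named tips.
#'   Branch lengths are replaced by Grafen lengths before drawing the
#'   phylogenetic effects.
#' @param endothermic Logical vector flagging endothermic species, either
#'   named by tip label or in tip order.
#' @param coef_warm,coef_cool Generating allometries per endothermy group:
#'   lists with elements `endo` and `ecto`, each `c(intercept, slope)` on the
#'   log10 scale (`log10 k = intercept + slope * log10 mass`). Defaults are
#'   the fitted lines reported for 25 fish species (e.g. warming coefficient
#'   0.11 * mass^-0.21 for endotherms).
#' @param sd_phylo,sd_species,sd_resid Standard deviations (log10 units) of
#'   the phylogenetic effect, the i.i.d. species effect and the individual
#'   residual. All must be >= 0.
#' @param individuals_per_species Number of individuals drawn per species.
#' @param mass_range Range (kg) for the log-uniform mass draw.
#' @param seed Integer seed.
#' @return A `species_k_table` data frame with columns `species`,
#'   `individual`, `mass_kg`, `k_warm`, `k_cool`, `endothermic`.
#' @export
simulate_comparative_dataset <- function(
    tree, endothermic,
    coef_warm = list(endo = c(log10(0.11), -0.21),
                     ecto = c(log10(0.16), -0.50)),
    coef_cool = list(endo = c(log10(0.11), -0.68),
                     ecto = c(log10(0.11), -0.54)),
    sd_phylo = 0.15, sd_species = 0.10, sd_resid = 0.10,
    individuals_per_species = 3, mass_range = c(0.01, 1600), seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (anyDuplicated(tips)) stop("tip-name collision in tree")
  S <- length(tips)
  if (S < 3) stop("tree must have >= 3 tips")
  if (any(c(sd_phylo, sd_species, sd_resid) < 0))
    stop("all standard deviations must be >= 0")
  if (!is.null(names(endothermic))) {
    if (!all(tips %in% names(endothermic)))
      stop("`endothermic` names must cover all tips")
    endothermic <- endothermic[tips]
  }
  stopifnot(length(endothermic) == S, is.logical(endothermic))

  A <- phylo_covariance(assign_grafen_lengths(tree))
  A <- A[tips, tips]
  L <- t(chol(A))
  m <- individuals_per_species
  n <- S * m
  sp_of <- rep(tips, each = m)
  grp <- rep(endothermic, each = m)

  set.seed(as.integer(seed))
  mass <- 10^runif(n, log10(mass_range[1]), log10(mass_range[2]))

  draw_response <- function(coefs) {
    u <- as.vector(L %*% rnorm(S)) * sd_phylo
    s <- rnorm(S, 0, sd_species)
    eps <- rnorm(n, 0, sd_resid)
    ic <- ifelse(grp, coefs$endo[1], coefs$ecto[1])
    sl <- ifelse(grp, coefs$endo[2], coefs$ecto[2])
    names(u) <- names(s) <- tips
    10^(ic + sl * log10(mass) + u[sp_of] + s[sp_of] + eps)
  }
  k_warm <- draw_response(coef_warm)
  k_cool <- draw_response(coef_cool)

  species_k_table(data.frame(
    species = sp_of,
    individual = paste(sp_of, rep(seq_len(m), times = S), sep = "_"),
    mass_kg = mass, k_warm = k_warm, k_cool = k_cool,
    endothermic = grp, stringsAsFactors = FALSE))
}
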