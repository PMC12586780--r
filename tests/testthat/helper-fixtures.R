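# Shared fixture builders. All fixtures are generated in code, seeded.

# default stratified column used throughout: 25 degC mixed layer over 14 degC
# deep water, thermocline at 100 m, 10 m logistic half-width
default_column <- function() water_column(25, 14, 100, 10)

# two-regime generating truth at the scale estimated for a mid-sized tagged
# mako (k_warm 0.052, k_cool 0.0036, tm_dot 0.0062 per min)
mako1_params <- function() {
  heat_params(k_warm = 0.052, k_cool = 0.0036, tm_dot = 0.0062)
}

# a seeded synthetic deployment: dive schedule drawn from realistic ranges,
# 22-h record at 1-min step
make_deployment <- function(seed, noise_sd = 0.1,
                            params = mako1_params(), tb0 = 24, step = 1) {
  set.seed(seed + 1000L)
  nd <- 3L
  cfg <- sim_config(duration = 1320, step = step,
                    dive_depths = round(runif(nd, 150, 250)),
                    dive_durations = round(runif(nd, 30, 90)),
                    surface_intervals = round(runif(nd, 50, 110)),
                    descent_rate = 50, noise_sd = noise_sd, seed = seed)
  track <- simulate_dive_track(cfg)
  simulate_tag_deployment(track, default_column(), params, tb0 = tb0,
                          noise_sd = noise_sd, seed = seed, step = step)
}

# a deployment rich enough for profile work: repeated dives at varied depths
# with moderate vertical rates, so the 1-min record crosses the transition
# zone often enough to occupy (nearly) every 1-m depth bin
make_profile_series <- function(seed) {
  set.seed(seed + 2000L)
  cfg <- sim_config(duration = 1320, step = 1,
                    dive_depths = runif(12, 120, 250),
                    dive_durations = runif(12, 10, 30),
                    surface_intervals = runif(12, 10, 30),
                    descent_rate = runif(1, 10, 20),
                    noise_sd = 0.1, seed = seed)
  track <- simulate_dive_track(cfg)
  simulate_tag_deployment(track, default_column(), mako1_params(),
                          tb0 = 24, noise_sd = 0.1, seed = seed)
}

# a 1-min series with a prescribed uniform depth sweep (dense bin coverage)
sweep_series <- function(depths, ta_fun, tb = NULL) {
  n <- length(depths)
  ta <- ta_fun(depths)
  if (is.null(tb)) tb <- ta + 1
  tag_series(time = seq_len(n) - 1, depth = depths, ta = ta, tb = tb)
}

# fixed 25-tip comparative tree with 5 endothermic species
make_comp_tree <- function(n_tips = 25, n_endo = 5, seed = 42) {
  set.seed(seed)
  tree <- ape::rtree(n_tips)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  endo <- setNames(rep(FALSE, n_tips), tree$tip.label)
  endo[seq_len(n_endo)] <- TRUE
  list(tree = tree, endo = endo)
}

# quick MCMC settings for cheap module tests (kept above the 100-draw floor)
quick_mcmc <- function() mcmc_settings(n_iter = 8000, burn = 1000, thin = 10)
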