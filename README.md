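# thermofin

Heat-exchange modelling and comparative thermoregulation analysis for
fishes.

Regionally endothermic fishes — tunas, billfishes, lamnid sharks — retain
metabolic heat with vascular countercurrent heat exchangers. Some of them
do more than stay warm: they *modulate* their heat-exchange rate between
dive phases, warming fast in the mixed layer and cooling slowly below the
thermocline. `thermofin` implements the full analysis chain used to
quantify this ability from animal-borne tag records and to compare it
across species:

1. **Heat-exchange model** (`fit_heat_model`, `predict_muscle_temperature`,
   `select_heat_model`): the whole-body Newtonian heat budget
   `dTb/dt = k (Ta − Tb) + Ṫm`, fitted by bounded least squares either with
   a constant heat transfer coefficient `k` or with a two-regime
   coefficient (`k_warm` while `Ta ≥ Tb`, `k_cool` while `Ta < Tb`);
   models are compared by AIC with a relative-MAE overfit guard.
2. **Segmentation** (`build_profile`, `detect_thermocline`,
   `extract_dives`): depth-binned, smoothed temperature profiles, the
   thermocline as the steepest-gradient depth, and below-thermocline dives
   longer than 10 min.
3. **Preprocessing and summaries** (`read_tag_series`,
   `trim_capture_effect`, `resample`, `thermal_summary`): capture-effect
   trimming, 1-min resampling, per-deployment thermal statistics.
4. **Comparative analysis** (`fit_phylo_mixed`, `compute_dic`,
   `rank_models`, `contrast_at_mass`): Bayesian allometric regression of
   `log10 k` on `log10 mass × endothermy` with a Brownian phylogenetic
   species effect (Grafen branch lengths) and intraspecific random
   effects, Gibbs-sampled with closed-form conditionals, ranked by DIC.
5. **Synthetic data** (`water_column`, `simulate_dive_track`,
   `simulate_tag_deployment`, `simulate_comparative_dataset`): seeded
   generators for stratified water columns, dive trajectories, tag
   deployments and comparative datasets, so every stage is testable
   end-to-end without external downloads.

## Worked example

Simulate a deployment with a two-regime truth, fit both models, and select:

```r
library(thermofin)

column <- water_column(25, 14, thermocline_depth = 100, transition_scale = 10)
cfg    <- sim_config(seed = 7)          # 22-h record, 3 dives, 1-min step
track  <- simulate_dive_track(cfg)
truth  <- heat_params(k_warm = 0.052, k_cool = 0.0036, tm_dot = 0.0062)
ser    <- simulate_tag_deployment(track, column, truth, tb0 = 24,
                                  noise_sd = 0.1, seed = 7)

detect_thermocline(build_profile(ser))
#> [1] 100

fit_heat_model(ser, kind = "variable")
#> Heat-exchange model fit (variable k, euler scheme, n = 1320)
#>   k_warm = 0.0512  k_cool = 0.003592  ratio = 14.3  tm_dot = 0.00618
#>   MAE = 0.079 degC  RSS = 13.07  AIC = -6084
```

The fitted coefficients recover the generating truth to a few percent under
0.1 °C sensor noise, and the warming:cooling ratio (14.3) is the
controllability signature: this animal warms an order of magnitude faster
than it cools. `select_heat_model()` on the constant and two-regime fits
reports `"variable model: lower AIC and 78.9% MAE improvement"`.

For the comparative stage, the published group allometries shipped with the
package evaluate to the following endotherm:ectotherm fold differences at
140 kg body mass:

```r
pub <- published_allometry()
sapply(c("k_warm", "k_cool", "ratio"), function(r)
  signif(contrast_at_mass(pub[pub$response == r, ], 140, r), 2))
#> k_warm k_cool  ratio
#>    2.9    2.0    7.4
```

## Analysis workflow

The `analysis/` directory holds the numbered pipeline over the package —
each script is a thin driver that reports what it found and writes tables
under `results/`:

| script | stage |
| --- | --- |
| `01_simulate.R` | four synthetic 28-h deployments in a stratified column |
| `02_segment.R` | trim, profile, thermocline, dive extraction, summaries |
| `03_fit_heat.R` | constant vs two-regime fits with guarded selection |
| `04_comparative.R` | 25-species synthetic dataset, Gibbs fits, DIC table |
| `05_report.R` | assembled study-style summary tables |

```sh
Rscript analysis/01_simulate.R --seed 1
Rscript analysis/02_segment.R
Rscript analysis/03_fit_heat.R
Rscript analysis/04_comparative.R --seed 1
Rscript analysis/05_report.R
```

## Vignette

`vignettes/thermoregulation-modelling.Rmd` documents the model and its
assumptions, the discretisation and optimizer choices, the segmentation
conventions, what the synthetic-data generator does and does not emulate,
the Gibbs sampler and its priors, and known limitations.
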