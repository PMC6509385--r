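# batorpor

Quantifying torpor patterns in heterothermic endotherms from
temperature-sensitive radio-telemetry, and explaining them with Bayesian
multi-model inference.

Small insectivorous bats (the motivating system is female little brown
bats, *Myotis lucifugus*, tracked at summer roosts) use torpor — reversible
metabolic suppression with a drop in body temperature — to balance the
costs of reproduction against cold, wind and rain. Skin temperature
(*T*<sub>sk</sub>) logged every 10 minutes by external transmitters proxies
body temperature, and three daily responses summarize torpor use:
**frequency** (was the bat torpid at all on a given bat day?), **duration**
(minutes below the torpor threshold per day) and **depth** (the day's
minimum *T*<sub>sk</sub>). `batorpor` is for ecophysiologists who have this
kind of telemetry and want the full analysis chain — extraction, modeling,
model ranking, averaged effect sizes — as tested, reproducible code.

## What it computes

**Extraction.** Per individual, the torpor onset threshold
*T*<sub>onset</sub> = 80th percentile of all *T*<sub>sk</sub> − 3 °C.
Telemetry is segmented into *bat days* (final roost arrival → next-night
emergence; midnight→23:50 when the bat stays in), days missing > 60 min are
excluded, and a bout is ≥ 2 consecutive readings strictly below
*T*<sub>onset</sub> (≥ 20 min).

**Models.** Fourteen a priori candidate variable sets over
{reproductive condition, individual, min *T*<sub>a</sub>, wind,
precipitation} are fitted per response — Bernoulli-logit for frequency,
Normal for duration/depth — with the hierarchical linear predictor

> η<sub>i</sub> = β₀ + β₁[j(i)] + β₃[k(i)] + Σ<sub>v</sub> β<sub>v</sub>(x<sub>v,i</sub> − x̄<sub>v</sub>),
> β₁[j] ~ N(0, σ²<sub>cond</sub>), β₃[k] ~ N(0, σ²<sub>ind</sub>)

(conditions contain individuals; individuals contain days), weakly
informative priors, and an in-house adaptive Metropolis-within-Gibbs
sampler with Gelman–Rubin convergence checks.

**Multi-model inference.** Models are ranked by DIC
(D̄ + p<sub>D</sub>, p<sub>D</sub> = D̄ − D(θ̄)); DIC weights
w<sub>i</sub> = exp(−Δ<sub>i</sub>/2)/Σ exp(−Δ<sub>j</sub>/2) form a ≥ 95%
confidence set; normalized variable weights (> 0.60 ⇒ explanatory) score
predictors; model-averaged posterior estimates carry Burnham–Anderson
unconditional SDs, 95% highest-density intervals, and odds ratios
exp(θ̂ × Δx) for the logistic response.

**Synthetic data.** A generator with known ground truth (logistic
weather-driven torpor, Newtonian cooling toward ambient during bouts,
nightly foraging absences, configurable missingness) emulates the study
design — ~35 females across five reproductive conditions, ~150 bat days —
so every stage is testable without any download.

## Worked example

Simulate a small study, extract the bat-day table, and fit the
wind + precipitation frequency model:

```r
library(batorpor)

params <- truth_params(seed = 42, season_days = 24, missing_rate = 0)
env    <- generate_environment(24, params)
cohort <- generate_cohort(c(P = 4, L = 4, NOP = 3), params)
sim    <- simulate_telemetry(cohort, env, params)
sim
#> <torpor_simulation>
#>   11 individuals, 52 bat days (46 torpid), 5563 readings

daily <- extract_torpor_metrics(sim$telemetry, sim$occupancy, quiet = TRUE)
summarize_frequency(daily, condition)
#> # A tibble: 3 × 4
#>   condition n_days n_torpid frequency
#>   <chr>      <int>    <int>     <dbl>
#> 1 L             19       15     0.789
#> 2 NOP           14       12     0.857
#> 3 P             19       15     0.789

md  <- build_model_data(daily, env$weather,
                        model_spec("frequency", c("wind", "precip")))
fit <- sample_posterior(md, n_chains = 2, n_iter = 4000, burn_in = 2000,
                        thin = 4, seed = 42)
tidy(fit)
#> # A tibble: 3 × 6
#>   term   estimate std.error  hdi_lo hdi_hi  rhat
#>   <chr>     <dbl>     <dbl>   <dbl>  <dbl> <dbl>
#> 1 beta0    1.91      0.489   0.986   2.91   1.01
#> 2 wind     0.0399    0.0536 -0.0725  0.138  1
#> 3 precip   0.486     0.305  -0.0104  1.11   1.00
```

`beta0` ≈ 1.9 is the grand-mean log-odds of daily torpor (ilogit(1.9) ≈
0.87 — these bats are torpid most days even in fair weather); the `wind`
and `precip` rows are log-odds slopes per km/hr and per mm. Translated to
odds ratios for a 0→10 unit increase:

```r
odds_ratio(tidy(fit)$estimate[3], 10)   # precipitation, 0 -> 10 mm
#> 129.0  (wide HDI at n = 52 — interval estimates matter here)
odds_ratio(0.03, 10)                     # a slope of 0.03 per km/hr
#> 1.349859
```

The full pipeline (simulate → extract → fit all 14 models × 3 responses →
rank → variable weights → averaged estimates) is one call, writing CSV
tables and a JSON run report:

```r
report <- run_torpor_pipeline(pipeline_config(seed = 1, outdir = "run1"))
```

or from a shell via the thin wrapper
`Rscript inst/scripts/torpor-pipeline.R --seed 1 --outdir run1`.

## Documentation

The methods vignette (`vignettes/torpor-analysis.Rmd`) documents the
threshold/bout/bat-day rules and their corner cases, the model and priors,
the sampler and DIC plug-in choices, the multi-model machinery, what the
synthetic generator does and does not emulate, and known limitations.
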