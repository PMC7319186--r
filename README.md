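# airmes

Simulation framework for quantifying how measurement error in **modeled
ambient particle exposures** (land-use regression, dispersion models,
satellite/machine-learning products and their hybrids) biases health effect
estimates from a **multilevel Poisson model** that estimates short-term
(daily) and long-term (period-average) effects simultaneously.

## Who this is for

Air pollution epidemiologists and exposure-assessment developers who want to
know, before running a health analysis on a modeled exposure surface: *given
how well my surface validates against monitors, how biased will my effect
estimates be, and what happens to coverage and power?*

## The model

Each exposure method is represented by four validation statistics against
the true surface, computed separately for the two exposure dimensions:
spatial/temporal correlation coefficients (α_s, α_t) and variance ratios
(γ_s, γ_t, modeled over true). The pipeline per replicate:

1. sample `n` spatial units (small-area stand-ins) over a 50 km × 50 km
   region;
2. simulate the true daily surface
   `X*_it = μ + seasonal_t + T_t + S_i + R_it`, with a shared AR(1) daily
   series, a spatial Gaussian field with exponential covariance (calibratable
   via empirical-semivariogram fitting, with instrument-error adjustment for
   monitor-derived variances), and unit-day residuals;
3. simulate counts `Y_it ~ Poisson(λ_it)`,
   `log λ_it = β0 + b_i + β_short·w_it + β_long·m_i`, where `(m_i, w_it)` is
   the within/between decomposition of `X*` and `b_i ~ N(0, σ_b²)` is a unit
   random intercept; CRFs enter as relative risks per 10 µg/m³
   (`β = log(RR)/10`);
4. degrade `X*` into the modeled surface `Z` so that the realized
   correlations and variance ratios of `Z` vs `X*` equal (α_s, α_t, γ_s, γ_t)
   exactly;
5. refit the health model on `Z` (marginal likelihood, Laplace default /
   adaptive Gauss–Hermite option) and record both coefficients, SEs, Wald
   CIs and p-values.

Replicated scenarios report **percent bias** (signed: toward the null is
negative for positive CRFs), empirical SD, mean model SE, **coverage** of the
95% CI and **power** at the 5% level. For small effects the expected estimate
is `β·α/√γ` per dimension, so low correlation with γ ≥ 1 attenuates toward
the null and high correlation with γ < 1 biases away from it.

## Worked example

```r
library(airmes)
sites  <- sample_sites(200, seed = 1)
tf     <- true_field_params(mu = 22, seas_amp = 4, rho_t = 0.8, sigma_t = 5,
                            sigma_s = 3, range_m = 8000, nugget = 0.5, sigma_r = 2)
truth  <- simulate_true_surface(sites, tf, n_days = 365, seed = 2)
op     <- outcome_params(beta0 = -0.21, sigma_b = 0.05,
                         rr_short_per10 = 1.05, rr_long_per10 = 1.10,
                         outcome = "admissions-like")
counts <- simulate_outcome(truth, op, seed = 3)

# a LUR-like method: moderate spatial skill, good temporal skill
lur <- error_params(0.55, 0.80, 1.10, 0.85, method = "LUR", pollutant = "PM10")
z   <- apply_error(truth, lur, seed = 4)
round(measure_error_stats(z, truth), 3)
#> alpha_s alpha_t gamma_s gamma_t
#>    0.55    0.80    1.10    0.85

fit_poisson_ri(counts, truth)   # analyst sees the truth
#> <ri_fit> laplace, 200 units x 365 days (converged)
#>   short-term: 0.00508459 (se 0.000604, p 3.73e-17)
#>   long-term : 0.0106641 (se 0.00133, p 9.54e-16)
#>   sigma_b: 0.04102  loglik: -95053.8627
fit_poisson_ri(counts, z)       # analyst sees the LUR surface
#> <ri_fit> laplace, 200 units x 365 days (converged)
#>   short-term: 0.00437758 (se 0.000653, p 2.01e-11)
#>   long-term : 0.00502189 (se 0.00141, p 0.000372)
#>   sigma_b: 0.05263  loglik: -95088.7616
```

The generating coefficients are `β_short = 0.004879` and `β_long = 0.009531`
per µg/m³. On this single replicate the truth fit recovers both (within
sampling error), while the LUR surface attenuates the long-term estimate to
about half — matching the small-effect prediction `α/√γ`: `0.80/√0.85 = 0.87`
for the short-term term and `0.55/√1.10 = 0.52` for the long-term term.
Replicated scenarios (`run_scenario()`) average this over hundreds of
simulations and add coverage/power; `compare_methods()` then ranks methods by
absolute percent bias.

Batch runs are driven by a YAML config (see
`inst/extdata/scenario_example.yaml`, with an error-parameters table in
`inst/extdata/error_params_example.csv` — all values illustrative), either
from R via `run_scenario(read_scenario_config(path))` or from the shell:

```sh
Rscript inst/cli/airmes.R run --config scenario.yaml --reps 200 --seed 1 --out results/
Rscript inst/cli/airmes.R validate-config scenario.yaml
Rscript inst/cli/airmes.R rank --results results/scenario_results.csv
```

`--paper-scale` switches to the full study design (1000 units, 1826 days,
1000 replicates).

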