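# Example scenario configuration (desk scale). All numeric values are
# ILLUSTRATIVE: the validation statistics and concentration-response
# functions of the original London study are not reproduced here.
#
# Paper-scale analogue: sites n = 1000, n_days = 1826 (5 years),
# n_replicates = 1000.
sites:
  "n": 200   # quoted: bare n is YAML-1.1 shorthand for false
  width: 50000
  height: 50000
n_days: 365
n_replicates: 50
seed: 20260926
engine:
  integration: laplace
  q: 9
  truncate_at_zero: false
  short_term_raw: false
  fit_truth: false
true_field:
  - pollutant: PM10
    site_type: urban/suburban
    mu: 22          # ug/m3, city-background PM10 scale
    seas_amp: 4     # annual cycle amplitude
    seas_phase: 0
    rho_t: 0.8      # day-to-day persistence of the shared series
    sigma_t: 5      # marginal SD of the shared daily series
    sigma_s: 3      # spatial partial-sill SD
    range_m: 8000   # exponential covariance range
    nugget: 0.5     # non-spatial between-unit variance
    sigma_r: 2      # site-day residual SD
    sigma_inst: 1.5 # monitor instrument-error SD (calibration only)
    cov_model: exponential
error_params:
  - {pollutant: PM10, site_type: urban/suburban, method: LUR,        alpha_s: 0.55, alpha_t: 0.80, gamma_s: 1.10, gamma_t: 0.85}
  - {pollutant: PM10, site_type: urban/suburban, method: dispersion, alpha_s: 0.60, alpha_t: 0.85, gamma_s: 0.95, gamma_t: 1.30}
  - {pollutant: PM10, site_type: urban/suburban, method: hybrid1,    alpha_s: 0.65, alpha_t: 0.85, gamma_s: 1.05, gamma_t: 1.00}
  - {pollutant: PM10, site_type: urban/suburban, method: hybrid2,    alpha_s: 0.75, alpha_t: 0.90, gamma_s: 1.00, gamma_t: 1.05}
outcomes:
  - outcome: all-cause mortality
    beta0: -3.4         # log baseline daily count per unit at zero exposure
    sigma_b: 0.1        # between-unit heterogeneity (log scale)
    rr_short_per10: 1.01
    rr_long_per10: 1.07
output:
  dir: null
  write_replicates: false
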