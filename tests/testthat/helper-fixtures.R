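# Shared fixture builders. Everything is generated in code; no stored data.

fix_true_field <- function(...) {
  args <- modifyList(list(mu = 22, seas_amp = 4, seas_phase = 0, rho_t = 0.8,
                          sigma_t = 5, sigma_s = 3, range_m = 8000,
                          nugget = 0.5, sigma_r = 2, sigma_inst = 1.5), list(...))
  do.call(true_field_params, args)
}

# small complete surface + counts for fitter tests
fix_small_instance <- function(n_sites = 50, n_days = 100, beta0 = 0.7,
                               sigma_b = 0.3, rr_short = 1.05, rr_long = 1.10,
                               seed = 42) {
  sites <- sample_sites(n_sites, seed = seed)
  truth <- simulate_true_surface(sites, fix_true_field(), n_days, seed = seed + 1)
  op <- outcome_params(beta0 = beta0, sigma_b = sigma_b,
                       rr_short_per10 = rr_short, rr_long_per10 = rr_long,
                       outcome = "test")
  counts <- simulate_outcome(truth, op, seed = seed + 2)
  list(sites = sites, truth = truth, op = op, counts = counts)
}

# minimal valid scenario config (in-R), no output dir
fix_config <- function(n_sites = 40, n_days = 60, n_reps = 3, seed = 99,
                       methods = list(
                         list(method = "good", alpha_s = 0.9, alpha_t = 0.95,
                              gamma_s = 1.0, gamma_t = 1.0),
                         list(method = "poor", alpha_s = 0.5, alpha_t = 0.7,
                              gamma_s = 1.3, gamma_t = 1.3)),
                       ...) {
  eps <- lapply(methods, function(mth) {
    c(mth, list(pollutant = "PM10", site_type = "urban/suburban"))
  })
  scenario_config(
    sites = list(n = n_sites, width = 50000, height = 50000),
    n_days = n_days, n_replicates = n_reps, seed = seed,
    true_field = list(list(pollutant = "PM10", site_type = "urban/suburban",
                           mu = 22, seas_amp = 4, rho_t = 0.8, sigma_t = 5,
                           sigma_s = 3, range_m = 8000, nugget = 0.5, sigma_r = 2)),
    error_params = eps,
    outcomes = list(list(outcome = "mortality", beta0 = 0.0, sigma_b = 0.05,
                         rr_short_per10 = 1.05, rr_long_per10 = 1.10)),
    ...
  )
}
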