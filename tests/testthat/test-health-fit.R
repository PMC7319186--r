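test_that("the analytic gradient of the Laplace objective matches central differences", {
  inst <- fix_small_instance(n_sites = 25, n_days = 40, beta0 = 0.5, sigma_b = 0.2)
  dc <- decompose_exposure(inst$truth)
  fac <- airmes:::.ri_nll_factory(inst$counts$counts, dc$spatial_means,
                                  dc$temporal_devs, "laplace", 9)
  for (th in list(c(0.4, 0.004, 0.01, log(0.15)),
                  c(0.6, -0.002, 0.005, log(0.4)),
                  c(0.5, 0, 0, log(0.05)))) {
    ga <- fac$gr(th)
    gn <- airmes:::.num_grad(fac$nll, th, c(1e-5, 1e-6, 1e-6, 1e-5))
    expect_equal(unname(ga), unname(gn), tolerance = 1e-5)
  }
})

test_that("brute-force integration is grid-converged and exact at sigma_b = 0", {
  inst <- fix_small_instance(n_sites = 5, n_days = 10, beta0 = 2, sigma_b = 0.3)
  pars <- list(beta0 = 2, beta_short = 0.004, beta_long = 0.008, sigma_b = 0.3)
  l201 <- marginal_loglik_bruteforce(inst$counts, inst$truth, pars)
  l401 <- marginal_loglik_bruteforce(inst$counts, inst$truth, pars, n_grid = 401)
  expect_lt(abs(l401 - l201), 1e-8)

  pars0 <- modifyList(pars, list(sigma_b = 0))
  dc <- decompose_exposure(inst$truth)
  eta <- pars0$beta0 + pars0$beta_long * dc$spatial_means +
    pars0$beta_short * dc$temporal_devs
  plain <- sum(inst$counts$counts * eta - exp(eta) - lfactorial(inst$counts$counts))
  expect_equal(marginal_loglik_bruteforce(inst$counts, inst$truth, pars0), plain)

  big <- fix_small_instance(n_sites = 150, n_days = 100)
  expect_error(marginal_loglik_bruteforce(big$counts, big$truth, pars), "1e4|restricted")
})

test_that("a centered covariate sign-flip mirrors the brute-force log-likelihood", {
  inst <- fix_small_instance(n_sites = 8, n_days = 20, beta0 = 1, sigma_b = 0.2)
  x <- inst$truth$values
  dc <- decompose_exposure(x)
  flipped <- dc$spatial_means - dc$temporal_devs # negate the centered short-term covariate
  pars <- list(beta0 = 1, beta_short = 0.006, beta_long = 0.004, sigma_b = 0.2)
  pars_fl <- modifyList(pars, list(beta_short = -0.006))
  expect_equal(marginal_loglik_bruteforce(inst$counts, x, pars),
               marginal_loglik_bruteforce(inst$counts, flipped, pars_fl))
})

test_that("Laplace and AGHQ agree with brute force and with each other", {
  # near-Gaussian unit integrands: moderate counts, tight random intercept
  s5 <- sample_sites(5, extent = c(20000, 20000), seed = 11)
  tf <- true_field_params(mu = 20, rho_t = 0.5, sigma_t = 3, sigma_s = 2,
                          range_m = 5000, nugget = 0.2, sigma_r = 1)
  tr5 <- simulate_true_surface(s5, tf, n_days = 10, seed = 21)
  op5 <- outcome_params(beta0 = 3, sigma_b = 0.02, rr_short_per10 = 1.05,
                        rr_long_per10 = 1.10, outcome = "test")
  y5 <- simulate_outcome(tr5, op5, seed = 31)
  pars <- list(beta0 = 3, beta_short = crf_to_beta(1.05),
               beta_long = crf_to_beta(1.10), sigma_b = 0.02)
  bf <- marginal_loglik_bruteforce(y5, tr5, pars)
  expect_lt(abs(marginal_loglik(y5, tr5, pars, method = "laplace") - bf), 1e-4)
  expect_lt(abs(marginal_loglik(y5, tr5, pars, method = "aghq", q = 25) - bf), 1e-3)

  # wider random intercept: AGHQ(25) still tracks brute force; Laplace drifts
  op5b <- outcome_params(beta0 = 1, sigma_b = 0.5, rr_short_per10 = 1.05,
                         rr_long_per10 = 1.10, outcome = "test")
  y5b <- simulate_outcome(tr5, op5b, seed = 33)
  parsb <- modifyList(pars, list(beta0 = 1, sigma_b = 0.5))
  bfb <- marginal_loglik_bruteforce(y5b, tr5, parsb, n_grid = 801, half_width = 10)
  expect_lt(abs(marginal_loglik(y5b, tr5, parsb, method = "aghq", q = 25) - bfb), 1e-3)
})

test_that("with sigma_b = 0 data the mixed fit degenerates to plain Poisson regression", {
  s <- sample_sites(100, seed = 3)
  truth <- simulate_true_surface(s, fix_true_field(), 200, seed = 9)
  op0 <- outcome_params(beta0 = 1.3, sigma_b = 0, rr_short_per10 = 1.1,
                        rr_long_per10 = 1.1, outcome = "t")
  y0 <- simulate_outcome(truth, op0, seed = 13)
  fit <- fit_poisson_ri(y0, truth)
  dc <- decompose_exposure(truth)
  dat <- data.frame(y = as.vector(y0$counts), w = as.vector(dc$temporal_devs),
                    m = rep(dc$spatial_means, times = 200))
  g <- glm(y ~ w + m, poisson, dat)
  expect_lt(abs(fit$beta_short_hat - coef(g)[["w"]]) / abs(coef(g)[["w"]]), 1e-4)
  expect_lt(abs(fit$beta_long_hat - coef(g)[["m"]]) / abs(coef(g)[["m"]]), 1e-4)
  expect_lt(fit$sigma_b_hat, 1e-3)
})

test_that("the fit agrees with lme4::glmer on the same data (independent route)", {
  inst <- fix_small_instance(n_sites = 50, n_days = 100, beta0 = 0.7, sigma_b = 0.3)
  fit <- fit_poisson_ri(inst$counts, inst$truth)
  dc <- decompose_exposure(inst$truth)
  dat <- data.frame(y = as.vector(inst$counts$counts),
                    w = as.vector(dc$temporal_devs),
                    m = rep(dc$spatial_means, times = 100),
                    id = factor(rep(seq_len(50), times = 100)))
  gm <- suppressMessages(suppressWarnings(
    lme4::glmer(y ~ w + m + (1 | id), dat, stats::poisson, nAGQ = 1)))
  fe <- lme4::fixef(gm)
  expect_equal(fit$beta_short_hat, fe[["w"]], tolerance = 1e-3)
  expect_equal(fit$beta_long_hat, fe[["m"]], tolerance = 1e-3)
  expect_equal(fit$sigma_b_hat, sqrt(unname(unlist(lme4::VarCorr(gm)))),
               tolerance = 1e-2)
  expect_equal(fit$loglik, as.numeric(stats::logLik(gm)), tolerance = 1e-3)
  expect_equal(fit$se_short, sqrt(diag(as.matrix(stats::vcov(gm))))[2], tolerance = 2e-2,
               ignore_attr = TRUE)
})

test_that("fitting the true exposure recovers the generating coefficients", {
  # parameter-recovery at small scale: mean estimate within 2 empirical SEs
  n_rep <- 30
  est <- matrix(NA_real_, n_rep, 2)
  sites <- sample_sites(60, seed = 71)
  tf <- fix_true_field()
  op <- outcome_params(beta0 = 0, sigma_b = 0.05, rr_short_per10 = 1.05,
                       rr_long_per10 = 1.10, outcome = "t")
  for (r in seq_len(n_rep)) {
    tr <- simulate_true_surface(sites, tf, 120, seed = 1000 + r)
    y <- simulate_outcome(tr, op, seed = 2000 + r)
    f <- fit_poisson_ri(y, tr)
    if (f$converged) est[r, ] <- c(f$beta_short_hat, f$beta_long_hat)
  }
  est <- est[complete.cases(est), , drop = FALSE]
  expect_gt(nrow(est), 25)
  truth <- c(crf_to_beta(1.05), crf_to_beta(1.10))
  for (j in 1:2) {
    se <- sd(est[, j]) / sqrt(nrow(est))
    expect_lt(abs(mean(est[, j]) - truth[j]), 2.5 * se + 0.02 * abs(truth[j]))
  }
})

test_that("raw short-term covariate is a reparametrization of the centered fit", {
  inst <- fix_small_instance(n_sites = 30, n_days = 60)
  f_c <- fit_poisson_ri(inst$counts, inst$truth)
  f_r <- fit_poisson_ri(inst$counts, inst$truth, short_term_raw = TRUE)
  # same short-term coefficient; long-term absorbs the difference
  expect_lt(abs(f_r$beta_short_hat - f_c$beta_short_hat), 1e-5)
  expect_lt(abs(f_r$beta_long_hat + f_r$beta_short_hat - f_c$beta_long_hat), 1e-5)
})

test_that("fit input validation rejects malformed problems", {
  inst <- fix_small_instance(n_sites = 10, n_days = 12)
  expect_error(fit_poisson_ri(inst$counts, inst$truth$values[, 1:6]), "exposure is")
  zero <- matrix(0L, 10, 12)
  expect_error(fit_poisson_ri(zero, inst$truth), "all counts are zero")
  neg <- inst$counts$counts; neg[1, 1] <- -1
  expect_error(fit_poisson_ri(neg, inst$truth), "non-negative")
})
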