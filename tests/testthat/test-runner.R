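test_that("within a replicate all methods see identical truth and outcome data", {
  sites <- sample_sites(40, seed = 61)
  tf <- fix_true_field()
  op <- outcome_params(beta0 = 0, sigma_b = 0.05, rr_short_per10 = 1.05,
                       rr_long_per10 = 1.10, outcome = "t")
  eps <- list(error_params(1, 1, 1, 1, method = "identity"),
              error_params(0.7, 0.8, 1.2, 1.1, method = "noisy"))
  rep_out <- run_replicate(sites, tf, op, eps, rep_index = 1, master_seed = 7,
                           engine = list(n_days = 60, fit_truth = TRUE))
  # the injected identity method must reproduce the direct truth fit exactly
  f_truth <- rep_out$fits[[".truth"]]
  f_ident <- rep_out$fits[["identity"]]
  expect_equal(f_ident$beta_short_hat, f_truth$beta_short_hat)
  expect_equal(f_ident$beta_long_hat, f_truth$beta_long_hat)
  expect_equal(f_ident$loglik, f_truth$loglik)

  # identical seeds -> identical results; different replicate -> different truth
  rep_again <- run_replicate(sites, tf, op, eps, rep_index = 1, master_seed = 7,
                             engine = list(n_days = 60, fit_truth = TRUE))
  expect_equal(rep_out$fits[["noisy"]]$beta_short_hat,
               rep_again$fits[["noisy"]]$beta_short_hat)
  rep2 <- run_replicate(sites, tf, op, eps, rep_index = 2, master_seed = 7,
                        engine = list(n_days = 60))
  expect_false(identical(rep_out$truth$values, rep2$truth$values))
})

test_that("run_scenario aggregates replicates consistently with an independent pass", {
  cfg <- fix_config(n_sites = 40, n_days = 60, n_reps = 4)
  out <- run_scenario(cfg, quiet = TRUE)
  expect_setequal(unique(out$results$method), c("good", "poor"))
  expect_equal(nrow(out$results), 4) # 2 methods x 2 terms
  expect_true(all(out$results$n_total == 4))

  # independent aggregation from the per-replicate table
  for (i in seq_len(nrow(out$results))) {
    row <- out$results[i, ]
    d <- out$replicates[out$replicates$method == row$method &
                          out$replicates$term == row$term &
                          out$replicates$converged, ]
    expect_equal(row$mean_beta, mean(d$estimate))
    expect_equal(row$bias, mean(d$estimate) - row$true_beta)
    expect_equal(row$pct_bias, 100 * row$bias / row$true_beta)
    expect_equal(row$emp_sd, sd(d$estimate))
    expect_equal(row$mean_se, mean(d$se))
    expect_equal(row$coverage_pct,
                 100 * mean(d$ci_lo <= row$true_beta & row$true_beta <= d$ci_hi))
    expect_equal(row$power_pct, 100 * mean(d$p < 0.05))
    expect_equal(row$n_converged, nrow(d))
  }
})

test_that("a single replicate yields the single estimate and an undefined SD", {
  cfg <- fix_config(n_sites = 30, n_days = 40, n_reps = 1,
                    methods = list(list(method = "only", alpha_s = 0.9,
                                        alpha_t = 0.9, gamma_s = 1, gamma_t = 1)))
  out <- run_scenario(cfg, quiet = TRUE)
  expect_true(all(is.na(out$results$emp_sd)))
  expect_equal(out$results$mean_beta,
               out$replicates$estimate[match(out$results$term, out$replicates$term)])
})

test_that("identical configurations produce byte-identical result files", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg1 <- fix_config(n_sites = 25, n_days = 40, n_reps = 2,
                     output = list(dir = dir1, write_replicates = TRUE))
  cfg2 <- fix_config(n_sites = 25, n_days = 40, n_reps = 2,
                     output = list(dir = dir2, write_replicates = TRUE))
  run_scenario(cfg1, quiet = TRUE)
  run_scenario(cfg2, quiet = TRUE)
  for (f in c("scenario_results.csv", "replicates.csv")) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
  }
})

test_that("compare_methods ranks by absolute percent bias with documented tie-breaks", {
  base <- data.frame(pollutant = "PM10", outcome = "mort", site_type = "urban",
                     term = "long", stringsAsFactors = FALSE)
  res <- rbind(cbind(base, method = "A", pct_bias = -60, mean_se = 0.001),
               cbind(base, method = "B", pct_bias = -21, mean_se = 0.001),
               cbind(base, method = "C", pct_bias = 10, mean_se = 0.002))
  r <- compare_methods(res)
  expect_equal(r$method[r$rank == 1], "C")
  expect_equal(r$method[r$rank == 2], "B")
  expect_equal(r$method[r$rank == 3], "A")

  # |bias| tie: broken by mean SE, then label
  res2 <- rbind(cbind(base, method = "A", pct_bias = 10, mean_se = 0.002),
                cbind(base, method = "B", pct_bias = -10, mean_se = 0.001),
                cbind(base, method = "C", pct_bias = 10, mean_se = 0.002))
  r2 <- compare_methods(res2)
  expect_equal(r2$method, c("B", "A", "C"))

  single <- cbind(base, method = "solo", pct_bias = -3, mean_se = 0.1)
  expect_equal(compare_methods(single)$rank, 1L)
})

test_that("errors in one method are recorded per replicate without aborting the batch", {
  sites <- sample_sites(20, seed = 63)
  # constant-mean truth: spatial variance ~ 0 handled upstream, so force an
  # error via a degenerate error model on a valid truth instead
  tf <- fix_true_field(sigma_s = 0, nugget = 0, sigma_r = 0) # no spatial variation
  op <- outcome_params(beta0 = 0.5, sigma_b = 0.05, rr_short_per10 = 1.05,
                       rr_long_per10 = 1.10, outcome = "t")
  eps <- list(error_params(0.9, 0.9, 1, 1, method = "needs_spatial_var"))
  rep_out <- run_replicate(sites, tf, op, eps, 1, 17, engine = list(n_days = 30))
  expect_s3_class(rep_out$fits[["needs_spatial_var"]], "error")
  rows <- airmes:::.fit_to_rows(rep_out$fits[["needs_spatial_var"]],
                                data.frame(pollutant = "p", outcome = "o",
                                           method = "needs_spatial_var",
                                           site_type = "s", replicate = 1L),
                                0.005, 0.01)
  expect_false(any(rows$converged))
  expect_match(rows$error[1], "alpha_s")
})
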