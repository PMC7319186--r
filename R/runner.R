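# Scenario orchestration: pollutant x site-type x outcome x method cells,
# replicated simulations, and the bias / coverage / power summaries.

#' Run one simulation replicate for a scenario cell
#'
#' Composes the pipeline end-to-end for one replicate: simulate the true
#' surface, simulate counts from it, then for each exposure method create the
#' error-laden exposure Z and refit the multilevel Poisson model. Truth and
#' outcome are shared across methods within the replicate, so methods are
#' compared on identical data. All seeds derive deterministically from
#' `(master_seed, cell_index, rep_index)`, making results independent of
#' execution order.
#'
#' @param sites a `site_set`.
#' @param tf a `true_field_params`.
#' @param op an `outcome_params`.
#' @param error_list list of `error_params`, one per exposure method.
#' @param rep_index replicate number (1-based).
#' @param master_seed scenario master seed.
#' @param cell_index index of the scenario cell (default 1), folded into the
#'   seed stream so different cells see different data.
#' @param engine list of engine options: `integration` ("laplace"/"aghq"),
#'   `q`, `short_term_raw`, `fit_truth` (also fit the error-free truth,
#'   reported as method `".truth"`).
#' @return list with `fits` (named list of `ri_fit` or condition objects per
#'   method), `truth`, `outcome`, and the seeds used.
#' @export
run_replicate <- function(sites, tf, op, error_list, rep_index, master_seed,
                          cell_index = 1L, engine = list()) {
  eng <- modifyList(list(integration = "laplace", q = 9L,
                         short_term_raw = FALSE, fit_truth = FALSE, n_days = 365L),
                    engine)
  truth_seed <- derive_seed(master_seed, cell_index, rep_index, 1)
  outcome_seed <- derive_seed(master_seed, cell_index, rep_index, 2)
  truth <- simulate_true_surface(sites, tf, n_days = eng$n_days, seed = truth_seed)
  outcome <- simulate_outcome(truth, op, seed = outcome_seed)

  fit_one <- function(expo) {
    tryCatch(
      fit_poisson_ri(outcome, expo, method = eng$integration, q = eng$q,
                     short_term_raw = eng$short_term_raw),
      error = function(e) e
    )
  }

  fits <- list()
  if (isTRUE(eng$fit_truth)) fits[[".truth"]] <- fit_one(truth)
  for (k in seq_along(error_list)) {
    ep <- error_list[[k]]
    z <- tryCatch(
      apply_error(truth, ep, seed = derive_seed(master_seed, cell_index, rep_index, 3, k)),
      error = function(e) e
    )
    fits[[ep$method]] <- if (inherits(z, "error")) z else fit_one(z)
  }
  list(fits = fits, truth = truth, outcome = outcome,
       seeds = c(truth = truth_seed, outcome = outcome_seed))
}

.fit_to_rows <- function(fit, meta, true_bs, true_bl) {
  if (inherits(fit, "error")) {
    return(cbind(meta, data.frame(
      term = c("short", "long"), true_beta = c(true_bs, true_bl),
      estimate = NA_real_, se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
      p = NA_real_, converged = FALSE, error = conditionMessage(fit),
      stringsAsFactors = FALSE)))
  }
  cbind(meta, data.frame(
    term = c("short", "long"),
    true_beta = c(true_bs, true_bl),
    estimate = c(fit$beta_short_hat, fit$beta_long_hat),
    se = c(fit$se_short, fit$se_long),
    ci_lo = c(fit$ci95_short[1], fit$ci95_long[1]),
    ci_hi = c(fit$ci95_short[2], fit$ci95_long[2]),
    p = c(fit$p_short, fit$p_long),
    converged = fit$converged,
    error = "",
    stringsAsFactors = FALSE))
}

#' Aggregate per-replicate fits into scenario summaries
#'
#' Computes, per scenario cell and term, the evaluation metrics: mean
#' estimate, bias (mean estimate − true), percent bias (100·bias/true,
#' signed, so attenuation toward the null is negative for positive CRFs),
#' empirical SD of the estimates, mean model SE, coverage (% of replicates
#' whose 95% CI contains the true coefficient) and power (% of replicates
#' with two-sided p < 0.05). Non-converged replicates are excluded from the
#' metrics and accounted for in `n_converged`; cells with zero converged
#' replicates get `NA` metrics and a loud warning.
#'
#' @param replicates data frame of per-replicate rows (as produced by
#'   [run_scenario()], columns `pollutant,outcome,method,site_type,replicate,
#'   term,true_beta,estimate,se,ci_lo,ci_hi,p,converged`).
#' @return `scenario_results` data frame, one row per cell x term.
#' @export
summarize_replicates <- function(replicates) {
  key <- c("pollutant", "outcome", "method", "site_type", "term")
  split_idx <- split(seq_len(nrow(replicates)),
                     replicates[key], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split_idx, function(idx) {
    d <- replicates[idx, , drop = FALSE]
    ok <- d[d$converged %in% TRUE & is.finite(d$estimate), , drop = FALSE]
    n_total <- nrow(d)
    n_conv <- nrow(ok)
    true_beta <- d$true_beta[1]
    out <- d[1, key, drop = FALSE]
    if (n_conv == 0) {
      warning(sprintf("scenario cell %s has zero converged replicates; metrics are NA",
                      paste(unlist(out), collapse = "/")), call. = FALSE)
      metr <- data.frame(true_beta = true_beta, mean_beta = NA_real_,
                         bias = NA_real_, pct_bias = NA_real_, emp_sd = NA_real_,
                         mean_se = NA_real_, coverage_pct = NA_real_,
                         power_pct = NA_real_)
    } else {
      mean_beta <- mean(ok$estimate)
      bias <- mean_beta - true_beta
      metr <- data.frame(
        true_beta = true_beta,
        mean_beta = mean_beta,
        bias = bias,
        pct_bias = if (true_beta != 0) 100 * bias / true_beta else NA_real_,
        emp_sd = if (n_conv >= 2) sd(ok$estimate) else NA_real_,
        mean_se = mean(ok$se),
        coverage_pct = 100 * mean(ok$ci_lo <= true_beta & true_beta <= ok$ci_hi),
        power_pct = 100 * mean(ok$p < 0.05))
    }
    cbind(out, metr, data.frame(n_total = n_total, n_converged = n_conv))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Run a full scenario configuration
#'
#' Iterates over scenario cells (pollutant x site type from `true_field`
#' entries, crossed with outcomes and exposure methods), runs
#' `n_replicates` replicates per cell via [run_replicate()], and aggregates
#' with [summarize_replicates()]. When `config$output$dir` is set, writes
#' `scenario_results.csv` (long format), optionally `replicates.csv`, and a
#' run log with the master seed. Identical configurations (including the
#' seed) produce byte-identical CSVs.
#'
#' @param config a `scenario_config` (see [scenario_config()] /
#'   [read_scenario_config()]).
#' @param quiet suppress progress messages (default TRUE when
#'   non-interactive).
#' @return list with `results` (scenario summaries), `replicates`
#'   (per-replicate long table), `sites`, `config`.
#' @export
run_scenario <- function(config, quiet = !interactive()) {
  config <- validate_scenario_config(config)
  sites <- if (!is.null(config$sites$file)) {
    load_sites(config$sites$file)
  } else {
    sample_sites(config$sites$n, c(config$sites$width, config$sites$height),
                 seed = derive_seed(config$seed, 0))
  }
  eng <- config$engine
  eng$n_days <- config$n_days

  all_rows <- list()
  cell_idx <- 0L
  for (tf_entry in config$true_field) {
    tf <- tf_entry$params
    eps <- Filter(function(ep) ep$pollutant == tf_entry$pollutant &&
                    ep$site_type == tf_entry$site_type, config$error_params)
    for (op in config$outcomes) {
      cell_idx <- cell_idx + 1L
      if (!quiet) {
        message(sprintf("cell %d: %s / %s / %s (%d methods x %d replicates)",
                        cell_idx, tf_entry$pollutant, tf_entry$site_type,
                        op$outcome, length(eps), config$n_replicates))
      }
      true_bs <- crf_to_beta(op$rr_short_per10)
      true_bl <- crf_to_beta(op$rr_long_per10)
      for (r in seq_len(config$n_replicates)) {
        rep_out <- run_replicate(sites, tf, op, eps, r, config$seed,
                                 cell_index = cell_idx, engine = eng)
        for (meth in names(rep_out$fits)) {
          meta <- data.frame(pollutant = tf_entry$pollutant,
                             outcome = op$outcome, method = meth,
                             site_type = tf_entry$site_type, replicate = r,
                             stringsAsFactors = FALSE)
          all_rows[[length(all_rows) + 1L]] <-
            .fit_to_rows(rep_out$fits[[meth]], meta, true_bs, true_bl)
        }
      }
    }
  }
  replicates <- do.call(rbind, all_rows)
  rownames(replicates) <- NULL
  results <- summarize_replicates(replicates)

  if (!is.null(config$output$dir)) {
    dir.create(config$output$dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(results, file.path(config$output$dir, "scenario_results.csv"),
              row.names = FALSE)
    if (isTRUE(config$output$write_replicates)) {
      write.csv(replicates, file.path(config$output$dir, "replicates.csv"),
                row.names = FALSE)
    }
    writeLines(c(
      sprintf("airmes %s", as.character(utils::packageVersion("airmes"))),
      sprintf("seed: %d", config$seed),
      sprintf("n_replicates: %d", config$n_replicates),
      sprintf("n_days: %d", config$n_days),
      sprintf("cells: %d", cell_idx)
    ), file.path(config$output$dir, "run_log.txt"))
  }
  list(results = results, replicates = replicates, sites = sites, config = config)
}

#' Rank exposure methods within each scenario cell
#'
#' Orders methods per (pollutant, outcome, site type, term) by absolute
#' percent bias (best first); ties are broken by mean model SE, then by
#' method label.
#'
#' @param results a `scenario_results` data frame from [run_scenario()] or
#'   [summarize_replicates()].
#' @return the same rows with a `rank` column, ordered within each cell.
#' @export
compare_methods <- function(results) {
  need <- c("pollutant", "outcome", "site_type", "term", "method",
            "pct_bias", "mean_se")
  miss <- setdiff(need, names(results))
  if (length(miss) > 0) stop_airmes("results is missing column(s): %s",
                                    paste(miss, collapse = ", "))
  key <- c("pollutant", "outcome", "site_type", "term")
  split_idx <- split(seq_len(nrow(results)), results[key], drop = TRUE,
                     lex.order = TRUE)
  out <- lapply(split_idx, function(idx) {
    d <- results[idx, , drop = FALSE]
    ord <- order(abs(d$pct_bias), d$mean_se, d$method)
    d <- d[ord, , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
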