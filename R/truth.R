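#' Parameters of the "true" exposure surface
#'
#' Defines the generative model for the error-free daily concentration
#' surface X*:
#' \deqn{X^*_{it} = \mu + A \sin(2\pi \cdot doy_t / 365.25 + \phi) + T_t + S_i + R_{it}}
#' where `T_t` is a stationary AR(1) city-wide daily series with lag-1
#' correlation `rho_t` and marginal SD `sigma_t`; `S = (S_1..S_n)` is one
#' multivariate-normal draw with covariance
#' `sigma_s^2 * exp(-d_ij / range_m) + nugget * 1[i == j]` (exponential
#' spatial covariance in the distance matrix of the given site ordering);
#' and `R_it` are iid site-day residuals with SD `sigma_r`.
#'
#' @param mu overall mean concentration (µg/m³).
#' @param seas_amp amplitude of the annual sinusoid (µg/m³).
#' @param seas_phase phase of the annual sinusoid (radians).
#' @param rho_t lag-1 autocorrelation of the shared daily series, |rho_t| < 1.
#' @param sigma_t marginal SD of the shared daily series (µg/m³).
#' @param sigma_s spatial partial-sill SD (µg/m³).
#' @param range_m exponential-covariance range parameter (m), > 0.
#' @param nugget non-spatial between-unit variance ((µg/m³)²), >= 0.
#' @param sigma_r site-day residual SD (µg/m³).
#' @param sigma_inst instrument-error SD of monitor measurements (µg/m³);
#'   used by [adjust_for_instrument_error()] when calibrating parameters from
#'   monitor-like data, never at simulation time (X* is error-free truth by
#'   construction).
#' @param cov_model spatial covariance family, `"exponential"` (default) or
#'   `"spherical"`.
#' @param truncate_at_zero clip negative simulated concentrations to 0?
#'   Default `FALSE`: the health model is log-linear in concentration, and
#'   truncation distorts the moment contracts the error model relies on.
#'   When `TRUE` the number of clipped cells is recorded as an attribute.
#' @return a validated `true_field_params` list.
#' @export
true_field_params <- function(mu = 20, seas_amp = 0, seas_phase = 0,
                              rho_t = 0, sigma_t = 0,
                              sigma_s = 0, range_m = 1, nugget = 0,
                              sigma_r = 0, sigma_inst = 0,
                              cov_model = c("exponential", "spherical"),
                              truncate_at_zero = FALSE) {
  cov_model <- match.arg(cov_model)
  p <- list(mu = mu, seas_amp = seas_amp, seas_phase = seas_phase,
            rho_t = rho_t, sigma_t = sigma_t, sigma_s = sigma_s,
            range_m = range_m, nugget = nugget, sigma_r = sigma_r,
            sigma_inst = sigma_inst, cov_model = cov_model,
            truncate_at_zero = isTRUE(truncate_at_zero))
  num <- p[c("mu", "seas_amp", "seas_phase", "rho_t", "sigma_t", "sigma_s",
             "range_m", "nugget", "sigma_r", "sigma_inst")]
  if (any(!vapply(num, function(v) length(v) == 1 && is.finite(v), logical(1)))) {
    stop_airmes("all true-field parameters must be single finite numbers")
  }
  if (abs(p$rho_t) >= 1) stop_airmes("|rho_t| must be < 1, got %g", p$rho_t)
  for (nm in c("sigma_t", "sigma_s", "sigma_r", "sigma_inst", "nugget", "seas_amp")) {
    if (p[[nm]] < 0) stop_airmes("%s must be >= 0, got %g", nm, p[[nm]])
  }
  if (p$range_m <= 0) stop_airmes("range_m must be > 0, got %g", p$range_m)
  structure(p, class = "true_field_params")
}

spatial_cov_matrix <- function(d, sigma_s, range_m, nugget, cov_model = "exponential") {
  cov <- if (cov_model == "spherical") {
    h <- pmin(d / range_m, 1)
    sigma_s^2 * (1 - 1.5 * h + 0.5 * h^3)
  } else {
    sigma_s^2 * exp(-d / range_m)
  }
  cov + diag(nugget, nrow(d))
}

# One zero-mean draw from N(0, Sigma) via Cholesky; a single small ridge is
# tried before giving up so that near-singular but valid covariances pass.
draw_mvn <- function(sigma_mat) {
  n <- nrow(sigma_mat)
  ch <- tryCatch(chol(sigma_mat), error = function(e) NULL)
  if (is.null(ch)) {
    ridge <- 1e-8 * mean(diag(sigma_mat))
    ch <- tryCatch(chol(sigma_mat + diag(ridge, n)), error = function(e) NULL)
    if (is.null(ch)) {
      stop_airmes(paste0(
        "spatial covariance matrix is not positive definite even after a ",
        "ridge of %g; check sigma_s/range_m/nugget and site coordinates"), ridge)
    }
  }
  drop(crossprod(ch, rnorm(n)))
}

#' Simulate the true daily concentration surface X*
#'
#' Draws one realization of the true surface over `sites` for `n_days` days
#' under [true_field_params()]. Component streams (AR(1) series, spatial
#' draw, site-day residuals) use substream seeds derived from `seed` by fixed
#' offsets, so each component is independently reproducible. The spatial
#' vector is drawn against the distance matrix of the given site ordering:
#' permuting the rows of `sites` changes the realization (only the
#' distribution, not the draw, is exchangeable).
#'
#' @param sites a `site_set`.
#' @param params a `true_field_params`.
#' @param n_days number of days T >= 2.
#' @param seed integer master seed for this realization.
#' @param start_doy day-of-year of day 1 (default 1).
#' @return a `true_surface`: list with `values` (n_units x n_days matrix,
#'   µg/m³), `calendar` (day index and day-of-year), `sites`, `params`,
#'   `seed`.
#' @export
simulate_true_surface <- function(sites, params, n_days, seed = 1L, start_doy = 1L) {
  validate_site_set(sites)
  if (!inherits(params, "true_field_params")) params <- do.call(true_field_params, params)
  if (length(n_days) != 1 || !is.finite(n_days) || n_days < 2) {
    stop_airmes("n_days must be >= 2, got %s", paste(n_days, collapse = ","))
  }
  n_days <- as.integer(n_days)
  n <- nrow(sites)
  doy <- (start_doy - 1 + seq_len(n_days) - 1) %% 365.25
  seasonal <- params$seas_amp * sin(2 * pi * doy / 365.25 + params$seas_phase)

  # city-wide AR(1) daily series, stationary initialization
  tt <- numeric(n_days)
  if (params$sigma_t > 0) {
    set.seed(derive_seed(seed, 1))
    e <- rnorm(n_days)
    tt[1] <- params$sigma_t * e[1]
    innov_sd <- params$sigma_t * sqrt(1 - params$rho_t^2)
    for (t in 2:n_days) tt[t] <- params$rho_t * tt[t - 1] + innov_sd * e[t]
  }

  # one spatially correlated between-unit draw
  s_vec <- numeric(n)
  if (params$sigma_s > 0 || params$nugget > 0) {
    d <- site_distances(sites)
    sig <- spatial_cov_matrix(d, params$sigma_s, params$range_m, params$nugget,
                              params$cov_model)
    set.seed(derive_seed(seed, 2))
    s_vec <- draw_mvn(sig)
  }

  vals <- params$mu +
    matrix(seasonal + tt, n, n_days, byrow = TRUE) +
    s_vec
  if (params$sigma_r > 0) {
    set.seed(derive_seed(seed, 3))
    vals <- vals + matrix(rnorm(n * n_days, 0, params$sigma_r), n, n_days)
  }

  n_trunc <- 0L
  if (params$truncate_at_zero) {
    n_trunc <- sum(vals < 0)
    vals[vals < 0] <- 0
  }
  rownames(vals) <- sites$unit_id

  structure(list(
    values = vals,
    calendar = data.frame(day = seq_len(n_days), doy = doy),
    sites = sites,
    params = params,
    seed = seed,
    n_truncated = n_trunc
  ), class = "true_surface")
}

#' @export
print.true_surface <- function(x, ...) {
  cat(sprintf("<true_surface> %d units x %d days, mu=%g\n",
              nrow(x$values), ncol(x$values), x$params$mu))
  invisible(x)
}

#' Correct an observed temporal variance for instrument error
#'
#' Monitor measurements carry instrument error; when calibrating the true
#' surface's temporal variance from monitor-like data, the instrument
#' variance is subtracted: `corrected = max(observed - sigma_inst^2, 0)`.
#' A warning is emitted when the subtraction is clipped at zero.
#'
#' @param observed_temporal_var observed variance ((µg/m³)²), >= 0.
#' @param sigma_inst instrument-error SD (µg/m³), >= 0.
#' @return corrected variance ((µg/m³)²).
#' @examples
#' adjust_for_instrument_error(25, 3) # 16
#' @export
adjust_for_instrument_error <- function(observed_temporal_var, sigma_inst) {
  if (observed_temporal_var < 0) stop_airmes("observed_temporal_var must be >= 0")
  if (sigma_inst < 0) stop_airmes("sigma_inst must be >= 0")
  out <- observed_temporal_var - sigma_inst^2
  if (out < 0) {
    warning(sprintf(
      "instrument variance (%g) exceeds observed variance (%g); corrected variance clipped to 0",
      sigma_inst^2, observed_temporal_var), call. = FALSE)
    out <- 0
  }
  out
}

# Exported surface values for any of the package's exposure containers.
exposure_values <- function(x) {
  if (inherits(x, "true_surface") || inherits(x, "modeled_exposure")) return(x$values)
  if (inherits(x, "health_series")) return(x$counts)
  if (is.matrix(x)) return(x)
  stop_airmes("cannot extract an exposure matrix from an object of class %s",
              paste(class(x), collapse = "/"))
}

#' Export a surface to long format
#'
#' @param surface a `true_surface`, `modeled_exposure`, or matrix.
#' @return data frame `unit_id, day, value`.
#' @export
surface_to_long <- function(surface) {
  v <- exposure_values(surface)
  ids <- rownames(v) %||% sprintf("U%05d", seq_len(nrow(v)))
  data.frame(
    unit_id = rep(ids, times = ncol(v)),
    day = rep(seq_len(ncol(v)), each = nrow(v)),
    value = as.vector(v),
    stringsAsFactors = FALSE
  )
}
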