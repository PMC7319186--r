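#' Error parameters of one exposure-assessment method
#'
#' Each exposure method (LUR, dispersion, hybrid/ML combinations) enters the
#' simulation only through four validation statistics relating its modeled
#' concentrations to the truth: the spatial correlation `alpha_s` (between
#' modeled and true period-average concentrations across units), the temporal
#' correlation `alpha_t` (between modeled and true daily deviations from unit
#' means), and the corresponding variance ratios `gamma_s`, `gamma_t`
#' (modeled over true). Differential error by monitoring-site type is purely
#' parametric: scenarios carry distinct quadruples per site type.
#'
#' @param alpha_s spatial correlation, in `[-1, 1]`.
#' @param alpha_t temporal correlation, in `[-1, 1]`.
#' @param gamma_s spatial variance ratio (modeled / true), > 0.
#' @param gamma_t temporal variance ratio (modeled / true), > 0.
#' @param method method label (e.g. `"LUR"`, `"dispersion"`, `"hybrid2"`).
#' @param site_type label (e.g. `"urban/suburban"`, `"roadside/kerbside"`).
#' @param pollutant label (e.g. `"PM10"`, `"PM2.5"`).
#' @return a validated `error_params` list.
#' @export
error_params <- function(alpha_s, alpha_t, gamma_s, gamma_t,
                         method = "method", site_type = "", pollutant = "") {
  for (nm in c("alpha_s", "alpha_t", "gamma_s", "gamma_t")) {
    v <- get(nm)
    if (length(v) != 1 || !is.finite(v)) stop_airmes("%s must be a single finite number", nm)
  }
  if (abs(alpha_s) > 1) stop_airmes("|alpha_s| must be <= 1, got %g", alpha_s)
  if (abs(alpha_t) > 1) stop_airmes("|alpha_t| must be <= 1, got %g", alpha_t)
  if (gamma_s <= 0) stop_airmes("gamma_s must be > 0, got %g", gamma_s)
  if (gamma_t <= 0) stop_airmes("gamma_t must be > 0, got %g", gamma_t)
  structure(list(alpha_s = alpha_s, alpha_t = alpha_t,
                 gamma_s = gamma_s, gamma_t = gamma_t,
                 method = as.character(method), site_type = as.character(site_type),
                 pollutant = as.character(pollutant)),
            class = "error_params")
}

#' Within/between decomposition of an exposure matrix
#'
#' Splits a units x days matrix into the per-unit period mean (the spatial,
#' long-term component) and the per-unit-day deviation from that mean (the
#' temporal, short-term component). Reconstruction is exact:
#' `spatial_means[i] + temporal_devs[i, t] == X[i, t]`.
#'
#' @param surface exposure matrix, `true_surface`, or `modeled_exposure`.
#' @return list with `spatial_means` (length n_units) and `temporal_devs`
#'   (n_units x n_days).
#' @export
decompose_exposure <- function(surface) {
  x <- exposure_values(surface)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop_airmes("decomposition needs >= 2 units and >= 2 days, got %d x %d",
                nrow(x), ncol(x))
  }
  m <- rowMeans(x)
  list(spatial_means = m, temporal_devs = x - m)
}

# Draw a noise vector/matrix that is exactly orthogonal (in sample) to `ref`,
# has exactly zero mean (per row for matrices, so within-unit means stay 0),
# and exactly unit sample variance. Used so that the modeled exposure's
# sample correlation and variance ratio against the truth equal the target
# parameters exactly, not just in expectation.
.orthonormal_noise <- function(ref) {
  if (is.matrix(ref)) {
    v <- matrix(rnorm(length(ref)), nrow(ref), ncol(ref))
    v <- v - rowMeans(v)
    v <- v - (sum(v * ref) / sum(ref * ref)) * ref
    s <- sd(as.vector(v))
    if (!is.finite(s) || s == 0) {
      stop_airmes("degenerate noise draw; surface too small for an inexact error model")
    }
    v / s
  } else {
    if (length(ref) < 3) {
      stop_airmes("need >= 3 units for an exposure method with |alpha_s| < 1")
    }
    u <- rnorm(length(ref))
    u <- u - mean(u)
    u <- u - (sum(u * ref) / sum(ref * ref)) * ref
    s <- sd(u)
    if (!is.finite(s) || s == 0) {
      stop_airmes("degenerate spatial noise draw; increase the number of units")
    }
    u / s
  }
}

#' Create a modeled exposure from the truth under an error model
#'
#' Transforms the true surface X* into a "modeled" exposure Z whose spatial
#' and temporal components have the specified correlations with, and variance
#' ratios against, the corresponding components of X*. With
#' `(m_i, w_it) = decompose_exposure(truth)`, `m̄ = mean(m)`,
#' `V_s = var(m)`, `V_t = var(vec(w))`:
#' \deqn{z_i = \bar m + \alpha_s \sqrt{\gamma_s} (m_i - \bar m) +
#'       \sqrt{\gamma_s V_s (1 - \alpha_s^2)}\, \tilde u_i}
#' \deqn{\zeta_{it} = \alpha_t \sqrt{\gamma_t}\, w_{it} +
#'       \sqrt{\gamma_t V_t (1 - \alpha_t^2)}\, \tilde v_{it}}
#' \deqn{Z_{it} = z_i + \zeta_{it}}
#' where the Gaussian noise draws are orthogonalized against the true
#' component, centered (within unit for the temporal part, so
#' `decompose_exposure(Z)` returns exactly `(z, ζ)`), and standardized. The
#' sample correlation of `(z, m)` is therefore exactly `alpha_s` and the
#' sample variance ratio exactly `gamma_s` (likewise `(ζ, w)` for the
#' temporal pair); the error never alters X* itself. Noise is independent
#' across units and days (no spatially structured model error).
#'
#' The identity quadruple `alpha_s = alpha_t = gamma_s = gamma_t = 1` returns
#' `Z` identical to X*.
#'
#' @param truth a `true_surface` (or exposure matrix) with >= 2 units, days.
#' @param ep an [error_params()].
#' @param seed integer seed; the construction is deterministic given it.
#' @return a `modeled_exposure`: list with `values` (n_units x n_days),
#'   `error_params`, `seed`.
#' @export
apply_error <- function(truth, ep, seed = 1L) {
  if (!inherits(ep, "error_params")) ep <- do.call(error_params, ep)
  dc <- decompose_exposure(truth)
  m <- dc$spatial_means
  w <- dc$temporal_devs
  n <- length(m)

  set.seed(derive_seed(seed, 1))

  spatial_identity <- ep$alpha_s == 1 && ep$gamma_s == 1
  temporal_identity <- ep$alpha_t == 1 && ep$gamma_t == 1

  # spatial (between-unit) component; reproduced exactly at (alpha, gamma) = (1, 1)
  mbar <- mean(m)
  d <- m - mbar
  v_s <- var(m)
  a_s <- ep$alpha_s * sqrt(ep$gamma_s)
  noise_sd_s <- sqrt(ep$gamma_s * v_s * (1 - ep$alpha_s^2))
  if (noise_sd_s > 0) {
    if (v_s <= 0) {
      stop_airmes("spatial variance of the truth is 0; correlation alpha_s = %g is undefined",
                  ep$alpha_s)
    }
    z <- mbar + a_s * d + noise_sd_s * .orthonormal_noise(d)
  } else {
    if (v_s <= 0 && abs(ep$alpha_s) < 1) {
      stop_airmes("spatial variance of the truth is 0; correlation alpha_s = %g is undefined",
                  ep$alpha_s)
    }
    z <- if (spatial_identity) m else mbar + a_s * d
  }

  # temporal (within-unit) component
  v_t <- var(as.vector(w))
  a_t <- ep$alpha_t * sqrt(ep$gamma_t)
  noise_sd_t <- sqrt(ep$gamma_t * v_t * (1 - ep$alpha_t^2))
  if (noise_sd_t > 0) {
    if (v_t <= 0) {
      stop_airmes("temporal variance of the truth is 0; correlation alpha_t = %g is undefined",
                  ep$alpha_t)
    }
    zeta <- a_t * w + noise_sd_t * .orthonormal_noise(w)
  } else {
    if (v_t <= 0 && abs(ep$alpha_t) < 1) {
      stop_airmes("temporal variance of the truth is 0; correlation alpha_t = %g is undefined",
                  ep$alpha_t)
    }
    zeta <- a_t * w
  }

  vals <- if (spatial_identity && temporal_identity) {
    exposure_values(truth) # identity quadruple: Z is X* bit-for-bit
  } else {
    zeta + z
  }
  rownames(vals) <- rownames(exposure_values(truth))
  structure(list(values = vals, error_params = ep, seed = seed),
            class = "modeled_exposure")
}

#' @export
print.modeled_exposure <- function(x, ...) {
  ep <- x$error_params
  cat(sprintf(
    "<modeled_exposure> %d units x %d days | %s %s %s | alpha_s=%g alpha_t=%g gamma_s=%g gamma_t=%g\n",
    nrow(x$values), ncol(x$values), ep$pollutant, ep$method, ep$site_type,
    ep$alpha_s, ep$alpha_t, ep$gamma_s, ep$gamma_t))
  invisible(x)
}

#' Measure empirical error statistics of a modeled exposure against the truth
#'
#' Computes the realized spatial/temporal correlations and variance ratios of
#' `Z` against `X*` using the same within/between decomposition as
#' [apply_error()]. Useful for checking the moment contract.
#'
#' @param modeled a `modeled_exposure` (or matrix).
#' @param truth the `true_surface` (or matrix) it was derived from.
#' @return named numeric vector `alpha_s, alpha_t, gamma_s, gamma_t`.
#' @export
measure_error_stats <- function(modeled, truth) {
  dz <- decompose_exposure(modeled)
  dx <- decompose_exposure(truth)
  c(alpha_s = cor(dz$spatial_means, dx$spatial_means),
    alpha_t = cor(as.vector(dz$temporal_devs), as.vector(dx$temporal_devs)),
    gamma_s = var(dz$spatial_means) / var(dx$spatial_means),
    gamma_t = var(as.vector(dz$temporal_devs)) / var(as.vector(dx$temporal_devs)))
}

#' Read an error-parameters table (machine-readable validation statistics)
#'
#' CSV with header `pollutant,method,site_type,alpha_s,alpha_t,gamma_s,gamma_t`,
#' one row per exposure method x site type x pollutant.
#'
#' @param path path to the CSV.
#' @return list of [error_params()] objects.
#' @export
load_error_params <- function(path) {
  if (!file.exists(path)) stop_airmes("error-parameters file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("pollutant", "method", "site_type", "alpha_s", "alpha_t", "gamma_s", "gamma_t")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_airmes("error-parameters file %s is missing column(s): %s",
                path, paste(miss, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    error_params(df$alpha_s[i], df$alpha_t[i], df$gamma_s[i], df$gamma_t[i],
                 method = df$method[i], site_type = df$site_type[i],
                 pollutant = df$pollutant[i])
  })
}
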