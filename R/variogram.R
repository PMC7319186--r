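#' Empirical semivariogram of a spatial variable
#'
#' Classical (Matheron) semivariance per distance bin:
#' \deqn{\hat\gamma(h) = \frac{1}{2|N(h)|} \sum_{(i,j) \in N(h)} (v_i - v_j)^2}
#' with equal-width bins on (0, `max_dist`]. `values` may be a vector (one
#' value per site) or an `n_sites x K` matrix of `K` replicate fields (e.g.
#' daily surfaces), in which case pairs are pooled across columns — the usual
#' way station networks estimate a spatial variogram from daily data.
#' Bins with zero pairs are dropped.
#'
#' @param values numeric vector (length n_sites) or matrix (n_sites x K).
#' @param sites a `site_set`.
#' @param n_bins number of distance bins (default 15).
#' @param max_dist maximum pair distance considered (m); default half the
#'   maximum inter-site distance, the usual rule of thumb.
#' @return a `variogram_estimate`: data frame with `bin_center`, `gamma_hat`,
#'   `pair_count` plus attributes `max_dist`, `n_bins`.
#' @export
empirical_semivariogram <- function(values, sites, n_bins = 15, max_dist = NULL) {
  validate_site_set(sites)
  n <- nrow(sites)
  v <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  if (nrow(v) != n) {
    stop_airmes("values has %d rows but sites has %d units", nrow(v), n)
  }
  if (any(!is.finite(v))) stop_airmes("values must be finite")
  d <- site_distances(sites)
  if (is.null(max_dist)) max_dist <- max(d) / 2
  if (max_dist <= 0) stop_airmes("max_dist must be > 0")

  ut <- which(upper.tri(d), arr.ind = TRUE)
  dd <- d[ut]
  keep <- dd <= max_dist
  if (!any(keep)) {
    stop_airmes("no site pairs within max_dist = %g m; empirical semivariogram is empty", max_dist)
  }
  ut <- ut[keep, , drop = FALSE]
  dd <- dd[keep]
  # mean squared difference per pair, averaged over replicate columns
  sq <- rowMeans((v[ut[, 1], , drop = FALSE] - v[ut[, 2], , drop = FALSE])^2)

  breaks <- seq(0, max_dist, length.out = n_bins + 1)
  bin <- cut(dd, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  k <- ncol(v)
  fbin <- factor(bin, levels = seq_len(n_bins))
  est <- data.frame(
    # mean pair distance per bin, not the midpoint: the semivariance of a
    # curved model evaluated at the midpoint misattributes the bin's signal
    bin_center = as.numeric(tapply(dd, fbin, mean)),
    gamma_hat = as.numeric(tapply(sq, fbin, mean)) / 2,
    pair_count = as.integer(tabulate(bin, nbins = n_bins)) * k
  )
  est <- est[est$pair_count > 0, , drop = FALSE]
  rownames(est) <- NULL
  structure(est, class = c("variogram_estimate", "data.frame"),
            max_dist = max_dist, n_bins = n_bins)
}

variogram_curve <- function(h, nugget, partial_sill, range_m, model = "exponential") {
  if (model == "spherical") {
    hr <- pmin(h / range_m, 1)
    nugget + partial_sill * (1.5 * hr - 0.5 * hr^3)
  } else {
    nugget + partial_sill * (1 - exp(-h / range_m))
  }
}

# Weighted linear LS of gamma ~ nugget + psill * f(h) for a fixed range,
# with non-negativity by clamp-and-refit. Returns c(nugget, psill, objective).
.vfit_profile <- function(h, g, wts, range_m, model) {
  f <- variogram_curve(h, 0, 1, range_m, model)
  X <- cbind(1, f)
  wX <- X * wts
  xtx <- crossprod(wX, X)
  xty <- crossprod(wX, g)
  co <- tryCatch(drop(solve(xtx, xty)), error = function(e) c(mean(g), 0))
  if (co[1] < 0) {
    ps <- sum(wts * f * g) / sum(wts * f * f)
    co <- c(0, max(ps, 0))
  }
  if (co[2] < 0) {
    co <- c(sum(wts * g) / sum(wts), 0)
  }
  resid <- g - variogram_curve(h, co[1], co[2], range_m, model)
  c(co, sum(wts * resid^2))
}

#' Fit a bounded-variogram model to empirical semivariogram bins
#'
#' Weighted least squares fit of
#' \deqn{\gamma(h) = nugget + psill \,(1 - e^{-h/range})}
#' (or the spherical analogue) to binned semivariance estimates, with weights
#' `pair_count / h^2` (Cressie-style: short distances and well-populated bins
#' dominate) and all parameters constrained non-negative. A coarse profile
#' over the range parameter supplies starting values; Levenberg–Marquardt
#' (`minpack.lm::nlsLM`) polishes them, with a bounded quasi-Newton fallback.
#' Non-convergence is flagged, never silent.
#'
#' @param emp a `variogram_estimate` from [empirical_semivariogram()], or any
#'   data frame with columns `bin_center`, `gamma_hat`, `pair_count`.
#' @param model `"exponential"` (default) or `"spherical"`.
#' @return a `variogram_fit` list: `nugget`, `partial_sill`, `range_m`,
#'   `model`, `converged`, `objective`, and the bins used.
#' @export
fit_exponential_variogram <- function(emp, model = c("exponential", "spherical")) {
  model <- match.arg(model)
  need <- c("bin_center", "gamma_hat", "pair_count")
  if (!all(need %in% names(emp))) {
    stop_airmes("emp must have columns %s", paste(need, collapse = ", "))
  }
  emp <- emp[emp$pair_count > 0, , drop = FALSE]
  if (nrow(emp) < 3) {
    stop_airmes("need >= 3 populated bins to fit a variogram, got %d", nrow(emp))
  }
  h <- emp$bin_center
  g <- emp$gamma_hat
  wts <- emp$pair_count / h^2

  r_grid <- exp(seq(log(min(h) / 4), log(max(h) * 4), length.out = 48))
  prof <- vapply(r_grid, function(r) .vfit_profile(h, g, wts, r, model), numeric(3))
  best <- which.min(prof[3, ])
  start <- list(nug = max(prof[1, best], 0), ps = max(prof[2, best], 0),
                rg = r_grid[best])

  converged <- FALSE
  out <- NULL
  fit <- tryCatch(
    minpack.lm::nlsLM(
      g ~ variogram_curve(h, nug, ps, rg, model),
      start = start, weights = wts,
      lower = c(0, 0, min(h) / 100),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14, ptol = 1e-14)
    ),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (!is.null(fit)) {
    co <- unname(stats::coef(fit))
    resid <- g - variogram_curve(h, co[1], co[2], co[3], model)
    out <- list(nugget = co[1], partial_sill = co[2], range_m = co[3],
                objective = sum(wts * resid^2))
    converged <- fit$convInfo$isConv %||% TRUE
  }
  if (is.null(out)) {
    obj <- function(p) {
      resid <- g - variogram_curve(h, p[1], p[2], p[3], model)
      sum(wts * resid^2)
    }
    op <- optim(unlist(start), obj, method = "L-BFGS-B",
                lower = c(0, 0, min(h) / 100),
                control = list(factr = 1e4, maxit = 500))
    out <- list(nugget = unname(op$par[1]), partial_sill = unname(op$par[2]),
                range_m = unname(op$par[3]), objective = op$value)
    converged <- op$convergence == 0
  }
  structure(c(out, list(model = model, converged = converged, bins = emp)),
            class = "variogram_fit")
}

#' @export
print.variogram_fit <- function(x, ...) {
  cat(sprintf("<variogram_fit> %s: nugget=%.4g partial_sill=%.4g range_m=%.4g (%s)\n",
              x$model, x$nugget, x$partial_sill, x$range_m,
              if (x$converged) "converged" else "NOT CONVERGED"))
  invisible(x)
}
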