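# Multilevel Poisson fitting machinery.
#
# The model has a scalar random intercept per unit, so the marginal
# likelihood factorizes over units and each factor is a one-dimensional
# integral. For unit i with fixed linear predictor eta_it (excluding b_i):
#
#   h_i(b) = C_i + y_i+ b - A_i e^b - b^2/(2 sigma^2) - log sigma - log(2*pi)/2
#
# with sufficient statistics A_i = sum_t exp(eta_it),
# C_i = sum_t [y_it eta_it - log y_it!], y_i+ = sum_t y_it. Only A_i depends
# on the parameters through an S x T exponential; everything else is O(S).
# h_i is strictly concave in b, so the Newton mode search below is safe.

# Vectorized mode search: solves h'(b) = ysum - A e^b - b/sigma^2 = 0 for all
# units at once. Damped Newton on the concave objective.
.ri_modes <- function(ysum, a_i, inv_s2, tol = 1e-12, maxit = 100L) {
  b <- rep(0, length(a_i))
  hval <- ysum * b - a_i * exp(b) - 0.5 * inv_s2 * b^2
  for (it in seq_len(maxit)) {
    eb <- exp(b)
    grad <- ysum - a_i * eb - inv_s2 * b
    curv <- a_i * eb + inv_s2
    step <- grad / curv
    step <- pmax(pmin(step, 5), -5) # trust region against overshoot
    bnew <- b + step
    hnew <- ysum * bnew - a_i * exp(bnew) - 0.5 * inv_s2 * bnew^2
    bad <- hnew < hval - 1e-12
    k <- 0L
    while (any(bad) && k < 40L) {
      step[bad] <- step[bad] / 2
      bnew[bad] <- b[bad] + step[bad]
      hnew[bad] <- ysum[bad] * bnew[bad] - a_i[bad] * exp(bnew[bad]) -
        0.5 * inv_s2 * bnew[bad]^2
      bad <- hnew < hval - 1e-12
      k <- k + 1L
    }
    conv <- max(abs(step)) < tol
    b <- bnew
    hval <- hnew
    if (conv) break
  }
  b
}

# Marginal log-likelihood given sufficient statistics, by Laplace or AGHQ.
# Returns the sum over units of log integral exp(h_i(b)) db.
.ri_marginal_core <- function(ysum, a_i, c_i, sigma_b, method = "laplace",
                              gh = NULL) {
  if (sigma_b < 1e-8) {
    # point-mass limit: plain Poisson likelihood at b = 0
    return(sum(c_i) - sum(a_i))
  }
  inv_s2 <- 1 / sigma_b^2
  bhat <- .ri_modes(ysum, a_i, inv_s2)
  curv <- a_i * exp(bhat) + inv_s2 # -h''(bhat)
  h_hat <- c_i + ysum * bhat - a_i * exp(bhat) - 0.5 * inv_s2 * bhat^2 -
    log(sigma_b) - 0.5 * log(2 * pi)
  if (method == "laplace") {
    return(sum(h_hat + 0.5 * log(2 * pi) - 0.5 * log(curv)))
  }
  # adaptive Gauss-Hermite centered at the mode, scaled by 1/sqrt(curv)
  s <- 1 / sqrt(curv)
  x <- gh$x
  lw <- log(gh$w) + x^2
  # nodes: b_k = bhat + sqrt(2) s x_k  (S x Q)
  bk <- outer(bhat, rep(1, length(x))) + sqrt(2) * outer(s, x)
  hk <- c_i + ysum * bk - a_i * exp(bk) - 0.5 * inv_s2 * bk^2 -
    log(sigma_b) - 0.5 * log(2 * pi)
  hk <- sweep(hk, 1, h_hat) # stabilize around the mode value
  lse <- log(rowSums(exp(sweep(hk, 2, lw, "+"))))
  sum(h_hat + log(sqrt(2) * s) + lse)
}

# Builds closures evaluating the negative marginal log-likelihood (and, for
# the Laplace path, its exact gradient) at theta = (beta0, beta_short,
# beta_long, log sigma_b) for fixed data. The gradient differentiates the
# Laplace-approximated objective itself (envelope for the mode, implicit
# differentiation for the curvature term), so optimizer and gradient are
# mutually consistent.
.ri_nll_factory <- function(y, m, wmat, method, q) {
  s_units <- nrow(y)
  t_days <- ncol(y)
  ysum <- .rowSums(y, s_units, t_days)
  syw <- .rowSums(y * wmat, s_units, t_days)
  lfact <- sum(lfactorial(y))
  max_w <- max(abs(wmat))
  max_m <- max(abs(m))
  gh <- if (method == "aghq") pracma::gaussHermite(q) else NULL

  nll <- function(theta) {
    beta0 <- theta[1]; bs <- theta[2]; bl <- theta[3]
    sigma_b <- exp(theta[4])
    if (abs(beta0) + abs(bl) * max_m + abs(bs) * max_w > 200) return(1e10)
    eta0 <- beta0 + bl * m
    a_i <- exp(eta0) * .rowSums(exp(bs * wmat), s_units, t_days)
    c_i <- ysum * eta0 + bs * syw
    ll <- .ri_marginal_core(ysum, a_i, c_i, sigma_b, method, gh)
    if (!is.finite(ll)) return(1e10)
    -(ll - lfact)
  }

  gr <- function(theta) {
    beta0 <- theta[1]; bs <- theta[2]; bl <- theta[3]
    sigma_b <- exp(theta[4])
    if (abs(beta0) + abs(bl) * max_m + abs(bs) * max_w > 200) {
      return(rep(0, 4)) # matched to the nll plateau
    }
    eta0 <- beta0 + bl * m
    e0 <- exp(eta0)
    ew <- exp(bs * wmat)
    sw <- .rowSums(ew, s_units, t_days)
    sww <- .rowSums(wmat * ew, s_units, t_days)
    a_i <- e0 * sw
    # dA/dtheta_j per unit, j = beta0, beta_short, beta_long
    da <- cbind(a_i, e0 * sww, m * a_i)
    dc <- cbind(ysum, syw, m * ysum)
    if (sigma_b < 1e-8) {
      gbeta <- colSums(dc - da)
      return(-c(gbeta, 0))
    }
    inv_s2 <- 1 / sigma_b^2
    bhat <- .ri_modes(ysum, a_i, inv_s2)
    eb <- exp(bhat)
    curv <- a_i * eb + inv_s2
    fac <- eb * (1 + inv_s2 / (2 * curv^2))
    gbeta <- colSums(dc - da * fac)
    glsig <- sum(bhat^2 * inv_s2 - 1 -
                   (a_i * eb * bhat) * inv_s2 / curv^2 + inv_s2 / curv)
    -c(gbeta, glsig)
  }

  list(nll = nll, gr = if (method == "laplace") gr else NULL, ysum = ysum)
}

# Central-difference gradient and Hessian with per-parameter steps.
.num_grad <- function(f, x, h) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h[j]
    (f(x + e) - f(x - e)) / (2 * h[j])
  }, numeric(1))
}

.num_hessian <- function(f, x, h) {
  p <- length(x)
  hess <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (j in seq_len(p)) {
    ej <- numeric(p); ej[j] <- h[j]
    hess[j, j] <- (f(x + ej) - 2 * f0 + f(x - ej)) / h[j]^2
    if (j < p) {
      for (k in seq((j + 1), p)) {
        ek <- numeric(p); ek[k] <- h[k]
        hess[j, k] <- hess[k, j] <-
          (f(x + ej + ek) - f(x + ej - ek) - f(x - ej + ek) + f(x - ej - ek)) /
          (4 * h[j] * h[k])
      }
    }
  }
  hess
}

#' Fit the Poisson random-intercept model to counts and an exposure surface
#'
#' Builds the two exposure covariates by within/between decomposition of the
#' supplied exposure — the per-unit period mean (long-term term) and the
#' daily deviation from it (short-term term) — and maximizes the marginal
#' likelihood of the Poisson model with a normal random intercept per unit.
#' The unit integrals are handled by a Laplace approximation (default) or
#' adaptive Gauss–Hermite quadrature with `q` nodes; standard errors come
#' from the observed information (numerical Hessian of the approximated
#' marginal log-likelihood at the optimum), with Wald 95% intervals and
#' two-sided p-values. The convergence flag is honest: it requires optimizer
#' success, a small scaled gradient, and a positive-definite information
#' matrix.
#'
#' @param counts a `health_series` or non-negative integer matrix
#'   (n_units x n_days).
#' @param exposure exposure surface the analyst observes: `true_surface`,
#'   `modeled_exposure`, or matrix of the same shape.
#' @param method `"laplace"` (default) or `"aghq"`.
#' @param q number of quadrature nodes for AGHQ (default 9).
#' @param short_term_raw if `TRUE` the short-term covariate is the raw daily
#'   concentration rather than the within-unit deviation (the unit mean stays
#'   in the model, so the fits are reparametrizations of each other).
#' @return an `ri_fit` list: `beta_short_hat`, `beta_long_hat`, `se_short`,
#'   `se_long`, `ci95_short`, `ci95_long`, `p_short`, `p_long`, `beta0_hat`,
#'   `sigma_b_hat`, `converged`, `loglik`, `n_units`, `n_days`, `method`,
#'   plus optimizer diagnostics.
#' @export
fit_poisson_ri <- function(counts, exposure, method = c("laplace", "aghq"),
                           q = 9L, short_term_raw = FALSE) {
  method <- match.arg(method)
  y <- if (inherits(counts, "health_series")) counts$counts else counts
  x <- exposure_values(exposure)
  if (!all(dim(y) == dim(x))) {
    stop_airmes("counts are %d x %d but exposure is %d x %d",
                nrow(y), ncol(y), nrow(x), ncol(x))
  }
  if (nrow(y) < 2) stop_airmes("need >= 2 units")
  if (any(y < 0) || any(y != round(y))) stop_airmes("counts must be non-negative integers")
  if (sum(y) == 0) stop_airmes("all counts are zero; the model is not identifiable")

  dc <- decompose_exposure(x)
  m <- dc$spatial_means
  wmat <- if (short_term_raw) x else dc$temporal_devs

  # one-step moment start: linearized Poisson score around a flat rate
  ybar <- mean(y)
  tt <- ncol(y)
  mc <- m - mean(m)
  bs0 <- sum(y * wmat) / (ybar * max(sum(wmat^2), 1e-12))
  bl0 <- sum((rowSums(y) - tt * ybar) * mc) / (ybar * tt * max(sum(mc^2), 1e-12))
  beta0_0 <- log(ybar) - bl0 * mean(m)
  theta0 <- c(beta0_0, bs0, bl0, log(0.05))
  theta0[!is.finite(theta0)] <- 0

  fac <- .ri_nll_factory(y, m, wmat, method, q)
  nll <- fac$nll

  sd_w <- max(sd(as.vector(wmat)), 1e-8)
  sd_m <- max(sd(m), 1e-8)
  pscale <- c(1, 0.1 / sd_w, 0.1 / sd_m, 1)

  opt <- optim(theta0, nll, gr = fac$gr, method = "L-BFGS-B",
               lower = c(-Inf, -Inf, -Inf, log(1e-6)),
               control = list(parscale = pscale, factr = 1e2, pgtol = 1e-10,
                              maxit = 1000))

  theta <- opt$par
  hstep <- pmax(1e-4 * pscale, 1e-7)
  grad <- .num_grad(nll, theta, hstep)
  hess <- .num_hessian(nll, theta, hstep)
  # near the sigma lower bound the log-sigma direction is flat (the model
  # degenerates to plain Poisson), so the 4th coordinate carries no
  # information; drop it from the information matrix rather than report a
  # spurious SE. The same fallback covers a numerically singular full
  # Hessian with a healthy beta block.
  at_bound <- theta[4] <= log(1e-6) + 1e-9
  solve_pd <- function(h) {
    v <- tryCatch(solve(h), error = function(e) NULL)
    if (!is.null(v) && all(is.finite(diag(v))) && all(diag(v) > 0)) v else NULL
  }
  vcov <- if (at_bound) NULL else solve_pd(hess)
  if (is.null(vcov)) {
    at_bound <- TRUE
    vcov <- solve_pd(hess[1:3, 1:3])
  }
  pd <- !is.null(vcov)
  grad_ok <- {
    g <- grad * pscale
    if (at_bound) g <- g[1:3]
    max(abs(g)) < 0.05
  }
  converged <- (opt$convergence == 0) && pd && grad_ok

  se <- if (pd) sqrt(diag(vcov)) else rep(NA_real_, 4)
  est <- theta[2:3]
  se_b <- se[2:3]
  zq <- qnorm(0.975)
  ci <- cbind(est - zq * se_b, est + zq * se_b)
  pvals <- 2 * pnorm(-abs(est / se_b))

  structure(list(
    beta_short_hat = est[1], beta_long_hat = est[2],
    se_short = se_b[1], se_long = se_b[2],
    ci95_short = ci[1, ], ci95_long = ci[2, ],
    p_short = pvals[1], p_long = pvals[2],
    beta0_hat = theta[1], sigma_b_hat = exp(theta[4]),
    sigma_b_at_bound = at_bound,
    converged = converged, loglik = -opt$value,
    n_units = nrow(y), n_days = ncol(y),
    method = method, q = if (method == "aghq") as.integer(q) else NA_integer_,
    optim_convergence = opt$convergence, grad_norm = max(abs(grad * pscale)),
    short_term_raw = isTRUE(short_term_raw)
  ), class = "ri_fit")
}

#' @export
print.ri_fit <- function(x, ...) {
  cat(sprintf("<ri_fit> %s, %d units x %d days (%s)\n",
              x$method, x$n_units, x$n_days,
              if (x$converged) "converged" else "NOT CONVERGED"))
  cat(sprintf("  short-term: %.6g (se %.3g, p %.3g)\n",
              x$beta_short_hat, x$se_short, x$p_short))
  cat(sprintf("  long-term : %.6g (se %.3g, p %.3g)\n",
              x$beta_long_hat, x$se_long, x$p_long))
  cat(sprintf("  sigma_b: %.4g  loglik: %.4f\n", x$sigma_b_hat, x$loglik))
  invisible(x)
}

.check_ri_params <- function(params) {
  need <- c("beta0", "beta_short", "beta_long", "sigma_b")
  miss <- setdiff(need, names(params))
  if (length(miss) > 0) {
    stop_airmes("params needs elements %s", paste(miss, collapse = ", "))
  }
  if (params$sigma_b < 0) stop_airmes("sigma_b must be >= 0")
  params
}

#' Evaluate the approximate marginal log-likelihood at given parameters
#'
#' Evaluates the Laplace or AGHQ marginal log-likelihood of the Poisson
#' random-intercept model at fixed parameter values (no fitting). Useful for
#' validating the approximations against [marginal_loglik_bruteforce()].
#'
#' @param counts `health_series` or count matrix.
#' @param exposure exposure surface (decomposed as in [fit_poisson_ri()]).
#' @param params list with `beta0`, `beta_short`, `beta_long`, `sigma_b`.
#' @param method `"laplace"` or `"aghq"`.
#' @param q AGHQ node count.
#' @param short_term_raw as in [fit_poisson_ri()].
#' @return marginal log-likelihood value (includes all Poisson constants).
#' @export
marginal_loglik <- function(counts, exposure, params,
                            method = c("laplace", "aghq"), q = 9L,
                            short_term_raw = FALSE) {
  method <- match.arg(method)
  params <- .check_ri_params(params)
  y <- if (inherits(counts, "health_series")) counts$counts else counts
  x <- exposure_values(exposure)
  dc <- decompose_exposure(x)
  wmat <- if (short_term_raw) x else dc$temporal_devs
  fac <- .ri_nll_factory(y, dc$spatial_means, wmat, method, q)
  sig <- params$sigma_b
  -fac$nll(c(params$beta0, params$beta_short, params$beta_long,
             log(max(sig, 1e-300)))) # log(0) guarded; core switches at 1e-8
}

#' Brute-force marginal log-likelihood by trapezoid integration
#'
#' Test oracle: per unit, numerically integrates the Poisson likelihood
#' against the `N(0, sigma_b^2)` random-intercept density on a regular grid
#' of `n_grid` points spanning `±half_width` SDs around zero, and sums logs
#' across units. Guarded to small instances (`n_units * n_days <= 1e4`).
#' `sigma_b = 0` is handled analytically (point mass at zero).
#'
#' @param counts `health_series` or count matrix.
#' @param exposure exposure surface.
#' @param params list with `beta0`, `beta_short`, `beta_long`, `sigma_b`.
#' @param n_grid number of grid points (default 201).
#' @param half_width half-width of the grid in units of `sigma_b` (default 8).
#' @param short_term_raw as in [fit_poisson_ri()].
#' @return marginal log-likelihood value.
#' @export
marginal_loglik_bruteforce <- function(counts, exposure, params,
                                       n_grid = 201L, half_width = 8,
                                       short_term_raw = FALSE) {
  params <- .check_ri_params(params)
  y <- if (inherits(counts, "health_series")) counts$counts else counts
  x <- exposure_values(exposure)
  if (length(y) > 1e4) {
    stop_airmes("brute-force integration is restricted to n_units * n_days <= 1e4 (got %d cells)",
                length(y))
  }
  dc <- decompose_exposure(x)
  m <- dc$spatial_means
  wmat <- if (short_term_raw) x else dc$temporal_devs

  eta <- (params$beta0 + params$beta_long * m) + params$beta_short * wmat
  if (params$sigma_b == 0) {
    return(sum(y * eta - exp(eta) - lfactorial(y)))
  }
  ysum <- rowSums(y)
  a_i <- rowSums(exp(eta))
  c_i <- rowSums(y * eta - lfactorial(y))
  sig <- params$sigma_b
  b <- seq(-half_width * sig, half_width * sig, length.out = n_grid)
  # S x G matrix of h_i(b_g)
  hmat <- outer(c_i, rep(1, n_grid)) + outer(ysum, b) - outer(a_i, exp(b)) -
    matrix(rep(b^2 / (2 * sig^2) + log(sig) + 0.5 * log(2 * pi), each = length(c_i)),
           nrow = length(c_i))
  mx <- apply(hmat, 1, max)
  db <- b[2] - b[1]
  f <- exp(sweep(hmat, 1, mx))
  trap <- db * (rowSums(f) - 0.5 * (f[, 1] + f[, n_grid]))
  sum(mx + log(trap))
}
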