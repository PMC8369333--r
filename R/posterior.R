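#' Deterministic grid posterior of the standardized effect size
#'
#' The posterior of delta given an observed t-statistic is one-dimensional
#' and proportional to `T_df(t | sqrt(effective_n) * delta) * pi(delta)`.
#' This function evaluates it on a dense grid centered on the maximum
#' likelihood estimate `delta_hat = t / sqrt(effective_n)`, normalizes by
#' the trapezoid rule, and records the prior density on the same grid (the
#' posterior/prior ratio is what the support interval needs). The grid is
#' widened until it spans at least `delta_hat +/- 8` posterior standard
#' deviations, and always contains 0.
#'
#' @inheritParams marginal_t_density
#' @param grid_points Number of grid points, at least 501 (default 4001).
#' @return An object of class `posterior_grid`: a list with `delta`
#'   (increasing grid), `posterior_density`, `prior_density`, `cdf`
#'   (trapezoid cumulative), and the provenance fields `t`, `df`,
#'   `effective_n`, `prior`.
#' @export
posterior_grid <- function(t, df, effective_n, prior = cauchy_prior(),
                           grid_points = 4001) {
  .check_t_inputs(t, df, effective_n)
  prior <- .check_prior(prior)
  if (grid_points < 501) stop("grid_points must be >= 501", call. = FALSE)

  delta_hat <- t / sqrt(effective_n)
  # delta-method width of the likelihood in delta
  se0 <- sqrt((1 + t^2 / (2 * df)) / effective_n)
  lo <- min(delta_hat - 10 * se0, -2 * se0)
  hi <- max(delta_hat + 10 * se0, 2 * se0)

  for (iter in 1:6) {
    delta <- sort(unique(c(seq(lo, hi, length.out = grid_points), 0)))
    dens <- .t_likelihood(delta, t, df, effective_n) *
      stats::dcauchy(delta, prior$location, prior$scale)
    z <- .trapz(delta, dens)
    if (!is.finite(z) || z <= 0) {
      stop("posterior normalization failed (integral = ", z, ")",
           call. = FALSE)
    }
    dens <- dens / z
    m <- .trapz(delta, delta * dens)
    sdp <- sqrt(max(.trapz(delta, (delta - m)^2 * dens), 0))
    ok_span <- (delta_hat - 8 * sdp >= lo) && (delta_hat + 8 * sdp <= hi)
    ok_tail <- dens[1] < 1e-8 * max(dens) &&
      dens[length(dens)] < 1e-8 * max(dens)
    if (ok_span && ok_tail) break
    lo <- min(lo, delta_hat - 10 * sdp) - 2 * sdp
    hi <- max(hi, delta_hat + 10 * sdp) + 2 * sdp
  }

  cdf <- .trapz_cum(delta, dens)
  cdf <- cdf / cdf[length(cdf)]
  structure(
    list(delta = delta, posterior_density = dens,
         prior_density = stats::dcauchy(delta, prior$location, prior$scale),
         cdf = cdf, t = t, df = df, effective_n = effective_n, prior = prior),
    class = "posterior_grid"
  )
}

#' @export
print.posterior_grid <- function(x, ...) {
  cat(sprintf(
    "posterior grid for delta | t = %.4g (df = %.2f, n_delta = %.2f), %d points on [%.3g, %.3g]\n",
    x$t, x$df, x$effective_n, length(x$delta),
    min(x$delta), max(x$delta)))
  invisible(x)
}

.trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

.trapz_cum <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

.check_grid <- function(g) {
  if (!inherits(g, "posterior_grid")) {
    stop("expected a 'posterior_grid' object", call. = FALSE)
  }
  g
}

#' Posterior mean of a grid posterior
#' @param g A [posterior_grid()].
#' @return The posterior mean of delta.
#' @export
posterior_mean <- function(g) {
  g <- .check_grid(g)
  .trapz(g$delta, g$delta * g$posterior_density)
}

# grid quantile by linear interpolation of the trapezoid CDF; flat CDF
# stretches (zero density) are collapsed before interpolating
.grid_quantile <- function(g, p) {
  keep <- c(TRUE, diff(g$cdf) > 0)
  stats::approx(g$cdf[keep], g$delta[keep], xout = p, rule = 2,
                ties = "ordered")$y
}

#' Sample from a grid posterior
#'
#' I.i.d. draws by inverse-CDF interpolation on the grid; reproducible when
#' a seed is given.
#'
#' @param g A [posterior_grid()].
#' @param m Number of draws (>= 1).
#' @param seed Optional integer seed.
#' @return Numeric vector of `m` posterior draws of delta.
#' @export
sample_posterior <- function(g, m, seed = NULL) {
  g <- .check_grid(g)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  .grid_quantile(g, stats::runif(m))
}

interval_estimate <- function(lower, upper, kind, mass, k = NA_real_,
                              empty = FALSE) {
  structure(
    list(lower = lower, upper = upper, kind = kind, mass = mass, k = k,
         empty = empty),
    class = "interval_estimate"
  )
}

#' @export
print.interval_estimate <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("%s interval: empty (no value meets the criterion)\n", x$kind))
  } else {
    cat(sprintf("%s interval: [%.4g, %.4g] (posterior mass %.4f)\n",
                x$kind, x$lower, x$upper, x$mass))
  }
  invisible(x)
}

# interpolated crossing of dens = h between grid points i and i+1
.cross <- function(x, d, i, h) {
  if (d[i + 1] == d[i]) return(x[i])
  x[i] + (h - d[i]) * (x[i + 1] - x[i]) / (d[i + 1] - d[i])
}

# mass between interpolated bounds, from the trapezoid CDF
.mass_between <- function(g, lower, upper) {
  q <- stats::approx(g$delta, g$cdf, xout = c(lower, upper),
                     rule = 2)$y
  q[2] - q[1]
}

#' Highest-posterior-density interval
#'
#' Shortest interval containing at least `mass` posterior probability,
#' found by bisection on the density threshold (the posterior of delta
#' given t is unimodal, so the highest-density region is an interval).
#' Endpoints are refined by linear interpolation between grid points.
#'
#' @param g A [posterior_grid()].
#' @param mass Target probability mass, in (0, 1); default 0.95.
#' @return An `interval_estimate` with kind `"hpd95"` (for `mass = 0.95`)
#'   or `"hpd"`.
#' @export
hpd_interval <- function(g, mass = 0.95) {
  g <- .check_grid(g)
  if (!(mass > 0 && mass < 1)) stop("mass must be in (0, 1)", call. = FALSE)
  x <- g$delta
  d <- g$posterior_density
  h_lo <- 0
  h_hi <- max(d)
  bounds <- c(min(x), max(x))
  for (i in 1:80) {
    h <- (h_lo + h_hi) / 2
    idx <- which(d >= h)
    if (length(idx) == 0) {
      h_hi <- h
      next
    }
    i1 <- min(idx)
    i2 <- max(idx)
    lower <- if (i1 > 1) .cross(x, d, i1 - 1, h) else x[1]
    upper <- if (i2 < length(x)) .cross(x, d, i2, h) else x[length(x)]
    m <- .mass_between(g, lower, upper)
    if (m >= mass) {
      h_lo <- h  # shrink the interval (tie-break toward the shorter one)
      bounds <- c(lower, upper)
      if (m - mass < 1e-10) break
    } else {
      h_hi <- h
    }
  }
  interval_estimate(bounds[1], bounds[2],
                    kind = if (abs(mass - 0.95) < 1e-12) "hpd95" else "hpd",
                    mass = .mass_between(g, bounds[1], bounds[2]))
}

#' Full-posterior ("100%") interval
#'
#' Operationalizes the full posterior as the central interval holding
#' `1 - epsilon` of the mass (`method = "grid"`, default, deterministic), or
#' as the range (min/max) of posterior draws (`method = "draws"`). A literal
#' 100% interval would be the whole real line under a Cauchy prior, which
#' would make the full-ROPE test vacuous; see the package vignette.
#'
#' @param g A [posterior_grid()].
#' @param epsilon Excluded tail mass for grid mode (default `1e-6`).
#' @param method `"grid"` or `"draws"`.
#' @param draws Number of posterior draws for draw mode (default 5000).
#' @param seed Optional seed for draw mode.
#' @return An `interval_estimate` with kind `"hpd100"`.
#' @export
full_interval <- function(g, epsilon = 1e-6,
                          method = c("grid", "draws"), draws = 5000,
                          seed = NULL) {
  g <- .check_grid(g)
  method <- match.arg(method)
  if (method == "grid") {
    if (!(epsilon > 0 && epsilon < 1)) {
      stop("epsilon must be in (0, 1)", call. = FALSE)
    }
    q <- .grid_quantile(g, c(epsilon / 2, 1 - epsilon / 2))
    interval_estimate(q[1], q[2], kind = "hpd100", mass = 1 - epsilon)
  } else {
    s <- sample_posterior(g, draws, seed = seed)
    interval_estimate(min(s), max(s), kind = "hpd100",
                      mass = .mass_between(g, min(s), max(s)))
  }
}

#' BF = k support interval
#'
#' The set of delta values the data corroborated by at least a factor `k`:
#' `{delta : posterior_density(delta) / prior_density(delta) > k}`. The
#' ratio is unimodal here, so the set is an interval; it is empty when no
#' value exceeds `k`. With the default `k = 1` the interval contains exactly
#' those values whose point Bayes factor against the rest of the prior
#' exceeds 1 (at `delta = 0` the ratio is the Savage-Dickey value of BF01).
#'
#' @param g A [posterior_grid()].
#' @param k Corroboration factor, > 0 (default 1).
#' @return An `interval_estimate` with kind `"support"`; `empty = TRUE` and
#'   `NA` bounds when no parameter value is corroborated by factor `k`.
#' @export
support_interval <- function(g, k = 1) {
  g <- .check_grid(g)
  if (!(k > 0)) stop("k must be > 0", call. = FALSE)
  x <- g$delta
  ratio <- g$posterior_density / g$prior_density
  idx <- which(ratio > k)
  if (length(idx) == 0) {
    return(interval_estimate(NA_real_, NA_real_, kind = "support",
                             mass = 0, k = k, empty = TRUE))
  }
  i1 <- min(idx)
  i2 <- max(idx)
  lower <- if (i1 > 1) .cross(x, ratio, i1 - 1, k) else x[1]
  upper <- if (i2 < length(x)) .cross(x, ratio, i2, k) else x[length(x)]
  interval_estimate(lower, upper, kind = "support",
                    mass = .mass_between(g, lower, upper), k = k)
}
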