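#' Cauchy prior on the standardized effect size
#'
#' The effect-size prior of the Jeffreys-Zellner-Siow (JZS) family of
#' two-sample t-test models: `delta ~ Cauchy(location, scale)`, combined
#' (implicitly, through the marginal t-likelihood) with the Jeffreys prior
#' `1/sigma^2` on the common variance. A Student-t prior with `nu0 = 1`
#' degree of freedom is this Cauchy; other `nu0` are not implemented.
#'
#' @param location Prior center on the delta scale (0 for the default tests).
#' @param scale Prior scale, > 0. Conventional choices are `1/sqrt(2)`
#'   (medium), `1` (wide) and `sqrt(2)` (ultrawide).
#' @param nu0 Degrees of freedom of the t-form prior; only `1` (the Cauchy)
#'   is supported.
#' @return An object of class `cauchy_prior`.
#' @export
cauchy_prior <- function(location = 0, scale = 1 / sqrt(2), nu0 = 1) {
  if (!is.finite(location)) stop("prior location must be finite", call. = FALSE)
  if (!is.finite(scale) || scale <= 0) {
    stop("prior scale must be > 0", call. = FALSE)
  }
  if (!identical(as.numeric(nu0), 1)) {
    stop("only nu0 = 1 (the Cauchy prior) is implemented", call. = FALSE)
  }
  structure(list(location = location, scale = scale),
            class = "cauchy_prior")
}

#' @export
print.cauchy_prior <- function(x, ...) {
  cat(sprintf("Cauchy(%g, %g) prior on delta\n", x$location, x$scale))
  invisible(x)
}

.check_prior <- function(prior) {
  if (!inherits(prior, "cauchy_prior")) {
    stop("expected a 'cauchy_prior' object", call. = FALSE)
  }
  prior
}

.check_t_inputs <- function(t, df, effective_n) {
  if (!is.finite(t)) stop("t must be finite", call. = FALSE)
  if (!is.finite(df) || df <= 0) stop("df must be > 0", call. = FALSE)
  if (!is.finite(effective_n) || effective_n <= 0) {
    stop("effective_n must be > 0", call. = FALSE)
  }
}

# noncentral t likelihood of delta given the observed t statistic
.t_likelihood <- function(delta, t, df, effective_n) {
  suppressWarnings(stats::dt(t, df, ncp = sqrt(effective_n) * delta))
}

# adaptive quadrature of f over (lower, upper), split at interior points so
# the sharp likelihood peak at delta-hat never hides inside one panel
.quad <- function(f, lower, upper, splits = numeric(0),
                  rel.tol = 1e-10, abs.tol = 1e-13) {
  splits <- sort(unique(splits[splits > lower & splits < upper]))
  bounds <- c(lower, splits, upper)
  value <- 0
  err <- 0
  for (i in seq_len(length(bounds) - 1)) {
    r <- stats::integrate(f, bounds[i], bounds[i + 1],
                          rel.tol = rel.tol, abs.tol = abs.tol,
                          stop.on.error = FALSE)
    value <- value + r$value
    err <- err + r$abs.error
  }
  # individual panels may report roundoff trouble on negligible tails; what
  # matters is the achieved error bound on the whole integral
  if (!is.finite(value) || err > 1e-4 * abs(value) + 1e-12) {
    stop("quadrature failed on (", lower, ", ", upper,
         "): achieved error ", signif(err, 3), " for value ",
         signif(value, 6), call. = FALSE)
  }
  list(value = value, error = err)
}

# unnormalized marginal: integral of likelihood * prior density over (l, u).
# Integrated in the prior-CDF variable u = F(delta), which maps any prior
# scale (including near-point-mass priors) to a bounded, well-scaled domain;
# the integration is split at the image of the likelihood peak delta-hat.
.marginal_raw <- function(t, df, effective_n, prior, lower, upper) {
  ulo <- stats::pcauchy(lower, prior$location, prior$scale)
  uhi <- stats::pcauchy(upper, prior$location, prior$scale)
  f <- function(u) {
    .t_likelihood(stats::qcauchy(u, prior$location, prior$scale),
                  t, df, effective_n)
  }
  u_peak <- stats::pcauchy(t / sqrt(effective_n), prior$location,
                           prior$scale)
  .quad(f, ulo, uhi, splits = c(u_peak, 0.5))
}

#' Marginal likelihood of the t-statistic under an effect-size prior
#'
#' Computes `integral of T_df(t | sqrt(effective_n) * delta) * pi(delta)`
#' over the stated support, where `T_df(. | a)` is the noncentral t density
#' and `pi` is the Cauchy prior density, renormalized (truncated) to the
#' support when that is a finite interval. This is the building block of
#' every Bayes factor in the package.
#'
#' @param t Observed (pooled) t-statistic.
#' @param df Degrees of freedom.
#' @param effective_n Effective sample size `n1 * n2 / (n1 + n2)`.
#' @param prior A [cauchy_prior()].
#' @param support Length-2 numeric, the integration support; defaults to the
#'   full real line. Finite bounds truncate and renormalize the prior.
#' @return The marginal density (a nonnegative number) with attribute
#'   `"abs.error"`, a quadrature error bound.
#' @export
marginal_t_density <- function(t, df, effective_n, prior,
                               support = c(-Inf, Inf)) {
  .check_t_inputs(t, df, effective_n)
  prior <- .check_prior(prior)
  if (length(support) != 2 || !(support[1] < support[2])) {
    stop("support must be an increasing length-2 vector", call. = FALSE)
  }
  r <- .marginal_raw(t, df, effective_n, prior, support[1], support[2])
  mass <- stats::pcauchy(support[2], prior$location, prior$scale) -
    stats::pcauchy(support[1], prior$location, prior$scale)
  if (mass < 1e-12) {
    stop("prior mass on the support is numerically zero", call. = FALSE)
  }
  structure(r$value / mass, abs.error = r$error / mass)
}

bf_result <- function(bf01, numerical_error, model) {
  if (!is.finite(bf01) || bf01 <= 0) {
    stop("Bayes factor computation returned a non-positive value",
         call. = FALSE)
  }
  structure(
    list(bf01 = bf01, log_bf01 = log(bf01),
         numerical_error = numerical_error, model = model),
    class = "bf_result"
  )
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("%s model: BF01 = %.6g (log BF01 = %.4f, numerical error <= %.2g)\n",
              x$model$model, x$bf01, x$log_bf01, x$numerical_error))
  invisible(x)
}

#' JZS (point-null) Bayes factor from a t-statistic
#'
#' Bayes factor `BF01` for the precise null `H0: delta = 0` against
#' `H1: delta ~ Cauchy(location, scale)`:
#' `BF01 = T_df(t) / integral T_df(t | sqrt(n_delta) delta) pi(delta) ddelta`.
#' With `location = 0` this is the default JZS two-sample Bayes factor; a
#' nonzero location gives the informed point-null test.
#'
#' @inheritParams marginal_t_density
#' @return A `bf_result` with fields `bf01`, `log_bf01`, `numerical_error`
#'   and `model`.
#' @export
jzs_bf01 <- function(t, df, effective_n, prior = cauchy_prior()) {
  .check_t_inputs(t, df, effective_n)
  prior <- .check_prior(prior)
  m1 <- .marginal_raw(t, df, effective_n, prior, -Inf, Inf)
  m0 <- stats::dt(t, df)
  bf01 <- exp(log(m0) - log(m1$value))
  bf_result(bf01, bf01 * m1$error / m1$value,
            model = list(model = "jzs", prior = prior))
}

#' Overlapping-hypotheses (OH) Bayes factor
#'
#' Compares a narrow Cauchy prior on delta (the null, scale `r0`) against a
#' wider one (the alternative, scale `r1`); both hypotheses share support.
#' By transitivity of Bayes factors this equals the ratio of two point-null
#' Bayes factors, `BF01(r1) / BF01(r0)`, i.e. the ratio of the marginal
#' likelihoods under `Cauchy(0, r0)` and `Cauchy(0, r1)`. The recommended
#' default null scale is a tenth of the alternative scale.
#'
#' @inheritParams marginal_t_density
#' @param r1 Alternative prior scale (> 0).
#' @param r0 Null prior scale (> 0), default `r1 / 10`.
#' @return A `bf_result`.
#' @export
oh_bf01 <- function(t, df, effective_n, r1 = 1, r0 = r1 / 10) {
  .check_t_inputs(t, df, effective_n)
  if (!(r0 > 0 && r1 > 0)) stop("r0 and r1 must be > 0", call. = FALSE)
  m0 <- .marginal_raw(t, df, effective_n, cauchy_prior(0, r0), -Inf, Inf)
  m1 <- .marginal_raw(t, df, effective_n, cauchy_prior(0, r1), -Inf, Inf)
  bf01 <- exp(log(m0$value) - log(m1$value))
  err <- bf01 * (m0$error / m0$value + m1$error / m1$value)
  bf_result(bf01, err,
            model = list(model = "oh", r0 = r0, r1 = r1,
                         prior = cauchy_prior(0, r1)))
}

#' Non-overlapping-hypotheses (NOH) interval Bayes factor
#'
#' The interval-null Bayes factor for `H0: delta in (lower, upper)` against
#' `H1: delta outside (lower, upper)`, both under a common Cauchy prior on
#' delta truncated to the respective region:
#' `BF01 = [m(region) / P(region)] / [m(complement) / P(complement)]`
#' where `m(.)` integrates the noncentral-t likelihood against the prior and
#' `P(.)` is the prior mass. This is identical to the informed interval
#' Bayes factor obtained by shifting/truncating the Cauchy prior directly.
#'
#' @inheritParams marginal_t_density
#' @param region An [equivalence_region()] on the standardized-effect scale.
#' @return A `bf_result`.
#' @export
noh_bf01 <- function(t, df, effective_n, prior = cauchy_prior(),
                     region = equivalence_region(-0.1, 0.1)) {
  .check_t_inputs(t, df, effective_n)
  prior <- .check_prior(prior)
  region <- .check_region(region)
  if (region$scale != "standardized_effect") {
    stop("noh_bf01 needs a region on the standardized_effect scale",
         call. = FALSE)
  }
  parts <- .noh_marginals(t, df, effective_n, prior, region)
  bf01 <- exp(log(parts$m0) - log(parts$m1))
  bf_result(bf01, bf01 * (parts$err0 / parts$m0 + parts$err1 / parts$m1),
            model = list(model = "noh", prior = prior, region = region))
}

# normalized marginals inside / outside the region (shared with hybrid_bf01)
.noh_marginals <- function(t, df, effective_n, prior, region) {
  p_in <- stats::pcauchy(region$upper, prior$location, prior$scale) -
    stats::pcauchy(region$lower, prior$location, prior$scale)
  p_out <- 1 - p_in
  if (p_in < 1e-8 || p_out < 1e-8) {
    stop("degenerate region: prior mass ", signif(min(p_in, p_out), 3),
         " on one side", call. = FALSE)
  }
  m_in <- .marginal_raw(t, df, effective_n, prior, region$lower, region$upper)
  m_lo <- .marginal_raw(t, df, effective_n, prior, -Inf, region$lower)
  m_hi <- .marginal_raw(t, df, effective_n, prior, region$upper, Inf)
  list(m0 = m_in$value / p_in,
       m1 = (m_lo$value + m_hi$value) / p_out,
       err0 = m_in$error / p_in,
       err1 = (m_lo$error + m_hi$error) / p_out)
}

#' Hybrid (point-mass plus interval) Bayes factor
#'
#' Mixture null: with prior probability `pi0` the effect is exactly zero,
#' with `1 - pi0` it follows the truncated prior inside the equivalence
#' region; the alternative is the prior truncated outside the region.
#' `BF01 = (pi0 * T_df(t) + (1 - pi0) * m0_NOH) / m1_NOH`.
#' `pi0 = 0` recovers the NOH model; `pi0 = 1` compares the point null
#' against the outside-region alternative.
#'
#' @inheritParams noh_bf01
#' @param pi0 Prior probability of an exact nil effect, in `[0, 1]`.
#' @return A `bf_result`.
#' @export
hybrid_bf01 <- function(t, df, effective_n, prior = cauchy_prior(),
                        region = equivalence_region(-0.1, 0.1), pi0 = 0.5) {
  .check_t_inputs(t, df, effective_n)
  prior <- .check_prior(prior)
  region <- .check_region(region)
  if (!(pi0 >= 0 && pi0 <= 1)) stop("pi0 must be in [0, 1]", call. = FALSE)
  if (region$scale != "standardized_effect") {
    stop("hybrid_bf01 needs a region on the standardized_effect scale",
         call. = FALSE)
  }
  parts <- .noh_marginals(t, df, effective_n, prior, region)
  num <- pi0 * stats::dt(t, df) + (1 - pi0) * parts$m0
  bf01 <- exp(log(num) - log(parts$m1))
  err <- bf01 * ((1 - pi0) * parts$err0 / num + parts$err1 / parts$m1)
  bf_result(bf01, err,
            model = list(model = "hybrid", prior = prior, region = region,
                         pi0 = pi0))
}
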