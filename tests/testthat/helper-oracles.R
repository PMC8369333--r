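# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementations under test.

# Welch statistic straight from the textbook formulas
oracle_welch <- function(n1, m1, s1, n2, m2, s2) {
  se2 <- s1^2 / n1 + s2^2 / n2
  list(t = (m1 - m2) / sqrt(se2),
       df = se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1)))
}

# noncentral-t likelihood of delta (same mathematical object, used by the
# oracles below through R's integrate/Monte Carlo rather than the package's
# split quadrature)
oracle_lik <- function(delta, t, df, nd) {
  suppressWarnings(dt(t, df, ncp = sqrt(nd) * delta))
}

# NOH interval Bayes factor coded directly from the double-ratio form:
# [m(in)/P(in)] / [m(out)/P(out)], single integrate() calls, no splitting
oracle_noh_double_ratio <- function(t, df, nd, location, scale, lower, upper) {
  f <- function(d) oracle_lik(d, t, df, nd) * dcauchy(d, location, scale)
  p_in <- pcauchy(upper, location, scale) - pcauchy(lower, location, scale)
  m_in <- integrate(f, lower, upper, rel.tol = 1e-11)$value
  m_out <- integrate(f, -Inf, lower, rel.tol = 1e-11)$value +
    integrate(f, upper, Inf, rel.tol = 1e-11)$value
  (m_in / p_in) / (m_out / (1 - p_in))
}

# dense-grid trapezoid evaluation of the full-line marginal
oracle_grid_marginal <- function(t, df, nd, location, scale,
                                 half_width = 8, points = 100001) {
  d <- seq(location - half_width, location + half_width, length.out = points)
  y <- oracle_lik(d, t, df, nd) * dcauchy(d, location, scale)
  sum((y[-1] + y[-points]) / 2 * diff(d))
}

# Monte-Carlo marginal: average likelihood over prior draws
oracle_mc_marginal <- function(t, df, nd, location, scale, m, seed) {
  set.seed(seed)
  draws <- rcauchy(m, location, scale)
  vals <- oracle_lik(draws, t, df, nd)
  list(value = mean(vals), se = sd(vals) / sqrt(m))
}

# exhaustive shortest-interval search over all grid endpoint pairs with at
# least `mass` enclosed (two-pointer sweep over the grid CDF)
oracle_hpd_bruteforce <- function(g, mass = 0.95) {
  x <- g$delta
  cdf <- g$cdf
  best <- c(-Inf, Inf)
  j <- 1
  for (i in seq_along(x)) {
    while (j <= length(x) && cdf[j] - cdf[i] < mass) j <- j + 1
    if (j > length(x)) break
    if (x[j] - x[i] < best[2] - best[1]) best <- c(x[i], x[j])
  }
  best
}

make_summary <- function(n1, m1, s1, n2, m2, s2) {
  two_sample_summary(n1, m1, s1, n2, m2, s2)
}
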