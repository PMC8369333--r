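test_that("cauchy_prior validates and rejects non-Cauchy t priors", {
  p <- cauchy_prior(0, 1)
  expect_equal(p$location, 0)
  expect_error(cauchy_prior(0, -1), "scale")
  expect_error(cauchy_prior(0, 1, nu0 = 3), "nu0")
})

test_that("marginal_t_density matches Monte-Carlo integration", {
  m <- marginal_t_density(1.5, 18, 5, cauchy_prior(0, 1))
  or <- oracle_mc_marginal(1.5, 18, 5, 0, 1, m = 2e5, seed = 99)
  expect_lt(abs(as.numeric(m) - or$value), 3 * or$se)
  expect_lt(attr(m, "abs.error"), 1e-6)
})

test_that("marginal over a tiny interval degenerates to the central t density", {
  c0 <- 1e-6
  m <- marginal_t_density(0.7, 24, 6, cauchy_prior(0, 1),
                          support = c(-c0, c0))
  expect_equal(as.numeric(m), dt(0.7, 24), tolerance = 1e-6)
})

test_that("truncated marginals are additive to the full-line marginal", {
  t <- 1.1; df <- 38; nd <- 10
  prior <- cauchy_prior(0, 1 / sqrt(2))
  c0 <- 0.3
  full <- as.numeric(marginal_t_density(t, df, nd, prior))
  p_in <- pcauchy(c0, 0, prior$scale) - pcauchy(-c0, 0, prior$scale)
  inside <- as.numeric(marginal_t_density(t, df, nd, prior,
                                          support = c(-c0, c0))) * p_in
  lo <- as.numeric(marginal_t_density(t, df, nd, prior,
                                      support = c(-Inf, -c0)))
  hi <- as.numeric(marginal_t_density(t, df, nd, prior,
                                      support = c(c0, Inf)))
  outside <- (lo * pcauchy(-c0, 0, prior$scale) +
                hi * pcauchy(c0, 0, prior$scale, lower.tail = FALSE))
  expect_equal(inside + outside, full, tolerance = 1e-8)
})

test_that("jzs_bf01 matches a dense-grid quadrature oracle and its symmetries", {
  # data at the null are evidence for the null
  b0 <- jzs_bf01(0, 98, 25, cauchy_prior(0, 1))
  expect_gt(b0$bf01, 1)

  # independent trapezoid evaluation of the marginal, 6 significant digits
  b <- jzs_bf01(2.1, 58, 15, cauchy_prior(0, 1 / sqrt(2)))
  oracle <- dt(2.1, 58) /
    oracle_grid_marginal(2.1, 58, 15, 0, 1 / sqrt(2))
  expect_equal(b$bf01, oracle, tolerance = 1e-6)

  # symmetry in t for location-0 priors
  bp <- jzs_bf01(1.7, 40, 9, cauchy_prior(0, 1))
  bm <- jzs_bf01(-1.7, 40, 9, cauchy_prior(0, 1))
  expect_equal(bp$bf01, bm$bf01, tolerance = 1e-10)

  # bf01 = exp(log_bf01) by construction
  expect_equal(bp$bf01, exp(bp$log_bf01))
})

test_that("jzs_bf01 grows with the prior scale at fixed data", {
  scales <- c(0.3, 1 / sqrt(2), 1, sqrt(2), 3)
  bfs <- vapply(scales, function(g) {
    jzs_bf01(1.4, 78, 20, cauchy_prior(0, g))$bf01
  }, 0)
  expect_true(all(diff(bfs) > 0))
})

test_that("oh_bf01 equals the direct marginal ratio and its stated limits", {
  # identical hypotheses: BF exactly 1
  expect_equal(oh_bf01(2.3, 30, 8, r1 = 0.8, r0 = 0.8)$bf01, 1,
               tolerance = 1e-12)

  # transitivity identity: ratio of the two full-line marginals
  cases <- list(c(2.1, 58, 15, 1, 0.1), c(-0.4, 18, 5, sqrt(2), 0.2),
                c(3.3, 120, 30, 1 / sqrt(2), 1 / sqrt(2) / 10))
  for (cs in cases) {
    b <- oh_bf01(cs[1], cs[2], cs[3], r1 = cs[4], r0 = cs[5])
    m0 <- as.numeric(marginal_t_density(cs[1], cs[2], cs[3],
                                        cauchy_prior(0, cs[5])))
    m1 <- as.numeric(marginal_t_density(cs[1], cs[2], cs[3],
                                        cauchy_prior(0, cs[4])))
    expect_equal(b$bf01, m0 / m1, tolerance = 1e-8)
  }

  # r0 -> 0 recovers the point-null JZS Bayes factor
  oh <- oh_bf01(1.9, 58, 15, r1 = 1, r0 = 1e-6)
  jzs <- jzs_bf01(1.9, 58, 15, cauchy_prior(0, 1))
  expect_equal(oh$bf01, jzs$bf01, tolerance = 1e-4)
})

test_that("noh_bf01 equals the independently coded double-ratio to 1e-8", {
  cases <- list(
    list(t = 0.8, df = 198, nd = 50, loc = 0, scale = 1, l = -0.1, u = 0.1),
    list(t = -2.6, df = 38, nd = 10, loc = 0, scale = 1 / sqrt(2),
         l = -0.05, u = 0.05),
    list(t = 1.2, df = 58, nd = 15, loc = 0.2, scale = sqrt(2),
         l = -0.15, u = 0.3)
  )
  for (cs in cases) {
    b <- noh_bf01(cs$t, cs$df, cs$nd, cauchy_prior(cs$loc, cs$scale),
                  equivalence_region(cs$l, cs$u))
    oracle <- oracle_noh_double_ratio(cs$t, cs$df, cs$nd, cs$loc, cs$scale,
                                      cs$l, cs$u)
    expect_equal(b$bf01, oracle, tolerance = 1e-8)
  }
})

test_that("noh_bf01 matches a Monte-Carlo split-draw oracle", {
  t <- 0.8; df <- 198; nd <- 50
  set.seed(1234)
  draws <- rcauchy(2e5, 0, 1)
  lik <- oracle_lik(draws, t, df, nd)
  inside <- abs(draws) < 0.1
  mc <- mean(lik[inside]) / mean(lik[!inside])
  b <- noh_bf01(t, df, nd, cauchy_prior(0, 1), equivalence_region(-0.1, 0.1))
  se <- mc * (sd(lik[inside]) / sqrt(sum(inside)) / mean(lik[inside]) +
                sd(lik[!inside]) / sqrt(sum(!inside)) / mean(lik[!inside]))
  expect_lt(abs(b$bf01 - mc), 4 * se)
})

test_that("noh_bf01 limits, widening monotonicity and degenerate regions", {
  prior <- cauchy_prior(0, 1)
  # c -> 0 approaches the point-null JZS Bayes factor
  b <- noh_bf01(1.2, 58, 15, prior, equivalence_region(-1e-5, 1e-5))
  expect_equal(b$bf01, jzs_bf01(1.2, 58, 15, prior)$bf01, tolerance = 1e-4)

  # widening the region increases BF01 at fixed data
  widths <- c(0.05, 0.1, 0.15, 0.3)
  bfs <- vapply(widths, function(c0) {
    noh_bf01(0.9, 98, 25, prior, equivalence_region(-c0, c0))$bf01
  }, 0)
  expect_true(all(diff(bfs) > 0))

  # symmetry under t -> -t for symmetric priors and regions
  expect_equal(
    noh_bf01(1.3, 38, 10, prior, equivalence_region(-0.1, 0.1))$bf01,
    noh_bf01(-1.3, 38, 10, prior, equivalence_region(-0.1, 0.1))$bf01,
    tolerance = 1e-9)

  expect_error(noh_bf01(1, 38, 10, prior, equivalence_region(1e9, 2e9)),
               "degenerate region")
  expect_error(
    noh_bf01(1, 38, 10, prior,
             equivalence_region(-0.1, 0.1, "raw_difference")),
    "standardized_effect")
})

test_that("noh_bf01 accumulates evidence for a true interval null as n grows", {
  prior <- cauchy_prior(0, 1 / sqrt(2))
  region <- equivalence_region(-0.1, 0.1)
  null_setting <- builtin_settings()$null
  med <- vapply(c(20, 80, 320), function(n) {
    bfs <- vapply(1:40, function(r) {
      d <- simulate_dataset(null_setting, n, seed = 5000 + 13 * n + r)
      tt <- pooled_t(summarize(d$group1, d$group2))
      noh_bf01(tt$t, tt$df, tt$effective_n, prior, region)$bf01
    }, 0)
    median(bfs)
  }, 0)
  expect_true(all(diff(med) > 0))
})

test_that("hybrid_bf01 interpolates linearly between its stated limits", {
  prior <- cauchy_prior(0, 1)
  region <- equivalence_region(-0.1, 0.1)
  t <- 1.2; df <- 58; nd <- 15

  noh <- noh_bf01(t, df, nd, prior, region)
  h0 <- hybrid_bf01(t, df, nd, prior, region, pi0 = 0)
  expect_equal(h0$bf01, noh$bf01, tolerance = 1e-12)

  # pi0 = 1: point-null marginal over the NOH alternative marginal
  h1 <- hybrid_bf01(t, df, nd, prior, region, pi0 = 1)
  p_in <- pcauchy(0.1, 0, 1) - pcauchy(-0.1, 0, 1)
  m1 <- (as.numeric(marginal_t_density(t, df, nd, prior,
                                       support = c(-Inf, -0.1))) *
           pcauchy(-0.1, 0, 1) +
         as.numeric(marginal_t_density(t, df, nd, prior,
                                       support = c(0.1, Inf))) *
           (1 - pcauchy(0.1, 0, 1))) / (1 - p_in)
  expect_equal(h1$bf01, dt(t, df) / m1, tolerance = 1e-8)

  # numerator is linear in pi0
  h5 <- hybrid_bf01(t, df, nd, prior, region, pi0 = 0.5)
  expect_equal(h5$bf01, 0.5 * h0$bf01 + 0.5 * h1$bf01, tolerance = 1e-10)

  expect_error(hybrid_bf01(t, df, nd, prior, region, pi0 = 1.2), "pi0")
})

test_that("Savage-Dickey identity links the grid posterior to jzs_bf01", {
  cases <- list(c(1.2, 58, 15, 1 / sqrt(2)), c(0, 18, 5, 1),
                c(-2.4, 398, 100, sqrt(2)))
  for (cs in cases) {
    prior <- cauchy_prior(0, cs[4])
    g <- posterior_grid(cs[1], cs[2], cs[3], prior)
    at0 <- which(g$delta == 0)
    ratio <- g$posterior_density[at0] / g$prior_density[at0]
    b <- jzs_bf01(cs[1], cs[2], cs[3], prior)
    expect_equal(ratio, b$bf01, tolerance = 1e-4)
  }
})
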