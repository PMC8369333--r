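---
title: "Bayesian equivalence testing for two-sample designs: models, calibration and region selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian equivalence testing for two-sample designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bayesequiv)
```

## The model

Both groups are assumed normal with a common standard deviation,
$Y_{1i} \sim \mathcal N(\mu_1, \sigma^2)$,
$Y_{2j} \sim \mathcal N(\mu_2, \sigma^2)$, and inference targets the
standardized effect size $\delta = (\mu_1 - \mu_2)/\sigma$. Under the
Jeffreys prior $p(\sigma^2) \propto 1/\sigma^2$ and any proper prior
$\pi(\delta)$, the marginal likelihood of the observed pooled $t$-statistic
is

$$m(\pi) = \int T_\nu\!\left(t \mid \sqrt{n_\delta}\,\delta\right)
  \pi(\delta)\, d\delta,$$

where $T_\nu(\cdot \mid a)$ is the noncentral $t$ density,
$\nu = n_1 + n_2 - 2$ and $n_\delta = n_1 n_2/(n_1+n_2)$. Everything in the
package — all four Bayes factors and the posterior
$p(\delta \mid t) \propto T_\nu(t \mid \sqrt{n_\delta}\delta)\,\pi(\delta)$
— is built from this one integrand, with $\pi$ a Cauchy
$C(\mu_\delta, \gamma)$ distribution.

**Which $t$?** The common-$\sigma$ model above underlies the marginal
$t$-likelihood, so the Bayes factors and the posterior condition on the
*pooled* (Student) statistic with $\nu = n_1+n_2-2$. The literature often
frames the two-sample problem in terms of Welch's test, but never specifies
a Welch-based marginal likelihood for these models; feeding a Welch
statistic into a common-$\sigma$ marginal would be internally inconsistent.
`welch_t()` is therefore used only for descriptive output and for the
frequentist `tost()`, which is genuinely Welch-based. With equal group
sizes the two statistics coincide (only the degrees of freedom differ), so
the simulation study, which uses equal $n$, is unaffected by this choice.

**Prior family.** The $t_{\nu_0}$ effect-size prior is supported for
$\nu_0 = 1$ only, where it *is* the Cauchy; `cauchy_prior()` rejects other
$\nu_0$ rather than silently approximating. Conventional scales are
$\gamma = 1/\sqrt 2$ (medium), $1$ (wide), $\sqrt 2$ (ultrawide); they are
study conditions, not tuning knobs.

## The four Bayes factors

* **JZS point-null** (`jzs_bf01()`): $BF_{01} = T_\nu(t)/m(\pi)$, the
  default Bayesian $t$-test; a nonzero prior location gives the informed
  variant.
* **Overlapping hypotheses** (`oh_bf01()`): null $\delta \sim C(0, r_0)$
  versus alternative $\delta \sim C(0, r_1)$, $r_0 = r_1/10$ by default. By
  transitivity $BF_{01}^{OH} = BF_{01}(r_1)/BF_{01}(r_0) = m(r_0)/m(r_1)$.
  Because the hypotheses share support, this BF is not consistent: it
  converges to a finite value, which is why the model has near-zero type I
  error but very low power.
* **Non-overlapping hypotheses** (`noh_bf01()`): null
  $\delta \in (l, u)$, alternative $\delta \notin (l, u)$, both under the
  common prior truncated to their region:
  $BF_{01} = \frac{m_{(l,u)}/P_\pi(l,u)}{m_{(l,u)^c}/P_\pi((l,u)^c)}$.
  This equals the informed interval Bayes factor obtained by truncating the
  Cauchy prior directly; the test suite keeps an independently coded copy
  of the double ratio and requires agreement to $10^{-8}$ relative error.
  Under a true $\delta$ inside the region, $BF_{01}$ grows without bound as
  $n \to \infty$ (and falls to 0 for $\delta$ outside): the convention here
  is always that indices read "null first", $BF_{01} = m_0/m_1$.
* **Hybrid** (`hybrid_bf01()`): the null is a mixture
  $\pi_0 \mathbb 1_{\{0\}} + (1-\pi_0)\,\pi|_{(l,u)}$, so
  $BF_{01}^{hyb} = \bigl(\pi_0 T_\nu(t) + (1-\pi_0) m_0^{NOH}\bigr) /
  m_1^{NOH}$. It recovers the NOH model at $\pi_0 = 0$. Because an exact
  nil effect is rarely credible in biomedical settings and $\pi_0$ cannot
  realistically be elicited, the hybrid model is implemented and tested but
  excluded from the default simulation grid.

**Decision rule** (`bf_decision()`): accept the null at $BF_{01} \ge 3$,
reject at $BF_{01} \le 1/3$ (equivalently $BF_{10} \ge 3$, at least
moderate evidence on conventional scales), inconclusive otherwise. Boundary
values count toward the decisive side so the rule is deterministic; the
threshold is a parameter (`bf_threshold`).

## ROPE decisions

`posterior_grid()` evaluates the normalized posterior of $\delta$ on a
dense grid spanning at least $\hat\delta \pm 8$ posterior standard
deviations around the MLE $\hat\delta = t/\sqrt{n_\delta}$ (the grid always
contains 0, so the Savage–Dickey ratio can be read off directly). Three
intervals feed `rope_decision()`:

* `hpd_interval()` — shortest interval with the target mass (default
  0.95), found by bisection on the density threshold with interpolated
  endpoints; ties at flat density levels resolve toward the shorter
  interval.
* `full_interval()` — the "full posterior". A literal 100% interval under
  a Cauchy prior is the whole real line, which would make the full-ROPE
  test vacuous, so the default is the central $1 - 10^{-6}$ mass interval;
  a draw-based mode (range of `draws` posterior draws, default 5000)
  matches the practice of reading the full posterior off an MCMC sample.
  Both $\varepsilon$ and the mode are configurable.
* `support_interval()` — $\{\delta : p(\delta\mid t)/p(\delta) > k\}$,
  default $k = 1$: the values the data corroborated. The set is an
  interval here (the ratio is unimodal); it can be empty, and an empty
  interval maps to *inconclusive* — an empty set is vacuously inside any
  region, and accepting equivalence on no corroborated value would be
  absurd.

Containment is closed (an interval endpoint exactly on the region boundary
counts as inside — an interval like $[-0.05, 0.04]$ is inside
$[-0.05, 0.05]$), rejection requires strict separation, and everything else
is inconclusive.

## The simulation study

`builtin_settings()` defines the four data-generating conditions: a null
(both groups standard normal) and three effects,

| label  | group 1            | group 2            | true $\delta$ |
|--------|--------------------|--------------------|---------------|
| null   | N(0, SD 1)         | N(0, SD 1)         | 0             |
| small  | N(2.89, SD 1.84)   | N(3.50, SD 1.56)   | −0.357        |
| medium | N(254.08, SD 2.36) | N(255.84, SD 3.04) | −0.647        |
| large  | N(15.01, SD 3.4)   | N(19.91, SD 5.8)   | −1.031        |

The second parameter of every normal is a **standard deviation**: the
effect sizes above only reproduce when those numbers are squared inside
$\delta = (\mu_1-\mu_2)/\sqrt{(\sigma_1^2+\sigma_2^2)/2}$, which fixes the
interpretation. The effect settings are mildly heteroscedastic; the tests
tolerate this the way practice does, and the common-$\sigma$ machinery is
applied regardless.

The default grid (`simulation_design()`) crosses these settings with
per-group $n = 10, 20, \ldots, 200$, prior scales
$\{1/\sqrt2, 1, \sqrt2\}$, regions $[-0.05, 0.05]$, $[-0.1, 0.1]$,
$[-0.15, 0.15]$ and six methods, at 1000 replicates per cell. Within a
cell, every method and region is evaluated on the *same* simulated
datasets and the same posterior grid: per-replicate seeds derive only from
(master seed, setting, $n$, replicate), so results are identical whatever
order cells run in, and method comparisons are paired. A type I error is a
rejection under the null setting; a type II error is an *acceptance* under
an effect; power counts rejections under an effect; inconclusive outcomes
enter no error rate, so power + type II + inconclusive = 1 in every effect
cell. Each rate is reported with its binomial Monte-Carlo standard error,
and the total error rate is the type I plus type II sum.

What the generator does **not** emulate: non-normal or contaminated data,
unequal group sizes, dependence between observations, and unequal
variances under the null. Passing tests therefore certify the methods'
operating characteristics under the stated normal conditions, not
robustness beyond them.

**Problem sizes in the shipped tests.** The packaged test-suite and
acceptance script run desk-scale versions of the study: 200–500 replicates
per checked cell and a 1001-point posterior grid for simulation cells
(the user-facing `posterior_grid()` default is 4001 points; at $n = 170$
the two resolutions produce identical decisions on every checked
replicate). All stochastic checks carry tolerances of three Monte-Carlo
standard errors.

## Numerical choices

* **Quadrature.** Marginals are integrated in the prior-CDF variable
  $u = F_\pi(\delta)$, which maps any prior scale — including
  near-point-mass priors — onto $(0, 1)$ with bounded integrand, and the
  domain is split at the image of the likelihood peak $\hat\delta$ so the
  adaptive rule never misses it. Piecewise `integrate()` runs at
  `rel.tol = 1e-10`; a computation is rejected only when the achieved
  error bound exceeds $10^{-4}$ of the integral (plus $10^{-12}$
  absolute), and the achieved bound is propagated into every
  `bf_result$numerical_error`.
* **Ratios in log space.** $BF_{01} = \exp(\log m_0 - \log m_1)$; the
  marginal integrands themselves stay comfortably inside double range for
  this problem class, so the quadrature itself runs in linear space.
* **Degenerate regions.** A region carrying less than $10^{-8}$ prior mass
  on either side raises an explicit error rather than returning a
  meaningless ratio; per-replicate numerical failures in a simulation cell
  abort it unless a failure budget is configured.
* **Grid posterior instead of MCMC.** The posterior is one-dimensional, so
  a deterministic grid plus inverse-CDF sampling (`sample_posterior()`)
  reproduces what an MCMC sample of the same posterior would provide,
  without tuning or Monte-Carlo error in the intervals themselves. Draw
  mode exists for users who want the sampling variability of the
  draw-based workflow.

## Region selection

`select_design()` is a pure function of a results table and
`selection_criteria()`: it reads the type I error of each candidate
(method, region) pair off the null cells and the power off the chosen
effect cells at the matched sample size (the largest simulated
$n \le$ the attainable $n$) and prior, keeps the pairs with
$\hat\alpha \le \alpha_{max}$ and $\widehat{power} \ge power_{min}$, and
ranks narrowest region first, then smallest $\hat\alpha$, then largest
power — a narrower region makes the equivalence statement more precise.
Admissibility uses point estimates; `conservative = TRUE` demands
$\hat\alpha + 2\,SE \le \alpha_{max}$ and
$\widehat{power} - 2\,SE \ge power_{min}$, which is advisable for
reduced-replicate tables. The prior is deliberately *not* ranked over: one
call, one prior scale. `select_by_total_error()` replaces the two
constraints with $\hat\alpha + \hat\beta \le total_{max}$, which prices a
false positive and a false negative equally — often unrealistic, and said
so in its documentation.

When no pair is admissible the recommendation reports `chosen: none`
together with the nearest miss. This matters in practice: calibrated
power frequently sits *on* a round requirement like 80% (in the packaged
end-to-end check, the 95%-HPD-ROPE power estimate at $n = 170$ with the
$[-0.05, 0.05]$ region is within Monte-Carlo error of the 0.80
requirement), and a point-estimate admissibility rule will then flip with
the table's Monte-Carlo noise. The nearest-miss diagnostics and the
conservative mode are the two honest ways to read such a table.

## Known limitations

* The full-ROPE test under the $1-10^{-6}$ proxy is extremely
  conservative: its interval is wide enough that rejections are rare even
  for moderate true effects, so its power against the small effect is near
  zero at every simulated $n$. The draw-based mode is less extreme but
  shares the behaviour; users wanting power from interval methods should
  use the 95% HPD or support variants.
* The $k=1$ support interval is narrower than the 95% HPD at small $n$
  (hence more type I errors there) but wider at large $n$ — its half-width
  grows like $\sigma\sqrt{2\log(\text{peak}/\text{prior})}$ against the
  HPD's $1.96\sigma$ — so at large $n$ its power falls slightly below the
  95% HPD's.
* Only equivalence regions are implemented; one-sided
  superiority/inferiority regions, raw-scale posteriors for ROPE tests on
  mean differences, paired designs and non-Cauchy effect-size priors are
  out of scope.
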