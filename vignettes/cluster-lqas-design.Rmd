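---
title: "Designing cluster LQAS surveys: models, choices, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing cluster LQAS surveys: models, choices, and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clqas)
```

## The classification problem

An LQAS survey samples $n$ subjects from a supervision area, counts
successes $X$, and declares the area *acceptable* when $X > d$. The
design is pinned down by a threshold couplet $p_l < p_u$ and risk caps:

$$P(X \le d \mid p \ge p_u) \le \alpha, \qquad
  P(X > d \mid p \le p_l) \le \beta.$$

Both constraints bind at the boundary of the grey region, so all
computations in this package evaluate $\alpha$ at $p_u$ and $\beta$ at
$p_l$. Under simple random sampling $X \sim \mathrm{Binomial}(n, p)$
and `find_srs_design()` scans $n = 1, 2, \dots$ for the first size
admitting a feasible rule.

Two-stage cluster sampling ($k$ clusters, $m$ subjects each, clusters
drawn with probability proportional to size so the design is
self-weighting) changes the distribution of $X$. Cluster coverages
$p_j$ scatter around $p$ with standard deviation $\sigma$; equivalently
the intraclass correlation is $\rho = \sigma^2 / \{p(1-p)\}$. The
package implements the three design-phase models in use:

* **binomial-scaled**: $p_j = B/\eta$, $B \sim \mathrm{Binomial}(\eta, p)$,
  with $\eta$ the nearest integer to $p(1-p)/\sigma^2 = 1/\rho$;
* **beta-binomial**: $p_j \sim \mathrm{Beta}$ with mean $p$ and
  intraclass correlation $\rho$ (shapes $p(1-\rho)/\rho$,
  $(1-p)(1-\rho)/\rho$);
* **quasi-binomial**: no distribution for $p_j$; $X$ is judged on the
  effective scale $X^* \sim \mathrm{Binomial}(n^*, p)$ with
  $n^* = n/D$ and design effect $D = 1 + (m-1)\rho$.

In all cases $X_j \mid p_j \sim \mathrm{Binomial}(m, p_j)$ and
negative intraclass correlation (within-cluster *dissimilarity*) is out
of scope — it is not a feature of monitoring-and-evaluation surveys.

## Exact evaluation instead of simulation

The survey total under the two distributional models is a sum of $k$
iid cluster counts, so its law is the $k$-fold convolution of the
cluster pmf (`convolve_iid()`, iterated direct convolution — supports
stay below a few thousand points, so FFT machinery would buy nothing;
accumulated drift beyond $10^{-12}$ is renormalized). The
binomial-scaled coverage distribution has only $\eta + 1$ support
points, so its cluster pmf is a finite mixture and exact; the original
method selected rules by simulation, which `pezzoli_design(mode =
"simulate")` retains for fidelity checks, but exact evaluation is the
default and the two modes agree on the returned geometry at
$10^5$ draws per threshold for the vaccination couplets (a seeded test
asserts this). Monte-Carlo standard errors of any simulated risk $r$
are reported as $\sqrt{r(1-r)/n_{\mathrm{sims}}}$, and the simulation
of $\alpha$ and $\beta$ uses independent draw sets — no common random
numbers — matching how such studies are reported.

## Clustering resolved per threshold

A single specification (`clustering_spec()`) may fix $\sigma$, fix
$\rho$, or give $\rho(p)$ as a function or interpolated grid (linear
interpolation, flat extrapolation; any upstream smoother can populate
the grid — the package deliberately does not commit to one). Every
evaluation resolves the specification *at the coverage being
evaluated*: with $\sigma$ fixed, $\rho$ (and $\eta$) differ between
$p_l$ and $p_u$; with $\rho$ fixed, $\sigma$ differs. This is exactly
the cross-parameterization exercise behind the published design
comparisons, and it is why a design's record carries
$(\rho_l, \rho_u, \sigma_l, \sigma_u)$. A specification is invalid at
$p$ when $\sigma^2 > p(1-p)$ (the implied $\rho$ would exceed 1); such
points raise a classed error naming the offending coverage.

## Rounding and scale conventions

Three numerical conventions matter and are applied uniformly:

* **Nearest-integer, halves away from zero** for $\eta$, $n/D$ and
  $d/D$. This convention reproduces the published effective-scale rows
  exactly (e.g. $n = 80$, $d = 66$, $\rho = .11$, $m = 10$ gives
  $D = 1.99$, $n^* = 40$, $d^* = 33$ and risks $.100/.096$, identical
  to the SRS $(40, 33)$ evaluation).
* **Success vs failure scale.** The framework counts successes, but
  nutrition surveys state rules as a maximum case count. A failure
  rule $d_f$ converts exactly to $d = n - d_f - 1$ for the
  distribution-based models; for the quasi-binomial model rounding
  does not commute with that conversion, so `scale = "failures"`
  rounds the case threshold itself ($d_f/D$) and evaluates the failure
  count on the effective scale. The classic 33×6 design with case rule
  13 at $\rho = .1$ gives $D = 1.5$, effective size 132, effective
  threshold 9, and population risk $P\{Y \le 9 \mid
  \mathrm{Binomial}(132, .10)\} = .139$.
* **Smallest feasible rule.** Risk curves are monotone in $d$, so the
  feasible set is an interval; searches return its lower end and attach
  the full interval. Published tables occasionally print an interior
  point — the 80-subject effective-scale design above admits both 65
  and 66 (identical risks because their effective images coincide); we
  return 65 and the interval $[65, 66]$. Equality checks against
  published rules therefore target achieved risks at the printed
  geometry, not the printed $d$ itself.

Search caps default to $n \le 10^4$ (SRS scan), $k \le 2000$ and
$m \le 500$; impossible targets fail fast with a classed infeasibility
error rather than looping. A search that succeeds with a single
cluster warns, since a real survey cannot estimate clustering from
$k = 1$.

## Estimating clustering from published summaries

Reports give the estimated coverage $\hat p$ and the standard
deviation $s$ of *estimated* cluster coverages $\hat p_j = X_j/m$.
Since each $\hat p_j$ carries binomial noise $p_j(1-p_j)/m$, $s$
systematically overstates $\sigma$; the moment correction

$$\hat\sigma^2 = \frac{m s^2 - \hat p(1-\hat p)}{m - 1}$$

removes it, and is truncated at zero when within-cluster noise exceeds
the observed spread. Two design choices here:

* Rows reporting a standard error of $\hat p$ instead of $s$ are
  converted by $s = \mathrm{se}\sqrt{k}$ — the standard error of a
  $k$-cluster mean is the cluster-level standard deviation over
  $\sqrt{k}$.
* The output carries both the truncated estimate (never negative, with
  a `truncated` flag so "no clustering observed" is distinguishable
  from "truncated") and the raw moment estimate `sigma2_raw`. The raw
  column exists because truncation biases any *pooled* mean upward:
  $E(\hat\sigma^2_{\mathrm{raw}}) = \sigma^2 +
  \mathrm{Var}(\hat p)/(m-1)$, which is nearly unbiased at survey
  scale, whereas the truncated mean overshoots noticeably whenever
  $\sigma^2$ is small against $p(1-p)/m$. At a typical geometry
  ($k = m = 10$, $p = .8$, $\rho = .1$) the truncation plus finite-$k$
  bias is about three standard errors of a 2000-area mean — visible,
  and worth knowing before pooling truncated estimates.

## What the synthetic generator does and does not emulate

`simulate_survey_summaries()` draws complete two-stage surveys (latent
$p_j$ from the chosen model, binomial cluster counts) and reduces them
to the published summary format. It emulates the *sampling* structure
of real summary tables: estimation noise in $\hat p_j$, finite $k$,
identical geometry across areas. It does not emulate features real
collections show: coverage varying across areas, clustering varying
with coverage, unequal cluster sizes, non-response, or reporting
idiosyncrasies. Passing recovery tests therefore demonstrate that the
estimator chain is correct under its own model assumptions — not that
fixed-$\sigma$ or fixed-$\rho$ is the right description of any field
setting. Indeed the historical data analyses this toolkit accompanies
found *both* parameters declining with coverage, which is why
`clustering_spec()` accepts a $\rho(p)$ profile and `oc_curve()`
re-resolves it at every grid point; the external per-area datasets
behind those analyses are not redistributed here, so the
coverage-varying machinery is exercised on synthetic profiles instead.

## Problem sizes used in the checks

The test suite evaluates exact designs up to $n = 550$ (convolutions
of length a few hundred), runs the distributional comparison at 2,000
draws per cell with exact pmfs as the noiseless reference, uses
$10^5$-draw total-variation checks for the samplers, and 2,000-area
recovery studies for the estimator — sizes chosen so the whole suite
completes in well under a minute per file while leaving Monte-Carlo
margins of at least three standard errors.

## Known limitations

* The quasi-binomial model is defined only through its effective-scale
  evaluation; different published analyses have evidently rounded
  through different paths, and a handful of published simulation cells
  for the fixed-$\sigma$ quasi-binomial setting are not reproducible
  under any single rounding convention we tried. The convention here
  (round $n/D$ and $d/D$, halves away from zero, on the scale the rule
  is stated on) reproduces every published effective-scale *design*
  row exactly.
* Published achieved risks for the beta-binomial designs were
  simulation estimates; exact convolution lands within one
  Monte-Carlo standard error of them, and tests compare at that
  resolution rather than pretending three printed decimals are exact.
* Sequential designs, unequal sampling weights, negative intraclass
  correlation, and surveys that sample supervision areas (rather than
  clusters within one area) are out of scope.
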