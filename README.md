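# clqas — cluster sampling designs for LQAS surveys

Lot quality assurance sampling (LQAS) classifies a supervision area as
having acceptable or unacceptable coverage of a health indicator
(vaccination, nutrition, ...) by comparing the number of successes *X*
in a sample of size *n* against a decision rule *d*. The design
parameters are a threshold couplet *p_l* < *p_u* and risk caps
(α, β):

    P(X ≤ d | p ≥ p_u) ≤ α        (provider risk)
    P(X > d | p ≤ p_l) ≤ β        (population risk)

Field teams rarely draw simple random samples; they use two-stage
cluster sampling (*k* clusters of *m* subjects, *n = km*). When
individuals within a cluster are more alike than between clusters, the
binomial model understates the spread of *X* and the design misstates
its risks. `clqas` implements, compares, and evaluates the three
published ways of building clustering into the design:

| model | cluster coverage *p_j* | clustering parameter |
|---|---|---|
| binomial-scaled ("Pezzoli") | Binomial(η, p)/η lattice, η ≈ p(1−p)/σ² | σ = sd(*p_j*) fixed |
| beta-binomial ("Hedt") | Beta with mean p, intraclass correlation ρ | ρ fixed |
| quasi-binomial ("Hund") | none; X evaluated on the effective sample size n* = n/D, D = 1 + (m−1)ρ | ρ fixed |

with *X_j* | *p_j* ~ Binomial(m, *p_j*) and X = Σ *X_j* for the two
distributional models. The two parameterizations are linked by
ρ = σ²/{p(1−p)}, so each can be resolved at either threshold; which one
is held fixed materially changes the design when the thresholds sit
near 0 or 1.

The package computes survey totals **exactly** — beta-binomial and
binomial-scaled cluster distributions convolved *k*-fold — instead of
relying on simulation (the lattice coverage distribution has η + 1
support points, so the binomial-scaled marginal is a finite mixture).
Seeded Monte-Carlo evaluation is retained for cross-checks and for
reproducing the historical simulation-based workflow.

## What it does

* **Design searches**: minimal SRS designs; minimal whole-cluster
  designs at fixed *m* or fixed *k* for all three cluster models;
  cost-minimizing searches over a grid of cluster sizes
  (`find_srs_design`, `find_cluster_design`,
  `find_cluster_design_fixed_k`, `pezzoli_design`, `hund_design`,
  `cost_optimal_design`).
* **Risk evaluation**: exact achieved risks (`model_risks`,
  `binomial_risks`), seeded Monte-Carlo estimates (`simulate_risks`),
  operating characteristic curves with fixed or coverage-varying
  clustering (`oc_curve`), and side-by-side design tables
  (`compare_designs`). Failure-count rules (e.g. malnutrition cases)
  are supported via `scale = "failures"`.
* **Clustering from data**: the moment estimator
  σ̂² = (m s² − p̂(1−p̂))/(m−1), truncated at zero, applied to published
  per-area summaries (`estimate_sigma2`, `estimate_clustering`,
  `read_survey_summaries`), plus a seeded generator of synthetic
  summary tables for estimator-recovery studies
  (`simulate_survey_summaries`, `generate_fixture`).
* **A thin CLI** (`inst/cli/clqas.R`) wrapping the same functions:
  `design`, `risks`, `simulate`, `oc`, `estimate`, `fixture`,
  `compare` subcommands.

## Worked example

Design a vaccination survey for the 75–90% couplet with α = β = 0.1,
ten children per cluster, intraclass correlation 0.1:

```r
library(clqas)
tg <- design_targets(0.75, 0.90)
find_cluster_design("hedt", tg, clustering_spec(rho = 0.1), m = 10)
#> HEDT LQAS design: n = 90 (k = 9 clusters x m = 10), decision rule d = 75
#>   couplet (0.75, 0.90), caps alpha = 0.1, beta = 0.1
#>   clustering at thresholds: rho_l = 0.100, rho_u = 0.100 (sigma_l = 0.137, sigma_u = 0.095)
#>   achieved risks: alpha = 0.090, beta = 0.072 (exact evaluation)
```

Nine clusters of ten: classify coverage as acceptable when more than 75
of the 90 children are vaccinated; the chance of flagging a truly
high-coverage area is 0.090 and of clearing a truly low-coverage area
0.072. Compare all methods under a fixed coverage spread σ = 0.1:

```r
compare_designs(list(tg), m = 10,
                clustering_list = list(clustering_spec(sigma = 0.1)),
                methods = c("pezzoli", "hedt", "hund"))
#>    p_l p_u  method  clustering  n  d  k  m  alpha   beta
#> 1 0.75 0.9     srs             40 33 NA NA 0.0995 0.0962
#> 2 0.75 0.9 pezzoli sigma = 0.1 80 66  8 10 0.0842 0.0785
#> 3 0.75 0.9    hedt sigma = 0.1 80 66  8 10 0.0851 0.0785
#> 4 0.75 0.9    hund sigma = 0.1 70 57  7 10 0.0552 0.0708
```

Clustering doubles the required sample relative to simple random
sampling. Finally, turn a published area summary (p̂ = 0.9, s = 0.2
across clusters of m = 6) into a clustering estimate:

```r
estimate_sigma2(p_hat = 0.9, s = 0.2, m = 6)
#>   sigma2     sigma       rho truncated sigma2_raw
#> 1   0.03 0.1732051 0.3333333     FALSE       0.03
```

The naive estimate s² = 0.04 nearly halves after removing the
within-cluster binomial noise.

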