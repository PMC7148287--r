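---
title: "Cluster-bootstrap GLMs: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-bootstrap GLMs: model, algorithm, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glmcb)
```

## The problem and the model

Hierarchical data — repeated measurements within subjects, pupils within
classes — violate the independence assumption of ordinary GLMs.
Mixed models handle this by modelling the dependency through random
effects, but inference is then conditional on the random-effects
structure being right: omitting a needed random slope inflates type-I
error, and it is rarely knowable whether the specification is adequate.
GEE instead requires a working correlation choice and relies on
asymptotics that are doubtful for small numbers of clusters.

`glmcb` takes the marginal route: fit the ordinary GLM

$$ g(\mu_i) = \eta_i = \alpha + \sum_j \beta_j x_{ij} $$

for the mean structure, and get the sampling variability of the
coefficients from a **cluster bootstrap** that resamples whole clusters
with replacement (drawing pairs, not residuals, so no assumption about
the error structure or the correctness of the functional form beyond the
mean model). Because every draw carries all rows of a cluster, the
within-cluster dependency — whatever its form — is present in each
bootstrap sample. The only structural assumption is that clusters were
sampled independently; the resampling mirrors that original sampling
process. When clusters were themselves subsampled (e.g., some children
per class), this scheme is not appropriate as-is.

## Balanced resampling

Rather than drawing each bootstrap sample independently, the package
concatenates $B$ copies of the cluster indices $1..N$, shuffles the
$NB$-vector uniformly, and reshapes it into an $N \times B$ matrix whose
columns index the samples (`build_balanced_indices()`). Consequences,
all tested exactly:

* every cluster appears exactly $B$ times in the whole matrix (an
  efficiency gain over unbalanced resampling);
* with unequal cluster sizes, the average bootstrap-sample row count
  equals the parent row count;
* the matrix is fully reproducible from `(N, B, seed)`.

All randomness of an analysis is exhausted by this one matrix. The
refits are deterministic, so the result is bit-identical for any number
of workers — reproducibility does not depend on per-worker RNG streams.
The shuffle algorithm is R's `sample.int()` (any uniform permutation is
acceptable; the seed pins it).

A cluster drawn $k$ times contributes $k$ full copies of its rows,
relabelled `A#1, A#2, ...`: the GLM ignores cluster identity, but
failure forensics need provenance, and the relabelling keeps copies
distinct for any downstream per-cluster computation.

## Confidence intervals

Per coefficient, with $\hat\beta$ the original-sample estimate and
$\beta^*_{(r)}$ the sorted successful bootstrap estimates
($B_{\mathrm{eff}} \le B$ of them):

* **parametric**: $\hat\beta \pm z_{1-\alpha/2}\,\mathrm{SD}(\beta^*)$.
* **percentile**: ranks $\lfloor B_{\mathrm{eff}}\alpha/2 \rfloor$
  (floored, at least 1) and $\lceil B_{\mathrm{eff}}(1-\alpha/2) \rceil$
  (ceiled, at most $B_{\mathrm{eff}}$) — 125 and 4875 at $B=5000$,
  level .95.
* **BCa**: bias factor
  $\hat z_0 = \Phi^{-1}\!\big[\#(\beta^* < \hat\beta)/B_{\mathrm{eff}}\big]$
  (strictly less; ties with $\hat\beta$ count as not-below — documented
  because heavy ties under discrete responses shift $\hat z_0$), and
  acceleration
  $\hat a = \sum_i (\bar\beta_{(\cdot)}-\hat\beta_{(-i)})^3 \big/
  6\big[\sum_i (\bar\beta_{(\cdot)}-\hat\beta_{(-i)})^2\big]^{3/2}$
  over **leave-one-cluster-out** jackknife estimates
  $\hat\beta_{(-i)}$ (all rows of cluster $i$ removed). Endpoint ranks
  are $B_{\mathrm{eff}}\,\Phi[\hat z_0 + (\hat z_0+z_q)/(1-\hat a(\hat
  z_0+z_q))]$ for $q=\alpha/2, 1-\alpha/2$.

Numerical choices where the formulas leave freedom:

* the endpoint expression yields a real index with no stated rounding
  rule; we round half away from zero, then clamp to
  $[1, B_{\mathrm{eff}}]$. With $\hat z_0 = \hat a = 0$ the BCa ranks
  then collapse to the percentile ranks exactly (tested);
* if **all** bootstrap estimates fall on one side of $\hat\beta$,
  $\hat z_0$ is infinite; the interval is reported missing with a
  diagnostic — no silent clamping, since a clamped $\hat z_0$ would
  manufacture an arbitrary interval;
* if all jackknife estimates coincide the acceleration denominator is
  zero; $\hat a$ is defined as 0 (the no-variation limit is no
  acceleration). $\hat a$ is location/scale invariant (tested to
  1e-12);
* jackknife refit failures degrade $\hat a$ per coefficient (remaining
  clusters are used, with a warning) rather than invalidating the whole
  table;
* normal quantiles throughout, no $t$-correction;
* samples with a missing coefficient are excluded per coefficient, so
  $B_{\mathrm{eff}}$ varies by coefficient and is reported.

`confint()` recomputes any type/level post hoc from the stored matrices;
no refitting occurs.

## Failure taxonomy and forensics

A bootstrap refit never throws for statistical reasons; it returns a
code: `no_response_variation` (constant response under a binomial/Poisson
family — the MLE does not exist; common when a rare binary outcome
misses a sample entirely), `rank_deficient_or_dropped_level` (only the
affected coefficients are `NA` — the signature of a factor level not
drawn into the sample), `nonconvergence` (iteration cap, or a
binomial-family fit with coefficients beyond the separation threshold),
and `numerical_error` (the routine itself raised). Non-converged
coefficients are excluded from the bootstrap distribution by default;
`keep_nonconverged = TRUE` overrides, since divergent estimates can
still be informative to inspect.

The separation threshold (12 on the logit scale, configurable in
`glm_controls()`) is deliberately conservative: logistic coefficients of
that size imply odds ratios near $e^{12}$, which in practice only arise
from (quasi-)separation. IRLS defaults are a deviance tolerance of 1e-8
and 25 iterations.

`get_bootstrap_sample()` rebuilds any sample exactly from the index
matrix, so a failed sample can be refitted and examined standalone.

## The synthetic-data generator

`simulate_dataset()` draws from the two-level linear growth model

$$ Y_{ti} = \beta_0 + \beta_1 G_i + \beta_2 T_{ti} + \beta_3 G_i T_{ti}
   + U_{0i} + U_{1i} T_{ti} + \epsilon_{ti} $$

with defaults that *are* the validation study's stated world:
$\beta = (167.46, 0, 0, 5.54)$, $\epsilon \sim N(0, 1229.93)$, and three
built-in $\Sigma$ choices (`sim_sigma()`) holding the intercept variance
(2111.33) and intercept–slope correlation ($\approx -.33$) fixed while
the slope variance sets the slope ICC
$\Sigma_{22}/(\Sigma_{22}+\sigma^2_\epsilon)$ to .05, .30 or .50 (the
ICC formula is our reconstruction — it reproduces all three labels
exactly). Design choices the stated world leaves open, decided once:

* group assignment is not specified; we assign exactly
  $\lceil N/2 \rceil$ subjects to $G=1$ — a two-arm trial allocation
  that keeps power comparable across seeds;
* unbalanced designs give each subject $t=0$ plus 1–3 follow-ups at
  integer times "uniform in [1,3]"; whether duplicates are allowed is
  unstated, and we sample follow-up times **without** replacement so a
  subject never has two measurements at the same time;
* per-replication seeds are drawn up front from the master seed, so any
  single replication is re-runnable in isolation, and each replication
  re-randomizes its own balanced index matrix.

What the generator emulates is the covariance anatomy of a longitudinal
trial (between-subject heterogeneity in level and trend, plus
measurement noise). What it does not emulate: non-normal residuals,
informative dropout, time-varying covariates, autocorrelated
within-subject noise beyond what the random slope induces. A green
Monte Carlo test therefore establishes calibration *under this
generating model*, not robustness to those features. The diary fixture
(`simulate_diary_data()`) reuses the same machinery to mimic the shape
of a one-week thrice-daily diary study, including two non-compliant
participants and a rare outcome dichotomized at the 99th percentile; it
is synthetic and carries no real study's values.

## Operating characteristics

`run_condition()` scores, per the study's definitions: bias
$\frac{1}{R}\sum_r (\hat\beta_r - \beta)$; type-I error for the null
time effect (zero outside the 95% BCa interval); power for the
interaction (zero outside the interval *and* the estimated sign matching
the generating sign); and coverage (generating value inside the
interval). Rates carry Agresti–Coull bands, switching to Wilson when the
denominator is at most 40. Replications whose interval is undefined are
excluded and the denominator is reported.

At the acceptance scale (N = 64, slope ICC .05, balanced, 200
replications, B scaled down to 999 from the full design's 5000) the
type-I rate sits near the upper Bradley bound (.025–.075): across master
seeds we observed rates between .055 and .09 (Monte-Carlo SE $\approx$
.018). This matches the method's known mild type-I inflation at these
sample sizes — coverage is satisfactory for $N \ge 32$ but the rejection
rate of a true null runs slightly above nominal — so individual seeds
can land on either side of the bound; nothing in the package tunes
toward it.

A degenerate note: with $\Sigma = 0$ and $\sigma^2_\epsilon = 0$ every
estimate is exact and every bootstrap estimate equals $\hat\beta$, so
$\hat z_0$ is undefined and BCa intervals are (correctly) reported
missing; the parametric interval collapses to the true point. Tests
assert exact recovery and zero bias in this limit rather than a BCa
coverage number.

## Known limitations

* No wild cluster bootstrap-$t$ (which may perform better for few
  clusters), no studentized intervals, no prediction method, no
  penalized likelihood; quasi-families affect only the variance function
  used in fitting, not dispersion inference.
* Few clusters (roughly $N \le 10$–15) underestimate sampling
  variability; the jackknife needs $\ge 3$ clusters and BCa needs the
  bootstrap distribution to straddle $\hat\beta$.
* One level of clustering only; two-stage designs need a two-step
  bootstrap this package does not implement.
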