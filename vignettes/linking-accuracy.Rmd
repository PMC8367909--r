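---
title: "Evaluating performance-test linking accuracy under a many-facet Rasch model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating performance-test linking accuracy under a many-facet Rasch model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

In performance assessment — essay tests, speaking exams, clinical skills
examinations — human raters score examinee work on practical tasks. Observed
scores then confound three sources of variation: the examinee's ability, the
task's difficulty, and the rater's severity. The many-facet Rasch model
(MFRM) separates these. For a rating in categories $k = 1, \dots, K$ the
adjacent-categories form used here is

$$
P_{ijrk} =
\frac{\exp \sum_{m=1}^{k} (\theta_j - \beta_i - \gamma_r - d_m)}
     {\sum_{l=1}^{K} \exp \sum_{m=1}^{l} (\theta_j - \beta_i - \gamma_r - d_m)},
$$

with examinee ability $\theta_j$, task difficulty $\beta_i$, rater severity
$\gamma_r$, and category-transition parameters $d_k$ shared across tasks and
raters. The model is invariant under the translations
$(\theta + a + b,\ \beta + a,\ \gamma + b)$, so identification requires
constraints: structurally $d_1 = 0$ and $\sum_{k \ge 2} d_k = 0$ always, and
$\gamma_1 = 0$ for a stand-alone fit. `category_probabilities()` evaluates
the expression with max-subtraction before exponentiation, which keeps it
stable for combined logits up to and beyond $|\eta| \approx 8$ — values that
arise when generated abilities, severities, and drift combine unluckily.

When two tests are administered to *different* examinees, their separately
estimated parameters sit on different scales. The linking design studied
here shares $C_R$ raters and $C_I$ tasks between a calibrated *base test*
and a *new test*; the new test is estimated with the shared (anchor)
parameters held fixed at their base-test values — the fixed
common-parameter method, the performance-assessment analogue of fixed
common-item-parameter linking with nonequivalent groups. The practical
question the package answers by simulation: **how many common raters and
tasks does accurate linking need**, as a function of distribution shifts
between tests, test size, missing-data rates, and anchor drift?

## The simulation procedure

One replication of `run_replication()` executes six steps:

1. generate base-test truth with all classes drawn from $N(0, 1)$;
2. generate new-test truth from the configured (usually shifted)
   distributions;
3. embed $C_R$ common raters and $C_I$ common tasks: randomly chosen
   base-test values overwrite randomly chosen new-test slots
   (`embed_common()`);
4. sample the new test's ratings — fully crossed, or under a rater-set
   assignment design (`sample_dataset()`, `build_design()`);
5. estimate the new test by MCMC/EAP with anchors fixed
   (`estimate_eap()`);
6. compute the error between estimates and truth (`compute_error()`).

Averaging the error over replications and comparing it with a calibration
threshold (below) gives the cell verdict; `run_grid()` does this for every
$(C_R, C_I)$ combination.

### Generating distributions

The base test always uses standard normals, which double as the estimation
priors. The canonical new-test shift scenarios (`scenario_spec()`):

| scenario | $\theta$ | $\beta$ | $\gamma$ | interpretation |
|---|---|---|---|---|
| 1 | $N(-0.5, 1)$ | $N(0,1)$ | $N(0,1)$ | baseline ability shift |
| 2 | $N(-0.2, 1)$ | $N(0,1)$ | $N(0,1)$ | small ability shift |
| 3 | $N(-0.5, 1)$ | $N(0.5,1)$ | $N(0,1)$ | ability + task shift |
| 4 | $N(-0.5, 1)$ | $N(0,1)$ | $N(0.5,1)$ | ability + rater shift |

The 0.5 baseline shift is the edge of plausibility: the mean ability of
$n = 100$ examinees sampled from a unit-normal population has standard
error $1/\sqrt{100} = 0.1$ (`sem_of_mean()`), so two tests rarely differ by
more than $2 \times 2.5$ SEM $= 0.5$.

Category parameters are generated to respect their constraints and the
empirical ordering of thresholds: $K - 1$ draws are sorted ascending and
mean-centered, becoming $d_2 \le \dots \le d_K$ with $\sum_{k\ge2} d_k = 0$
exactly; the mean subtraction is the linear transformation that achieves a
zero total while preserving order. $K = 5$ throughout, the common rubric
size.

### Rater-set designs and missing data

Real assessments assign few raters per performance. `build_design()`
generalizes the judge-pair idea: all $\binom{R}{N_R}$ rater subsets are
listed in lexicographic order, and evaluation targets — enumerated
examinee-major — are dealt to subsets cyclically. This yields exactly
$N_R$ raters per target, balanced loads, and (whenever
$J \cdot I \ge \binom{R}{N_R}$) a connected rater graph, which linking
requires; `connectivity_check()` verifies it by graph traversal. The
implied missing rate is $(1 - N_R/R) \times 100\%$ (`missing_rate()`):
60% for $(R, N_R) = (5, 2)$, 70% for $(10, 3)$, 80% for $(10, 2)$, 90% for
$(20, 2)$. The subset order and traversal order are fixed conventions of
this package; any order with the same coverage, balance, and connectivity
properties is statistically equivalent here because results are averaged
over random parameter draws.

### Anchor drift

Rater severities and task difficulties can change between administrations
(rater drift, item parameter drift). `inject_drift()` perturbs about half
of the commons — $\lceil C_I / 2 \rceil$ tasks and
$\lceil (C_R - 1)/2 \rceil$ raters, chosen uniformly — with zero-mean
normal fluctuations (SD 0.05 for tasks, 0.10 for raters, matching reported
drift magnitudes). The drifted copy is used *only to sample data*;
estimation keeps the undrifted anchor values, which is exactly the
mismatch that degrades linking in practice. Whether to drift a fixed
subset across replications or redraw per replication is not determined by
the problem; the package redraws per replication, which averages over the
drift dose.

## Estimation

`estimate_eap()` is Bayesian: standard-normal priors on all free
parameters, posterior means (EAP) from a Metropolis-within-Gibbs sampler
written in C++. Design choices:

* **Sampler.** Per-class Gaussian random-walk proposals; each scalar
  update touches only that parameter's records via cached per-record
  log-probabilities; the free category components are updated as one
  block. No gradients are needed for a unimodal posterior of at most a
  few hundred dimensions.
* **Adaptation.** Proposal SDs adapt every 50 sweeps during burn-in
  toward a 20–50% acceptance rate, then freeze (so the post-burn-in
  chain is a valid fixed-kernel sampler).
* **Category constraints by construction.** The sampler walks on the
  $K - 2$ free components $d_2, \dots, d_{K-1}$ and sets
  $d_K = -\sum_{2}^{K-1} d_k$; every retained draw satisfies the
  constraints exactly rather than approximately.
* **Identification.** With anchors present the $\gamma_1 = 0$ pin is
  dropped — the fixed anchors resolve the translation invariance, and
  pinning would fight them. Stand-alone fits pin $\gamma_1 = 0$.
  New-test abilities are never anchored.
* **Defaults.** One chain, 5000 iterations, 2000 burn-in, thinning 2
  (1500 retained draws). For trend-style comparisons where only
  differences of means matter, the package's own tests use 2500/1000;
  the residual Monte-Carlo error of an EAP at these lengths is an order
  of magnitude below the replication-to-replication spread.
  `glance()` reports acceptance rates and a split-half convergence
  statistic; `tidy()` reports posterior SDs and batch-means Monte-Carlo
  standard errors.

Parameters with no observations (possible under degenerate designs) are
flagged with a warning and shrink to the prior mean — a deliberate,
visible behavior rather than an error, since anchored settings can still
identify the rest.

## The accuracy criterion

The linking error has no absolute scale: even a perfectly linked test has
estimation noise. The threshold therefore comes from calibration runs
(`compute_threshold()`): the same procedure with the new test regenerated
from the *base* distributions, where linking is complete by construction
and residual error is pure estimation noise. With calibration mean
$\mu_e$ and sample SD $\sigma_e$ (the $n - 1$ estimator — the natural
choice for an SD estimated from tens of replications),

$$\delta = \mu_e + 2\sigma_e,$$

and a cell "links accurately" when its mean error is below $\delta$.
$\delta$ depends on the data size and $(C_R, C_I)$, not on the shift
scenario, so one calibration per cell serves all scenarios at that size.

Error indices: RMSE (default), MAE, and absolute mean bias, over scopes
`all_free`, `ability`, `task`, `rater`, `category`. Deviations are taken
over **free parameters only**: anchored entries deviate by exactly zero,
and including them would deflate every index by a factor depending on
$C_R + C_I$ — exactly the variable under study. `include_anchored = TRUE`
exposes the alternative for sensitivity analysis. The category scope is
$d_2, \dots, d_K$ ($d_1$ is structural).

## Reproducibility and the seed plan

Every replication stage (base generation, new generation, embedding,
drift, sampling, MCMC) draws from its own child seed, derived by a stable
byte-hash of `(master seed, C_R, C_I, rep, stage)` (`derive_seed()`).
Consequences: cells and replications are order-independent and
individually replayable; calibration and target runs use disjoint
streams; and a drift-on configuration shares its generation and sampling
randomness with the matching drift-off configuration, which pairs those
comparisons tightly (scores are sampled by inversion from one uniform per
record, so common random numbers carry through). A failed replication is
retried once on a fresh derived seed and otherwise excluded with a
warning.

## Desk-scale sizes and what the tests show

The package's tests and acceptance script run the reference setting
$J = 100$, $I = 10$, $R = 10$, $K = 5$ at 10 replications per cell
(the full study convention is 30), with smaller toy sizes for structural
checks. These sizes were fixed once, from the statistical requirements of
each check: 10 replications put the standard error of a cell mean near
0.005–0.015 logits, tight enough for the headline comparisons; the paired
drift contrast uses 24 replication pairs, sized for the small reported
drift effect. One complete-data replication at the reference size costs a
few seconds; a full $5 \times 5$ grid at 30 replications (plus
calibration) is an hours-long job and is provided as
`scripts/full_grid.R` rather than as a test.

Two caveats the desk-scale results make visible:

* **Weak anchors are fragile.** At $C_R = C_I = 1$ the entire scale
  rests on one rater and one task. When the lone anchor rater is extreme
  (severity $|\gamma| \gtrsim 1.5$), floor/ceiling effects make its data
  nearly uninformative about location, and occasional replications show
  errors near 0.3 logits — the long right tail behind the finding that
  one common rater and task do not suffice under a 0.5 ability shift.
* **The drift contrast at $C_R = C_I = 1$ is below the noise floor.**
  At that cell the drift dose is a single task perturbed at SD 0.05 and
  no raters (the count formulas give $\lceil 1/2 \rceil = 1$ and
  $\lceil 0/2 \rceil = 0$), a second-order perturbation of the RMSE. The
  paired comparison at feasible replication counts is statistically
  indistinguishable from zero, and the corresponding acceptance trend
  check reports whatever sign the frozen-seed run produces. Drift
  effects become detectable at larger commonality counts, where more
  anchors drift and the rater dose (SD 0.10) enters.

## What the generator does and does not emulate

Synthetic truth is i.i.d. normal within each class, with independent
raters, no rater-by-task interactions, no examinee-level missingness, and
drift that is additive, zero-mean, and confined to common raters/tasks.
Real rating data violate several of these (severity drifts within a
session, raters interact with task types, categories are used unevenly).
Passing tests therefore certify the linking *procedure* under the stated
generating conditions — they do not certify that one common rater and
task suffice for any real examination. The intended use on real decisions
is to rerun the grid with distributions and designs matched to the
assessment at hand, via `experiment_config()`/`load_config()`.

## Known limitations

* Only the adjacent-categories MFRM with shared category parameters; no
  per-rater thresholds, discrimination parameters, or graded-response
  variants.
* Only the fixed common-parameter linking method; no scale
  transformation or concurrent calibration.
* Two tests at a time; no common-examinee designs.
* Anchors are fixed at the base test's *true* generated values — the
  simulation never estimates the base test, so base-test estimation
  error is outside the loop. (Fixing anchors at base-test *estimates*
  would compound both tests' errors; the pipeline accepts any values in
  `fixed_mask()`, so the variant is expressible, but it is not the
  studied condition.)
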