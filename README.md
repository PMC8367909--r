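# facetlink

Simulation and estimation toolkit for studying the accuracy of
**performance-test linking** under a **many-facet Rasch model (MFRM)**.

## The problem

In performance assessments (essay exams, speaking tests, OSCEs), human
raters score examinees on practical tasks. The MFRM models the probability
that examinee *j* receives category *k* from rater *r* on task *i* as

    P_ijrk = exp( sum_{m<=k} (theta_j - beta_i - gamma_r - d_m) )
             / sum_l exp( sum_{m<=l} (theta_j - beta_i - gamma_r - d_m) )

with ability theta, task difficulty beta, rater severity gamma, and
category-transition parameters d (d_1 = 0, sum_{k>=2} d_k = 0). When two
tests are taken by different examinees, their parameter scales must be
*linked*. The common design shares C_R raters and C_I tasks between a
calibrated base test and a new test, and estimates the new test while
holding the shared (anchor) parameters fixed at base-test values — the
fixed common-parameter linking method.

`facetlink` answers, by simulation: **how many common raters and tasks are
needed for accurate linking**, as a function of between-test distribution
shifts, test size, missing-data rate (rater-set assignment designs), and
drift in anchor characteristics. A cell (C_R, C_I) counts as accurately
linked when its mean error stays below the calibration threshold
delta = mu_e + 2 sigma_e, computed from replications in which base and new
distributions coincide (linking complete by construction).

It is aimed at psychometricians and test administrators planning multi-test
performance assessment programs, and written tidyverse-style: data frames
in, tibbles out, `tidy()`/`glance()` for fits, `autoplot()` for results.

## Worked example

Simulate one linked administration at desk scale and estimate it:

```r
library(facetlink)

set.seed(42)
base <- generate_parameters(J = 50, I = 5, R = 5, K = 5)        # base-test truth
new  <- generate_parameters(J = 50, I = 5, R = 5, K = 5,
                            spec = scenario_spec(1))             # ability shift -0.5
emb  <- embed_common(base, new, C_R = 2, C_I = 2)                # share 2 raters, 2 tasks
dat  <- sample_dataset(emb$params)                               # complete ratings
fit  <- estimate_eap(dat, J = 50, I = 5, R = 5, K = 5,
                     mask = fixed_mask(emb$layout),              # anchors fixed
                     config = mcmc_config(seed = 1))
glance(fit)
compute_error(fit$estimates, emb$params, mask = fixed_mask(emb$layout))
```

```
#> # A tibble: 1 × 11
#>   n_records iterations burn_in thinning chains n_draws accept_theta accept_beta
#>       <int>      <int>   <int>    <int>  <int>   <int>        <dbl>       <dbl>
#> 1      1250       5000    2000        2      1    1500        0.438       0.383
#>   accept_gamma accept_d max_split_rhat
#>          <dbl>    <dbl>          <dbl>
#> 1        0.370    0.302           1.02
#> [1] 0.2229264
```

The fit summary shows a well-behaved sampler (acceptance rates in the
20-50% band, split-half convergence statistic near 1). The final number is
the RMSE: the estimated free parameters of the new test sit on average
0.22 logits from their true values; the two anchored raters and two
anchored tasks are excluded since they are fixed by design. Whether 0.22
is "small" is judged against the calibration threshold; a grid run makes
the comparison per cell:

```r
cfg <- experiment_config(J = 50, I = 5, R = 5, new_spec = scenario_spec(1),
                         C_R = 1:2, C_I = 1:2, replications = 5,
                         mcmc = mcmc_config(iterations = 2500, burn_in = 1000),
                         seed = 7)
report <- run_grid(cfg)
format_grid(report)
```

```
#> rmse over all_free ('*' = accurate linking, mean < delta)
#> C_R              C_I=1           C_I=2
#> 1       0.3092(0.2620) *0.2636(0.2944)
#> 2      *0.2859(0.3224)  0.2837(0.2715)
```

Cells marked `*` have mean RMSE below their threshold (shown in
parentheses): accurate linking. At this toy scale (5 replications per
cell) both the means and the thresholds are noisy, so verdicts flip
between neighboring cells; study-scale runs use 30 replications.
`autoplot(report)` draws the same grid as a heat map. Full-scale grids (5x5 cells, 30 replications, J = 100) run via
`scripts/full_grid.R` from a YAML config (see `?load_config`).

## Package tour

| area | functions |
|---|---|
| model core | `category_probabilities()`, `expected_score()`, `mfrm_loglik()`, `sample_response()`, `mfrm_params()` |
| synthetic truth | `distribution_spec()`, `scenario_spec()`, `generate_parameters()`, `embed_common()`, `inject_drift()`, `sample_dataset()` |
| rating designs | `enumerate_rater_sets()`, `build_design()`, `missing_rate()`, `connectivity_check()` |
| estimation | `mcmc_config()`, `fixed_mask()`, `log_posterior()`, `estimate_eap()` + `tidy()`/`glance()`/`autoplot()` |
| linking study | `experiment_config()`, `run_replication()`, `compute_error()`, `compute_threshold()`, `run_grid()`, `format_grid()` |
| I/O & seeds | `read_ratings()`/`write_ratings()`, `read_params()`/`write_params()`, `write_design()`, `write_grid_report()`, `load_config()`, `derive_seed()`, `sem_of_mean()` |

The methods vignette (`vignettes/linking-accuracy.Rmd`) documents the
model, the six-step simulation procedure, the threshold construction, the
sampler, the seed plan, and the design decisions and limitations.
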