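# gridbhm

Biomarker-grid subgroup identification and Bayesian adaptive enrichment
designs for targeted combination therapy.

## The problem

A combination therapy directed at two targets stratifies patients by the
ordinal levels of two predictive biomarkers into a `K x J` grid of
subgroups — e.g. three PD-L1 levels by four HER2 levels gives twelve
subgroups of perhaps ten patients each.  Per-subgroup testing at that size
has no conjunctive power once the family-wise error rate (FWER) is
controlled, and pooling everything biases the estimates whenever the grid
is heterogeneous.  `gridbhm` implements the middle road for trial
statisticians designing or analysing such studies:

* Under **marginal monotonicity** (efficacy non-decreasing in each
  biomarker separately), the admissible high-efficacy patient subsets are
  the nonempty up-sets of the grid partial order.  `enumerate_divisions()`
  lists all `choose(K+J, K) - 1` of them (5 for a 2x2 grid, 34 for 3x4).
* For each candidate division the **two-subset Bayesian hierarchical
  model** borrows information separately within the high- and low-efficacy
  subsets,

  ```
  Ybar(k,j) | theta(k,j) ~ N(theta(k,j), sigma^2 / n(k,j))
  theta(k,j) ~ N(theta_g,  sigma_g^2)   if (k,j) in the high subset
  theta(k,j) ~ N(theta_cg, sigma_cg^2)  otherwise,      theta_g > theta_cg
  ```

  with vague priors `theta_g ~ N(1, 1e3)`, `theta_cg ~ N(0, 1e3)` and
  `IG(1e-3, 1e-3)` shrinkage variances, fitted by a conjugate Gibbs
  sampler (Rcpp).
* The division maximising the **Jensen–Shannon divergence** between the
  posteriors of `theta_g` and `theta_cg` is selected
  (`select_optimal_division()`), and per-subgroup **Bayes factors**
  `BF(k,j) = Pr(H1|D)/Pr(H0|D)` for `H0: theta(k,j) <= theta0` drive
  effective / promising / ineffective decisions with monotone propagation
  up the grid (`decide_ibis_final()`, `classify_interim()`).
* A **multi-stage adaptive enrichment engine** (`run_enrichment_trial()`)
  restricts accrual to promising subgroups at each interim, and a
  **simulation engine** computes FWER, conjunctive/disjunctive power,
  expected sample size and the decision score
  `Score = Power - beta1 * FWER + beta2 * (1 - EN/Nmax)`, calibrates
  thresholds against an FWER cap, and scans threshold grids for design
  heatmaps (`operating_characteristics()`, `calibrate_threshold()`,
  `threshold_heatmap()`).

Comparator analyses (independent per-subgroup t tests, a fully
exchangeable hierarchical model, and a pooled-subset frequentist rule) are
included for benchmarking.

## Worked example

Analyse one simulated trial of the linear-gradient scenario (twelve
subgroups, effects rising from 0 to 1.5, ten patients each):

```r
library(gridbhm)

length(enumerate_divisions(subgroup_grid(3, 4)))
#> [1] 34

scenario <- scenario_library()$scenario8
data <- generate_trial_data(scenario, n_per_subgroup = 10, sigma = 1, seed = 7)
result <- decide_ibis_final(
  data,
  mcmc = mcmc_settings(seed = 7),
  config = decision_config(bf_effective = 100, bf_promising = 10))
result
#> decision grid (ibis): 9 effective, 0 promising, 3 ineffective
#>    j1          j2        j3        j4
#> k1 ineffective effective effective effective
#> k2 ineffective effective effective effective
#> k3 ineffective effective effective effective
```

The pipeline examined all 33 non-trivial divisions, selected the one whose
subset posteriors are most separated, and declared the nine subgroups in
its high-efficacy subset effective (Bayes factor above 100, plus monotone
propagation):

```r
sel <- attr(result, "selection")
sel$chosen
#> division of 3 x 4 grid (9 high / 3 low)
#>    j1 j2 j3 j4
#> k1  0  1  1  1
#> k2  0  1  1  1
#> k3  0  1  1  1
round(sel$divergence[sel$chosen_index], 3)
#> [1] 0.656

head(posterior_summary(sel$chosen_fit), 4)
#>   k j      mean      lower     upper
#> 1 1 1 0.1927021 -0.2699406 0.6212455
#> 2 2 1 0.2486241 -0.1791108 0.7262296
#> 3 3 1 0.2100482 -0.2354511 0.6545709
#> 4 1 2 1.1122278  0.7122565 1.4912742
```

The low-column subgroups (true effects 0–0.5) are pooled near 0.2 with
intervals covering zero; the effective subgroups sit near their true
effects with sub-`sigma/sqrt(n)` interval widths thanks to within-subset
borrowing.  The selected divergence 0.656 is close to its `log 2 ~ 0.693`
ceiling, i.e. the two subsets are almost completely separated.

For a design study, calibrate the threshold under the global null and
simulate any scenario at the calibrated value:

```r
cal <- calibrate_threshold("ibis", scenario_library()$scenario1,
                           fwer_cap = 0.1,
                           threshold_grid = exp(seq(log(2), log(995), length.out = 400)),
                           n_sim = 500, seed = 1)
operating_characteristics(scenario_library()$scenario5, "ibis",
                          decision_config(bf_effective = cal$threshold, bf_promising = 1),
                          n_sim = 500, seed = 2)
```

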