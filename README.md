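# recallsim

Monte Carlo bias analysis for case-control studies that model a continuous
exposure through *deciles among regular users*, with never-regular users as
the reference category — the design used by the largest case-control studies
of mobile phone use and glioma risk. Those studies reported a J-shaped
exposure-outcome curve: reduced odds ratios at low-to-moderate use and an
elevated odds ratio only in the top decile. `recallsim` asks the quantitative
question behind that picture: **can differential recall error and
differential participation alone, with no true effect, produce such a
curve — and how badly do they distort per-decile coverage and type-1
error?**

## The model

Each simulated cohort of `n` subjects (default 1000 cases / 2000 controls)
is drawn as:

* regular-use status ~ Bernoulli(P); never-regular users have exactly zero
  (accurately reported) exposure,
* true log exposure among regular users `X ~ N(mu_X, sigma_X^2)`,
* disease `D | X ~ Bernoulli(expit(alpha* + beta* X))`, with
  `beta* = log(OR*)/delta` and `delta` the expected exposure gap between the
  top and bottom decile; `alpha*` is calibrated so the expected case count
  matches the design.

Observed exposure for a regular user follows the additive log-scale error
law, per arm:

    Y = X + tau + gamma (X - mu_X) + eps,    eps ~ N(0, sigma_T^2)

Four preset scenarios (`scenario_preset(1:4)`) cover differential
systematic + random error (cases: `tau = 0.34`, `gamma = 0.02`, SD ratio
1.1; controls: `sigma_T0 = 1.22`), differential random only, differential
systematic only (common SD 1.28), and nondifferential random error. The
analysis layer rebuilds decile cutpoints from the regular controls of each
replicate, fits the never-regular-reference categorical logistic model by
maximum likelihood, and reduces 5000 replicates to per-decile mean
estimates, empirical intervals, coverage, and type-1 error / power.

A selection-bias module implements the nonresponse-questionnaire analysis:
W ratios (exposure proportion among participants vs NRQ responders),
participation probabilities by Bayes inversion `p = r / (r + (1-r)/W)`,
Greenland's correction factor
`B = (s_case_e s_ctrl_ref)/(s_case_ref s_ctrl_e)` (corrected OR =
observed / B), and record-level thinning of simulated cohorts by start-year
category.

## Worked example

Scenario 1 (differential systematic + random error) under the null, 300
replicates:

```r
library(recallsim)
cfg  <- default_config(scenario_id = 1, n_replicates = 300, master_seed = 2024)
fits <- run_replicates(cfg, 300, estimator = "naive", master_seed = 2024)
summarize_fits(fits)
#>  decile mean_estimate mean_or est_lo est_hi coverage_pct rejection_pct
#>       1     -0.190896   0.826 -0.568  0.131         84.3         15.67
#>       2     -0.200430   0.818 -0.591  0.128         83.7         16.33
#>       5     -0.095360   0.909 -0.542  0.232         90.0         10.00
#>       8      0.049212   1.050 -0.302  0.341         95.3          4.67
#>       9      0.146612   1.158 -0.171  0.451         85.7         14.33
#>      10      0.396194   1.486  0.134  0.666         25.7         74.33
```

(abridged; `n_valid_replicates = 300` everywhere). Although the true odds
ratio is 1 in every decile, differential error alone produces the J shape:
apparent *protection* at low use (`OR = 0.83`, D1), near-null middle
deciles, and a spurious *increased* odds ratio in the top decile
(`OR = 1.49`) whose 95% CI excludes the null in 74% of replicates. Exact
magnitudes depend on the exposure-law inputs (`p_regular`, `mu_X`,
`sigma_X`), which are configurable placeholders; the nominal-level behavior
of the error-free estimator and of nondifferential error does not.

Selection bias under the null, thinned with the packaged participation
table and corrected with Greenland's factor:

```r
selection_experiment(n_replicates = 5, master_seed = 1)
#>           level crude_or bias_factor corrected_or
#> 1        >=2001    1.029       0.967         1.06
#> 2     1998-2000    0.896       0.856         1.05
#> 3     1993-1997    0.885       0.832         1.06
#> 4        <=1992    0.935       0.833         1.12
#> 5 regular (all)    0.932       0.868         1.07
```

Differential participation alone depresses the crude regular-use odds ratio
to 0.93; dividing by the bias factor returns it to 1 within Monte Carlo
error.

A one-command experiment driver writes long/wide CSV results, a JSON
manifest, and a log (`run_experiment(cfg, "out_dir")`; CLI front-end in
`inst/scripts/recallsim-cli.R`).

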