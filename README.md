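# ctbayes

Bayesian ideal-observer analysis of the **central tendency effect** in
auditory and visual magnitude reproduction.

## What problem this solves

In magnitude reproduction tasks (how long did the tone last? how far apart
were the flashes?), estimates regress toward the mean of the experienced
stimulus distribution — small values are overestimated, large ones
underestimated. A Bayesian observer explains this as reliability weighting:
the response is the posterior mean of a Gaussian likelihood centered on the
stimulus and a prior reflecting the stimulus distribution,

    mu_R(S_i) = S_i * (1 - w_P) + mu_P * w_P,
    w_P(S_i)  = sigma_L(S_i)^2 / (sigma_L(S_i)^2 + sigma_P^2)

so the regression slope is `1 - w_P` and the **Regression Index**
`RI = 1 - slope` estimates the prior's weight (0 = veridical, 1 = complete
regression).

`ctbayes` is a reproducible pipeline for a two-task (temporal / spatial),
two-modality (auditory / visual) reproduction design with single-modality
baseline sessions and an interleaved session. It provides, as tested
library functions and a CLI:

* a **synthetic-observer generator** with configurable generative priors
  (`veridical`, `seg_audio`, `seg_vision`, `cte`, `wcte`), affine sensory
  noise, motor noise and bias — the pipeline's test bed;
* **preprocessing**: response normalization, perceived-vs-real OLS fits,
  RMSE-based outlier screening (±3 group SD from the group median, whole-task
  exclusion);
* **psychometrics**: RI, intercept bias, per-stimulus sensory precision
  corrected for central tendency (residual variance / slope²), and modality
  reliability weights `w_A = sigma_V^2 / (sigma_A^2 + sigma_V^2)`;
* **truncated-normal prior machinery**: forward moments and inverse moment
  matching by constrained least squares;
* four **observer models** (SegAudio, SegVision, CTE, WCTE) predicting
  interleaved-session responses per participant;
* **model comparison** by linear mixed models (`observed ~ stimulus +
  prediction + (1 | participant)`, ML), AIC/BIC/logLik/deviance, R² and
  cross-validated predicted R².

## Worked example

Simulate a small temporal cohort whose responses follow an auditory
segregation prior (audition reliable, vision noisy), run the analysis
chain, and ask which model explains the interleaved session:

```r
library(ctbayes)
cfg   <- default_config()
base  <- default_observer_params("temporal", cfg)   # RI ~0.2 (A) / ~0.6 (V)
spec  <- cohort_spec(8, base, bias_sd = 20, seed = 42)
trials <- simulate_cohort(spec, cfg, "temporal")

prep  <- preprocess_cohort(trials, cfg)
psych <- psychometrics_table(prep$trials, cfg)
aggregate(ri ~ session + modality, psych$metrics, mean)
#>       session modality        ri
#> 1       audio        A 0.1799413
#> 2 interleaved        A 0.1790791
#> 3 interleaved        V 0.5315209
#> 4      vision        V 0.5450328
mean(psych$weights$omega_A)
#> [1] 0.839

pred   <- predict_models(prep$trials, cfg)
report <- compare_models(prep$trials, pred$predictions, folds = 5, seed = 1)
report
#> <comparison_report> best by BIC: SegAudio; best by AIC: SegAudio
#>      model     aic     bic   loglik deviance       r2 predicted_r2 delta_aic degenerate
#>   SegAudio 32375.1 32404.9 -16182.5  32365.1 0.466582     0.378419     0.000       TRUE
#>       WCTE 32594.3 32624.1 -16292.2  32584.3 0.424993     0.311148   219.252      FALSE
#>  SegVision 33052.8 33082.6 -16521.4  33042.8 0.317413     0.309842   677.734      FALSE
#>        CTE 33066.3 33096.1 -16528.1  33056.3 0.316795     0.290193   691.235      FALSE
```

Reading the output: the auditory trials barely regress (RI ≈ 0.18) while
visual trials regress strongly (RI ≈ 0.53), audition carries most of the
reliability weight (`w_A ≈ 0.84 > 0.5`), and model comparison recovers the
generating regime — the auditory segregation prior — by both BIC and AIC,
with the reliability-weighted WCTE model closest behind (the two become
indistinguishable as `w_A -> 1`).

The same chain runs end to end with provenance tracking:

```r
run_full(cfg, out_dir = "run1", seed = 1)
# -> trials.csv, normalized.csv, outliers.json, metrics.csv, precision.csv,
#    weights.csv, priors.json, predictions.csv, table1_<task>.csv,
#    report.json, manifest.json
```

or from the shell via the CLI (`inst/cli/ctbayes`): `simulate`,
`analyze preprocess|psychometrics|predict`, `compare`, `run-full`,
`validate-config`.

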