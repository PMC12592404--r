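---
title: "Bayesian observer models of central tendency in duration and length reproduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian observer models of central tendency in duration and length reproduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctbayes)
```

## The problem

When people reproduce magnitudes — how long a tone lasted, how far apart two
flashes were — their estimates gravitate toward the mean of the stimulus
distribution they have experienced: small magnitudes are overestimated, large
ones underestimated. This *central tendency effect* is well described by a
Bayesian ideal observer that combines a noisy sensory measurement (the
likelihood) with an expectation about plausible magnitudes (the prior). The
strength of the pull depends on relative reliability: the noisier the sense,
the stronger the regression toward the prior mean.

`ctbayes` implements the full analysis chain for a two-task, two-modality
reproduction design: auditory and visual duration reproduction (temporal
task, milliseconds) and auditory and visual length reproduction (spatial
task, degrees of visual angle). Each modality carries its own stimulus range,
measured first in single-modality baseline sessions and then in an
interleaved session mixing both modalities. The scientific question is
whether the prior acting in the interleaved session is supra-modal (one
pooled expectation) or dominated by the task's more reliable modality
(audition for time, vision for space).

## The observer model

On a trial with stimulus $S_i$, the likelihood is Gaussian with mean $S_i$
and SD $\sigma_L(S_i)$ (the participant's sensory precision for that
stimulus and modality). With a prior of mean $\mu_P$ and SD $\sigma_P$, the
predicted response is the posterior mean

$$\mu_R(S_i) = S_i\,\bigl(1 - \omega_P(S_i)\bigr) + \mu_P\,\omega_P(S_i),
\qquad
\omega_P(S_i) = \frac{\sigma_L(S_i)^2}{\sigma_L(S_i)^2 + \sigma_P^2}.$$

The regression slope of responses on stimuli is $1-\omega_P$, so the
*Regression Index* $RI = 1 - \text{slope}$ directly estimates the prior
weight: 0 is veridical, 1 complete regression.

Four models differ only in the prior applied to the interleaved session:

* **SegAudio** — prior matched to the auditory stimulus set only;
* **SegVision** — prior matched to the visual set only;
* **CTE** — supra-modal prior matched to the pooled set of both modalities;
* **WCTE** — prior mean $\mu_W = \mu_A\omega_A + \mu_V\omega_V$ and SD
  $\sqrt{\omega_A\sigma_A^2 + \omega_V\sigma_V^2}$, combining the two
  segregation priors by the participant's measured reliability weights.

A single model prior applies to auditory and visual trials alike; only the
likelihood width is modality-specific (looked up per stimulus in the
baseline precision profile of the trial's own modality). This is the reading
under which the model algebra is consistent with the schematic in which
modality-specific likelihoods share one prior; the alternative readings of
the ambiguous segregation-model subscripts are not implemented.

## Truncated-normal priors and an infeasibility the data force on us

Stimulus ranges are bounded, so the prior is modeled as a normal
distribution truncated to the range $[a, b]$ of the relevant stimulus set,
with parent parameters $(\mu, \sigma)$ chosen so that the truncated
distribution's mean and variance match those of the experienced stimulus
distribution (`solve_prior()`, bounded least squares on the two moment
residuals, deterministic initialization, Levenberg–Marquardt polish to a
`1e-8` scaled tolerance).

Two provenances of the moment target are supported (`prior_provenance`):

* `"discrete_set"` (default): mean and population variance of the values
  actually presented;
* `"continuous_uniform"`: moments of the boxcar on $[a, b]$.

Here a structural fact intervenes: a truncated normal on $[a,b]$ can realize
any variance *strictly below* the uniform variance $(b-a)^2/12$, and a
discrete uniform design with $n$ levels has variance $(n+1)/(n-1)$ times
that ceiling. Neither target is therefore exactly attainable for equally
spaced designs. The solver accepts targets within a slack factor of the
ceiling (default 0.75, admitting any discrete uniform design with at least
4 levels), returns the closest attainable prior — effectively the uniform
limit, e.g. implied SD $\approx 103.9$ ms for the auditory 490–850 ms
range — and records `matched = FALSE` with the residuals; pipelines surface
this in their warnings. Targets beyond the slack raise an infeasibility
error. Downstream, the prior enters the posterior through its
*post-truncation* moments (`prior_mean()`, `prior_sd()`): using the parent
$\sigma$ (which diverges at the ceiling) would abolish the central tendency
the prior is meant to produce.

## The synthetic cohort: what it emulates, and what it does not

The generator (`simulate_participant()`, `simulate_cohort()`) stands in for
the study's participant data, which are not shipped. Its stated world:

* **Design**: 9 durations per modality (auditory 490–850 ms, mean 670;
  visual 760–1120 ms, mean 940; 45 ms steps, three shared values), 6
  lengths per modality (auditory 22–50°, visual 5.5–33°), baselines of
  180 / 120 trials and interleaved sessions of 360 / 240 trials. Stimulus
  schedules are a seeded uniform shuffle driven by a config-level
  `schedule_seed`, so schedules depend only on the design while response
  noise follows the simulation seeds.
* **Response model**: the observer draws a measurement
  $m \sim N(S_i, \sigma_L(S_i))$, reports the posterior mean of its
  regime's prior given $m$, and adds motor noise and a constant bias;
  responses are truncated at zero (with truncation events counted). Placing
  the sensory noise *before* the posterior is what makes the
  residual-variance/slope² correction meaningful: response noise is shrunk
  by the same factor as the signal, and `sensory_precision()` undoes it.
* **Noise law**: affine in magnitude, $\sigma_L(S) = \text{floor} +
  \text{coef}\cdot S$, covering constant and Weber-like regimes. The
  empirical analysis estimates precision per stimulus and never commits to
  a generative form; the affine law is this package's choice.
* **Calibration**: `default_observer_params()` sets constant noise floors
  from the solved dominant-modality prior so the expected RI is ~0.2 for
  the dominant and ~0.6 for the non-dominant modality (the qualitative
  ordering of the empirical findings): $\sigma_L = \sigma_P\sqrt{RI/(1-RI)}$,
  i.e. ≈52 and ≈127 ms for the temporal task. Motor noise defaults to 10 ms
  / 0.5°; cohort pipelines add a per-participant response bias
  (SD 20 ms / 1°) that the normalization step exists to remove, and 15%
  log-normal jitter on all noise parameters.
* **Not emulated**: serial dependence and other trial-order effects, lapse
  or attention mixtures, reaction times, and the deposit's native data
  layout. A green recovery test therefore establishes that the pipeline
  identifies the generating prior regime under its own assumptions — not
  that real observers satisfy those assumptions.

## Preprocessing conventions

* **Normalization**: the description of the response-centering step is
  ambiguous in the source procedure. The implemented convention centers
  responses within each session × modality cell and re-anchors them by a
  task constant (the mean of the two modality sets' median values, 805 ms /
  27.625°). Slopes, RIs and within-cell variances are invariant to it; only
  intercepts shift by a constant. It can be disabled (`normalize = FALSE`).
* **Outlier rule**: per task × session, a participant is excluded when
  their linear-fit RMSE deviates from the *group median* by more than 3
  *group SDs*, and an exclusion applies to the whole task. The rule is
  implemented exactly as printed, but note its detectability floor: a
  single spike among $n$ participants can reach at most $\sqrt{n}$
  deviation/SD (the spike inflates the SD it is judged against), so the
  3-SD rule cannot flag any single outlier in cohorts smaller than ~10, and
  two co-occurring spikes are bounded by $\sqrt{n/2}$. Test fixtures
  respect these bounds.
* **RMSE** uses the degrees-of-freedom-adjusted denominator $\sqrt{SSE/(n-2)}$,
  matching the curve-fitting-toolbox convention of the original analysis.
* **Weights**: per-stimulus corrected variances are pooled by an unweighted
  mean across stimulus levels (the estimator is unstated in the source;
  trial-count weighting is available via `precision_pooling`), and
  $\omega_A = \sigma_V^2 / (\sigma_A^2 + \sigma_V^2)$ from baseline
  sessions only.

## Model comparison

Each model is scored by the linear mixed model
`observed ~ stimulus + prediction + (1 | participant)`, fitted by **maximum
likelihood** (not REML): models share the fixed-effect structure but differ
in the prediction regressor, and only ML likelihoods make their AIC/BIC
comparable. $R^2$ is the squared Pearson correlation between observations
and fitted values; predicted $R^2$ uses participant-grouped, seeded
$k$-fold cross-validation (default 10 folds) with held-out participants
predicted from fixed effects only. Models are ranked by BIC, with ΔAIC < 2
flagged as degenerate (substantial support for both models). On normalized
synthetic cohorts the random-intercept variance is typically ~0 (the
normalization removes participant offsets), so fits are flagged singular /
non-converged while their criteria remain valid and are reported.

Two empirical regularities reproduce the headline findings on synthetic
cohorts: the generating segregation model wins BIC in recovery sweeps, and
when one modality's weight approaches 1 the WCTE model becomes functionally
indistinguishable from the corresponding segregation model. For the latter,
note an estimator limit: measured weights saturate around 0.998 no matter
how noisy the non-dominant modality is made, because a near-zero regression
slope makes the corrected precision estimate (residual variance / slope²)
noise-dominated. The degeneracy suite therefore demonstrates the ΔAIC
collapse by sweeping the WCTE weight parameter itself toward 1 on a fixed
extreme cohort, alongside the empirical convergence of measured weights and
predictions.

## Numerical choices

* Truncated-normal moments use complementary-CDF normalizers in the upper
  tail; stable for $|\alpha|, |\beta|$ well beyond 8. Infinite bounds are
  handled by vanishing boundary terms.
* The moment solver is deterministic (fixed start at the target moments, no
  random restarts); σ is box-constrained to $[10^{-6}, 10]\times(b-a)$.
* Stimulus-set membership and profile lookups use an absolute tolerance of
  `1e-9` in task units; trial CSVs are written with 15 significant digits.
* All randomness flows from named seeds (master → per-participant,
  cross-validation, schedule); reruns are byte-identical except for the
  manifest timestamp.

## Limitations

* The pipeline's quantitative outputs on synthetic cohorts (AIC/BIC, $R^2$)
  are not comparable to the published values, which were computed on the
  authors' participant data; only design constants and qualitative/
  property-level behavior are asserted.
* Group-level inferential statistics (t tests, REML mixed models with
  post-hoc contrasts) are out of scope; psychometric quantities are
  reported descriptively.
* The spatial stimulus sets are reconstructed as 6 equally spaced values
  over the printed ranges; the published shared lengths (22°, 28°, 33°) and
  the visual mean of 19.5° are mutually inconsistent with any equal
  spacing, so the true speaker-grid values are unrecoverable from the text.
  Sets are config-overridable.
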