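---
title: "Models and methods behind gapoverlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gapoverlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapoverlap)
```

This vignette documents the generative model, the preprocessing algorithms,
the statistical procedures, and the design decisions of the package — the
material a reviewer or maintainer needs to judge what the package computes
and what its tests do and do not establish.

## The task and its outcome measures

In the Gap-Overlap task a participant fixates a central stimulus; a
peripheral target appears at ±20.8° and the saccadic reaction time (SRT) to
it is measured under three regimes of central-stimulus offset: *gap*
(offset 200 ms before target onset), *baseline* (simultaneous), and
*overlap* (center stays on). Per participant and condition the outcome is
the median SRT over retained trials; the *gap effect* (median overlap −
median gap) indexes the cost of attentional disengagement and the
*facilitation effect* (median baseline − median gap) the benefit of
anticipatory disengagement.

One timing convention deserves note: a literal "target onset minus fixation
end" difference would be negative for ordinary responses, so the package
computes SRT as *fixation end minus target onset*, making valid SRTs
positive and the 150/2000 ms trimming bounds directly interpretable.

## The generative model

The synthetic-data generator exists so that every pipeline stage can be
validated against known ground truth; its defaults aim to be a plausible
developmental eye-tracking cohort, not a fit to any particular dataset.

**Latency model.** Trial SRTs in the gap condition follow an ex-Gaussian
distribution — the standard reaction-time family, a Gaussian (mean `mu`,
SD `sigma`) plus an exponential tail (mean `tau`). The overlap and baseline
conditions add the participant's gap effect and facilitation effect as
deterministic shifts, which makes the two difference scores exactly
identified for recovery tests. Age trends (age `a` in months):

- `mu(a) = mu_scale * (250 + 400 * exp(-a/24))` ms
- `gap_effect(a) = gap_scale * (30 + 170 * exp(-a/30))` ms
- `facilitation(a) = fac_scale * (10 + 60 * exp(-a/30))` ms

with `sigma = 50` ms and `tau = 100` ms. The exponential declines produce
infant SRTs around 600–700 ms falling to ~300 ms by late childhood and a
gap effect falling from ~190 ms to ~30 ms — qualitatively the monotone
developmental pattern the analysis is designed to detect. No published
per-age latency distributions exist for this design, so the constants are
the package's own choices, config-overridable via the `trend` argument of
`latent_profile()`. The `*_scale` multipliers are per-participant
log-normal random effects (log-SDs 0.15/0.30/0.30) giving stable individual
differences, which the longitudinal and cross-wave analyses need.

**Gaze signal.** Before the saccade both eyes sit at screen center with
isotropic Gaussian noise of per-axis SD `noise_rms_deg / 2`; with
independent samples the two-axis, two-eye RMS sample-to-sample statistic
then equals `noise_rms_deg` in expectation (per axis the expected squared
sample-to-sample step is `2 * (r/2)^2`, and summing the two axes gives
`r^2`). The default `noise_rms_deg = 0.5` is between typical adult
(~0.1–0.3°) and poor infant (~1°+) precision and is compatible with the
default 1.5° dispersion threshold of the fixation classifier; at 1° and
above, dispersion classification of this kind starts to fragment badly (a
limitation shared with all plain dispersion classifiers). At
`peripheral_onset + latency` the gaze moves over a 2-sample linear ramp to
the target plus a 1° SD landing error; no main-sequence kinematics are
modelled because fixation classification only requires a fast transition.
Each sample of each eye is invalidated independently with
`data_loss_prob = 0.15` by default.

**Contaminants.** Per trial, mutually exclusive contaminant draws override
the clean process: *premature* (latency drawn uniformly in 30–149 ms, not
condition-shifted, emulating anticipatory saccades), *wrong direction*
(landing on the unscheduled side), *no movement* (gaze never leaves
center); 5% each by default. Labels are returned as hidden ground truth for
filter-validation tests and never consumed by preprocessing.

**Cohort structure.** Six waves (5 mo, 10 mo, 3 y, 6 y, 9 y, 12 y) with
truncated-normal age jitter inside configured bounds; per-wave sample sizes
default to cohort scale (1900/1809/1009/336/1269/382) and retention
probabilities (0.85/0.65/0.30/0/0.28) were chosen so that roughly half of
the ~6700 datasets come from returning participants (~3300–3450 unique
children), with zero retention across the 6 y → 9 y boundary because the
two sub-cohorts enrol independently.

**Questionnaires.** Item responses are generated through a Gaussian copula:
gap effects are mapped to normal scores, the latent trait is
`rho * z_gap + sqrt(1 - rho^2) * noise`, items load 0.6 on the trait and
are thresholded — Likert items to 1–7 with equal-mass categories, 3-point
problem items to 0/1/2 with 70/20/10% mass (problem behaviours are
right-skewed in non-clinical samples). Reverse-coded items are stored
reversed so that scoring recovers the coupling. Instrument assignment
follows administration ages (early-childhood temperament form at 18–35 mo,
childhood form at 36–95 mo, problem checklist from 18 mo). The shipped
subscale definitions mirror the real instruments' *structure* (8-item
shifting, 6-item focusing, 7-item summed problem scale) but their item
identities and the shipped linear norms are synthetic: publisher item keys
and normative tables must be user-supplied for real data.

**What the generator does not emulate.** Calibration error and drift,
age-dependent data quality, smooth pursuit and blinks, saccade kinematics,
online gaze-contingent trial logic (the extra block is triggered by a
simple hidden-valid-trial count), non-stationary noise, and item-level
questionnaire structure beyond a single latent trait. Passing tests
therefore demonstrate algorithmic correctness under a controlled data
model, not robustness to every pathology of real infant eye-tracking data.

## Preprocessing

**Fixation classification.** A dispersion classifier on the
binocular-averaged signal (per-sample mean of whichever eyes are valid): a
candidate window must span ≥ 60 ms with x-range + y-range ≤ 1.5°; windows
grow greedily until the threshold would be exceeded. Because the greedy
pass ends a window wherever *cumulative* dispersion happens to cross the
threshold, the samples between that break and the next classifiable window
— often the last few tens of milliseconds before a saccade — would
otherwise be discarded, biasing fixation ends (hence SRTs) early by up to
the minimum duration. A boundary-refinement pass therefore re-attaches
adjacent samples lying within the dispersion threshold of the window
centroid, without crossing neighbouring fixations. After refinement,
adjacent fixations separated by < 75 ms and < 1° are merged. With this
refinement, injected latencies are recovered with sub-millisecond median
bias at default noise (the pre-refinement bias was ≈ −30 ms). All four
parameters are exposed via `fixation_params()`. This classifier is a
deliberately simple, fully specified stand-in for cluster-based classifiers
used in practice; it is behind a small functional interface
(`classify_fixations()`) so a different classifier can be substituted.

**Quality metrics.** Precision is the median over a 0.1 s moving window
(stepped one sample) of the RMS of sample-to-sample deviations, axes
combined per window by Pythagoras, then averaged over eyes (one eye used
when the other has no usable window). Combining axes *before* the median
was chosen over median-then-combine; with equal pair counts the per-window
combination equals the RMS of Euclidean step lengths. Data loss is the
invalid-sample fraction averaged over eyes. A trial with no usable
precision window in either eye automatically fails the precision filter.

**SRT extraction and filters.** AOIs are three equal-width vertical bands,
left-closed/right-open (a centroid exactly on the left/center boundary is
center). The SRT comes from the first center-AOI fixation immediately
followed by a side-AOI fixation. The exclusion cascade runs in a fixed
order — precision > 2.0°, data loss > 0.7, no movement, wrong side,
SRT < 150 ms, SRT > 2000 ms — with strict inequalities so boundary values
are retained; the order only affects which reason a multiply-flawed trial
is booked under, not the surviving set. Condition medians require ≥ 4
retained trials (even counts use the midpoint). Age-window violations in
the cohort table (outside own wave bounds, or inside the next wave's
bounds) are flagged by `validate_wave_assignment()`, not silently dropped.

## Statistics

**Bootstrap age correlation.** Accelerated longitudinal data mix
cross-sectional and repeated measurements, so a plain correlation
double-counts returning participants. Per iteration (5000 by default), one
measurement is sampled uniformly per unique participant and the Spearman
correlation between age and the measure is computed; the distribution is
summarised by its median and 2.5/97.5 percentiles. The shuffled-age null
permutes ages within each iteration *after* the per-participant sampling,
so observed and null distributions share the same per-iteration n and
marginals. How a p value attaches to a bootstrap median is genuinely
underdetermined, so two summaries are emitted: an empirical
`(k + 1) / (n + 1)` tail probability of the observed median under the null
(never exactly zero; below `1/n_iter` when no null iteration reaches it)
and a two-sample Wilcoxon rank-sum comparison of the two r distributions.

**Models.** The age-slope mixed model is `value ~ age_months` with
participant random intercepts (REML, Wald z inference — appropriate at
cohort n); with no repeated measurements it degrades to OLS with a warning,
and singular fits are flagged. Paired wave contrasts use a paired t-test,
or Wilcoxon signed-rank when a Shapiro-Wilk check on the paired differences
rejects at 0.05 (the rule is an argument; effect sizes are paired Cohen's d
and the matched-pairs rank-biserial correlation), with Holm correction over
the contrast family. The repeated-measures omnibus is delegated to the
standard multivariate linear model machinery with Huynh-Feldt correction;
the package owns only its result contract (with two waves the F equals the
squared paired t, which the tests verify). T-scores of exactly 70 are
classified clinical: the conventional wording leaves 70 unassigned, and the
standard convention (clinical at T ≥ 70) is adopted.

## Numerical and degenerate-input conventions

Time is ms from trial start, coordinates are degrees from screen center
(x rightward, y downward), and all windows are half-open `[start, end)`.
Spearman correlations on constant vectors are signalled as errors rather
than returned as NA; bootstrap procedures require ≥ 3 unique participants
and non-constant values; cells of the cross-wave matrix with < 3
overlapping participants are reported absent; degenerate paired contrasts
(all-zero differences) return effect 0 with a warning. All stochastic
functions accept a seed and are bit-reproducible under it; the pipeline
derives per-stage seeds from one master seed.

## Test problem sizes

The simulation tests run at sizes chosen to make each check informative at
interactive runtimes: the shuffled-null calibration uses the cohort-scale
generator (~3400 unique participants, 5000 iterations), where the null
median is expected to round to 0.00 and the CI half-width to match the
asymptotic `1.96 / sqrt(n - 1)` within 20%. The gaze-level end-to-end
recovery uses 100 measurements per wave: per-participant recovered gap
effects have an SD of roughly 30–45 ms (median-of-~13-trials noise), so 100
per wave puts the 3-standard-error recovery band near ±12 ms — materially
smaller than the smallest true gap effect in the design (~31 ms at the
oldest wave), which a markedly smaller sample would not resolve. A small
residual negative bias (≈ −0.6 ms) remains in recovered gap effects at the
oldest ages, traceable to the 150 ms premature-trimming bound clipping the
lower tail of the gap condition slightly more than the shifted overlap
condition; it is an inherent property of the trimming design, an order of
magnitude inside the recovery band.

## Known limitations

- The dispersion classifier degrades above ~1° RMS noise; real infant data
  at that quality would need a cluster-based or adaptive classifier behind
  the same interface.
- Lost samples are never interpolated; long both-eye loss streaks can split
  fixations and, in extreme cases, cost the center-to-side sequence.
- The latency model's additive condition shifts rule out age-by-condition
  interactions in trial-level variance; real data need not comply.
- Questionnaire generation uses a single latent trait with equal loadings;
  no item content, method variance, or informant effects.
- The mixed model fits a linear age slope; the generative age trend is
  exponential, so the slope is an average decline over the sampled range,
  not a structural parameter (a caveat that applies equally to linear
  mixed-model summaries of real developmental data).
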