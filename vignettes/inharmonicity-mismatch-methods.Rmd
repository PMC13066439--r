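---
title: "Methods: simulating and modeling mismatch responses to inharmonic tones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and modeling mismatch responses to inharmonic tones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inharmmn)
```

# The scientific problem

The auditory system treats harmonic complex tones — sums of sinusoids at
integer multiples of a fundamental F0 — as privileged objects: pitch,
streaming, and memory all lean on harmonicity. `inharmmn` provides the
computational machinery for experiments that degrade harmonicity
parametrically and ask where auditory deviance detection breaks down. The
manipulated variable is a multiplicative frequency jitter: every harmonic
above the fundamental is scaled by `1 + J` with `J ~ U(-jc, jc)`. The jitter
rate `jc` runs over a geometric schedule from 0.005 to 0.5 (`j1`..`j10`,
`jitter_schedule()`), the largest value that cannot reorder adjacent
components. A geometric schedule spends its resolution at small rates, where
pitch discrimination is still possible; on a log scale the levels are
equally spaced, which the staircase observer model exploits.

Two further transforms anchor the statistics:

* **Differential entropy.** For `J ~ U(-jc, jc)` the differential entropy
  of the jitter distribution is `I = log10(2 jc)`
  (`differential_entropy()`). It linearizes the geometric schedule, and it
  is undefined at `jc = 0`, which is why the harmonic condition is excluded
  from all entropy-based models (it still participates in the ANOVA and
  t-test layers). The exact inverse is `jc = 10^I / 2`
  (`inflection_to_jitter()`); the pair round-trips to machine precision.

* **The sigmoid mixed model.** MMN amplitude as a function of entropy is
  modeled as `y_pc = L_p / (1 + exp(k (I_c - I0))) + e_pc` with a
  participant-random left asymptote `L_p ~ N(L, sigma_L^2)` and Gaussian
  residuals. The right asymptote is pinned at 0 (MMN disappears for heavily
  jittered tones). `I0` is the inflection — the entropy at which the MMN has
  collapsed halfway — and `k` the steepness of the collapse.

# Stimulus synthesis

`tone_spec()` fixes the tone parameters: 70 ms duration, 48 kHz sampling,
5 ms half-Hanning onset/offset ramps, a 4th-order Butterworth high-pass at
3500 Hz, and a −12 LUFS loudness target. The cutoff equals the 10th harmonic
of the mean F0 of the 200–500 Hz (step 50) grid, i.e. `3500 / 350 = 10`,
which pushes processing toward unresolved upper harmonics while leaving a
gradual 24 dB/octave skirt below.

Synthesis order is: sum sinusoids (one per component, phases i.i.d. uniform
on `[0, 2π)` — the natural reading of "random phase"), high-pass filter,
ramps, loudness normalization. Filtering precedes ramping so the ramps are
not distorted by filter transients, and normalization comes last so the
target level is authoritative on the final signal. A tone whose
normalization would push samples past full scale triggers a warning rather
than silent clipping, and the WAV writer refuses out-of-range samples
outright.

**Rejection sampling.** Adjacent components closer than 30 Hz cause audible
beating, so jitter draws are constrained to keep at least 30 Hz spacing. We
implement this *per component*: components are realized in ascending order
and only a violating draw is redrawn. The alternative — redrawing the whole
jitter vector until every adjacent pair clears 30 Hz — looks cleaner but has
acceptance probability that decays geometrically in the number of
components; with harmonics up to 24 kHz at the F0s used here the joint
acceptance probability is effectively zero and the sampler never terminates.
Per-component redrawing always terminates because consecutive base
harmonics are at least `f0 (1 - jc) ≥ 100` Hz apart. The cost is a slight
conditional distortion of the jitter distribution at components where the
constraint binds; the zero-mean property of the jitter is exact only where
the constraint is slack, and the test suite checks it there.

**Loudness.** No loudness meter exists on CRAN, so the package implements
an ITU-R BS.1770-style K-weighted integrated loudness: the published
two-biquad weighting at 48 kHz (RBJ designs at other rates), 400 ms gating
blocks with 75% overlap, absolute gate at −70 LUFS and a relative gate
10 LU down. The 70 ms stimuli are shorter than one gating block, so short
signals are measured ungated over their full length. A plain-RMS mode
(`method = "rms"`) is exposed for speed in tight loops.

# Roving paradigm and labeling

`generate_roving_sequence()` draws train lengths uniformly from 4–7,
changes F0 at each train boundary (uniform over the grid minus the current
F0; earlier F0s may recur — only immediate repeats are barred), and
truncates the last train to hit the requested 600 events. Role labeling
(`label_events()`) follows three rules, in precedence order: the first five
events of a sequence are excluded; the first event of every train after the
first is a deviant; the two events after each deviant position are excluded.
Everything else is a standard, and the three roles partition the sequence.
The opening tone of the first train is never a deviant (it has no preceding
context); the first-five rule covers it in any case.

# Adaptive staircase

The behavioral layer simulates a 2AFC pitch-discrimination task controlled
by a 3-up-1-down staircase over jitter-level indices 0–10. "Up" means
*harder* (more jitter) after three consecutive correct responses; any error
steps down. This is the only direction convention consistent with the
procedure's convergence at `p^3 = 1/2`, i.e. 79.37% correct. Conventions
the literature leaves open were fixed as follows:

* a move blocked by the level bounds (0 or 10) records no reversal and does
  not touch the direction memory — only realized direction changes count;
* reversals are recorded at the turning-point level (the extremum reached);
* a block halts at the 6th reversal and its threshold is that final
  reversal's level; participant thresholds average 15 blocks;
* a trial cap (default 1000) guards against degenerate observers (a
  perfect observer marches to the ceiling and never reverses; the cap
  reports the ceiling with a warning).

The default simulated observer (`logistic_observer()`) is logistic in the
level index with guess rate 0.5 and zero lapse. Because the jitter schedule
is geometric, level index is affine in `log10` jitter, so this is a
logistic psychometric function in log jitter rate. Defaults — midpoint 5,
slope 1.5 levels — place the 79.37% point mid-scale with a spread wide
enough that the discrete staircase resolves it. Finite blocks and integer
steps leave a small downward bias (about a percentage point at these
settings) in the accuracy read off at the mean converged level; the
convergence checks in the test suite use the tolerance this implies.

# Synthetic ERP data

`generate_peak_table()` draws per-participant, per-condition MMN/P3a
amplitudes and latencies directly from the generative model above —
`L_p ~ N(L_mean, L_sd^2)`, sigmoid mean, Gaussian residuals; P3a follows a
quadratic in entropy (an inverted-U peaking at moderate entropy); latencies
are condition-independent. Defaults (`generative_params()`): `L_mean`
−1.5 µV, `L_sd` 0.5 µV, `k` 8, `I0` −1.18, `resid_sd` 0.5 µV, 34
participants, conditions `j1`–`j7`. The design quantities (participant
count, condition set, inflection) mirror the study regime this package
models; the spread parameters are unreported there and are configuration
values chosen to be plausible for fronto-central mean amplitudes — they are
arguments, not constants.

`generate_epochs()` goes one level deeper and produces per-event waveforms:
−100 to 500 ms epochs (default 500 Hz) carrying a common ERP shape, plus,
on deviants only, a negative Gaussian MMN deflection (center 150 ms, SD
40 ms, depth = the participant-condition sigmoid value) and a positive P3a
deflection (center 250 ms), under white or 1/f noise. This emulates the
*statistical* structure the measurement pipeline assumes — averaging,
subtraction, baseline correction, windowed peak extraction — and nothing
more: no multichannel topography, volume conduction, ocular artifacts, or
artifact-rejection behavior. Passing tests therefore certify the analysis
machinery, not robustness to real-EEG pathologies.

# ERP measurement

The measurement chain is `average_by_role()` → `difference_wave()` →
`baseline_correct()` (−100–0 ms mean) → `peak_measures()`. MMN latency is
the minimum over 70–250 ms, P3a latency the maximum over 150–350 ms, and
each amplitude is the mean over latency ±25 ms. Numerical conventions:

* the extremum is the *windowed global* one by default — robust on noisy
  waves; a strict local-extremum mode exists behind `local = TRUE` and
  falls back (with a warning) when no interior extremum exists;
* ties resolve to the earliest latency, so flat waves are deterministic;
* a ±25 ms window that would cross the epoch edge is truncated with a
  warning rather than an error (impossible on spec-conformant −100–500 ms
  epochs, since 350 + 25 < 500);
* extremum selection on pure noise is biased (a windowed minimum of white
  noise has negative expectation); the test suite quantifies this against a
  direct Monte-Carlo so users are not surprised by "MMN" in noise.

When the two deflections overlap (40 ms SDs at 150 and 250 ms centers do,
slightly), the extremum of the *summed* injected waveform — not the nominal
center — is the ground truth; the oracle tests compute it analytically.

# Statistical layer

All models are fit by **maximum likelihood**, never REML, because the
workflow compares fixed-effect structures by likelihood-ratio tests and
information criteria.

**Sigmoid fit** (`fit_sigmoid_mixed()`): conditional on `(k, I0)` the model
is linear in `L_p`, so the marginal likelihood is Gaussian in closed form —
no quadrature. Writing `lambda = sigma_L^2 / sigma^2`, both `L` (by GLS)
and `sigma^2` are profiled analytically, leaving a 3-parameter optimization
over `(log k, I0, log lambda)`. The optimizer is Nelder-Mead from the best
points of a coarse `(k, I0, lambda)` grid, polished by BFGS; the multi-start
dodges the local optima typical of logistic-shape fits, and optimizing
`log k` keeps the slope positive (the decreasing-magnitude orientation).
`sigma_L` collapsing to ~0 is flagged as a boundary fit rather than an
error. The residual variance is floored at 1e−12 so noise-free data (used
by the recovery tests) remain finite.

**Polynomial and null fits** (`fit_polynomial_mixed()`, `fit_null_mixed()`)
are random-intercept models delegated to `nlme::lme` under ML; the sigmoid
fit is authored here because its random effect multiplies a nonlinear
function of the parameters, which is the model family `lme` does not cover.

**Information criteria.** The parameter count is fixed effects plus
variance components: sigmoid 5 (`L, k, I0, sigma_L, sigma`), null 3,
degree-d polynomial d+3. BIC uses the total observation count. Counting
conventions differ across software, so absolute AIC/BIC values are only
comparable within this package; all comparisons the package reports are
internal, which is the only use the workflow needs.

**LRT nesting** (`lr_test()`): null ⊂ polynomial(d) ⊂ polynomial(d+1) and
null ⊂ sigmoid (df 2: `k` and `I0` appear with the sigmoid's variance pair
replacing the null's). Sigmoid-vs-polynomial pairs are refused — the
likelihood-ratio distribution for non-nested mixed models is unknown — and
compared by AIC/BIC instead. A "larger" model with a materially lower
log-likelihood is treated as an optimization failure, not clamped.

**Group tests.** `amplitude_ttests()` runs per-condition one-sample t-tests
with Benjamini-Hochberg adjustment within each component family.
`rm_anova()` implements the one-way within-participant F-test with
Greenhouse-Geisser epsilon from the double-centered condition covariance
and Mauchly's test (first-order chi-square approximation; the test suite
cross-checks W exactly and p closely against `stats::mauchly.test`, and F,
epsilon and the corrected p exactly against `car::Anova`). The corrected p
is always reported; callers can consult Mauchly to decide when it matters.
`posthoc_pairwise()` tests all paired mean differences against the ANOVA
error term with studentized-range (Tukey) adjustment; on balanced designs
this reproduces the estimated-marginal-means machinery (cross-checked
against `emmeans` to 1e-8), which is the approximation chosen in place of
carrying a full EMM dependency.

# Power analysis

`power_at_n()` reproduces the simulation design used to size such studies:
8 conditions whose means are equal except one offset by 1 µV (worst case),
participant random intercepts, Gaussian residuals; each replicate is tested
with the repeated-measures ANOVA above (GG-corrected p), which for this
balanced one-way design is exchangeable with a mixed-model ANOVA with
participant as a random effect. Defaults put both SDs at 1.5 µV — explicit
configuration, because the SDs behind any published minimal-N figure of
this design are not recoverable from the design alone; consequently the
package treats the resulting minimal N as configuration-dependent output
(`minimal_n()` scans 20–40 ascending), and its own guarantees are the
testable ones: type-I calibration at zero effect and monotonicity in `n`
and in effect size.

# Reproducibility, scale, and interfaces

Every generator consumes either an explicit `seed` argument or the current
RNG state; `run_pipeline()` derives all stage seeds from one global seed,
and reruns are byte-identical. Test-suite problem sizes were chosen so the
full suite runs in well under a minute while keeping Monte-Carlo standard
errors inside the asserted tolerances: 200 replicates for sigmoid parameter
recovery and AIC model selection, 200 simulated participants × 15 blocks
for staircase convergence, 300–1000 replicates for power calibration, and
300–4000 draws for sampler properties. The package's interface is its
functions plus `run_pipeline()`/`make_fixtures()`; the one script shipped
(`scripts/acceptance.R`) is a thin wrapper that recomputes the headline
staircase-convergence quantity and writes JSON.

# Known limitations

* Synthetic epochs are single-trace (already cluster-averaged); the
  channel-set helper averages named traces but there is no spatial model.
* The sigmoid fit supports exactly the random-asymptote structure; the
  all-parameters-random variant (with diagonal covariance) is out of scope.
* Per-component rejection sampling slightly biases jitter where the 30 Hz
  constraint binds (high harmonics at large `jc`).
* The BS.1770 meter is mono and, for sub-400 ms signals, ungated by
  necessity.
* Latency analyses reuse the polynomial path; no sigmoid model for latency
  is provided (none is warranted — latencies are generated
  condition-independent).
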