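---
title: "Models and methods behind dualcue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dualcue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dualcue)
```

`dualcue` implements, end to end, the computational machinery of a
dual-cue spatial-cueing study of exogenous visual attention: cue
construction from a constrained maximum-entropy model of early vision,
exact trial-schedule generation for a covert (2AFC contrast
discrimination) task and a gaze-orienting (saccade) task, synthetic
observers for both tasks, psychometric threshold estimation, saccade
detection and classification, and the group statistics used to summarise
such experiments. This vignette documents the models, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic-data tests do and do not establish.

## 1. The constrained maximum-entropy feature model

The cue stimuli are small binary patches (3 × 3 cells rendered as 9 × 9
pixels). The theory behind them treats early vision as a compressive
filter that can store only a limited dictionary of pattern detectors
(*limited storage*, at most $N$ patches) and transmit only a bounded
amount of data per unit time (*limited bandwidth*, total probability mass
at most $W$). Given the empirical probability $p_i$ of each patch in an
image ensemble, the *optimal* dictionary solves

$$\max_{D} \; H(D) = -\sum_{i \in D} p_i \log_2 p_i
  \quad \text{s.t.} \quad |D| \le N, \;\; \sum_{i \in D} p_i \le W .$$

*Non-optimal* patches are simply the $N$ patches with the lowest positive
probability of occurrence (ties broken by ascending patch code).

Numerical choices:

* **Patch statistics** (`estimate_patch_distribution`) count every
  stride-1 window with no wraparound; codes are row-major with the
  most-significant bit at the top-left cell. Binarization
  (`binarize_image`) thresholds at the image median with ties mapped
  to 1.
* **Solver** (`select_optimal_features`): the problem is a knapsack with
  a cardinality constraint. Alphabets with ≤ 20 positive-probability
  patterns are solved exactly by branch and bound (bound: the sum of the
  largest remaining entropy terms); the full 512-pattern alphabet uses a
  heuristic — rank patches by $|p_i - W/N|$ (the solution concentrates at
  $p \approx W/N$), fill greedily under both constraints, then improve by
  pairwise swaps — and is guaranteed never to fall below a
  greedy-by-entropy baseline. The test suite holds the solver to an
  exhaustive-enumeration oracle on 200 random small alphabets.
* **Entropy base**: bits (log2). The base rescales the objective without
  changing the argmax.
* **Defaults** $N = 50$ (the experiments use 50-feature cue sets) and
  $W = 0.05$. The bandwidth actually used to produce the published cue
  sets is not printed anywhere, so this package makes no claim of
  reproducing those exact dictionaries; $W$ is exposed and documented.
* **Rendering** (`render_cue`): black cells at 4 cd/m², white at
  44 cd/m²; the luminance-control cues are uniform 20 / 23 cd/m² patches
  on a 16 cd/m² background (the "equivalent contrast" calibration).
  `check_luminance_balance` verifies that two dictionaries match in mean
  luminance.
* **Image input**: plain PGM (P2/P5) only — the sandbox has no R PNG
  reader. `simulate_natural_images` provides a smoothed-noise stand-in
  ensemble whose binarized patch statistics are spatially correlated;
  it reproduces no higher-order structure of natural scenes, so tests on
  it establish correctness of the estimator and solver, not ecological
  claims about feature sets.

## 2. Experiment design

Both tasks present two brief peripheral cues at ±5° eccentricity and,
after a 150 ms SOA, a target on one side. Non-neutral trials place the
salient cue on the target side (*valid*) or opposite (*invalid*);
neutral trials show two equally (non-)salient cues. Each session fixes
the cue validity — the percentage of non-neutral trials that are valid —
at 50% (125/125 per condition) or 80% (200/50 per condition).

`build_covert_schedule` and `build_gaze_schedule` generate one session
each with the printed per-cell counts (covert: 112 neutral + 250
non-neutral per condition and session, 1448 trials over two sessions;
gaze: 100 + 250, 1400 trials). Contrast levels (8 log-spaced values in
[0.01, 0.09] by default), target side and gabor tilt are balanced within
every design cell to within one trial; the trial order is a seeded
permutation, so a seed reproduces a schedule exactly. Cue duration is
not printed in the source design; it is stored as metadata (default
25 ms) and plays no computational role. The composition of the covert
neutral block (whether experimental- and control-condition neutral cues
interleave) is ambiguous in the source; totals are not, and this package
interleaves them.

## 3. Synthetic observers

The simulators inject the effects at the summary level rather than via an
attention mechanism — deliberately: the point is to make every analysis
stage testable against known ground truth, not to model attention.

**Covert observer.** A correct response is Bernoulli with probability

$$\Psi(c) = \gamma + (1 - \gamma - \lambda)\,
  \Phi\!\left(\frac{c - \mu_t}{\sigma}\right),$$

with guess rate $\gamma = 0.5$ (2AFC), lapse $\lambda = 0$, and
trial-type-dependent location $\mu_t = \mu_\text{neutral}(1 +
\text{effect}_t)$. Defaults: $\mu_\text{neutral} = 0.045$,
$\sigma = 0.012$ (the measured group thresholds sit near 0.041–0.051),
effects −5% (valid) and +10% (invalid).

**Gaze observer.** Traces sample fixation noise (Gaussian, sd 0.05° per
axis) at 1 kHz from cue onset to 650 ms after target onset. Regular
saccades have amplitude 5° toward the target (flipped with a
type-dependent error probability: 2.5% / 1% / 5.5% for
neutral/valid/invalid, inside the 0.2–7% range of the measured data) and
latency drawn from a Gaussian (mean 165 ms, the type effect −4%/+5%
multiplicative, sd 30 ms) truncated to (80, 500) ms. With
type-dependent probability (3% neutral, 6% non-neutral) an anticipatory
saccade precedes the regular one: amplitude uniform in 1–2.5°, onset
uniform in (−70, 80) ms, directed to the salient side with probability
0.85, always followed by a corrective saccade to the target. Those
percentages are not printed in the source; they were fixed once at
values a practitioner would call realistic for cue-driven anticipation
and are config-exposed.

**Saccade kinematics.** Waveforms are minimum-jerk:
$x(s) = A(10 s^3 - 15 s^4 + 6 s^5)$, $s = (t - t_0)/D$, with duration
$D = 1.875/\text{slope}$ so that peak velocity equals
$\text{slope} \times A$ exactly (linear main sequence, default slope
55 s⁻¹ → 275 °/s at 5°) and displacement integrates to $A$ exactly. The
profile has compact support, which makes the *programmed onset* (the
support start) well defined — a Gaussian velocity profile has no
principled onset and, after the mandated 30 Hz acausal filtering, shows
a ~3 ms systematic onset bias that would violate the pipeline's own
round-trip tolerance. Simulator and detector agree to within ~0.4 ms
mean absolute latency error at 5° amplitude under noise.

## 4. Oculomotor analysis

Position channels are filtered with a zero-phase (forward–backward)
order-2 Butterworth low-pass at 30 Hz (designed by bilinear transform
with prewarping, so the squared response is exactly 0.5 at the cutoff;
at 1 kHz sampling the gain at 60 Hz is 0.0567 versus the analog 1/17 —
the difference is bilinear frequency warping, and the analog contract is
verified at 20 kHz sampling in the tests). Mirror padding of six filter
time constants makes start-up transients irrelevant (< 1e−9 on DC).
Velocity and acceleration come from central differences (one-sided at
the ends).

Detection is conjoint: a candidate event is a contiguous run of samples
with 2-D speed above `v_thresh`/3; it fires only if some sample exceeds
both `v_thresh` (30 °/s) and `a_thresh` in acceleration magnitude, and
the first such sample is the reported onset (the latency marker). Runs
closer than 20 ms merge; events shorter than 8 ms are dropped.

Two deliberate deviations from common tracker defaults:

* **`a_thresh` = 2000 °/s², not 8000.** With the stated main-sequence
  slope, the 30-Hz-filtered peak acceleration of a 1–1.5° anticipatory
  saccade is only ~2800–4500 °/s² (measured); an 8000 threshold would
  make small anticipatory saccades undetectable by construction.
  2000 °/s² keeps the conjoint character: fixation noise at sd 0.05°
  peaks near 22 °/s and 1900 °/s² and never crosses the joint criterion.
* **Amplitude from fixation plateaus.** The instantaneous
  $|x(\text{offset}) - x(\text{onset})|$ is biased under the acausal
  filter (−0.2° for 1° saccades, +0.13° for 5° ones depending on the
  boundary convention). Amplitude is instead the difference of 20 ms
  pre/post plateau means around the event (clipped away from
  neighbouring events), which is unbiased on noiseless traces and has
  ~0.04° noise at the default fixation noise. Direction is the sign of
  that displacement.

Classification follows the event taxonomy: the *regular* saccade is the
first event with latency strictly in (80, 500) ms and amplitude > 2°
(40% of the 5° eccentricity), labelled *correct*/*erroneous* by side;
*anticipatory* saccades have latency strictly in (−70, 80) ms and
amplitude ≥ 1°; boundary values are unclassified (open intervals,
matching the "longer than / shorter than" wording of the source
criteria); trials without events are *aberrant*. Summaries report mean
correct-regular latency per cell, latency change relative to the
same-condition neutral baseline, and error/anticipatory percentages over
all detected saccades (switchable to regular-only); across participants,
anticipatory statistics use weighted averages with the per-participant
anticipatory counts as weights.

## 5. Psychometric analysis

`fit_psychometric` maximises the binomial log-likelihood over
$(\mu, \log\sigma)$ by Nelder–Mead from a 5 × 5 coarse grid (three best
grid points refined; relative tolerance 1e−10). Guess and lapse are
fixed (0.5 / 0), on a linear contrast abscissa — the tested range
(0.01–0.09) is narrow enough that a log abscissa is a reparameterisation,
not a different model. Data with every level at ceiling, or none above
the guess rate, are flagged `converged = FALSE` rather than fitted. The
80%-correct threshold is the analytic inverse
$\mu + \sigma\,\Phi^{-1}\!\big((0.8 - \gamma)/(1 - \gamma -
\lambda)\big)$, so evaluating the fitted curve at the returned threshold
reproduces the criterion to machine precision — the identity the
acceptance target checks. Cells that never reach the criterion are
reported missing, never extrapolated.

Relative changes are $100(\text{value} - \text{baseline}) /
\text{baseline}$ against the same condition-and-validity neutral cell,
computed per participant and then averaged (the mean of per-participant
changes is not the change of mean thresholds; the source reports the
former).

## 6. Group statistics

`rm_factorial_anova` uses the classical within-subject strata
decomposition (condition × trial type × validity, one observation per
participant and cell; trial type with 16 participants gives the familiar
df = (2, 30)); effect size is classical $\eta^2 = SS_\text{effect} /
SS_\text{total}$ with the between-participant stratum included in the
total — which is why large F values can coexist with small $\eta^2$.
Sphericity corrections are deliberately off by default.
`friedman_conover` implements the classical Friedman $\chi^2$ on
midranks (cross-checked against `stats::friedman.test`), Kendall's
$W = \chi^2 / (n(k-1))$, and Conover's rank-sum post-hoc t tests with
Bonferroni correction. `two_proportion_z` is the pooled-variance normal
test, appropriate for the large saccade counts. Null calibration of the
rank and proportion tests (empirical size within [0.03, 0.07] at nominal
0.05) is asserted in the test suite.

## 7. What the synthetic tests do and do not establish

A green suite establishes that: the designs carry exactly the printed
trial bookkeeping; the analytic identities (threshold inversion, filter
gains, SS partition) hold; the exact solver matches brute force; and the
full simulate → analyse loop recovers the parameters it was given, at
the trial counts of the real experiment, with the right effect signs and
orderings. It does **not** establish anything about human observers: the
simulators inject effects directly, have no attention dynamics, no
pursuit, blinks, pupil artefacts or drift, stationary Gaussian fixation
noise, a fixed 5° saccade amplitude, and a deterministic main sequence.
Reproducing the published group means and test statistics would require
the human data and is explicitly out of scope.

Replicate-unit choices in the stochastic acceptance checks are dictated
by power at desk scale: threshold ordering uses 100 cohorts of 16
simulated participants (full 1448-trial design, fits pooled per trial
type); latency ordering uses 100 replicates of one simulated
participant's 1400 trials, because a single 700-trial session leaves the
100-trial invalid cell with ~3 ms standard error against a ~7 ms effect
and orders correctly only ~90% of the time — a power statement, not a
pipeline defect.

## 8. Reproducibility

Every stochastic function takes a seed; the pipeline derives
per-participant, per-stage child seeds from the root seed by a counter
hash, so whole cohorts are reproducible and extensible participant by
participant. `run_end_to_end` writes CSV artifacts with MD5 checksums in
a JSON manifest; identical configs produce byte-identical artifacts.
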