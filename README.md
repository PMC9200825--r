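# dualcue

Simulation and analysis pipeline for **dual-cue spatial-cueing experiments
on exogenous visual attention**, in which the two competing peripheral cues
are tiny binary patches selected by a constrained maximum-entropy model of
early vision ("optimal" information-carrying features vs. "non-optimal"
lowest-probability features).

The package is aimed at visual psychophysicists and oculomotor researchers
who want to (a) build such cue sets from image statistics, (b) generate the
exact dual-cue Posner-style trial designs of a covert-attention (2AFC
contrast discrimination) task and a gaze-orienting (saccade) task, (c)
simulate observers with known ground truth, and (d) run the full analysis
chain — psychometric thresholds and saccade detection/classification — with
every stage testable against the simulators.

## The models in brief

**Cue selection.** Given patch probabilities $p_i$ estimated from binarized
images, the optimal dictionary maximises transmitted entropy under a
storage bound $N$ and a bandwidth bound $W$:

$$\max_D \; -\sum_{i\in D} p_i \log_2 p_i
 \quad\text{s.t.}\quad |D|\le N,\;\; \sum_{i\in D} p_i \le W$$

(exact branch-and-bound for small alphabets, a swap-improvement heuristic
for the full 512-pattern alphabet). Non-optimal features are the $N$ rarest
patches.

**Psychometrics.** 2AFC performance follows a cumulative Gaussian
$\Psi(c) = \gamma + (1-\gamma-\lambda)\,\Phi((c-\mu)/\sigma)$ with guess
rate $\gamma = 0.5$; cell thresholds are the contrasts where the
maximum-likelihood fit reaches 80% correct, reported as percent change
against the same-condition neutral baseline.

**Oculomotor analysis.** Gaze traces are low-pass filtered (zero-phase
order-2 Butterworth, 30 Hz), differentiated, and scanned by a conjoint
velocity–acceleration detector; saccades are classified as *regular*
(latency 80–500 ms, amplitude > 2°; *correct* vs. *erroneous* by side) or
*anticipatory* (latency −70…80 ms, amplitude ≥ 1°).

## Worked example

```r
library(dualcue)

# 1. Cue dictionaries from (synthetic stand-in) image statistics
imgs <- simulate_natural_images(6, size = 96, seed = 42)
dist <- estimate_patch_distribution(lapply(imgs, binarize_image), patch_side = 3)
opt  <- select_optimal_features(dist, N = 50, W = 0.05)
non  <- select_nonoptimal_features(dist, N = 50)
opt
#> optimal feature dictionary: 50 patches (N = 50, W = 0.05), H = 0.4973 bits, mass 0.0500
non
#> nonoptimal feature dictionary: 50 patches (N = 50), H = 0.0219 bits, mass 0.0015
check_luminance_balance(opt, non)   # mean cue luminance difference, cd/m^2
#> 1.244 cd/m2

# 2. End-to-end synthetic cohort: design -> simulate -> analyse
res <- run_end_to_end(run_config(seed = 1, n_participants = 4))
subset(res$covert_group, condition == "experimental",
       c(validity_block, trial_type, threshold, relative_change_pct))
#>    validity_block trial_type threshold relative_change_pct
#> 2              50    invalid    0.0503               0.376
#> 4              80    invalid    0.0534              13.040
#> 6              50    neutral    0.0501                  NA
#> 8              80    neutral    0.0475                  NA
#> 10             50      valid    0.0468              -6.545
#> 12             80      valid    0.0459              -2.813
subset(res$gaze_group, condition == "experimental",
       c(validity_block, trial_type, mean_latency_ms, latency_change_pct))
#>    validity_block trial_type mean_latency_ms latency_change_pct
#> 2              50    invalid             174               5.66
#> 4              80    invalid             171               5.47
#> 6              50    neutral             165                 NA
#> 8              80    neutral             162                 NA
#> 10             50      valid             158              -4.07
#> 12             80      valid             158              -2.58
```

Read: with simulated cueing effects of −5 %/+10 % on contrast thresholds and
−4 %/+5 % on saccade latencies, the recovered group tables show exactly that
structure — thresholds and latencies drop in valid trials and rise in
invalid ones relative to the neutral baseline, in both validity blocks.
Anticipatory saccades in this run go to the salient side 85–89 % of the
time (simulated preference: 85 %).

The full design bookkeeping is exact: two covert sessions total 1448 trials
(112 neutral + 250 non-neutral per condition and session; the 80 % block
splits 200 valid / 50 invalid, the 50 % block 125/125) and two gaze
sessions total 1400.

See `vignettes/dualcue-methods.Rmd` for the models, parameter defaults,
numerical conventions (filter design, saccade kinematics, detection
thresholds) and the limits of what the synthetic tests establish.

## Acceptance script

`scripts/acceptance.R` recomputes the pipeline's acceptance quantity from
scratch against the installed package — it regenerates noiseless expected
proportions from known psychometric parameters, refits them by maximum
likelihood, inverts the fit for the 80 %-correct threshold, evaluates the
fitted curve there, and writes the result as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Command line

A thin wrapper over the same functions lives in `inst/scripts/`:

```sh
Rscript inst/scripts/run_pipeline.R --seed 1 --participants 16 --out runs/cohort1
```
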