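---
title: "Simulating and analysing dopaminergic value and identity prediction errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing dopaminergic value and identity prediction errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vipe)
```

## The scientific problem

Midbrain dopamine neurons classically signal *value* prediction errors: they
fire when a reward is larger than predicted and pause when a predicted reward
is omitted. They also respond to value-neutral changes in what a reward *is*
— its sensory identity, such as the flavor of a milk drop — so-called
*identity* prediction errors. Where those predictions come from is an open
question; candidate sources are the hippocampus (HC) and the orbitofrontal
cortex (OFC), both of which project (indirectly) to the ventral tegmental
area (VTA).

The experimental design this package models records VTA single units in rats
performing an odor-guided choice task while either HC or OFC is lesioned on
the recording side. The behavioral task arranges five blocks over a session:
two wells deliver a big (3-drop) and a small (1-drop) flavored-milk reward;
blocks 2 and 4 swap the drop counts between wells without touching flavors
(**value shifts**), and blocks 3 and 5 swap the flavors without touching drop
counts (**identity shifts**). Because the raw recordings are not publicly
deposited, the package pairs the full analysis chain with a synthetic
generator whose presets encode the three observed neural phenotypes, so that
every statistic in the chain can be exercised and validated end to end.

## The task generator

`task_config()` fixes the structural parameters: block 1 runs 30–50 trials
and later blocks 60–100; a block can only end once the animal chose the
big-reward well on at least 6 of the last 10 free-choice trials; odors are
pseudorandom with the free-choice odor on exactly 7 of every aligned
20-trial window and at least 6 of each forced odor, never more than 3
identical odors in a row. Since 7 + 6 + 6 fills only 19 of 20 trials, the
remaining trial in each window is a forced odor with a random side — the
strongest reading of the published mix that keeps the window arithmetic
consistent. The composition is enforced by constrained shuffling with
rejection, with run-lengths checked across window boundaries.

Behavior is a small Rescorla–Wagner chooser (`behavior_params()`): per-well
drop-count beliefs updated after each rewarded trial (rate 0.25), a softmax
over the belief difference for free choices (sensitivity 3 per drop), and
forced-choice accuracy and shifted-lognormal reaction times that favor the
big reward (0.95 vs 0.85 correct; 0.40 vs 0.70 s mean RT). These values are
not fitted to animals; they are chosen so that the qualitative behavioral
signature — faster, more accurate, and strongly big-preferring by block end —
holds robustly, which is all the downstream neural analysis requires (the
switch criterion guarantees every shift is preceded by a learned
prediction). Beliefs start at the block-1 truth, as in an extensively
trained animal. Forced-choice errors end the trial unrewarded but still
count toward block length. All event times are seconds from session start
and every analysis window is half-open `[start, end)`.

## The prediction-error rate model

The simulated animal carries, per well, a probability of receiving a drop in
each of three drop slots and a belief distribution over flavors
(`td_state_init()`, initialized at the block-1 truth). After each rewarded
trial, `td_update()` computes per-slot value errors
`delivered_k − expected_k`, an identity error
`1 − belief(delivered flavor)` evaluated at the first drop, and moves the
visited well's expectations toward the observation at rates `alpha_value`
and `alpha_identity` (defaults 0.3). Unrewarded trials produce no errors and
no update — the animal never samples the well outcome.

`firing_rate_profile()` turns one trial's errors into a piecewise-constant
rate: a tonic baseline (5 spikes/s), plus for every delivered drop a box
kernel 0.1–0.5 s after the drop whose height is

* an unconditional reward response (`reward_gain`, 8 spikes/s),
* `value_gain_pos` (10 spikes/s) times the positive part of that slot's
  value error,
* `identity_gain` (8 spikes/s) times the trial's identity error (applied at
  every delivered drop, matching the observation that identity responses
  ride on each drop of both rewards),

minus, in a window anchored at the expected time of an omitted drop,
`value_gain_neg` (4 spikes/s) times the negative error magnitude, floored at
zero — at a fully unexpected omission the default brings the rate to 20% of
baseline. The unconditional reward response is a deliberate extension of a
pure error-coding scheme: lesioned animals retain reward-responsive dopamine
neurons even when error modulation is abolished, so responsiveness and error
coding must be separable terms. Spike trains are sampled from the profile as
an inhomogeneous Poisson process (`sample_spikes()`; exact per-segment
sampling for piecewise-constant rates, thinning against a supplied bound for
arbitrary rate functions). Per-unit heterogeneity comes from a lognormal
baseline spread and a ±30% multiplicative gain jitter.

### Group presets

* **control** — the full model; value and identity errors are transient
  because learning updates the predictions within a block.
* **HCx** — prediction-error gains set to zero and learning rates to 1:
  priors update instantly, so nothing is ever surprising, but the
  unconditional reward response is intact. This implements the
  prior-updating account of the hippocampal lesion rather than a noise
  injection.
* **OFCx** — `alpha_identity = 0` (identity predictions never update, so
  identity errors persist indefinitely), the positive value gain attenuated
  to 60%, and no omission dip.

A consequence worth making explicit: with frozen flavor beliefs, the first
identity shift (block 3) raises the OFCx identity error to 1 and it stays
there through block 4, while the second shift (block 5) returns the flavors
to the frozen prior and the error collapses to 0. Averaged across the two
shifts, OFCx early-vs-late identity difference scores therefore center on
zero *while* post-shift firing after the first shift stays persistently
elevated — exactly the published pair of observations. The persistence and
level analyses (`identity_shift_timecourse()`) accordingly anchor on the
first identity shift, where the prediction history is clean.

## Waveform classification

Putative dopamine neurons are identified from the mean waveform alone, by
two features: the **half-duration** (read as the full width at half maximum
of the dominant deflection, in ms; the published description — "the half
time of the spike duration" — does not pin the definition down, and the FWHM
reading is the one that is well-defined for any biphasic shape) and the
**amplitude ratio** `(n − p)/(n + p)` of the first negative and first
positive waveform segments in temporal order. Initial partitioning uses
k-means (10 restarts, standardized features, fixed seed); the
longer-half-duration cluster is designated dopamine-like, following the
waveform literature. Assignment then follows the leave-one-out rule: each
cluster's center and per-axis s.d. are recomputed without the unit of
interest, and the unit joins a cluster only if it lies within 3 s.d. —
implemented as within-threshold on *both* axes, with a diagonal-covariance
Mahalanobis option (`classifier_config(metric=)`) since the published
phrase "within 3 s.d." is ambiguous in two dimensions. Units within the
threshold of zero or of two clusters stay unclassified; units with undefined
features (flat traces) are excluded before clustering and reported, never
silently dropped. The number of clusters is configurable (default 2).

The synthetic waveform generator draws target features from per-cluster
bivariate normals and constructs a biphasic Gaussian-lobed trace realizing
them exactly, so classification can be validated against ground truth; the
default clusters are separated by more than 6 s.d. on the half-duration
axis, as in the recorded data where the classifier was validated against
tyrosine-hydroxylase-positive units.

## Screening and difference scores

`is_reward_responsive()` pairs each rewarded trial's firing 100–500 ms after
the first delivered drop with the same trial's 400 ms pre-trial baseline and
applies a one-sided paired t-test at p < 0.05. The test is paired (the
stronger reading of a per-trial baseline) and one-sided (only units that
*increase* firing to reward are kept). No multiplicity correction is applied
across units, matching the original screen. Calibration on homogeneous
Poisson units is part of the test suite: the empirical false-positive rate
sits at the nominal 5%.

Difference scores (`value_shift_scores()`, `identity_shift_scores()`)
contrast mean windowed firing between the first 5 and last 5 qualifying
rewarded trials. For value shifts both sides lie within the post-shift
block, at the well whose reward grew (delivery of the now-unexpected 2nd
drop) or shrank (the window where the expected 2nd drop no longer arrives,
anchored at first drop time + 500 ms). For identity shifts the early side is
the start of the new block and the late side the end of the previous block,
separately for the 1st and 2nd drops of the big reward and the single small
drop, plus a no-shift comparison window 0.5–1.0 s after the small reward.
"Early/late" counts qualifying rewarded trials per destination well, forced
and free pooled (the published text does not specify the pooling; this is
exposed in `analysis_config()`). Identity scores are baseline-normalized by
default — the published level analyses are explicitly baseline-normalized,
and normalization cannot change a score's sign — with a raw mode available.

`summarize_scores()` reports the mean score *u* and a two-sided Wilcoxon
signed-rank p against a zero median, dropping exact zeros before ranking
(classical convention) and mid-ranking ties; for n ≤ 10 without ties this
matches exhaustive sign-assignment enumeration exactly. Factorial ANOVAs on
per-trial window rates (`run_factorial_anova()`) absorb unit identity as a
fixed blocking factor before the stated factors; the published degrees of
freedom are not fully reconstructable from the methods text, so printed F
values from the recordings are treated as qualitative anchors only, never as
numeric targets. `chi_square_proportions()` is a Pearson chi-square without
continuity correction; on the published classification counts (80/408,
110/513, 90/412) it reproduces the printed statistic of 0.71 with df 2.

## Numerical and degenerate-input conventions

Window counting is half-open everywhere (a spike exactly at a window's end
belongs to the next window). Rates are counts divided by window length. A
unit with no spikes has zero rates and zero scores; baseline normalization
falls back to raw rates when a unit's baseline is zero. A zero-variance
difference vector in the screen is flagged and treated as non-responsive
unless the constant difference is positive. ANOVA terms with zero
between-cell variance report F = 0, p = 1 rather than a 0/0. Spike times are
strictly increasing (measure-zero collisions are dropped), and every
pipeline stage is deterministic given its configuration and seed, down to
the serialized bundle bytes.

## What the synthetic data does and does not show

The generator reproduces the task structure exactly and the neural
phenotypes at the level the published analyses measure them: direction,
transience/persistence, and approximate effect scale of window rates. It
does not emulate drift, bursting or other non-Poisson spike statistics,
cue-period (odor-evoked) responses, satiety, or electrode instability, and
its behavioral module is not fitted to animals. Passing tests therefore
demonstrate that the *analysis chain* recovers the intended signatures from
data that contain them — not that real VTA recordings would. Effect-size
parameters (gains, learning rates) are free parameters of the generator,
chosen once at physiologically sensible values (phasic responses of 8–18
spikes/s over a 5 spikes/s baseline); the published work quantifies these
contrasts only relatively, so cohort-level acceptance checks are
pattern-level, not numeric.

One statistical property of the pattern checks deserves note: the lesion
presets are exact nulls on four to five contrasts each, so at alpha = 0.05
per contrast a cohort seed shows at least one nominally significant null
contrast with probability roughly 1 − 0.95⁴⁻⁵ ≈ 0.19–0.23. The multi-seed
criterion (16 of 20 seeds) sits close to the resulting expected pass rate;
occasional failing seeds are the correct behavior of the statistics, not a
generator defect, and the study driver reports them as such.

## Problem sizes

The shipped drivers and tests use sessions of ~350–420 trials (the drawn
block lengths plus the switch criterion's overshoot), cohorts of 46
reward-modulated units (the analysed control cohort size) for the phenotype
study and 120 mixed-population units for the classification stages, 20
cohort seeds per preset, 10,000 odor windows for the composition scan, and
1,000 replicates for screen calibration. These sizes keep a full run on one
CPU in the low minutes while leaving every statistic well inside its
asymptotic regime.
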