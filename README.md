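# vipe — value and identity prediction errors in simulated VTA recordings

`vipe` re-implements, as a tested R pipeline, the analysis of dopaminergic
prediction-error signaling in a blockwise odor-guided choice task, together
with a synthetic task and spike-train generator that stands in for the
(non-deposited) recordings. It is written for computational and systems
neuroscientists who want to exercise, validate, or extend this family of
analyses: waveform-based identification of putative dopamine neurons,
reward-responsiveness screening, and early-versus-late difference-score
statistics around reward **value** shifts (number of drops) and reward
**identity** shifts (milk flavor).

## The model at the core

Each well carries predictions: a drop probability per slot
$k \in \{1,2,3\}$ and a belief over flavors. After a rewarded trial,

$$\delta_k = \text{delivered}_k - E_k, \qquad
  \delta_{id} = 1 - b(\text{flavor delivered}),$$

with Rescorla–Wagner updates $E_k \mathrel{+}= \alpha_V \delta_k$ and
$b \mathrel{+}= \alpha_{id}(\mathbf{1}_{flavor} - b)$. A unit's firing rate
is a baseline plus, per delivered drop, a 0.1–0.5 s box kernel of height
$g_{rew} + g_V^+ \max(\delta_k, 0) + g_{id}\,\delta_{id}$, minus
$g_V^-\max(-\delta_k,0)$ in the window where an omitted drop was expected
(floored at 0), sampled as an inhomogeneous Poisson process. Group presets:
**control** (full model, errors learned away within a block), **HCx**
(error gains 0, $\alpha \to 1$: priors update instantly; reward response
intact), **OFCx** ($\alpha_{id} = 0$: identity errors never attenuate;
positive value gain at 60%; no omission dip).

Putative dopamine units are classified from two waveform features — spike
half-duration and the amplitude ratio $(n-p)/(n+p)$ of the first negative
and positive segments — by k-means followed by a leave-one-out 3-s.d.
assignment rule; units within threshold of two clusters (or none) stay
unclassified. Reward-responsive units (one-sided paired t, 100–500 ms
post-drop vs 400 ms pre-trial baseline, p < 0.05) enter the difference-score
analyses, summarized per contrast by the mean score *u* and a two-sided
Wilcoxon signed-rank p.

## Worked example

```r
library(vipe)

task    <- simulate_task(seed = 1)                       # 5-block session
session <- simulate_session(task, sim_params("control", n_units = 120),
                            seed = 2)
labels  <- classify_units(session, seed = 1)             # waveform classes
screen  <- screen_responses(session,
                            unit_ids = labels$unit_id[labels$label == "dopamine"])
resp    <- screen$unit_id[screen$reward_responsive]
scores  <- difference_scores(session, resp)
do.call(rbind, lapply(split(scores, scores$contrast),
                      function(d) summarize_scores(d$score, d$contrast[1])))
```

On the control preset this prints (15 responsive units; `analysis/` stage 4):

```
            contrast           u            p n_units
 comparison_no_shift  0.04232155 0.6386718750      15
            delivery  4.40000000 0.0008876252      15
  identity_drop1_big  1.03023705 0.0001220703      15
  identity_drop2_big  0.52052976 0.0020141602      15
      identity_small  0.74078621 0.0003051758      15
            omission -1.86666667 0.0008812369      15
```

Read: after value shifts, firing to the now-delivered 2nd drop is ~4.4
spikes/s higher on the first 5 than the last 5 trials (unexpected delivery,
learned away), and ~1.9 spikes/s lower where an expected drop is omitted;
after identity shifts, baseline-normalized firing to every drop of the
newly-flavored rewards rises (scores > 0), while the no-shift comparison
window stays at zero. The HCx preset nulls every contrast; the OFCx preset
keeps a reduced delivery effect, loses the omission dip, and centers the
identity scores on zero while post-shift firing stays persistently high —
run `analysis/04_shift_analysis.R` to see all three side by side.

The published chi-square on classification proportions is reproduced from
its printed counts:

```r
chi_square_proportions(data.frame(group = c("control", "HCx", "OFCx"),
                                  n_dopamine = c(80, 110, 90),
                                  n_total   = c(408, 513, 412)))
#> $statistic 0.7142128   $df 2   $p 0.6996981
```

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end and write their
tables under `results/`:

1. `01_simulate_cohorts.R` — one mixed-population session per preset.
2. `02_classify_units.R` — waveform classification; chi-square on
   proportions (simulated and published counts).
3. `03_screen_responses.R` — reward-responsiveness screen.
4. `04_shift_analysis.R` — difference scores, signed-rank summaries,
   identity-shift firing time courses.
5. `05_phenotype_study.R` — 20 seeded 3-preset cohorts of 46 units scored
   against the expected per-group signature.

The methods vignette (`vignettes/methods.Rmd`) documents the model, the
parameter choices, the numerical conventions, and what the synthetic data
can and cannot show.

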