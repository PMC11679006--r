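---
title: "Methods: plantar-pressure FOG prediction with fogsentry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plantar-pressure FOG prediction with fogsentry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fogsentry)
```

`fogsentry` predicts and detects freezing-of-gait (FOG) episodes from 100 Hz
two-foot plantar-pressure recordings. This vignette is the package's own
account of the method: the signal model, every constant that matters, what the
synthetic-data generator does and does not emulate, and the numerical choices
made where the design was genuinely open.

## Signal model and labeling

A trial carries, per foot, total ground reaction force and the center of
pressure (COP) in a foot-fixed frame: `x` mediolateral (ML, mm, positive
lateral), `y` anteroposterior (AP, mm, positive anterior). When only a
pressure-sensel grid is available, the COP is the pressure-weighted centroid of
the sensel coordinates (`compute_cop()`).

Event annotations are intervals of three kinds: `FOG`, `TURN`, `STAND`.
Per-sample gait-state labels follow from the FOG intervals alone:

* `FOG` inside an episode (onset inclusive; the end inclusive of the last
  on-grid sample);
* `PREFOG` in the 2 s immediately preceding an onset — the precursor window
  used to make prediction (not just detection) learnable. FOG takes precedence
  when two episodes are closer than 2 s: freezing is the observed state.
* `NONFOG` everywhere else. Turning and standing are *not* relabelled; they
  matter only at evaluation time.

Annotations scored on 30 Hz video are transferred to the 100 Hz pressure clock
by nearest-in-time assignment with ties broken toward the earlier frame
(`resample_labels()`). Labels are categorical, so nearest-neighbour assignment
is the categorical reading of interpolating to the closest data point.

Time convention: seconds from trial start; sample *i* (0-based) sits at
*i*/fs; windows and non-FOG intervals are half-open `[start, end)`.

## COP validity, gap filling, differentiation

During swing, residual insole pressure yields meaningless COP positions. A
foot's COP at a sample is therefore valid only when that foot carries strictly
more than 5% (`validity_threshold = 0.05`) of the instantaneous two-foot total
force. The rule is scale invariant; samples with both feet at zero force are
invalid for both.

Invalid spans must still be bridged before differentiation and the FFT/wavelet
features, or validity edges would inject spurious velocity spikes. Interior
runs are linearly interpolated between the flanking valid samples;
leading/trailing runs are held (`fill_invalid()`). The validity mask is kept
and carried forward — the AP-reversal counter uses it to reset across gaps, so
no reversal is ever counted across a swing phase. Whether the original
processing interpolated, held, or dropped such samples is not documented
anywhere we know of; interpolation is our choice and the mask keeps it
auditable. A foot with *no* valid sample in a window is degenerate: its four
features are emitted as 0 (fixed-length vectors for the classifier) and the
window is flagged.

COP velocity is the first derivative by central differences
(`(x[i+1] − x[i−1])·fs/2`), one-sided at the ends — second-order accurate,
exact for linear trajectories, identically zero for constants.

## Windows and features

Windows are 1 s long on a 0.2 s grid aligned to the trial start (the alignment
is our choice; nothing in the protocol pins it), emitted only while fully
inside the trial: `floor((T − 1)/0.2) + 1` windows for a `T`-second trial. A
window is `TARGET` iff every sample is `PREFOG` or `FOG`; a single `NONFOG`
sample disqualifies it.

Eight features per window (left and right of each pair):

| feature | unit | meaning |
|---|---|---|
| `rev_ap_l/r` | count | AP COP direction reversals |
| `dom_ml_l/r` | Hz | dominant frequency of ML COP velocity |
| `dom_ap_l/r` | Hz | dominant frequency of AP COP velocity |
| `wav_ap_l/r` | mm² | mean wavelet approximation-coefficient power of AP COP position |

Numerical choices, all recorded in `fog_config()`:

* **Reversals** are alternating local extrema whose excursion from the last
  accepted extremum exceeds a 1 mm hysteresis (`reversal_delta`) — COP noise
  of insole magnitude would otherwise dominate the count. No threshold is
  documented for the original system; 1 mm is our default and configurable.
* **Dominant frequency**: mean-removed segment, plain FFT without zero-padding
  (1 Hz resolution on 100 samples), magnitude argmax over bins 1…Nyquist, ties
  to the lowest frequency. A constant segment has no spectral content; the
  lowest non-DC bin is returned with a `degenerate` attribute rather than an
  arbitrary unmarked number.
* **Wavelet power**: Daubechies-4, level 4, symmetric padding — at 100 Hz the
  level-4 approximation band is ≈ 0–3.1 Hz, the locomotor band, which is what
  makes the feature a step-amplitude summary. Family and level are not
  documented for the original system; both are configurable
  (`wavelet_level`). The segment is mean-removed first so the feature is
  invariant to where the foot sits in the insole frame; without mean removal a
  constant `c` yields power `2⁴·c²` (the test suite pins this closed form and
  cross-checks the transform against an independent convolution
  implementation).

## The classifier

Freezing data are heavily imbalanced, so the model is a from-scratch binary
RUSBoost: AdaBoost over shallow trees where each round's tree is trained on a
class-rebalanced random undersample. Defaults (`fog_config()`): 100 learners,
5 internal splits per tree, 1:1 round sampling ratio, learn rate 0.1,
decision threshold 0.5 (strict).

Per round: all minority-class examples are kept and the majority class is
undersampled without replacement with selection probabilities proportional to
the current boosting weights; a tree is grown best-first by weighted Gini
reduction to at most 5 splits; the weighted error ε is computed on the *full*
training set; `α = learn_rate · ln((1−ε)/ε)`; weights of correctly classified
examples shrink by `exp(−α)` and are renormalized. Rounds with ε = 0 keep the
learner with a capped α; rounds with ε ≥ 0.5 discard the learner and resample
(after 50 consecutive failures the ensemble stops early — on hard overlapping
data ensembles may legitimately hold fewer than 100 learners).

Determinism contracts: rows are canonically sorted before any random draw, so
permuting the training set does not change the fit; per-round seeds derive
from the root seed through a counter, so identical `(data, params, seed)`
give bit-identical ensembles. Tree ties break toward the lowest feature index,
then the lowest threshold, then the earliest-created leaf. Zero-gain splits of
impure nodes are admissible (an XOR-like structure only pays off one level
deeper); pure nodes never split. The learn rate, sampling ratio and tie rules
for the original MATLAB implementation are unknown; ours are defaults logged
in the model metadata.

## Episode-level evaluation

Window metrics (sensitivity/specificity, pooled over held-out windows) treat
every window equally. Cueing devices, though, act on *triggers*:

* **MTD**: every window that is the 3rd or later member of a consecutive
  target run raises a candidate trigger at that window's end. A 2.5 s no-cue
  (refractory) interval then thins candidates greedily left-to-right — the
  only reading under which the no-cue rule has any effect.
* **Target zone** per episode: from `max(onset − 6 s, trial start)` to the
  episode end, with the start pushed to 1 s after any overlapping turn/stand
  (so turning false positives are not mistaken for early predictions) and to
  the end of any overlapping prior episode (no extra delay there — the 1 s
  delay attaches to turning and standing events only; configurable).
* An MTD inside a zone is a true positive for that episode; outside all zones
  it is ignored during stands and the first 1 s of gait initiation after
  them, and a false positive otherwise (reported per walking trial).
* An episode is **predicted** if a matched MTD fires before onset,
  **detected** if one fires between onset and episode end, **identified** if
  either; episodes can be both, so
  `max(predicted%, detected%) ≤ identified% ≤ predicted% + detected%` — an
  invariant asserted on every run. The **identification delay** is measured
  from the *first* true-positive MTD.

Cross-validation is leave-one-freezer-out: each freezer is held out once;
non-freezers always stay in training (they contribute non-target windows but
cannot be evaluated at episode level). Window metrics are pooled across folds
(per-fold reports are also returned; pooling vs averaging is not pinned down
by the protocol, and pooling weights every window equally). Whether the
original evaluation excluded standing/turning windows from specificity is
unstated; here *all* held-out windows are scored and the stand/gait-initiation
exclusions apply only to episode-level false positives, which is what the
protocol literally says.

## The synthetic gait simulator

No public recordings exist for this task, so `simulate_trial()` /
`simulate_cohort()` generate the study conditions: 100 Hz, 50 s trials;
alternating single-support gait at 1.8 steps/s with 0.1 s double-support load
crossfades; stance AP COP progressing heel→toe over 150 mm with 5 mm ML sway;
swing feet carrying a 2% residual force (invalid under the 5% rule); turns
(slower, wider sway) and stands (slow postural sway) as annotated segments;
Gaussian force (SD 5) and COP (SD 1 mm) noise throughout. Trial length mirrors
typical walking-path trials (~50 s); cadence, excursion and noise magnitudes
are ordinary values for instrumented-walkway gait in older adults with PD.

Freezing comes in two phenotypes, 50/50 by default: **trembling** (both feet
loaded, AP/ML COP oscillating in the 3–8 Hz freezing band, default 6 Hz at
8 mm) and **akinetic** (both feet loaded, COP static but for noise). The third
clinically described phenotype, shuffling, is not modelled. Episodes arrive at
~1.5 per freezer trial with log-normal durations (meanlog log 2.5 s, sdlog
0.5). The 2 s before each onset ramps linearly into a festination-like
precursor — cadence ×1.8, AP excursion ×0.4. That pre-FOG carries *any*
signal is an assumption the prediction task needs; its plantar-pressure
signature is not characterized in the literature, so the precursor's shape and
effect sizes are free simulator parameters, not physiological claims. Cohorts
jitter cadence, excursion, trembling frequency (4–7 Hz, on-bin) and episode
rate per participant; non-freezers get rate 0. All randomness flows from one
root seed via per-participant/per-trial sub-seeds.

What passing tests on this generator show: the pipeline recovers planted,
learnable freezing signatures end to end (features pick up the configured
trembling frequency exactly; cross-validation recovers most planted episodes).
What they cannot show: performance on real freezing, whose precursors,
phenotype mixture, sensor artifacts and between-subject variability are far
richer than this generator.

## Problem sizes and runtime choices

The shipped tests exercise: oracle equivalence on 1000 random classification
streams and 1000 random 1 s segments (FFT argmax and wavelet power against
brute-force implementations); exhaustive window-count checks for trial lengths
1–60 s; and an end-to-end cross-validation on a 7-freezer + 4-non-freezer
cohort with 10 × 50 s trials per participant, repeated over 3 seeds — about
27,000 windows per cohort, a size chosen so the full suite runs comfortably on
one CPU while keeping ≥ 1500 target windows in every training fold.
`scripts/acceptance.R` runs the same cohort at a single seed.

## Known limitations

* The simulator's pre-FOG precursor is a modelling convenience; real pre-FOG
  dynamics are uncharacterized, and festination is only one candidate
  precursor.
* Ensembles may stop short of 100 learners on strongly overlapping data (the
  discard-and-resample rule); the fitted count is in the model metadata.
* Window specificity includes standing/turning windows by design; systems that
  exclude them will report different numbers on identical predictions.
* Proprietary insole exports are out of scope; trials enter as the documented
  CSV + JSON sidecar formats.
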