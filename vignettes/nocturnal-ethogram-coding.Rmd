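---
title: "Methods: rule-based nocturnal ethogram coding and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based nocturnal ethogram coding and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`ethonight` turns two kinds of automated video-coding output into
second-by-second ethogram sequences and quantifies how well they agree with
manual scoring:

1. **Pose route** — keypoint trajectories (per frame and bodypart: x, y,
   likelihood), classified by coordinate-zone rules;
2. **Detector route** — per-frame behavior labels with confidences from an
   object-detection classifier, adopted directly.

Both converge on the same `behavior_sequence` representation, on which the
evaluation layer (time budgets, cumulative curves, confusion matrices,
Kendall's W, Spearman correlations) operates. This vignette documents the
model assumptions, the tunable parameters and their defaults, the
synthetic-data generator used for validation, and the numerical choices a
maintainer would want stated explicitly.

```{r}
library(ethonight)
cfg <- default_ethogram_config()
cfg
```

## The classification model

### Zone rules

A behavior is coded positionally when all of its constrained bodyparts lie
inside axis-aligned pixel boxes (origin top-left, y downward, 1920 x 1080
frames in the shipped configuration). Boxes are the minimal model for
"distinct coordinate limits" per behavior: each nocturnal behavior of the
elephant ethogram happens at a fixed station in the enclosure (foraging
boxes at the back wall, hay net at the top, water bowl, lying-down area),
so a box on the relevant bodypart — usually the trunk tip, or the back for
the lying posture — separates them. The shipped boxes are **illustrative**:
they are consistent with the simulator geometry, but a real deployment
calibrates them for each camera view against a manually scored control
period.

When several rules match one frame the rule with the lowest priority
number wins. The shipped order (lying down < foraging < hay-net <
drinking) is a deterministic, testable convention; with disjoint boxes it
never fires, but overlapping calibrations resolve predictably.

### Validity, the p-cutoff, and out-of-view

A keypoint sample is *valid* when it is present and its likelihood is at
or above the p-cutoff (default 0.5). The closed lower bound (`>=`) is the
conventional reading of a cutoff; the boundary sample is retained. Two
distinct failure modes are kept apart:

- *missing* — the network did not label the bodypart (empty CSV cell);
- *low likelihood* — labeled, but below the cutoff.

Both make a sample invalid, but the distinction survives I/O round-trips
so that re-conditioning at a different cutoff remains well defined.

A frame is **out of view** only when *all* anchor bodyparts (head and
trunk root by default) are invalid. If any anchor survives, the animal is
considered in view and an unmatched frame falls back to the default
behavior (standing/walking). This makes the out-of-view rate an explicit
function of tracking dropout — on fixed nocturnal cameras the animal
rarely leaves the frame, so out-of-view time is dominated by the models'
failure to label, and the rate rises monotonically with the cutoff (a
property the tests assert).

### From frames to seconds

Manual scoring operates at 1-s resolution, model output at 25 FPS. Second
`s` covers frames `floor(s*fps) .. floor((s+1)*fps) - 1` (half-open
intervals, 0-based frames) and takes the majority label of its frames.
Ties break by the config's rank (zone-ruled behaviors by priority, then
ruleless behaviors, then the default), with out-of-view losing every tie —
a second containing any positive evidence of behavior is coded as
behavior. Majority voting is this package's documented choice for the
frame-to-second bridge; it is deliberately the simplest temporal smoother,
and no further smoothing is applied.

Minimum bout durations are enforced *after* aggregation, in whole seconds,
because ethograms state them in seconds: every maximal run of a
constrained behavior shorter than its minimum (swaying: 5 s) is relabeled
to the default behavior.

## Sway detection

Stereotypic swaying is a rhythmic side-to-side motion of head and trunk
that can occur anywhere in the enclosure, so zone rules cannot code it;
the shipped configuration deliberately ships no sway zone rule. Instead
the detector works on the displacement signal of one bodypart (trunk root
by default):

- `step_displacements()` — per-frame Euclidean steps between consecutive
  valid samples. Steps adjacent to invalid samples are zero: charging the
  jump across a dropout gap would fabricate motion, and dropout is common.
- `cumulative_displacement()` — the running sum; sway appears as a steep
  sustained increase in this trace.
- `detect_sway_bouts()` — a second is *active* when the centered rolling
  mean (window `window_s = 10` s, partial windows at the edges) of the
  per-second displacement rate is at or above `rate_threshold` (px/s);
  active runs merged across gaps `<= merge_gap_s = 2` s and lasting
  `>= min_duration_s = 5` s are bouts.

Detection is by displacement *rate*, not oscillation frequency: the
rate rule reproduces the cumulative-slope evidence with one interpretable
threshold, and it is translation-invariant by construction.
Frequency-domain stereotypy classification is out of scope. No
field-calibrated threshold exists — visual presentation remains the
reference for real footage — so the threshold is a user parameter,
validated here only on synthetic data. A useful anchor: background jitter
of SD `s` px per coordinate produces a baseline rate of about
`fps * s * sqrt(pi)` px/s (Rayleigh mean of the step), while a sinusoidal
sway of amplitude `A` px and period `T` s adds about `4A/T` px/s; the
validation suite places the threshold midway between the two.

## Agreement statistics

**Time budgets** are the percentage of observation time per behavior with
out-of-view as an explicit category; they always total 100%.
**Confusion matrices** put predicted behavior in rows and manually
observed behavior in columns; column normalization turns each observed
behavior's column into the distribution of predictions for it.

**Kendall's W** is computed from the raw behavior-time sums, ranked within
each rater (method, or night) with average ranks for ties, using the
tie-corrected form

$$W = \frac{12\sum_j (R_j - m(n+1)/2)^2}{m^2(n^3-n) - m\sum_i T_i},
\qquad T_i = \sum_{\text{tie groups}} (t^3 - t),$$

and tested with the chi-square approximation $\chi^2 = m(n-1)W$ on $n-1$
degrees of freedom. With the six categories of a nocturnal elephant
ethogram (five behaviors plus out-of-view), this approximation reproduces
published concordance p-values from their W coefficients at both m = 3
(methods against manual scoring) and m = 7 (nights) to two significant
figures — the acceptance suite recomputes all six.

A caveat the package measures rather than hides: for small m the
chi-square approximation is **conservative in the significance tail**. At
m = 3, n = 6 a 10,000-draw permutation null puts the exact p for W near
0.87 at about 0.002 where the approximation reports 0.022 — an order of
magnitude, and far outside Monte-Carlo error (the corresponding acceptance
check fails honestly and is kept as a characterization of the
approximation, not a defect of the implementation). Substantive
conclusions of the "high concordance, significant" kind are unaffected —
the exact p is smaller — but exact small-m inference should use a
permutation test, which `kendalls_w` does not currently provide.

**Spearman correlations** (average ranks, via `stats::cor`) compare
night-to-night activity; for the lying-down analysis the package correlates
per-minute cumulative seconds (`cumulative_minutes()`, step 60 s). The
sampling resolution is a documented default, adjustable everywhere it
appears: cumulative curves make onset differences visible as rank
displacements, so shared sleep onset yields high positive correlations and
shifted onset degrades them (a property the tests assert). Constant series
have no defined rank correlation and raise an error. No multiplicity
correction is applied anywhere; outputs are single-comparison statistics.

## The synthetic night generator

The simulator exists so that every pipeline stage can be validated with
known ground truth; no real footage or its annotations ship with the
package.

- **Scripts** (`random_script()`) tile a night (default 25,200 s — seven
  hours, 22:00 to 05:00) with an alternating-renewal sequence: behaviors
  drawn uniformly without immediate repetition, bout lengths exponential
  with per-behavior means, rounded to whole seconds and clamped at 1 s.
  Default behavior means in the validation suite (standing 600 s, lying
  down 1800 s, foraging 300 s, hay-net 200 s, drinking 60 s) give a night
  dominated by recumbent rest with intermittent foraging — the structure
  reported for captive elephants at night (roughly 2.5 h of lying down,
  feeding next).
- **Keypoints** sit exactly at the behavior's geometry point (inside its
  zone box) before noise; noise adds Gaussian jitter (`coord_sd`), dropout
  (`dropout_p`), and low-likelihood draws (`low_conf_p`, uniform below the
  cutoff). Likelihoods are otherwise uniform on `[p_cutoff, 1]`.
- **Sway bouts** oscillate head and trunk root laterally,
  `x(t) = x0 + A sin(2*pi*t/T)` with defaults A = 40 px, T = 4 s. These
  kinematic parameters are illustrative (no published values exist) and
  are exposed in the configuration.
- **Detections** emit the true label per frame through a row-stochastic
  confusion matrix, with misses at `det_miss_p` and confidences uniform on
  `[0.5, 1]`. The known confusion matrix gives the evaluation layer an
  exact recovery target.

All stochastic draws flow from one explicit seed; a fixed seed reproduces
a night bit-identically.

**What the simulator does not emulate** — and hence what passing tests do
*not* show about real data: continuous locomotion between stations
(transitions teleport), posture deformation within a behavior, correlated
or bursty dropout (real tracking fails in streaks, e.g. whole lying-down
periods going unlabeled), lighting- or occlusion-dependent confusion, and
multi-animal interference. Recovery results on synthetic nights are
therefore upper bounds: they validate the *computations*, not the
field-readiness of any particular zone calibration or threshold.

## Validation problem sizes and numerical choices

The test suite runs noiseless pipeline identity on twenty 600-s scripted
segments (identity is length-independent); confusion recovery on one full
25,200-s night at 25 FPS (630,000 frames, every column-normalized cell
within 3 multinomial SDs of its target); and sway recovery on ten 3600-s
nights with three planted bouts of 90–120 s each (precision and recall
1.0, mean interval overlap above 0.99, under jitter SD 0.3 px and 2%
dropout).

Numerical conventions, in one place: 0-based frame indices; half-open
time intervals; likelihood-at-cutoff retained; average ranks for all ties;
out-of-view loses all aggregation ties; zone-rule priority is the only
other tie-break; gaps contribute zero displacement; empty columns stay
zero under column normalization; budgets sum to 100 within 1e-9.

## Known limitations

- Zone boxes cannot separate behaviors that share a station (a hay net
  above the foraging boxes); the configuration supports omitting a rule,
  which reassigns that behavior's time to the default/neighboring codes,
  as a calibration decision.
- The sway detector reports displacement-rate bouts; slow pacing through
  the frame can exceed the rate threshold and register as activity. On
  fixed stations this is mitigated by the stationarity of the remaining
  behaviors; on free-ranging footage a frequency-domain method would be
  needed.
- Chi-square p-values for W are approximate for small m (see above).
- The classifier carries no temporal model beyond majority vote and
  minimum durations; brief true behaviors shorter than half a second are
  invisible at second resolution.
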