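# ethonight

Rule-based nocturnal ethogram coding from pose-estimation keypoints, with a
validation layer for comparing automated and manual behavioral scoring.

## The problem

Behavioral studies of captive animals (the motivating case is nocturnal
monitoring of zoo elephants on fixed CCTV cameras) traditionally rely on
manual scoring: an observer codes one behavior from a predefined ethogram
for every second of footage. Markerless pose estimation (DeepLabCut-style
keypoint tracking) and frame-wise object detection (Create ML-style
classifiers) can automate this, but their raw output is per-frame
coordinates or labels, not ethogram codes, and their reliability has to be
quantified against manual scoring before they can be trusted.

`ethonight` provides the post-processing and evaluation side of that
workflow for ethologists and zoo researchers:

- **Zone-rule classification.** Each behavior is coded when designated
  bodyparts fall inside configured pixel boxes (foraging box, hay net,
  water bowl, lying-down area ...). Keypoint estimates are first conditioned
  by a likelihood *p-cutoff* (default 0.5; estimates below it are treated
  as missing). A frame with no matching zone but a valid anchor bodypart
  gets the default behavior (standing/walking); a frame whose anchors are
  all invalid is *out of view*. Frame labels are aggregated to seconds by
  majority vote and minimum bout durations are enforced (swaying counts
  only when sustained for at least 5 s).
- **Stereotypy (sway) detection.** Swaying — a rhythmic side-to-side motion
  of head and trunk — is not localizable by zone. It is detected from the
  trunk-root displacement signal: per-frame Euclidean steps between valid
  samples, their cumulative sum, and bouts flagged where the windowed mean
  displacement rate exceeds a threshold.
- **Agreement statistics.** Time budgets (percent of observation time per
  behavior, out-of-view included), cumulative behavior curves, confusion
  matrices (rows = predicted, columns = manually observed,
  column-normalized), Kendall's coefficient of concordance with its
  chi-square test, and Spearman rank correlations of night-to-night
  activity.
- **A synthetic-night simulator** that generates keypoint tracks, detection
  streams and ground-truth label sequences for a scripted night, with
  configurable jitter, dropout, low-likelihood draws, detector misses and a
  row-stochastic label-confusion matrix — so every stage of the pipeline
  can be validated with known truth.

## The statistics at the core

Agreement among *m* rankings of *n* items (e.g. three coding methods
ranking six behavior-time categories) is measured by Kendall's W with the
tie-corrected form

    W = 12 S / ( m² (n³ − n) − m Σ Tⱼ ),   S = Σᵢ (Rᵢ − m(n+1)/2)²

where `Rᵢ` are column rank sums and `Tⱼ = Σ (t³ − t)` over each ranking's
tie groups, tested against the null of independent rankings via
`χ² = m (n − 1) W` on `n − 1` degrees of freedom. Spearman correlations use
average ranks for ties. See the methods vignette
(`vignettes/nocturnal-ethogram-coding.Rmd`) for the full model description,
parameter defaults and known limitations.

## Worked example

Simulate a noisy 7-h night, code it with both automated routes, and
evaluate against the ground truth:

```r
library(ethonight)
cfg <- default_ethogram_config()

# detector that confuses visually similar behaviors 20% of the time
beh <- c("Standing", "Lying down", "Foraging", "Hay-net", "Drinking")
C <- diag(0.8, 5); dimnames(C) <- list(beh, beh)
C["Drinking", "Standing"] <- 0.2; C["Hay-net", "Foraging"]  <- 0.2
C["Standing", "Drinking"] <- 0.2; C["Lying down", "Standing"] <- 0.2
C["Foraging", "Hay-net"]  <- 0.2

script <- random_script(cfg, seed = 7,
  mean_bout_s = c(Standing = 600, "Lying down" = 1800, Foraging = 300,
                  "Hay-net" = 200, Drinking = 60),
  total_duration_s = 25200)
night <- simulate_night(script, cfg,
  noise_model(coord_sd = 2, dropout_p = 0.05, low_conf_p = 0.05,
              det_miss_p = 0.10, det_confuse = C), seed = 7)

coded <- classify_to_seconds(night$track, cfg)       # pose route
print(time_budget(coded, cfg), digits = 3)
#>      behavior seconds percent
#> 1    Standing    3321   13.18
#> 2  Lying down   16845   66.85
#> 3    Foraging    2405    9.54
#> 4     Hay-net    1895    7.52
#> 5    Drinking     734    2.91
#> 6     Swaying       0    0.00
#> 7 Out of view       0    0.00
```

The elephant of this night lay down 67% of the time, foraged 10%, and the
pose route recovers the scripted truth second for second
(`mean(coded$labels == night$truth$labels)` is 1). The frame-level
confusion of the detection route recovers the planted confusion matrix
scaled by the 10% miss rate:

```r
pred <- detections_to_sequence(night$detections)
cm <- confusion_matrix(pred, rasterize_script(script, cfg, "frame"), cfg)
round(column_normalize(cm)[c(beh, "Out of view"), beh], 3)
#>              observed
#> predicted     Standing Lying down Foraging Hay-net Drinking
#>   Standing       0.721       0.18    0.000   0.000    0.178
#>   Lying down     0.000       0.72    0.000   0.000    0.000
#>   Foraging       0.000       0.00    0.718   0.182    0.000
#>   Hay-net        0.000       0.00    0.180   0.721    0.000
#>   Drinking       0.180       0.00    0.000   0.000    0.721
#>   Out of view    0.099       0.10    0.102   0.097    0.101
```

Concordance across the manual, pose, and detector time budgets:

```r
detected <- enforce_min_duration(
  aggregate_to_seconds(detections_to_sequence(night$detections), cfg), cfg)
budgets <- rbind(manual = time_budget(night$truth, cfg)$seconds,
                 pose = time_budget(coded, cfg)$seconds,
                 detector = time_budget(detected, cfg)$seconds)
kendalls_w(budgets)
#> Kendall's W = 1.0000 (m = 3 rankings, n = 7 items)
#> chi-square = 18.000, df = 6, p = 0.00623  [tie-corrected]
```

All three routes rank the behaviors identically (W = 1): second-level
majority voting absorbs the frame-level detector noise almost completely
(99.9% per-second agreement).

## Command-line use

A thin launcher over the same functions is installed with the package:

```sh
ETHONIGHT=$(Rscript -e 'cat(file.path(find.package("ethonight"), "exec", "ethonight"))')
$ETHONIGHT simulate --config config.yaml --seed 7 --out-dir night1
$ETHONIGHT classify --config config.yaml --pose night1/pose.csv --out night1/coded.csv
$ETHONIGHT sway     --config config.yaml --pose night1/pose.csv \
                    --rate-threshold 28 --out night1/bouts.csv
```

Subcommands: `validate-config`, `simulate`, `classify`, `sway`, `evaluate`,
`budget`, `concord`, `correlate`; every run writes a JSON manifest with the
resolved parameters and seed.

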