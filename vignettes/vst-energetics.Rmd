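---
title: "Heart-rate-derived energetics for vaquejada simulation tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-rate-derived energetics for vaquejada simulation tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaquetics)
```

## The problem and the model

Vaquejada subjects two horses to a high-intensity, short-duration effort
with distinct roles: the pull horse (PH) accelerates to topple the bull,
the helper horse (HH) flanks it through constant accelerations and
decelerations. A vaquejada simulation test (VST) is three races of
40–50 s on a sand track with 5-min walking rests, recorded at 1 Hz by a
combined heart-rate/GPS monitor, with plasma lactate sampled at rest (T0),
after each race (T1–T3) and at 30/240 min of recovery (T4/T5).

Field oxygen-uptake measurement being impractical, energetic load is
estimated from heart rate. For a segment with mean HR (beats/min), carried
mass $m$ (kg), distance $d$ (m) and duration $t$:

$$EE = a \cdot \mathrm{HR}^{b}, \qquad a = 0.0566,\; b = 1.9955
\quad (\mathrm{J\,kg^{-1}\,min^{-1}})$$

$$COT = (\mathrm{HR} - \mathrm{HR}_0)\cdot \frac{t/60}{m\,d} \times 10^3,
\qquad P_{met} = \frac{\mathrm{HR} - \mathrm{HR}_0}{m} \times 10^3$$

with resting baseline $\mathrm{HR}_0 = 35$ bpm. Gaits come from speed
thresholds: walk $<1.67$, trot $1.94$–$4.17$, gallop $>4.44$ m/s.

## Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `baseline_hr_bpm` | 35 | beats/min | resting HR subtracted in COT/Pmet; below-baseline segments clamp to 0 with a warning rather than going negative |
| `ee_coeff`, `ee_exp` | 0.0566, 1.9955 | – | the published HR→EE power law, taken literally |
| `scale_factor` | 1000 | – | the "×10³" of the printed COT unit; the published Pmet magnitudes (hundreds) are only reachable with the same factor, so it applies to both, explicitly and configurably |
| `cot_mode` | `"dimensional"` | – | the printed COT unit is dimensionally ambiguous (beats/min divided by metres needs a time basis); `dimensional` integrates beats over the segment (time-consistent), `paper_numeric` divides beats/min by speed and reproduces the printed magnitudes (~46 at gallop for 513 kg). Neither is asserted to be the original authors' arithmetic; reports name the mode |
| `ee_on` | `"samples"` | – | segment EE as the mean of per-sample EE uses the full 1 Hz stream; `"mean_hr"` (EE of the segment-mean HR) is what a summary-table reconstruction would do — they differ because the power law is convex |
| `smooth_window` | 3 | samples | running median on speed; suppresses single-sample GPS jitter while moving bout edges by at most 1 s |
| `min_gallop_s`, `min_rest_s` | 5, 60 | s | race detection: races last 40–50 s and rests 300 s, so both defaults sit far from either scale |
| lactate recovery tolerance | 0.5 | mmol/L | "recovered" is defined relative to the subject's own T0 + tolerance; the study states recovery only qualitatively |
| `alpha` | 0.05 | – | the study's significance level; no correction across table rows, as in the source analysis |

Boundary semantics follow the printed inequalities literally (walk strict,
trot inclusive, gallop strict). The two unclassified speed gaps get an
explicit `transition` label excluded from per-gait energetics — the
package never silently attributes a gait the thresholds do not define.

## The synthetic generator: what it emulates, what it does not

The study's raw recordings are not deposited, so `vst_preset("coelho2021")`
generates cohorts with the statistical structure the analysis assumes:

* **Protocol**: warm-up walk (60 s), then three blocks of approach trot
  (15 s), gallop (duration uniform on 40–50 s), a 5 s deceleration ramp
  crossing the transition band, and a 300 s walking rest.
* **Heart rate**: first-order relaxation toward a per-block asymptote,
  solved in closed form so the block *mean* equals the role × gait target
  — the published values are segment means, not asymptotes. Targets are
  the across-race means of the published per-race values (e.g. PH gallop
  185.2, HH gallop 179.1, PH trot 135.6, HH trot 156.4 bpm), with
  between-subject SD 1.5 bpm (the published SDs, ~1.1–1.6, taken at face
  value) and 2 bpm per-sample jitter. Recovery time constants are
  role-specific (PH 180 s, HH 45 s): pull horses recover more slowly,
  which builds in the reported direction of the time-below-150-bpm
  contrast between roles. The recovery asymptote is solved over the rest
  portion only, so walk cells hit their targets even though the
  deceleration prefix is labelled non-walk.
* **Speed**: clipped Gaussians inside each gait band (so labels are
  recoverable by construction); transition speeds appear only on the
  deceleration ramps.
* **Lactate**: T0 baseline, per-race increments, then exponential decay
  toward a role-specific late-recovery level with a role-specific
  half-life (PH 15.5 min, HH 5 min). The decay target is the
  late-recovery level, *not* T0, because the published 240-min PH value
  (1.8 mmol/L) lies below the resting value (2.2): pre-exercise arousal
  elevates T0, and decay-to-baseline cannot reproduce the printed curve.
  Noise-free defaults reproduce the published group means within a few
  percent at every timepoint.
* **Determinism**: one master seed expands into per-subject substreams
  (derived from seed, role and index), so cohorts are bitwise reproducible
  and stable under subject reordering.

What it does **not** emulate: bull and rider biomechanics, track surface,
GPS dropouts and multipath error, HR artefacts (electrode slip,
arrhythmia), within-gait autocorrelated speed profiles, or any
between-race fatigue drift (the published per-race differences in walk HR,
e.g. the elevated second-race walk, are averaged into a single per-gait
target). A green test on generator output therefore establishes that the
pipeline recovers the parameters of *this* stated world — thresholds,
segment means, protocol structure, kinetic shapes — not that it is robust
to real-device artefacts.

One internal tension in the source material is resolved in favour of
duration: gallop speeds of ~6.3–7.3 m/s sustained for 40–50 s imply
~280–340 m per race, which is incompatible with the printed 130–150 m
track. The generator honours the race *duration* and the per-gait speed
targets (both are published and both are analysis surfaces); the realized
distance follows from their product, and the nominal track length is
recorded in manifests only.

## Numerical and design choices

* **Race × gait cells.** Race detection finds gallop-dominated spans
  (merging spans separated by less than `min_rest_s`). For the per-race
  tables, epoch boundaries are found by walking back from each race start
  through contiguous non-walk labels: the approach trot belongs to the
  race it precedes, each rest to the race it follows, and pre-race-1
  samples to race 1.
* **Trot cells are small and slightly hot.** At the default protocol a
  trot cell holds ~15 approach samples plus 2–3 deceleration samples whose
  HR is still falling from the gallop, biasing the cell mean upward by a
  few bpm. Parameter-recovery guarantees are therefore stated for cells
  with ≥ 30 samples (walk, gallop); the bias affects both roles alike and
  leaves the trot role contrast intact.
* **Peak ties** in lactate curves resolve to the earliest timepoint;
  threshold exceedance is strict (`> 4`), matching "above the threshold".
* **Degenerate inputs**: zero-variance samples are rejected by the KS
  screen; a repeated-measures panel with zero error mean square returns
  F = 0 when the condition effect is also zero and F = ∞ (p = 0)
  otherwise; sessions need ≥ 2 samples; missing seconds are permitted but
  flagged, and means are computed over the samples present.
* **Statistics build-vs-buy**: KS, Tukey HSD and one-way ANOVA wrap the
  standard `stats` implementations; the repeated-measures F is computed
  from its sums of squares directly (three matrix reductions), which makes
  the 2000-replicate type-I calibration test cheap, and is verified in the
  test suite against the independent `aov(y ~ cond + Error(subj/cond))`
  decomposition.
* **KS with estimated parameters** is anti-conservative, as ubiquitous in
  the applied literature this pipeline mirrors; a simulation-calibrated
  Lilliefors-style p value is available (`lilliefors = TRUE`).

## Known limitations

* The published energetics tables cannot be reproduced numerically: the
  printed EE values are inconsistent with the stated formula evaluated at
  the printed heart rates, so only directional structure (which role is
  higher, where letters fall) is a meaningful target, and that is what the
  acceptance suite checks.
* Whether individual or group-mean masses were used per horse is
  unpublished; the package carries masses per subject and ships the group
  means as presets.
* The repeated-measures ANOVA assumes sphericity and complete panels; no
  mixed-effects fallback is provided.
* `transition` fractions above 10% of a session are reported as warnings;
  heavy transition content usually means the speed channel, not the horse,
  needs attention.
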