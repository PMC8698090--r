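# vaquetics

Heart-rate-derived energetics for vaquejada simulation tests (VST).

Vaquejada is a Brazilian equestrian sport in which two Quarter Horse/rider
pairs run a bull down a ~130–150 m sand track: the *pull horse* (PH)
topples the bull by the tail, the *helper horse* (HH) keeps it aligned. A
VST is three timed races with 5-min rests, instrumented with a 1 Hz heart
rate (HR) + GPS monitor and serial blood lactate sampling. Because field
oxygen-uptake measurement is impractical, energetic load is estimated from
HR. This package is for exercise physiologists and veterinary sports
medicine practitioners who want that analysis as a tested, reproducible
pipeline rather than spreadsheet arithmetic.

## The model

Each 1 Hz sample is assigned a gait from speed $v$ (m/s):
walk $v < 1.67$, trot $1.94 \le v \le 4.17$, gallop $v > 4.44$, and an
explicit `transition` label inside the two unclassified gaps. Per
race × gait segment with mean heart rate $\mathrm{HR}$ (beats/min),
carried mass $m$ (horse + rider + tack, kg), distance $d$ (m) and duration
$t$ (min):

- Energy expenditure: $EE = 0.0566 \cdot \mathrm{HR}^{1.9955}$
  (J kg⁻¹ min⁻¹)
- Cost of transport: $COT = (\mathrm{HR} - 35)\, t \, / (m\, d) \times
  10^{3}$ (beats kg⁻¹ m⁻¹ × 10³; a second convention dividing beats/min by
  speed is available as `cot_mode = "paper_numeric"`)
- Metabolic power: $P_{met} = (\mathrm{HR} - 35) / m \times 10^{3}$
  (beats min⁻¹ kg⁻¹)

with 35 bpm the resting HR baseline. Lactate curves (T0 rest, T1–T3 after
each race, T4/T5 at 30/240 min of recovery) are summarized by baseline,
peak, delta, 4 mmol/L anaerobic-threshold exceedance and recovery
timepoint. Group comparisons follow the field's standard pipeline:
Kolmogorov–Smirnov normality screen, repeated-measures one-way ANOVA, and
Tukey pairwise tests at p ≤ 0.05, reported as lettered mean (±SD) tables.

A seeded synthetic cohort generator (`vst_preset("coelho2021")`) emulates
the published protocol and group means, so the whole pipeline is testable
without the unpublished raw recordings.

## Worked example

```r
library(vaquetics)
res <- run_vst_analysis(run_config("synthetic", out_dir = "vst_out",
                                   generator = vst_preset(seed = 1L)))
head(res$tidy[, c("subject_id", "race", "gait", "mean_hr_bpm",
                  "ee_J_per_kg_min", "cot_scaled", "pmet_scaled")], 3)
#>   subject_id race   gait mean_hr_bpm ee_J_per_kg_min cot_scaled pmet_scaled
#> 1       PH01    1   walk       104.9           665.6     2.3787       136.2
#> 2       PH01    1   trot       145.5          1189.9     1.1666       215.3
#> 3       PH01    1 gallop       186.4          1923.3     0.7171       295.2
```

Eight simulated horses (4 PH + 4 HH) each yield three detected races; the
first rows above are pull horse 1: mean gallop HR 186 bpm gives an EE of
~1923 J/kg/min, and COT/Pmet are beats above the 35 bpm baseline
normalised by the 513 kg carried mass (×10³). The lettered group tables
reproduce the published directionality — PH higher than HH at gallop,
lower at trot, with distinct letters marking Tukey-significant rows:

```r
res$energetics_table$table[3, ]
#>                       condition               HH               PH     p
#> 3 mean_hr_bpm | race 1 | gallop 178.14 (±1.35) b 185.00 (±1.36) a 0.000

res$lactate_table$table[4, ]   # T3 = after the third race, mmol/L
#>   condition           HH            PH     p
#> 4        T3 7.0 (±0.5) b 10.3 (±1.0) a 0.001
```

The published group-mean lactate curves ship as a fixture:

```r
curve_summary(published_lactate_means()$PH)
#> $baseline 2.2 | $peak 10.6 | $peak_timepoint "T3" | $delta 8.4
```

A command-line interface wraps the same pipeline:

```sh
VST_CLI=$(Rscript -e 'cat(system.file("cli/vst.R", package = "vaquetics"))')
Rscript "$VST_CLI" report --seed 1 --out vst_out        # synthetic end-to-end
Rscript "$VST_CLI" simulate --seed 1 --out cohort_csv   # emit cohort CSVs
Rscript "$VST_CLI" analyze --in cohort_csv --out vst_out
```

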