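# sicklemetry

Quantitative analysis of red-blood-cell sickling for in-vitro therapy
models, in R.

When hemoglobin S polymerizes under deoxygenation, red cells distort from
discs into elongated crescents. Studies of anti-sickling interventions (for
example, globin gene therapy of CD34+ progenitors) quantify this with two
read-outs: **imaging cytometry** of fixed induced cells, and **time-lapse
video microscopy** of live cells during induction. `sicklemetry` implements
both analysis arms end to end, driven by a ground-truthed synthetic
generator of cell images and sickling videos, so the whole pipeline is
testable without patient material. It is written for quantitative
hematology / image-cytometry researchers who want a reproducible, inspectable
version of this analysis.

## What it computes

**Imaging arm.** Multi-channel single-cell events (brightfield + DNA stain +
surface marker) are segmented and measured: area, length *L* (extent along
the major principal axis), minimum/maximum thickness from the distance
transform along the pruned medial axis, Shape Ratio = T_min / L, two-fold
boundary symmetry S2 = |c2|/|c0| of the radius function's Fourier
coefficients, co-occurrence texture (H Contrast, H Entropy), focus and
intensities. A sequential gating chain (non-nucleated → non-debris →
mid-focus → marker-positive) isolates mature red cells. Candidate metrics
are ranked by Fisher's discriminant Fd = |μ1 − μ2| / (σ1 + σ2) between
labeled training sets; the classifier is the **Sickle Score** =
S2 / Shape Ratio, gated at a threshold calibrated for ~10% spillover on a
non-sickling control (the 0.90 quantile of control scores), giving a
percent-sickled endpoint compared between groups by Student's t test.

**Video arm.** Cells are simulated/scored under a delay + exponential
model: susceptible fraction p_s, absolute delay t0, hazard λ, censoring at
T = 30 min (4 frames/s). Analysis samples every 256th frame and detects,
per cell, the first sampled frame whose mask changes from the previous one
by more than 0.25 intersection-over-union (with a persistence check).
Endpoints: percent sickled, median time to sickling (sickled cells only),
delay time, and maximum sickling rate in sickling cells/total cells/sec.
Groups are compared with the Gehan–Breslow–Wilcoxon weighted log-rank test
(weights = number at risk) and the rank-sum test on event times.

## Worked example

```r
library(sicklemetry)

# one induced trial and an uninduced reference, 2000 events each
pop <- sample_population(population_config(2000, seed = 1))
fx  <- featurize_events(pop$events)
kept <- apply_gates(fx, calibrate_gates(fx))
kept
#> gating_result:  input=2000 -> non_nucleated=1572 -> non_debris=1494
#>   -> mid_focus=1413 -> marker_positive=1363

ref <- sample_population(population_config(
  2000, class_fractions = default_class_fractions("uninduced"), seed = 2))
ref_fx <- featurize_events(ref$events)
ref_kept <- apply_gates(ref_fx, calibrate_gates(ref_fx))
gate <- calibrate_sickle_gate(
  sickle_score(ref_fx[ref_fx$event_id %in% ref_kept$final_ids, ]))

percent_sickled(sickle_score(fx[fx$event_id %in% kept$final_ids, ]), gate)
#> [1] 0.3499633

# kinetics: one control-like video trial, sparse rendering + detection
trial <- run_kinetics_trial(kinetics_config(568, 0.54, seed = 1))
trial$summary
#> kinetics: n=568, 51.9% sickled, median 8.53 min, delay 5.33 min,
#>   max rate 0.00135 /s
```

Reading the output: the gating chain keeps ~68% of events (the rest are
nucleated precursors, free nuclei, debris, aggregates, defocused or
marker-negative cells); ~35% of gated induced events exceed the sickle gate
(≈10% spillover baseline plus the truly distorted cells); and in the video
trial about half the cells sickle, with the median event in the eighth
64-second sampling interval and no event before the configured 4.3-minute
delay (first detectable at the 5.33-min sampled frame).

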