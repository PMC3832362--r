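---
title: "Quantifying red-blood-cell sickling: morphometry, gating and kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying red-blood-cell sickling: morphometry, gating and kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sickle-cell disease is driven by deoxygenation-induced polymerization of
hemoglobin S, which distorts red blood cells from their discoid resting shape
into elongated crescents. Candidate therapies — for example an anti-sickling
globin transgene delivered to hematopoietic progenitors — are judged by how
much they reduce this distortion in the mature red-cell progeny. Two
complementary read-outs are standard:

* **imaging cytometry** of fixed, metabisulfite-induced cells: each event is
  a multi-channel image crop (brightfield, DNA stain, erythroid surface
  marker), gated down to single, in-focus, enucleated, marker-positive
  mature cells and then classified as sickled or not from shape metrics;
* **time-lapse video microscopy** of live cells during induction: each cell
  is scored for the time of its rapid disc-to-crescent transition, giving
  percent sickled, median time to sickling, delay time and maximum sickling
  rate, compared between groups with survival-style tests.

`sicklemetry` implements both arms as a tested pipeline. Because patient
material is not distributable, the package ships a first-class synthetic
generator that produces ground-truthed image events and videos with the
statistical structure the analysis assumes; every stage of the analysis is
validated against that ground truth.

## The shape classifier

For each event the brightfield object mask is measured. The two metrics at
the core of the classifier are:

* **Shape Ratio** — minimum object thickness divided by object length.
  Length is the mask extent along the major principal axis; thickness is
  read off the Euclidean distance transform along the medial-axis skeleton.
  Near 1 for discs, small for elongated cells.
* **Symmetry 2** — the two-fold harmonic content of the boundary: the
  radius function $r(\theta)$ is sampled at 256 angles about the centroid
  and $S_2 = |c_2|/|c_0|$ is computed from its discrete Fourier
  coefficients. Near 0 for circles, large for elongated cells.

The **Sickle Score** is $S_2 / \mathrm{ShapeRatio}$, high exactly when a
cell is both elongated and thin. Candidate metrics are ranked by Fisher's
discriminant between labeled training sets,

$$F_d = \frac{|\mu_1 - \mu_2|}{\sigma_1 + \sigma_2},$$

with sample standard deviations; this is the convention of the
imaging-cytometry software family, and a pooled-SD denominator is available
as an option because reported discriminant values alone cannot
adjudicate between the two conventions. The candidate list contains only measured
mask-based metrics: acquisition quality (focus) is handled upstream by the
gating chain, and the Sickle Score itself is the combination *derived from*
the ranking, so its discriminant is compared against the single metrics
separately rather than being ranked among them.

The classification gate on the Sickle Score is calibrated on a
non-sickling control population at ~10% spillover: the threshold is the
0.90 linear-interpolation quantile of the control scores, and an event
counts as sickled when its score strictly exceeds the threshold. The
percent-positive endpoint is compared between groups with a classical
equal-variance two-sided t test (Welch available via a flag).

## The gating chain

Four conjunctive gates applied in a fixed order reproduce the standard
chain for isolating mature cultured red cells: **non-nucleated** (integrated
DNA-stain intensity below an automatic bimodal split), **non-debris** (mask
area inside the 2.5th–97.5th percentile window of the non-nucleated
population; degenerate masks fail here), **mid-focus** (gradient-RMS focus
score above a lower bound) and **marker-positive** (mean in-mask marker
intensity above an automatic bimodal split). The trail records, per event,
each gate's verdict with later gates left unevaluated after a failure;
because the gates are conjunctive, permuting the order changes only the
trail, never the final set.

Two calibration choices deserve comment:

* *Focus bound.* A fixed 25th-percentile bound discards a quarter of all
  events regardless of how many are actually defocused. The default is
  therefore the robust lower fence $Q_1 - 1.5\,\mathrm{IQR}$ of the focus
  score, which removes a separated out-of-focus cluster while retaining
  essentially all of the in-focus bulk; the plain quantile rule remains
  available (`focus_rule = "quantile"`).
* *Marker split on mean, not integrated, intensity.* Integrated intensity
  confounds positivity with object size — a small marker-positive edge-on
  cell integrates less signal than a large marker-negative one. Mean
  in-mask intensity is bimodal by positivity alone. The DNA gate, by
  contrast, uses integrated intensity, since DNA content is an amount.

## Video kinetics

The kinetic model: each cell is independently *susceptible* with probability
$p_s$; a susceptible cell sickles at $t_0 + \mathrm{Exponential}(\lambda)$
minutes after induction, morphing from disc to crescent within seconds, and
cells that have not sickled by the end of the recording ($T = 30$ min at 4
frames/s) are right-censored. The delay $t_0$ reflects the lag before
hemoglobin polymerization; assays of this kind summarize the observed
kinetics only by delay, median and maximum rate, so the
delay-plus-exponential form is this package's modeling choice rather than
an observed distribution.

Analysis samples every 256th frame (one frame per 64 s at 4 fps). In
laboratory practice this scoring is done by a blinded human observer; the
automated stand-in detects, per
cell, the first sampled frame whose mask differs from the previous sampled
frame by more than an intersection-over-union change of 0.25 *and* remains
changed at the next sampled frame (persistence check, last interval exempt).
The event time is the detecting frame's time, so every detected time is a
multiple of the sampling interval and never precedes the true transition.
Endpoints per trial: percent sickled at $T$; median time among sickled cells
(lower median on ties); delay (first event); and maximum rate, the largest
per-interval event fraction divided by the interval length, in sickling
cells/total cells/second, computed on raw intervals without smoothing (an
optional moving average is deliberately absent from the default path).

Curves are compared with the Gehan–Breslow–Wilcoxon test — a weighted
log-rank test whose weight at each event time is the total number at risk,
emphasizing early events — implemented directly (the `survival` package's
`rho` family gives Peto–Peto weights, not at-risk counts) and checked
against a hand-worked example and a chi-square(1) null calibration. Median
times are compared with the two-sided Wilcoxon rank-sum test on event times
only, using mid-ranks and the tie-corrected normal approximation (the
sampling grid makes ties pervasive), or the exact distribution for small
tie-free samples.

## What the generator emulates — and what it does not

Events are rendered on a 0-based, row-major pixel grid (origin top-left),
default 0.4 µm/pixel in 72 px crops. Brightfield objects are dark-rimmed on
a bright background (background 0.80, interior 0.55, rim 0.30 of full
scale) with additive Gaussian pixel noise at 2% of full scale. Ten shape
classes cover mature morphologies (disc, edge-on "sideways" presentation,
crescent, star, wrinkled, spiculated) and contaminants (nucleated precursor,
expelled free nucleus, debris, doublet aggregate). Crescents are the
difference of two offset ellipses parameterized by elongation and curvature;
spicules are 1–2 px radial fibers. Population defaults emulate a cultured
red-cell preparation: ~8 µm cells with mild ellipticity and boundary
roughness, >95% marker-positive, >75% non-nucleated events, a few percent
each of nuclei, debris and aggregates, 2% rendered out of focus, and (for
induced mixes) 20% crescent/spiculated cells. Seeding is counter-based: one
master seed per run, with every event's parameters, rendering and noise
derived from its own counter seed, so any single event is reproducible in
isolation and population manifests are byte-identical across reruns.

Training sets emulate *hand-picked* example cells and are therefore drawn
from narrow parameter ranges — manual selection picks canonical examples,
not population-typical ones. The non-sickle set is 80% face-on discs and
20% edge-on presentations: cells pass the detector in any orientation, and
a tilted disc is a genuinely non-sickled example that no honest manual
selection can exclude. This composition matters scientifically: against
pure face-on discs, single thickness-based metrics separate synthetic
crescents essentially perfectly and the ratio score gains nothing, whereas
under orientation heterogeneity the Sickle Score's combination is what
recovers the separation — the reason a dedicated sickled-versus-sideways
comparison is informative in the first place. With it, the package shows
the expected ordering: Length ranks highest, Shape Ratio and
Symmetry 2 rank in the top five, the combined score beats Shape Ratio
alone, and star/wrinkled alternative outcomes separate only weakly.

Videos place cells on a static grid (the imaged cells settle in the dish;
there is no motion model), each cell in its own tile, rendered sparsely at
exactly the requested frame indices with per-frame seeded noise so sparse
and dense renderings agree pixel-for-pixel at shared indices.

Deliberately *not* modeled: optics (point-spread functions, phase
contrast), hemoglobin polymerization physics, cell motion or flow
hydrodynamics, sickling reversal during fixation, and spectral
compensation. Passing tests therefore demonstrate that the analysis
recovers known ground truth under the stated image model — not that the
renderer is photorealistic, nor that thresholds transfer unchanged to real
instruments.

## Numerical choices

* Texture: in-mask intensities quantized to 16 gray levels (min–max within
  the mask); co-occurrence at 1 px offset over the four axial directions
  (up/down/left/right), symmetrized and normalized; contrast
  $\sum P_{ij}(i-j)^2$, entropy $-\sum P \log_2 P$ in bits. Diagonal
  offsets are excluded deliberately: on a strict 1-px checkerboard the
  diagonal neighbors are same-colored, and the axial convention keeps the
  checkerboard reference values (contrast 225, entropy 1 bit) exact.
* Skeleton: Zhang–Suen thinning with a distance-transform-argmax fallback
  for small symmetric blobs that parallel thinning annihilates; side
  branches shorter than 10% of the length are pruned and the terminal 10%
  of the remaining path is excluded at each end before reading the minimum
  thickness — unpruned skeleton tips would drive the minimum to zero on
  every shape.
* Perimeter: chain-code length with $\sqrt2$ diagonal steps and the 0.948
  digitization correction; circularity clipped to $(0, 1]$.
* Quantiles: linear interpolation between order statistics (type 7)
  everywhere a threshold is calibrated, so calibrations are bit-stable.
* Bimodal splits: between-class-variance maximization on a 256-bin
  histogram, falling back to a 99.5th-percentile rule (with a warning flag)
  when the split explains less than half the variance, i.e. when the
  distribution is not convincingly bimodal.
* Degenerate events (blank crops, masks under 16 px) are flagged and carry
  `NA` features — never silent zeros — and fail the non-debris gate.

## Worked example

```{r example}
library(sicklemetry)

# imaging arm on one synthetic induced trial
pop <- sample_population(population_config(2000, seed = 1))
fx <- featurize_events(pop$events)
gates <- calibrate_gates(fx)
kept <- apply_gates(fx, gates)

# sickle gate at 10% spillover on an uninduced reference
ref <- sample_population(population_config(
  2000, class_fractions = default_class_fractions("uninduced"), seed = 2))
ref_fx <- featurize_events(ref$events)
ref_kept <- apply_gates(ref_fx, calibrate_gates(ref_fx))
gate <- calibrate_sickle_gate(
  sickle_score(ref_fx[ref_fx$event_id %in% ref_kept$final_ids, ]))
percent_sickled(sickle_score(fx[fx$event_id %in% kept$final_ids, ]), gate)

# kinetics arm: one control-like trial
trial <- run_kinetics_trial(kinetics_config(568, 0.54, seed = 1))
trial$summary
```

## Problem sizes and verification

The test suite exercises the pipeline at sizes chosen to give tight Monte
Carlo error while remaining quick to run: 20 replicate video trials of
568/609 cells per group for kinetic parameter recovery; 10,000-event
held-out populations for spillover calibration; 10 generator seeds of
200-per-set training sets for the discriminant-ranking properties; 20
analytic shapes against independent geometric oracles for the thickness
metrics; 1000-replicate null simulations at 300 cells/group for test
calibration; and 1200–3000-event mixes for gating recall/precision against
generator truth. `scripts/acceptance.R` re-runs the kinetic
parameter-recovery simulations from scratch at full size.

## Known limitations

* The IoU-change detector is a reproducible surrogate for blinded human
  scoring; its 0.25 threshold is exposed in configuration, and cells whose
  mask is lost in more than 20% of frames are dropped rather than censored
  to avoid informative censoring.
* The maximum sickling rate is computed on cells pooled across trials;
  per-trial computation is available by summarizing trials separately.
* Star-shaped and wrinkled outcomes are modeled as mild radial
  distortions; they are not well separated from normal cells, and the Sickle Score endpoint will
  underestimate total polymerization where such outcomes dominate.
* Synthetic measurement noise is cleaner than real imaging cytometry;
  absolute discriminant values are therefore larger than real instruments
  produce, and only orderings carry meaning.
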