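---
title: "Quantifying EAE recovery: gait kinematics, histology, expression and clinical scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying EAE recovery: gait kinematics, histology, expression and clinical scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eaequant)
```

`eaequant` bundles the quantification machinery used to measure recovery in
the mouse experimental autoimmune encephalomyelitis (EAE) model of multiple
sclerosis: treadmill hindlimb gait kinematics from markerless pose
estimation, fluorescence and electron-microscopy histology, relative gene
expression, and ordinal clinical scoring. Every stage has a matching
synthetic-data generator with exported ground truth, so the whole pipeline
is verifiable end to end without any animal data.

## Gait kinematics

### From pixels to centimetres

Pose-estimation software tracks six sagittal-plane landmarks of the right
hindlimb — iliac crest, hip, knee, ankle, metatarsophalangeal joint (MTP)
and toe — at 250 frames/s while the mouse walks on a treadmill, and writes
one CSV per recording in the scorer/bodyparts/coords three-header dialect.
A calibration frame with four markers at the corners of a 4 cm (height) by
7 cm (width) rectangle fixes the pixel scale: the horizontal and vertical
cm/px scales are averaged into a single conversion coefficient. We treat a
relative disagreement of the two scales above 5% (anisotropy) as a setup
error rather than averaging it away silently, because a single coefficient
is meaningless for a genuinely anisotropic view.

Pose estimators emit a per-landmark confidence. Frames below a confidence
gate (default 0.9) are treated as dropouts and linearly interpolated between
the nearest confident frames; interpolation never leaves the convex hull of
its bounding samples, and a landmark confident in less than half of the
frames aborts the recording. The gate value is our convention: confident
detections in this setting are typically reported near 1, so the analysis is
insensitive to the exact gate over a wide range. The y axis is flipped to
y-up so joint heights are positive upward.

### Joint angles and phase segmentation

Interior angles at the hip (iliac crest–hip–knee), knee (hip–knee–ankle) and
ankle (knee–ankle–MTP) are the arc-cosine of the normalized dot product of
the two segment vectors, in degrees within [0, 180]; no signed or reflex
angles are used.

Step cycles are segmented from the toe's horizontal velocity. On a
treadmill the belt carries the stance foot rearward at near-constant speed
while the swing foot is brought forward, so with the animal facing +x the
smoothed toe velocity is negative through stance and positive through
swing. The rule is: moving-average smoothing of toe x (window 7 frames,
i.e. 28 ms at 250 frames/s), central-difference velocity, a ±0.5 cm/s
hysteresis dead band whose frames inherit the previous label, minimum-run
merging (10 frames), and emission of only those stance→swing pairs flanked
by valid phases on both sides, so partial cycles at the recording edges are
discarded. Animal orientation is auto-detected from the sign of the median
smoothed velocity (stance occupies the majority of the cycle) and the x
axis is mirrored for animals facing −x; this heuristic assumes a duty
factor above one half, which holds for walking gaits.

The smoothing window matters more than any other parameter here: windows
much wider than the velocity reversal at foot contact smear the boundary
and bias the duty factor. With the 7-frame default, synthetic noiseless
recordings are segmented within ±2 frames of the generator's boundaries and
the duty factor is recovered within one percentage point.

### The 200-frame representative cycle and the gait metrics

Each stance and each swing phase is time-normalized to 100 samples by
linear interpolation (endpoints preserved exactly), all normalized stances
averaged pointwise, likewise all swings, and the two mean phases
concatenated — stance first — into the 200-frame representative step cycle
of the recording. Two metrics summarize it per joint:

* **average angle** — the arithmetic mean of the 200 samples; disease
  lowers the average knee angle (a crouched, flexed gait);
* **RMS difference** — the root mean squared sample-wise difference between
  the recording's cycle and a reference cycle. This is a scaled Euclidean
  metric (symmetric, triangle inequality), used as the joint-movement
  variability measure.

Two reference conventions are defensible and the field's description leaves
the choice open: referencing each animal's own pre-induction baseline
recording (longitudinal drift from healthy gait) or the recording's own
mean cycle (within-recording step-to-step variability). We default to the
baseline reference, which matches reporting RMS per timepoint along a
longitudinal study, and expose the within-recording mode
(`within_recording_rms()`, `rms_mode = "within"` in the pipeline) behind a
flag rather than guessing silently. Hip angles are computed but the
headline metrics are the knee and ankle, which are the joints reported in
this assay.

The pipeline applies the study's inclusion rule before any gait
computation: recordings from days on which the animal scored above 2.5 on
the clinical scale (severe walking deficits) are excluded with a
machine-readable reason, since gait on a treadmill is only meaningful for
animals still able to walk.

## Histology

### Axonal transection from punctate eYFP fluorescence

In Thy1-eYFP mice, transected axons accumulate bright eYFP puncta in white
matter. Because overall section brightness varies stochastically while
grey-matter fluorescence is unaffected by disease or treatment, thresholds
are anchored to grey matter: per image, the mean intensity over
healthy-appearing white matter is divided by the mean over grey matter;
these ratios are averaged across the analysis batch into a standardized
ratio R; each image's threshold is R × (its own grey-matter mean) × 1.5;
and the percent area of white-matter pixels strictly above threshold is the
percent-area axonal transection. The ×1.5 factor is an empirical margin
and is exposed as a parameter with 1.5 as the default. The whole statistic
is invariant to global rescaling of image intensities — a tested
invariance, which is also why storing intensities rescaled to [0, 1] in
TIFF is lossless for this analysis. The batch over which R is averaged is a
config choice; the pipeline computes it once per run.

### White-matter loss from EC/NR staining

Eriochrome Cyanine stains intact myelin blue and the Neutral Red
counterstain exposes demyelinated area. The underlying ImageJ-style
thresholding is not standardized, so we state ours: a white-matter pixel is
NR-positive when red/(blue + 1e-6) exceeds 1.2 (a parameter), and percent
white-matter loss is the NR-positive fraction of the white-matter mask.

### Remyelination from g-ratios

Axon/myelin segmentation of TEM images is performed by an external
deep-learning tool; this package consumes its label masks. We use the
area-equivalent g-ratio, g = sqrt(A_axon / (A_axon + A_myelin)), rather
than a diameter along a chord, because it is robust to non-circular fiber
profiles and is the standard choice for automated segmentation output.
Objects touching the image border (areas truncated) and axons under 10 px
(segmentation specks) are excluded; myelin labels without a matching axon
are skipped with a warning. Myelinated axons with g strictly above 0.8 are
counted as remyelinating — thin sheaths relative to caliber — following the
established cutoff for this model; both the density (per µm²) and the
percentage are reported. The percentage denominator (all retained axons vs
myelinated axons only) is ambiguous in common usage; both are available and
the default is all axons.

## Gene expression (RT-qPCR)

Technical triplicates are collapsed by the arithmetic mean of available
replicate Cq values (an optional outlier rule — drop replicates more than
0.5 cycles from the pair median — exists but is off by default, since plain
averaging is the stated practice). Reference stability uses the classical
geNorm M: for candidate genes j, k, the per-sample pairwise log2 ratio is
Cq_k − Cq_j, V_jk its SD over samples, and M_j the mean of V_jk over the
other candidates; acceptance thresholds are M < 1.0 for tissue and M < 0.5
for cultures. Only per-gene M and threshold flags are computed — the full
iterative geNorm exclusion procedure is not needed for a fixed reference
pair.

Relative expression uses the ΔΔCq method with amplification efficiency
fixed at 2: per sample, dCq = Cq_target − mean(Cq of references)
(arithmetic mean of Cq, i.e. geometric-mean expression normalization);
ddCq centres dCq on the control group's mean (a single calibrator sample is
available behind a flag); fold = 2^(−ddCq). By construction the control
group's geometric-mean fold is exactly 1, and per-sample global Cq shifts
cancel — both tested invariants.

## Clinical scores and the exact Mann–Whitney test

Daily ordinal scores (0–5 in 0.5 steps) are summed per animal over the
inclusive window DPI 16–44 (treatment onset at peak disease through study
end) into a cumulative score; missing days are an error unless explicit
interpolation is requested. The two-group comparison is a one-tailed
Mann–Whitney U test computed exactly: ties get midranks, and the
conditional permutation distribution of the rank sum given the observed
values is obtained by dynamic programming over subset counts — an exact
count of all C(n+m, n) group assignments, feasible well beyond the n = 10
per group used in such studies. Exactness matters because half-point scores
make ties pervasive, where the normal approximation misbehaves; for pooled
sizes above 20 the tie- and continuity-corrected normal approximation is
used and labelled as such.

## Synthetic data: what it emulates and what it does not

Every generator is a pure function of its parameters and seed and exports
machine-readable ground truth at the level the pipeline measures.

* **Gait** (`gen_gait_recording()`): interior-angle waveforms — Fourier
  series over a warped cycle phase with a triangle-like hip profile so the
  toe tracks the belt rearward at near-constant speed and reverses sharply
  at the transitions — drive a forward-kinematic chain hung from a
  quasi-fixed iliac crest; pixel coordinates come from inverse-applying a
  known calibration. Study conditions chosen once: 250 frames/s, cadence
  2.5 Hz, duty factor 0.6, 800×600 px frames at 0.01 cm/px, EAE-like knee
  offset −15°, cycle-to-cycle angle noise ~1.5° where noise is wanted. The
  stance-velocity sign constraint is asserted post hoc (the hip excursion
  is widened and the construction retried up to 10 times if violated).
  What this does *not* emulate: muscle dynamics, perspective or lens
  distortion, paw-shape tracking error structure. Passing tests show the
  measurement chain is correct, not that a real mouse walks like the model.
* **eYFP sections** (`gen_eyfp_image()`): banded GM / lesioned-WM /
  healthy-WM layout with puncta painted at a stated multiple of the
  analytic threshold; the painted pixel count is the exact truth. Real
  sections have textured autofluorescence, not flat bands with Gaussian
  noise.
* **TEM fields** (`gen_axon_field()`): non-overlapping elliptical annuli;
  the exported g is recomputed from the rasterized pixel counts, so truth
  is exact under the area definition. Real fields have touching fibers and
  segmentation errors; those enter through the mask inputs, not this
  generator.
* **Clinical cohorts** (`gen_clinical_cohort()`): onset U{9–12}, linear
  rise to a U(2.5, 3.5) peak at DPI 16, group-specific linear recovery,
  daily noise, rounding to the 0.5 grid. n = 10 per group by default.
* **qPCR plates** (`gen_qpcr_plate()`): per-gene base Cq, per-sample global
  shifts (SD 0.3 cycles), reference jitter and replicate noise (SD 0.05
  cycles each), injected true folds.

## Numerical choices and degenerate inputs

Angle arc-cosines are clamped to [−1, 1] before `acos`; coincident
landmarks give a missing angle, interpolated unless they exceed 10% of
frames. Phase resampling requires at least two samples per phase.
Calibration corners are matched by lexicographic sort; rotated rectangles
are rejected rather than silently fit. Thresholds at classification
boundaries are strict (`>`) everywhere — suprathreshold fluorescence and
g above the 0.8 cutoff — so boundary values never count. Empty
segmentations, empty masks, zero-replicate wells and empty axon-record
lists fail fast (or warn and return zero summaries where the contract says
so). All file outputs use stable orderings so identical configs reproduce
byte-identical tables.

Problem sizes in the shipped tests and acceptance script are scaled for a
desk run — 2-second recordings (~5 step cycles), 200×200 px sections,
≤900×900 px axon fields, 2000-replicate null calibration — chosen so the
whole suite completes in well under a minute while every tolerance stated
above is still exercised.

## The pipeline interface

`run_gait_study()`, `run_histology()`, `run_qpcr()` and `run_clinical()`
consume a config list or YAML file and emit tidy long-format CSVs (metrics,
exclusions with reason codes, per-axon records, fold changes, test
reports). Routine downstream statistics that act on these tables — two-way
repeated-measures ANOVA with Šidák contrasts across timepoints, one-way
ANOVA with Dunnett contrasts across doses, Kruskal–Wallis with Dunn — are
deliberately left to standard tools; the tables are shaped for them. These
functions are the package's interface; `inst/scripts/run_study.R` is a thin
shell wrapper over them for command-line use.

## Known limitations

* The phase rule assumes treadmill locomotion with duty factor > 0.5;
  overground or running gaits would need a different orientation heuristic.
* 2-D sagittal kinematics only; out-of-plane motion projects into the
  angles.
* The eYFP analysis trusts the provided region masks; ROI delineation is
  upstream.
* Amplification efficiency is fixed at 2; efficiency-corrected ΔΔCq
  variants are out of scope.
* The exact Mann–Whitney route is capped at pooled n = 20 before switching
  to the corrected normal approximation.
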