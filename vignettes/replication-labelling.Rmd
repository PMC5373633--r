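---
title: "Quantifying DNA-replication labelling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA-replication labelling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replicyte)
```

## The measurement problem

Pulse-labelling cells with a thymidine analogue (BrdU, EdU, IdU, TFdU)
marks nuclei that were in S phase during the pulse. Immunofluorescent
detection of the incorporated analogue then yields, per nucleus, a signal
whose usefulness depends on two things: how well the labelled (replicating)
population separates from the unlabelled background, and how stable the
analogue–antibody complex is during the washes between the primary and the
secondary antibody. `replicyte` provides the quantitative machinery for
both questions: per-nucleus measurement from two-channel images, a robust
signal/background statistic, a dissociation-kinetics model with
formaldehyde stabilisation, and bivariate cell-cycle gating — together with
a synthetic-data generator that makes every stage testable against known
ground truth.

## The R/non-R statistic

Let *F* be the fraction of cells exhibiting replication signal after the
pulse (*F* = 0.44 is the default, the value measured for a 30-minute pulse
in a typical cycling human line, with day-to-day spread of about ±6
percentage points). Sort the *n* per-nucleus signals in descending order.
Then

* the **R group** is the top `round((F − 0.1)·n)` nuclei (at *F* = 0.44 and
  *n* = 10,000: 3,400 nuclei),
* the **non-R group** is the bottom `round((0.9 − F)·n)` nuclei (4,600),
* the statistic is the ratio of the two group means.

The 0.1 buffers on either side of the expected class boundary exclude
borderline nuclei, so modest errors in *F* do not mix the classes. A ratio
above 3–4 indicates separation good enough to classify individual nuclei.

Numerical choices worth stating explicitly:

* group sizes are rounded half-away-from-zero and clamped to at least one
  nucleus; `r_nonr_ratio()` refuses *f* outside (0.1, 0.9) and inputs too
  small for both groups to be non-empty;
* the sort is stable, so ties at a group boundary are broken by input
  order — since tied values are equal, this cannot change either group
  mean;
* a zero non-R mean (all-zero background) makes the ratio undefined and is
  an error rather than `Inf`.

**The statistic is a comparator, not an unbiased estimator.** Because the
R group keeps only the upper part of the labelled component and the non-R
group only the lower part of the background component, both truncations
push the ratio upward relative to the raw ratio of component means. At the
generator's default component CVs (0.3 labelled, 0.1 background) the
statistic reads roughly 10–15% above the underlying mean contrast; with
tight components (CV ≤ 0.1) it converges to within a few percent. This
does not affect its intended use — comparing conditions measured the same
way — and the property suite pins both behaviours.

`estimate_f()` provides a data-driven *F* when none is known: Otsu's
threshold on `log(signal + 1)` splits the distribution, `f_hat` is the
fraction above threshold, and the estimate carries a reliability flag that
is false when the ratio of class means falls below 3, mirroring the 3–4
guideline. Otsu on the log scale was chosen because it is deterministic
and parameter-free; any mixture-model alternative would add fitting
choices without changing the well-separated case, which is the only case
in which per-nucleus classification should be trusted anyway.

## Dissociation kinetics and stabilisation

The loss of specific signal during post-antibody washes is modelled as
first-order decay: the retained fraction after washing for *t* minutes is
`exp(−k_off · t)`. A single rate is used because a three-point time course
(full signal at a 5-second wash, ~20% at 5 minutes, essentially zero at 30
minutes) is fully consistent with one exponential; nothing in the data
demands biexponential behaviour. The default `k_off = log(5)/5 ≈ 0.322`
per minute is calibrated to the 80% five-minute loss observed for a
low-affinity/high-specificity antibody clone under enzymatic detection; it
is stored per antibody (`antibody_kinetics()`) so other clones can be
parameterised. The 5-second "time zero" wash is treated as *t* = 0: at the
default rate the decay over five seconds is under 3%, well below
measurement noise.

`fit_k_off()` estimates the rate from observed (t, retained) pairs by
least squares of `−log(retained)` on *t* through the origin — the model
form makes the regression linear, and the origin constraint encodes
retained = 1 at *t* = 0. Observations at or below zero retention must be
floored at a detection limit by the caller; the fitter refuses them.

Formaldehyde post-fixation cross-links the complex and stops the decay.
`stabilisation_factor()` interpolates a concentration–response curve
anchored at measured efficiencies relative to the 2% reference
(0.05% → 0.827, 0.1% → 0.967, 0.2% → 1.023, 0.5% → 0.953, 1% → 1.05,
2% → 1.00). Anchors slightly above 1 are retained as measured rather than
clipped — they are noise around a plateau, and clipping would bias the
plateau downward. Below the lowest anchor the curve falls linearly to
(0, 0) (no formaldehyde, no stabilisation); above the highest it is held
constant. In `apply_wash_dissociation()`, a stabilised wash multiplies the
specific component by this factor and decays no further, while an
unstabilised wash multiplies it by the retained fraction. The
non-specific background component is left untouched in both cases: the
time-course data quantify the loss of specific signal only, and modelling
background decay would be an invented parameter (this is the main open
modelling question; if background decayed at the same rate, washed-out
ratios would be unchanged but absolute intensities lower).

## Cell-cycle gating

Gating operates on (signal, DNA content) pairs, whether from flow-style
events or from per-nucleus image measurements (mean signal, integrated
DAPI). DNA content is first normalised to the G1 peak, located as the
highest mode of a kernel-density estimate over the signal-negative events
(excluding S-phase events makes the 2N mode dominant); values are divided
by the peak so G1 ≈ 1 and G2/M ≈ 2, which also makes gating invariant to
the arbitrary intensity scale. The S gate is Otsu on log signal by default
— deliberately the same machinery as `estimate_f()`, so the image and flow
paths and the F estimate cannot disagree about what "labelled" means — with
a k·sigma alternative (threshold at the background mean plus k standard
deviations, default k = 3) because that is common flow practice.
Signal-negative events are split G1 versus G2/M at 1.5× the G1 peak (3N),
the simplest rectangular gate; no curved gates and no doublet
discrimination are attempted. Degenerate inputs are handled as follows: a
constant signal column is treated as all-unlabelled (gating proceeds, no S
events); an apparently bimodal signal whose class means differ by less
than a factor of 2 is refused with advice to use a longer labelling pulse.

## The synthetic-data generator

The generator emulates the population structure the analysis assumes:

* a replicating fraction of 0.44 (binomially realised per cell), phase
  fractions G1/S/G2M = 0.45/0.44/0.11 — the S fraction is the measured
  default, the G1:G2M split a typical cycling-line choice;
* per-nucleus signal = specific + background, both log-normal
  (fluorescence is positive and right-skewed). Defaults: S-phase total
  mean 2,000 a.u. over a 100 a.u. background (contrast 20, comfortably
  above the 3–4 guideline), CV 0.3 for the specific component. The
  background CV is 0.1: nuclear background in flat-field images varies on
  the order of 10%, and this choice keeps the trimmed ratio of a fully
  dissociated (background-only) population near 1 — consistent with
  observed behaviour of unstable clones without stabilisation, where the
  ratio collapses to about 1. (A much wider background CV would inflate
  that floor through the trimmed-mean bias described above: ~1.2 at
  CV 0.1, ~1.7 at CV 0.3.)
* DNA content 2N for G1, 4N for G2/M, uniform on (2N, 4N) for S (no
  replication-timing structure), each perturbed by a 5% measurement CV —
  S-phase values are kept strictly inside the (2N, 4N) interval so phase
  remains recoverable from content;
* images: nuclei as non-overlapping disks (radius 8–14 px, ≥2 px
  perimeter gap) in a 1024×1024 16-bit frame; DAPI per-pixel intensity is
  `gain · dna_content / area` so integrated DAPI is proportional to DNA
  content; the signal channel is flat at the nucleus' true signal;
  Gaussian read noise (SD 10 a.u.) plus optional Poisson shot noise;
* flow events: one per cell, truth values times independent log-normal
  measurement noise (CV 0.05), in randomised acquisition order.

What the generator deliberately does **not** emulate: optics (no PSF, no
z-structure), photobleaching, illumination gradients, nuclear shape
variation (disks only), overlapping/clumped nuclei, doublets and debris in
flow, or replication-timing substructure within S phase. Passing tests on
synthetic data therefore demonstrate correctness of the measurement and
statistics pipeline under its stated model, not robustness to every
real-microscope artefact; segmentation accuracy on real images in
particular will depend on focus, clumping and staining quality in ways the
disk model cannot probe.

## Segmentation and measurement choices

Nuclei are identified on the DAPI channel: Gaussian smoothing (sigma 2 px)
to suppress read noise, Otsu threshold (a fixed threshold is available),
hole filling, and — when splitting is enabled — a watershed on the distance
transform (tolerance 0.5) to divide touching nuclei; objects outside
[50, 5000] px² are discarded and labels renumbered consecutively.
"Average nuclear signal" is the per-pixel arithmetic mean of raw signal
intensities within the nucleus mask, not the integrated intensity: the
ratio statistic compares nuclei of broadly similar size, and the mean is
insensitive to segmentation-area errors at flat nuclear signal. No
background subtraction is applied; the statistic's non-R group plays that
role. On constructed noise-free fixtures, smoothing should be disabled:
blurring a binary disk pair fills the waist between them and can defeat
the watershed split that the unsmoothed geometry supports.

## Problem sizes and determinism

The validation suite exercises the statistic at n = 10,000 nuclei (the
standard per-experiment count), segmentation on 300-nucleus fields, and
1,000 randomised oracle-equivalence instances; these sizes give tight
parameter-recovery checks (3-SE criteria) while keeping the whole suite
around half a minute. All stochastic stages take explicit seeds, and
`run_pipeline()` derives per-stage seeds from one global seed, so a config
plus seed reproduces every table, image and manifest hash bit-for-bit (the
gating PNG is listed in the manifest but not hashed; PNG encoders are not
guaranteed byte-stable across libraries).

## Known limitations

* The first-order decay model is anchored by three time points; it cannot
  distinguish single- from multi-exponential dissociation, and the no-
  post-fixation wash series is not modelled separately.
* `estimate_f()` and the S gate assume an (approximately) bimodal signal;
  short pulses or low-affinity clones without stabilisation violate this,
  and the reliability flag / separation error are deliberately
  conservative there.
* The trimmed-ratio's upward bias relative to the raw component contrast
  (see above) means absolute ratios from different dispersion regimes are
  not directly comparable; compare conditions measured under the same
  protocol.
* The G1/G2M boundary is a fixed 3N rectangle; aneuploid lines or strong
  DNA-staining nonlinearity would need a different boundary.
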