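---
title: "Suspect screening for GC-EI-HRMS: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suspect screening for GC-EI-HRMS: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcscreen)
```

## The screening problem

Gas chromatography coupled to electron-ionization high-resolution mass
spectrometry (GC-EI-HRMS) separates the constituents of a complex extract in
time and fragments each of them, at 70 eV, into a reproducible pattern of
accurate-mass ions. Suspect screening asks, for hundreds of compounds in an
accurate-mass spectral library, whether each is present in a sample — without
authentic standards being run alongside. Because EI spectra of co-eluting
compounds superimpose, the raw chromatogram must first be *deconvoluted*
into pseudo-compounds ("components"), and each component spectrum is then
scored against the library. Two independent lines of evidence enter the
score: spectral similarity, and agreement between the observed retention and
the library's Kovats retention index (RI).

`gcscreen` implements this workflow end to end — profile-to-centroid
conversion, extracted-ion-chromatogram (EIC) construction, chromatographic
peak detection, component assembly, weighted forward/reverse library
matching with a trapezoidal retention penalty — together with the machinery
used to *optimize* such a method (false-positive/false-negative scoring,
match-factor cutoff calibration, tolerance and weight-factor sweeps,
screening-detection-limit estimation) and a synthetic-data generator that
makes every stage testable without instrument data.

## The processing model, stage by stage

### Centroiding

A profile spectrum is split into contiguous regions above an intensity
floor. Regions are further split at m/z gaps larger than 250 ppm — far
beyond the 40–60 ppm point pitch that a time-of-flight analyzer of resolving
power 5,700–8,400 produces — because sparse storage can place points of
distinct ions at adjacent indices. Within a region, a cut between two local
maxima is made only where the valley drops below half the smaller apex, so
sampling noise does not fragment a single peak. Each surviving region with
at least `min_points` (default 3) points yields one centroid at the
intensity-weighted mean m/z with the region's apex intensity. The weighted
mean was chosen over a parabolic fit deliberately: different vendors
interpolate differently at this step, which is precisely why screening
methods end up needing mass tolerances of tens of ppm, and the simulator can
plant a systematic centroiding bias to reproduce that effect.

### EIC construction

Centroid peaks across scans are clustered into mass traces. The extraction
window `mz_delta` (default 0.05 Da) is interpreted as the **full** window:
any two peaks in one trace differ by at most 0.05 Da. Trace building is
greedy in decreasing intensity order with nearest-mass assignment and ties
toward lower m/z, with at most one peak per scan per trace; every centroid
is assigned to exactly one trace, so total ion current is conserved exactly
(a tested invariant). Scans without a member contribute zero intensity.

### Peak detection and integration

Each trace is smoothed with a Savitzky–Golay filter (window ≈ half the
expected 3 s peak base, forced odd), local maxima are found on the smoothed
trace, and each peak is integrated valley-to-valley on the *raw* trace with
the trapezoidal rule. Peaks below the absolute-area threshold (default
10,000 counts) are discarded. Two refinements matter in practice:

* the apex is located as the intensity-weighted centroid of the smoothed
  trace's top (points within 80% of the apex), which gives sub-scan apex
  estimates; flat, saturated tops resolve to the plateau midpoint;
* the peak's m/z is the local intensity-weighted mean of its own member
  centroids, not the global trace mean, which protects a peak from distant
  near-isobars that happen to share its trace.

### Component assembly

Peaks are grouped into components in decreasing height order: the tallest
unclustered peak seeds a component, and unclustered peaks join it when their
apex lies within the grouping window `Δt = rt_window_size_factor ×
scan_period / 100` of the seed (factor 100 ≈ one scan period, i.e. 0.2 s at
5 Hz; the factor values worth exploring span 25–200) *and* their resampled
peak shape correlates with the seed's model shape at Pearson r ≥ 0.9. Shapes
are fixed-length (21-point) resamplings of the smoothed trace over the
peak's own valley-to-valley base. Each peak joins at most one component;
`max_shapes_stored` (default 10) caps only correlation bookkeeping, never
the ion list. Components with fewer than `min_ion_peaks` ions (default 3)
are dropped. A component's spectrum is its ion abundances (areas by
default) normalized to base peak 999, the classic EI convention.

### Kovats retention indices

Retention is calibrated per batch with a C7–C40 n-alkane series: alkane Cn
defines RI = 100 n, and queries interpolate linearly between bracketing
alkanes (the van den Dool–Kratz form, the standard choice under temperature
programming; the logarithmic isothermal form is deliberately not the
default). The mapping is piecewise linear, strictly increasing, exactly
invertible on the calibrated range, and linearly extrapolated (flagged)
outside it. RT-annotated libraries acquired under a different program are
migrated by an ordinary-least-squares linear correction fitted on anchor
compounds (a dozen anchors spanning the calibrated range is typical),
followed by RI conversion — in that order.

### Library matching

Ions below `min_mz` (default 30 Da, cutting the uninformative low-mass
region) are excluded from both sides. Each library ion is paired one-to-one
with the nearest query ion within the accurate mass tolerance (AMT, default
50 ppm, computed against the library mass); conflicts resolve by smallest
ppm error, ties toward higher intensity. Both directions of similarity use
the Stein–Scott weighted cosine with weights `w = I^0.5 · m/z^1.3`
(exponents configurable):

* **reverse** score R — cosine restricted to the library's ions: query ions
  with no library counterpart are ignored;
* **forward** score F — cosine over the union of both ion sets, so
  unmatched ions on either side pull the score down.

The composite match factor is `100 · (pwf · F + (1 − pwf) · R)`, where the
*pure weight factor* (PWF) interpolates between a pure reverse search
(pwf = 0) and a pure forward search (pwf = 1). The vendor formula behind
the original workflow is unpublished; the weighted-cosine family with the
convex-combination semantics of the two endpoint searches is this package's
own definition and is exposed so the score family itself can be studied.

Retention evidence enters as a multiplicative trapezoidal penalty on the
|observed − expected| retention time, with the expected time of an
RI-annotated entry obtained through the *sample's own* alkane calibration:
no penalty within `penalty_free_s`, a linear ramp to `max_rt_penalty` score
points at `rt_range_s`, and outright rejection beyond (a soft-penalty mode
is available). The defaults (20/20/20 s) mirror an in-house-library
configuration; a retention-time-locked pesticide library would use
30/30/30. With the 20/20 setting the ramp is empty: the penalty degenerates
to a ±20 s acceptance gate. Hits below `min_match_factor` (default 75) are
dropped — by default on the *final*, post-penalty score, with pre-penalty
thresholding behind a flag since the reference software does not document
which it uses — and at most `max_hits` (default 1) best hits are kept per
component, with deterministic tie-breaking (raw match, then |Δrt|, then
name).

## The optimization machinery

Screening performance is always a trade-off between false negatives
(spiked/true compounds missed) and false positives (names reported that are
not present). `gcscreen` encodes the two-stage protocol used to tune such
methods:

1. at the **high** spike level, per-PWF match-factor cutoffs are calibrated
   as the largest integer cutoff keeping the false-negative fraction at or
   below a target (5% is the conventional screening target; 0% and 1%
   columns are also computed); missed compounds enter the score list as 0;
2. at the **low** spike level, each PWF is evaluated at its calibrated
   cutoff, tabulating FN and FP counts — the trade-off from which a working
   PWF is chosen.

Because the forward and reverse cosines do not depend on PWF, the package
computes them once per component×entry pair (`component_scores()`) and
derives all sweeps by arithmetic, which makes full AMT × PWF × cutoff grids
essentially free once deconvolution is done.

Two counting conventions are supported and deliberately kept apart. For
*screening reports*, one best hit per component (the production setting).
For *trade-off sweeps*, every candidate above the cutoff is counted: since
each candidate's composite score is affine and, for a fixed pairing,
monotone in PWF, false positives are then structurally non-increasing and
false negatives non-decreasing as PWF grows — the mechanism being measured —
whereas best-hit competition adds small non-monotone artifacts when a
component's top hit switches names between PWF values.

The screening detection limit (SDL) of a compound is the lowest tested
concentration at which it is detected in at least 95% of replicates, with
the additional requirement that every higher tested level also satisfies the
rule ("demonstrated" detection); compounds with no qualifying level are
reported as not determined.

## What the simulator emulates — and what it does not

The generator reproduces the acquisition geometry of the reference
instrument: 5 spectra/s over m/z 40–1000, resolving power interpolated
linearly between 5,700 at m/z 68 and 8,400 at m/z 502 (flat outside),
Gaussian peaks of 3 s FWHM (exponentially modified Gaussian when a tailing
constant is set). Each planted ion becomes an 11-point symmetric profile
cluster at FWHM/3 pitch, so a noiseless weighted-mean centroid recovers the
planted m/z exactly. Signal scale: a compound at concentration `level` has
base-ion area `level × response_factor` counts·s (default 2,000, placing a
50-unit spike at 100,000 counts·s — comfortably above the 10,000-count area
threshold for strong ions, while its weakest ions fall below it, which is
the intended low-level failure mode).

Error models, each switchable: systematic mass bias (ppm), per-scan random
mass error (default σ = 5 ppm), per-ion response jitter drawn once per ion
per run (log-normal, default 15%, emulating ion-ratio variability between
measurement and library), small per-scan intensity jitter (3%,
shot-noise-scale), additive per-point detector noise (20 counts), and
constant column-bleed-style background ions at the familiar siloxane masses
207.0329/281.0511.

The matrix background is modeled as random pseudo-components, generated once
per experiment and shared by all replicate injections. A quarter of them
embed the complete ion set of a random library entry (intensities
log-normally perturbed) inside a richer ion population — the classic
reverse-search false-positive bait; a further 15% are placed within a
fraction of a peak width of a random library compound, so low-level analytes
acquire interfering ions and forward search loses sensitivity there. The
standard benchmark screens 26 spiked compounds out of an 80-entry suspect
library at two levels (50 and 500 extract-concentration units) in five
replicates — the suspect library being larger than the spike list is what
makes name-level false positives observable at all.

The simulator makes no attempt at physically realistic EI fragmentation
(masses are integer nominal masses plus plausible CHNOClBrS-range defects,
intensities are draws, not chemistry), isotope structure, retention
modeling beyond the planted RI, or real mussel-extract composition. Passing
tests therefore demonstrate the correctness and qualitative behavior of the
*processing*, not instrument-grade figures of merit on real extracts.

## Numerical choices and degenerate inputs

* Problem sizes: the standard benchmark uses a C7–C30 alkane program at
  30 s per carbon (runs of ~13 min simulated time, ~3,900 scans) and 120
  matrix components — large enough to exercise co-elution and false-positive
  behavior while keeping a full 10-run benchmark in the low minutes on one
  core.
* Grouping tolerance comparisons use an absolute 1 ns slack so grid-aligned
  apex differences equal to Δt are included despite floating-point noise.
* An EIC whose total integral cannot reach the area threshold is skipped
  before smoothing; traces are processed in contiguous non-zero blocks.
* Ties: flat peak tops take the plateau midpoint; equal-score hits break by
  raw match, |Δrt|, then name; mass-pairing conflicts break by ppm error,
  then query intensity.
* Degenerate inputs: empty spectra centroid to empty spectra; empty
  component lists filter to empty lists; an empty pairing scores 0; a
  library entry with neither RI nor RT is scored without retention evidence
  and flagged; target false-negative rates must lie in [0, 1).
* Cutoffs are integers (floored), matching the reporting convention of
  screening optimization tables.

## Known limitations

* The match-factor family is this package's definition, not the vendor's;
  absolute score values are comparable only within `gcscreen`.
* Single-run processing: no cross-run alignment or correspondence.
* The greedy EIC builder can split ion populations of two co-eluting
  compounds closer than the extraction window in both time and mass; the
  affected ions lose area or mass accuracy (observed as occasional
  sub-0.98 spectral cosines for co-eluting near-isobars).
* Quantification utilities are limited to external-standard arithmetic;
  recovery/repeatability validation against real calibration curves is out
  of scope.
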