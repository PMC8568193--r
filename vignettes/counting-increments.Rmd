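---
title: "Counting cementum increments: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting cementum increments: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cementr)
```

## The measurement model

Dental cementum deposits one light/dark increment pair per year. In a
tomographic slice the cementum is a thin curved band around the dentine;
after straightening along a user-drawn midline, increments run
horizontally and a radial transect through the band yields a 1-D
luminance profile `g(x)` in which light increments are peaks and dark
increments troughs. The package estimates the number of increment pairs
as the number of genuine peak–trough systems along many such transects.

Two features of real data shape the algorithm. First, tomographic
cementum shows an overarching density gradient from the cemento-dentine
junction (bright, oldest tissue) out to the surface, so any threshold
defined on the whole transect would miss peaks near the outer edge and
troughs near the junction. The transect is therefore split into
sections and all statistics are local to a section. Second, the contrast
between increments varies between scans and taxa, so all thresholds are
*relative* — fractions of each section's own standard deviation — never
absolute greyscale values. A corollary, enforced by tests, is that
counts are invariant under affine transforms `a·g + b` (a > 0) of the
luminance scale, which also makes 8-bit and 16-bit input equivalent.

## The counting procedure

For one straightened slice:

1. **Transects.** 1000 bands of 10 px width are drawn uniformly at
   random (with replacement) over the valid column positions; random
   positions avoid the autocorrelation a regular grid would impose.
   With replacement is deliberate: narrow phantoms can have fewer than
   1000 distinct positions. Each band's rows are averaged into one
   profile, which suppresses pixel noise by √10 before any smoothing.
2. **Length screening.** The tissue extent of a profile starts at its
   first value above zero (straightening fills background with exact
   zeros). The acceptance threshold `mean(L) − sd(L)` is computed once
   from the original sample of lengths `L`; shorter transects are
   redrawn until they meet it. The threshold is deliberately *not*
   recomputed after resampling — the accepted set must satisfy the
   original sample's criterion — and redraws are capped at 100 per
   transect, after which an informative error reports the threshold and
   the best length seen (this happens only when no valid position
   exists, e.g. a slice with almost no tissue).
3. **Sections.** The tissue extent is split into 5 contiguous sections
   whose lengths differ by at most 1 px. Remainder pixels go to the
   innermost sections: inner cementum is the oldest and most compressed
   part of the record, where an extra pixel of context is most useful.
4. **Smoothing.** Each section is smoothed with a cubic smoothing
   spline (`stats::smooth.spline`); the smoothing parameter is chosen
   per section by generalized cross-validation, so the degree of
   smoothing adapts to the local noise level without user tuning. A
   fixed `spar` can be supplied through `run_config(smooth_spar = )`
   when reproducibility across sections matters more than adaptivity.
   Constant sections are passed through untouched (GCV is undefined
   there), yielding zero spread and no counted events.
5. **Detection.** In each smoothed section with mean `ḡ` and standard
   deviation `σ`, interior local maxima above `ḡ + 0.5σ` and interior
   local minima below `ḡ − 0.5σ` are candidate events (plateaus
   collapse to their centre index). Two rejection rules then remove
   piggy-back features — secondary wiggles riding on the limbs of real
   increments, produced by accessory increments or residual noise:
   counted events closer than 3 px are merged, keeping the larger
   departure from the mean (ties: the smaller index), and the counted
   sequence must alternate peak/trough, a run of same-kind events again
   keeping the largest departure. At the default 0.66 µm voxel size the
   3 px separation corresponds to 1.98 µm, well below the thinnest
   annual increment.
6. **Pair count.** The section's pair count is its number of counted
   peaks. After alternation enforcement every counted peak heads
   exactly one light–dark system, including systems whose trough falls
   just across a section boundary; counting `min(peaks, troughs)`
   instead would silently lose those straddling pairs (a clean 17-cycle
   profile over 5 sections would count 15). With peaks as the unit, the
   only features a section can miss are crests that themselves straddle
   a boundary, which the next step recovers.
7. **Boundary pass.** For each internal boundary, the left section's
   smoothed values after its last counted event are concatenated with
   the right section's values before its first counted event. One pair
   is added when this limb contains an *uncounted apex*: an interior
   local maximum of the limb exceeding the upper cut-off of the section
   it lies in, with the limb also dropping below the lower cut-off of
   the section containing its minimum (evidence of a full swing). The
   interior condition rejects the shoulders of already-counted peaks,
   so a crest lying fully inside a section is never double counted; at
   most one pair is added per boundary. A trough straddling a boundary
   needs no recovery — its flanking crests are interior to the sections
   and already counted.
8. **Aggregation.** The slice estimate is the mean pair count over the
   accepted transects (SD as dispersion); the specimen estimate is the
   mean of slice means, rounded to the nearest integer (ties away from
   zero). A quarter-rounding mode is provided for comparison against
   expected counts known only to fractional-year eruption uncertainty.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_transects` | 1000 | – | averages out transect-to-transect variation; SD over transects is the per-slice precision measure |
| `transect_thickness_px` | 10 | px | pre-averaging noise suppression without blurring oblique increments |
| `n_sections` | 5 | – | short enough that the radial gradient is locally ~linear, long enough to estimate mean and SD stably |
| `cutoff_factor` | 0.5 | fraction of σ | a counted extremum must clear half the section SD; smaller admits noise, larger drops faint increments |
| `min_separation_px` | 3 | px | 1.98 µm at 0.66 µm voxels; sub-increment-scale wiggles are merged |
| `n_slices_per_specimen` | 30 | – | slices averaged into a specimen estimate |
| `rounding_mode` | `"integer"` | – | final count granularity (`"quarter"` for fractional-year comparisons) |
| `smooth_spar` | GCV | – | per-section smoothing; fix it to decouple smoothing from noise level |
| voxel size | 0.66 | µm | physical scale of the px→µm conversion only; counting is scale-free |

The steerable filter default `sigma_px = 2` is below the thinnest
expected increment (≈3 px), so filtering cannot merge neighbouring
bands; filtering is optional because the counting statistics are
relative and work on unfiltered straightened images too.

## The synthetic generators and what they (don't) show

`make_sine()` emulates a single transect profile: exactly `true_count`
periods across `length_px` samples (default 1000 px, comparable to real
transect lengths), offset to non-negative luminance, plus i.i.d.
Gaussian noise. The noise level is indexed by a pattern SNR in (0, 1]
with noise SD `(1 − snr) · amplitude`: stepping the SNR from 0.9 down
to 0.1 in 0.1 decrements raises the noise SD linearly from 0.1 to 0.9
of the signal amplitude. Under this parameterisation the validation
suite shows graceful degradation: cell means within 0.5 of truth for
every count at SNR 0.9–0.5, within 1 at SNR 0.4–0.2, and a mean
absolute error at SNR 0.1 at least as large as at 0.9. The alternative
convention of an amplitude/σ *ratio* is deliberately not used for the
sweep labels: it would put σ at 10× the signal amplitude at "SNR 0.1",
a regime in which no counting algorithm could recover 5–30 cycles from
1000 samples. `noise_sd` can be set
directly to use any other noise convention, and the noise distribution
is Gaussian by assumption (the generator is the single place to change
it).

`make_phantom()` emulates a straightened slice: horizontal sinusoidal
band pairs, an optional monotone radial gradient rising toward the
cemento-dentine side, optional accessory-increment splits (a narrow
groove carved through a band's crest over a column range, turning one
maximum into two), and additive noise. Ground truth (pair count, crest
rows) is returned with the image.

What passing the synthetic suites does *not* show: real increments are
neither strictly periodic nor sinusoidal; their spacing compresses
toward the outer surface; noise in reconstructed CT is not i.i.d.
Gaussian (phase retrieval correlates it); and accessory increments in
real tissue are not clean grooves. The suites validate the *counting
rules* under controlled truth, not the imaging chain. Real-data use
still requires the user to choose high-contrast slices and annotate
midlines — the method is deliberately semi-automated at those two
points, and neither step is modelled here.

## Numerical choices and degenerate inputs

* **Midline interpolation** is a natural cubic spline through the
  control points, parameterised by cumulative chord length and
  resampled at 1 px arc-length steps (preserving circumferential
  sampling density). Natural end conditions distort the outermost few
  samples of a curved path; annotate slightly beyond the region of
  interest. A self-intersecting midline warns but does not error.
* **Straightening interpolation** is bilinear. On circular-phantom
  oracles the row-wise disagreement with direct polar resampling stays
  below 1% of the dynamic range, and bilinear is exactly the identity
  on axis-aligned integer geometry, which makes the resampler testable;
  higher-order schemes would change counts by less than the cut-off
  margins. The outward normal (row 1 of the output) is chosen as the
  field direction pointing away from the image centroid, fixing the
  outer-surface-first orientation of profiles.
* **Filter boundary handling** is mirror reflection; responses are
  signed, and only rescaled affinely when written to unsigned TIFF.
* **SNR/CNR** use the sample (n−1) standard deviation; at the default
  150 × 150 px ROI the population/sample distinction is < 0.1%.
* **Ties** in the separation merge resolve to the larger excess, then
  the smaller index; plateau extrema use the plateau's centre index.
* **Degenerate inputs**: constant sections and flat boundaries count
  zero; an image narrower than the transect thickness, tissue shorter
  than the section count, a zero-variance background ROI, and an
  all-zero image each raise immediate, specific errors rather than
  propagating NaNs.
* **Reproducibility**: pipeline entry points seed R's generator once
  from `run_config()$rng_seed`; sweep replicates derive per-cell seeds
  from the master seed by fixed offsets so any cell can be reproduced
  in isolation.

## Validation scale

The packaged validation runs the full grid of true counts 5–30 at SNR
levels 0.9–0.5 (accuracy/robustness) and 0.4–0.2 (degraded tolerance),
30 replicates per cell at 1000 samples per pattern — 3900 and 2340
patterns respectively, a few tens of seconds each on one CPU. Unit and
property suites (steerability, affine invariance, section-count
agreement, determinism, straightening oracles) run on reduced sizes
chosen to exercise every rule, not to re-measure the sweep.

## Known limitations

* No automatic midline detection or slice selection: both are expert
  input by design.
* The algorithm counts peak–trough systems that clear the relative
  cut-offs; it does not classify annual vs accessory increments. In
  regions of heavy splitting/coalescence the count is biased by
  whatever survives the separation and alternation rules, and the
  intended use is to *avoid* such regions when selecting slices.
* Counting assumes vertical transects in the straightened frame;
  strongly oblique increments (a poorly drawn midline) flatten the
  profile and depress counts — visible as a high per-slice SD.
* The boundary-recovery rule adds at most one pair per section
  boundary; a pathological profile with several uncounted crests
  crowded into one boundary region would still undercount.
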