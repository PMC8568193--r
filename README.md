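# cementr

Semi-automated counting of dental cementum growth increments in greyscale
tomographic images.

## The problem

Cementum — the mineralised tissue anchoring a tooth root to the
periodontal ligament — grows appositionally throughout life, laying down
one thick translucent ("light") and one thin opaque ("dark") increment per
year. Counting these increment pairs is a standard way of estimating age
at death in zooarchaeology, forensic science, anthropology and
palaeontology. Counting by eye in thin sections is subjective: accuracy
and precision track the experience of the reader, and accessory increments
formed by band splitting and coalescence bias counts. `cementr` is aimed
at researchers working with high-resolution (sub-micrometre) tomographic
slices of tooth roots who want increment-pair counts that do not depend on
who pressed the button.

## The method

For each slice the pipeline is:

1. **Straightening** — the circumferential cementum band is resampled
   along a user-annotated midline (a natural cubic spline through control
   points, resampled at unit arc length) into a rectangular image whose
   rows run from the outer cementum surface to the cemento-dentine
   junction; background stays exactly 0.
2. **Directional filtering** (optional) — a steerable first
   derivative-of-Gaussian filter, `R(θ) = cos θ (I * G_x) + sin θ
   (I * G_y)`, oriented at θ = 90° to the now-horizontal increments,
   enhances band contrast.
3. **Counting** — 1000 transects of 10 px width are drawn at random
   column positions; each transect's per-row mean luminance `g(x)` is
   screened for tissue length (redrawn if shorter than `mean − SD` of the
   original lengths), split into 5 equal sections, and smoothed with a
   cubic smoothing spline. In each section, with mean `ḡ` and standard
   deviation `σ` of the smoothed values, a peak counts only if it exceeds
   `ḡ + σ/2`, a trough only if it falls below `ḡ − σ/2`; counted events
   closer than 3 px (1.98 µm at 0.66 µm voxels) are merged and must
   alternate peak/trough, which rejects "piggy-back" accessory features.
   The per-section statistics make the count invariant to the overall
   radial density gradient and to any affine change of the luminance
   scale. A boundary pass recovers crests split across section
   boundaries. The slice estimate is the mean pair count over the 1000
   transects; the specimen estimate is the mean over (conventionally 30)
   slices, rounded to the nearest integer or quarter.
4. **Image quality** — `SNR = ḡ_c / σ_b` and
   `CNR = (ḡ_c − ḡ_b) / sqrt((σ_c² + σ_b²)/2)` from paired 150 × 150 px
   cementum/background ROIs.

A validation harness generates sine-wave patterns of known increment
number (5–30) at controlled noise levels and banded 2-D phantoms (with
density gradient, accessory splits and noise) and measures counting
accuracy (cell mean within ±0.5 of truth) and robustness (SD of 30
replicates < 1).

## Worked example

Count a noisy banded phantom with 10 known increment pairs, a radial
density gradient and additive noise:

```r
library(cementr)

phantom <- make_phantom(10, width_px = 120, height_px = 400,
                        gradient = 400, noise_sd = 150, seed = 42)
cfg <- run_config(n_transects = 1000, rng_seed = 1)
est <- count_slice(phantom$pixels, cfg, seed = cfg$rng_seed)
est
#> increment_estimate (slice): mean 10.00 pairs, sd 0.00 over 1000 transects

count_specimen(list(est, est, est), rounding_mode = "quarter")
#> increment_estimate (specimen): mean 10.00 pairs over 3 slice(s), count 10 (quarter rounding)
```

Despite a gradient of 400 luminance units across the profile and noise
with SD 150 on bands of amplitude 1000, every transect recovers the true
count of 10 pairs: the slice mean is 10.00 with SD 0.00.

A reduced robustness sweep (full grids use counts 5–30 and 30 replicates):

```r
rep <- robustness_sweep(cfg, counts = c(5, 10, 20), snrs = c(0.9, 0.5),
                        reps = 10, seed = 1)
assess_robustness(rep)$per_snr
#>   snr accuracy_rate robustness_rate n_counts
#> 1 0.9             1               1        3
#> 2 0.5             1               1        3
```

Every cell mean equals the known count and every cell SD is below 1, so
the accuracy and robustness pass rates are 1 at both noise levels.

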