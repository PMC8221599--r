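---
title: "Population tuning-curve mapping: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population tuning-curve mapping: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

A face-selective region like the inferior occipital gyrus responds to both
*where* a face part appears in the visual field and *which* part of the face
it is. ptcmap models both with the same machinery: each surface vertex gets a
one-dimensional Gaussian population tuning curve (pTC) over a normalized
stimulus axis `u ∈ [0, 1]` — the vertical meridian for spatial mapping
(`u = 0` is 5 d.v.a. above fixation), or a chin-to-hairline "face space" for
face-part mapping (`u = 0` is the hairline). The curve has a peak preference
μ and a width σ; σ is inverse selectivity, the quantity whose
posterior-to-anterior cortical gradient the map statistics are designed to
detect.

The forward model is the standard pRF chain: the stimulus aperture's
occupancy of each spatial bin at each TR (`build_aperture()`), integrated
against the unit-peak Gaussian (`neural_response()`), convolved with a
double-gamma HRF, and compared with the measured series by squared Pearson
correlation (R²). Fitting is a grid search (`coarse_fit()`) over μ from
−0.2 to 1.2 in steps of 0.005 (peaks may sit somewhat outside the stimulus
edges) and σ = 2^x, x from −5.6 to 1 in steps of 0.05 — 281 × 133 pairs —
optionally refined by a clamped Nelder–Mead local step (`fine_fit()`,
off by default; both behaviors are supported because a grid-only second
pass and a local refinement are both defensible readings of common
practice).

### Two-pass HRF handling

Pass 1 fits every vertex under a canonical SPM-style double-gamma HRF
(peak delay 6 s, undershoot delay 16 s, dispersions 1, positive/undershoot
ratio 6, 32 s support). Vertices with pass-1 R² > 0.2 are pooled across
conditions and hemispheres, their best neural predictions frozen, and the
HRF parameters fitted by maximizing the pooled mean R² — a coarse grid over
(peak delay, undershoot delay, dispersion, ratio) followed by Nelder–Mead
on log-parameters clamped to the grid's bounding box. The undershoot
dispersion is tied to the peak dispersion: with 192-point z-scored series
the two are barely separately identifiable, and the tie keeps the fit to
four free parameters. By construction the fitted HRF never scores below the
canonical one on the inclusion set (the optimizer returns the canonical
parameters if it cannot beat them), and an empty inclusion set falls back
to canonical with a warning. Pass 2 refits the tuning grid under the fitted
HRF.

The fine optimizer is derivative-free rather than a literal gradient
descent: the coarse-to-fine landscape is non-smooth at grid resolution and
a simplex step is robust to that; the criterion (mean R²) is identical.

## Definitions that matter downstream

* **R²** is the squared Pearson correlation between the convolved,
  variance-normalized prediction and the observed series. The amplitude β
  is a post-hoc least-squares scaling of the *mean-centered* prediction on
  the z-scored series, with no intercept — series are z-scored so the
  baseline is 0. This makes the simple Gaussian a 3-parameter model
  (μ, σ, β), which is what the BIC comparison's parameter count requires.
* **RSS for BIC** uses those β-scaled residuals; `BIC = n log(RSS/n) +
  k log n` with k = 3 (simple) and k = 4 (mixture). Both models center
  their predictions the same way — an early version centered only the
  simple model's and that inconsistency alone flipped the comparison.
* **Degenerate predictions** (grid pairs whose prediction variance is
  negligible, e.g. a tiny Gaussian far outside the sweep path) are excluded
  from the search rather than left to produce spurious correlations; the
  exclusion threshold is relative (1e-10 of the largest column SD).
* **Ties** in the grid search break deterministically to the first
  maximizer in (lowest μ, then lowest σ) order. Off-space pairs can tie to
  rounding error; the oracle-equivalence tests therefore assert maximizer
  equivalence, not parameter identity.
* **Thresholds are strict**: R² > 0.3 for maps, > 0.2 for HRF inclusion,
  > 0.5 for coverage selection. A fit at exactly the threshold is out.

## The mixture alternative

The bimodal control model is a sum of two Gaussians with peaks fixed at the
eye and mouth positions in face space and free widths and non-negative
amplitudes (k = 4). No canonical peak coordinates exist for this
stimulus set, so the defaults derive from the stimulus geometry: eye and
mouth locations about 0.8 d.v.a. above and 1.9 d.v.a. below fixation on a
10 d.v.a. face span 0.27 face units, centered mid-face → 0.365 and 0.635.
They are ordinary arguments (`peak_positions`) and every analysis accepts
others. Because R² is scale-invariant the search runs over
(σ_eye, σ_mouth, mixing weight w ∈ [0, 1]) — a grid plus Nelder–Mead on
(log σs, logit w) — and recovers β_eye = βw, β_mouth = β(1−w) afterwards,
which enforces the non-negativity constraint naturally.

## Preprocessing

Per run: drop the dummy volumes, band-pass by orthonormal DCT-II
projection, z-score, then average runs element-wise. The band-pass removes
the two lowest-frequency non-constant components (drift) and everything
above 0.26 Hz; component k of a length-T series at repetition time tr has
frequency k/(2 T tr). Two notes:

* The order filter → z-score → average is canonical here; preprocessing
  summaries of this kind rarely pin whether z-scoring preceded filtering,
  and nothing downstream depends on the order beyond reproducibility.
* A strict two-component drop leaves ~9% of a pure linear ramp's RMS (the
  ramp leaks into higher odd components). Tests assert agreement with the
  explicit projection oracle rather than a nominal "drift gone" figure.
* The averaged series is *not* re-standardized, so averaging R independent
  noise runs shrinks its SD by ≈ 1/√R — the property the FDR null
  distribution and the SNR calibration both rely on.
* Model predictions are **not** band-pass filtered. That mirrors the usual
  pRF practice (predictions come from stimulus × HRF only) but means the
  filter slightly reshapes even a noiseless simulated signal; the
  noiseless-recovery tests therefore assert exact recovery for unfiltered
  series and median-within-one-grid-step through the full simulator. We
  evaluated filtering the predictions identically (it reduces the mismatch
  and slightly improves width recovery) and kept it out of the default
  path for the sake of the plainer forward model.

## Map-level statistics

Vertex axis positions are the scalar projections of vertex *positions*
onto the posterior–anterior axis direction, min-max normalized to [0, 1]
(0 = most posterior). Projecting surface-normal *vectors* instead of
positions yields no positional information, so the positional reading is
the only one implemented.

All group tests use the hemisphere as the unit: per-hemisphere correlations
(Pearson by default, Spearman as the robustness variant; widths correlated
on a log2 scale), Fisher-z transformed, one-sample two-sided t test against
zero. |r| = 1 is excluded with a warning (infinite z). The restricted-range
control keeps σ < 1 and 0 < μ < 1 in both domains — the convention
follows the only consistent reading of the restriction: peaks *inside* the
mapped area. For split-condition comparisons, peak
"height" is reported as 0.5 − μ so that "higher in the face / visual
field" has one sign across domains, and the goodness-of-fit comparison
permutes the pooled R² values (10,000 by default) with an add-one-smoothed
two-sided p — identical inputs give p = 1 exactly.

The FDR bound is the empirical ratio P(null R² > thr) / P(ROI R² > thr),
a conservative upper bound (it books every null-level crossing in the ROI
as false). The null is pure noise pushed through the *identical*
preprocessing and fitting pipeline — the synthetic stand-in for
white-matter time courses; 5,000 series by default rather than the tens of thousands a whole-brain white-matter mask would supply, which
desk-scale testing does not need.

## Coverage contrast

Vertices with very good fits in both domains (R² > 0.5), narrow spatial
tuning (σ < 3 d.v.a.) and peaks at least 1 d.v.a. above/below fixation
form the UVF/LVF groups. Each vertex's fitted face-tuning curve is
evaluated on a 101-point grid, scaled to a maximum of exactly 1 (fitted
curves are the only option consistent with unit-amplitude scaling;
for peaks outside the grid the on-grid maximum is used), and averaged per
group. A grid point is significant when the observed |group difference|
exceeds that of *all* label shuffles, which makes 1/n_shuffles the
attainable p floor — 1e-5 at the canonical 100,000 shuffles. Shuffles
permute labels only and preserve group sizes.

## The synthetic world

`make_ground_truth()` states the world the tests live in: axis positions
uniform on [0, 1]; log2 σ linear in axis position (intercept −4.5, slope 3,
i.e. σ from ≈ 0.04 posterior to ≈ 0.35 anterior before jitter) plus
Gaussian jitter — SD 1.2 for the spatial domain and 3.0 for the face
domain, correlated at 0.3, chosen so the within-hemisphere width-gradient
correlations land near the ≈ 0.6 (spatial) and ≈ 0.26 (face) scale of real
maps; per-hemisphere slope jitter (SD 0.5) gives group tests realistic
between-hemisphere variance. Peaks are central-face-biased (normal, mean
0.5, SD 0.2, clamped to [0, 1]) with cross-domain correlation 0.2. Widths
clamp to the search range [2^−5.6, 2]. Noise is white Gaussian per run by
default (no noise model is stated for the real data), with an AR(1) option
(ρ = 0.3) for stress-testing; 17 runs per condition reflects the reported
per-participant average, and the default per-run noise SD of 5 is the
closed-form estimate for the median-R²-0.4 regime
(`calibrate_noise_sd()` matches a target exactly by pilot simulation).

What the generator does *not* emulate: spatially correlated noise across
vertices, cortical folding (the synthetic surface is a jittered line along
the axis), vertex-to-vertex tuning smoothness, duplicated time series from
surface projection, or any physiological noise structure. A green test
therefore establishes that the *procedures* behave as specified under
their own assumptions — not that those assumptions hold in real data.

## Known limitations

* **Width recovery at the real-data SNR.** With noise calibrated so the
  measured median R² is 0.4, the realized median |log2 σ̂ − log2 σ| is
  ≈ 0.26 across true σ ∈ [0.05, 0.5], nearly bias-free and stable across
  σ bands; a 0.2 bound is reached only around median R² ≈ 0.5. The
  corresponding acceptance assertion is intentionally left failing rather
  than recalibrated: width is simply weakly identified in a one-sweep
  design after hemodynamic smoothing at that SNR. Peak recovery meets its
  0.02 bound.
* **BIC scale dependence.** At short series (the 48-TR miniature used by
  fast unit tests) the ln(n) penalty per parameter outweighs any realistic
  mixture gain, so "bimodal data prefer the mixture" is only testable at
  the canonical 192-volume length, where it holds.
* The printed step sizes (0.055 normalized per 2 TRs; one-eighteenth for
  the face window) do not exactly carry the aperture from edge to edge in
  15 updates. The designs honor the step size and the start edge and end a
  sweep slightly short of the far edge; whether the printed bar position
  refers to its center or leading edge is likewise not stated, and the
  leading-edge reading is used.
* The exact double-gamma parameterization and free-parameter set of the
  original HRF fits are not stated; the SPM-style parameterization used
  here is documented and configurable but not asserted to be equivalent.
* NIfTI/GIFTI ingestion is not implemented (no R-side reader available in
  the target environment); TSV/JSON is the interchange format, and
  neuroimaging formats were only ever optional input adapters.
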