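# ptcmap

Vertex-wise population tuning-curve (pTC) mapping for fMRI: forward
modelling and fitting of one-dimensional Gaussian tuning curves from BOLD
time series, as used to map retinotopic elevation and face-part preferences
in face-selective visual cortex (inferior occipital gyrus, IOG), together
with the map-level statistics that test whether the two kinds of tuning
share a common cortical organization.

## Who this is for

Researchers modelling 1D sweep-stimulus fMRI experiments (traveling-bar
retinotopy along the vertical meridian, or a sampling window traveling a
normalized chin-to-hairline "face space"), and anyone who wants a fully
synthetic, seed-reproducible testbed for pRF/pTC-style fitting pipelines:
every stage can be exercised end-to-end against known ground truth without
any imaging data.

## The model

Each cortical vertex carries a Gaussian population tuning curve over a
normalized stimulus dimension `u ∈ [0, 1]` (`u = 0`: 5 d.v.a. above
fixation, or the hairline; `u = 1`: 5 d.v.a. below, or the chin):

    g(u) = exp( -(u - μ)² / (2σ²) )

The predicted neural response at each TR integrates `g` against the
stimulus aperture's occupancy, and the BOLD prediction is its convolution
with a double-gamma HRF. Fitting maximizes the squared Pearson correlation
(R²) over a grid with μ from −0.2 to 1.2 in steps of 0.005 and σ = 2^x,
x from −5.6 to 1 in steps of 0.05, in two passes: pass 1 under a canonical
HRF, then a pooled HRF fit on vertices with pass-1 R² > 0.2, then a pass-2
refit under the fitted HRF. Downstream: an empirical-null FDR bound for the
R² > 0.3 map threshold, posterior–anterior gradient and cross-map
correlations with Fisher-z one-sample t tests, a fixed-peak
mixture-of-Gaussians alternative compared by BIC, and a cumulative
face-coverage contrast with a 100,000-shuffle label-permutation test.

## Worked example

```r
library(ptcmap)

truth <- make_ground_truth(n_vertices = 60, n_hemispheres = 4, seed = 1)
sim   <- simulate_dataset(truth)
sim$spatial
#> <vertex_series: spatial, 192 TRs x 240 vertices, tr 1 s, runs averaged 17-17>

tp <- two_pass_fit(list(spatial = sim$spatial, face = sim$face), sim$apertures,
                   mu_grid = seq(-0.2, 1.2, by = 0.01),
                   sigma_grid = 2^seq(-5.6, 1, by = 0.1))
tp$hrf
#> <hrf_params: peak 5.93506 s (disp 0.815374), undershoot 16.4874 s (disp 0.815374), ratio 7.28344, length 32 s>

pairs <- tuning_pairs(tp$fits$spatial$pass2, tp$fits$face$pass2,
                      truth$axis_position, truth$hemisphere)
r <- map_correlations(pairs, "sigma_vs_axis", "spatial")
round(r, 3)
#>   H01   H02   H03   H04
#> 0.625 0.433 0.573 0.484
group_ttest(r)
#> <group_stat: median r = 0.528, t(3) = 9.83, p = 0.002236 (pearson)>
```

The 240-vertex cohort was generated with a posterior–anterior gradient of
log tuning width, so the per-hemisphere correlations between width and axis
position are strongly positive and the Fisher-z group test rejects zero.
The fitted HRF (peak 5.9 s) recovers the canonical generator (peak 6 s).
An FDR bound for the R² > 0.3 threshold comes from pure-noise series pushed
through the identical pipeline:

```r
nulls   <- simulate_null(500, seed = 2)
pg      <- prediction_grid(sim$apertures$spatial,
                           seq(-0.2, 1.2, by = 0.01),
                           2^seq(-5.6, 1, by = 0.1), tp$hrf)
null_r2 <- coarse_fit(nulls, pg)$r2
fdr_upper_bound(null_r2, c(pairs$sp_r2, pairs$face_r2), 0.3)$p_fdr
#> 0
```

(No null series crosses 0.3 after 17-run averaging, so the bound is 0 at
this scale.) `run_pipeline(pipeline_config(...), out_dir)` drives the full
simulate → fit → threshold → map-statistics → coverage chain and writes
fit tables (TSV), the fitted HRF (JSON), coverage curves and a
`report.json`.

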