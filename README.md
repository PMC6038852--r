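# firepatchr

Satellite burned-area products deliver *pixels* — each with a day-of-burn —
but fire science increasingly needs *fires*: individual patches with a
size, a shape, an orientation and a duration, the "functional traits" of a
fire regime. `firepatchr` turns per-pixel burn-date rasters into a fire
patch catalogue and gridded summary products:

1. **Patch reconstruction.** Burned pixels are aggregated by a temporally
   constrained flood-fill: two pixels belong to the same fire when they are
   linked by a chain of queen-adjacent (8-neighbor) burned pixels whose
   pairwise burn-date differences never exceed a cut-off Δt_co (3, 5, 9 and
   14 days are the conventional choices). Formally the patches are the
   connected components of the graph with burned pixels as vertices and
   edges between adjacent pixels with |Δdate| ≤ Δt_co.
2. **Functional traits.** For each patch of ≥ 5 pixels: pixel and core-pixel
   counts, geodesic areas A and A_core (ha, spherical Earth), perimeter P
   (pixel sides, holes included), perimeter-to-area ratio P.A.R. = P/N,
   shape index S.I. = P/p_min(N) (perimeter of the maximally compact patch
   of equal cell count; a square scores 1), fractal correlation dimension
   D₂ = 2·ln(P/4)/ln(N), core-area index C.A. = A_core/A, the standard
   deviation ellipse (half-axes σ_X ≤ σ_Y, azimuth θ, in degrees and in a
   local flat projection in km), ellipse ratio R_SDE = σ_X,km/σ_Y,km,
   eccentricity E_SDE = √(1 − R²), and the burn-date summary
   (BD_min/BD_max/BD_mean, year).
3. **Level-2 grids.** 1°×1° maps of trait means/standard deviations and
   fire counts, plus a per-cell fit of the fire-size distribution
   N_f = α·A_f^(−β) by χ² minimization with Poisson (√n) bin errors;
   σ_β is read off the Δχ² = 1 profile. Maps from two surveys can be
   compared cell-by-cell in units of combined σ_β.

A synthetic fire generator (elliptical daily-growth events with known
ground truth, first-burn-wins overlap) makes the whole pipeline testable
without satellite downloads, and a truncated-Pareto size sampler validates
the power-law fitter against known exponents.

## Worked example

```r
library(firepatchr)

ev <- fire_events(ignition_row = c(30, 30, 80), ignition_col = c(30, 80, 50),
                  start_day = c(120, 124, 200), spread_rate = c(2, 1.5, 2.5),
                  elongation = c(2, 1, 1.5), azimuth_deg = c(40, 0, 120),
                  duration_days = c(3, 4, 2))
sim <- simulate_burn_raster(ev, grid_shape = c(120, 120),
                            pixel_size = 1/240,      # 463 m at the equator
                            origin = c(-9.5, 14.0))
patches <- flood_fill_patches(sim$raster, cutoff_days = 5, survey = "DEMO")
traits  <- patch_traits(filter_patches(patches, min_pixels = 5))
```

`traits` has one row per fire with the full 24-column trait record:

```
         patch_id N_pixels    A  P   PAR   SI   D2    CA R_SDE E_SDE BD_mean
1 DEMO_co5_000001      223 4647 72 0.323 1.20 1.07 0.695 0.525 0.851     122
2 DEMO_co5_000002      113 2355 52 0.460 1.18 1.09 0.611 0.977 0.212     127
3 DEMO_co5_000003      119 2482 48 0.403 1.09 1.04 0.630 0.710 0.705     202
```

The three simulated fires are recovered as three patches. The first event
(elongation 2) shows the low ellipse ratio (R_SDE = 0.53, eccentric), the
circular second event is nearly round (R_SDE = 0.98), and areas are in
hectares at 463 m pixels. The size-distribution fitter recovers a known
power-law exponent from 20,000 sampled fire sizes:

```r
f <- fit_size_distribution(sample_patch_sizes(2, 20000, c(10, 1e4), seed = 42))
#> <powerlaw_fit> beta = 2.005 +/- 0.007 (chi2 = 11.09, 15 bins, 20000 fires)
tidy(f)      # broom-style coefficients; autoplot(f) draws the binned fit
```

`run_pipeline(run_config(...))` chains all stages and writes, per cut-off,
the catalogue CSV (`fire_patches_<SURVEY>_final_co_<N>.csv`), the gridded
NetCDF trait map (`trait_map_<SURVEY>_1.0deg_co_<N>.nc`) and a run report
with per-stage patch counts.

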