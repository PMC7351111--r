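# recruitkin

Quantification of DNA-damage recruitment kinetics from laser-microirradiation
live-cell imaging, with companion statistics for nuclear-foci burden and
clonogenic survival — driven end to end by a synthetic-microscopy generator
with known ground truth, so the whole pipeline is testable without any
external image data.

## Who this is for

Labs that follow the recruitment of fluorescently tagged DNA-repair proteins
(e.g. to DNA interstrand crosslinks created by a 405 nm laser stripe across a
psoralen/TMP-sensitized nucleus) and quantify it the standard way: hand-drawn
regions in Fiji, a ratio statistic per cell, mean ± SEM across cells,
normalization to the pre-irradiation frame, and per-timepoint t tests between
conditions. `recruitkin` turns that spreadsheet workflow into a reproducible,
tested pipeline.

## The statistic

For each cell and frame, with mean intensities over three hand-drawn (or
tracked) polygons — the irradiated stripe `Ax`, the rest of the nucleus
(avoiding the stripe) `Cx`, and the field background `B`:

```
Sx = (Ax − B) / (Cx − B)
```

`Sx` is the relative brightness of the stripe versus the rest of the nucleus
(1 = no enrichment). Being a background-subtracted ratio, it is invariant to
any gain/offset transform of the whole frame, hence robust to photobleaching
and illumination drift. Across cells the pipeline reports mean ± SEM
(SEM = sd/√n over all cells), then normalizes additively so the
pre-irradiation timepoint equals 1 exactly: the offset δ = mean(t_pre) − 1 is
subtracted from every timepoint (a pre-irradiation mean of 1.12 has 0.12
subtracted throughout). Conditions are compared per timepoint with a
two-sample Student's t test on per-cell Sx, with the usual tiers
(\* p < 0.05, \*\* p < 0.01, \*\*\* p < 0.001).

Two companion modules cover the other quantifications of such studies:

* **foci** — % of nuclei with > 10 foci (strict inequality) from
  Laplacian-of-Gaussian detection on max-intensity projections of z-stacks;
  mean ± SEM across independent experiments; Student's t at p < 0.05.
* **survival** — clonogenic surviving fractions, per-replicate
  plating-efficiency normalization (SF(0) = 1 by construction), mean ± SEM
  or SD across replicates.

## Worked example

```r
library(recruitkin)

cfg <- stripe_sim_config(n_cells = 10, a_true = 1.0, seed = 1)
sim <- simulate_stripe_movie(cfg)          # stack + ROIs + ground truth
m   <- measure_rois(sim$stack, sim$rois)   # cell_id, frame, t_s, Ax, Cx, B
agg <- normalize_to_t0(aggregate_curves(sx_curves(m), condition = "control"))
agg
#> <aggregate_curve> control: 11 timepoints, n = 10 cells, normalized (offset -0.00102)
#>    t_s  mean_sx         sem  n
#> 1   -5 1.000000 0.001347090 10
#> 2   30 1.447372 0.002745212 10
#> 3   60 1.695976 0.004303857 10
#> ...
#> 11 300 2.009311 0.003397935 10

fit_plateau(agg)$a_hat
#> 1.007  # simulated plateau amplitude was 1.0
```

The pre-irradiation frame (t = −5 s) is exactly 1 after normalization; the
mean rises along the saturating-exponential recruitment law toward
1 + A = 2. Comparing against a depleted condition (`a_true = 0.2`, seed 2)
at the late timepoints:

```r
depl <- simulate_stripe_movie(stripe_sim_config(n_cells = 10, a_true = 0.2, seed = 2))
cmp  <- compare_conditions(sx_curves(m),
                           sx_curves(measure_rois(depl$stack, depl$rois)))
tail(cmp, 1)
#>    t_s   mean_a   mean_b n_a n_b        p tier
#> 11 300 2.008291 1.208851  10  10 1.22e-29  ***
```

i.e. the ~5-fold reduction in recruitment amplitude is detected at tier
\*\*\* with 10 cells per arm.

## Command line

```sh
inst/cli/recruitkin demo     --out out/demo     --seed 1
inst/cli/recruitkin foci     --out out/foci     --seed 1
inst/cli/recruitkin survival --out out/survival --seed 1
```

Each run writes its CSV/TIFF/JSON artifacts plus `manifest.json` with MD5
hashes and the config snapshot; identical config + seed reproduces the CSVs
byte for byte. See `?run_pipeline` for the JSON config schema.

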