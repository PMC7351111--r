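---
title: "Quantifying stripe recruitment, foci burden and clonogenic survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stripe recruitment, foci burden and clonogenic survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recruitkin)
```

## The measurement model

A laser-microirradiation ("stripe") assay follows the accumulation of a
fluorescently tagged repair protein at a narrow line of localized DNA damage
drawn across a nucleus. Quantification works on three regions per cell and
frame: the irradiated stripe, the remainder of the nucleus selected to avoid
the stripe, and a background region shared by all cells in the field. With
mean intensities $A_x$, $C_x$ and $B$, the per-cell statistic is

$$S_x = \frac{A_x - B}{C_x - B},$$

the relative brightness of the stripe versus the rest of the nucleus.
$S_x = 1$ means no enrichment. Two properties make this ratio the right
summary for time-lapse data:

* **Affine invariance.** Replacing every pixel $I$ by $gI + c$ (gain and
  offset, $g > 0$) leaves $S_x$ unchanged. Photobleaching is a
  time-dependent gain applied to the whole frame, so it cancels exactly; the
  test suite asserts this on noiseless bleached stacks.
* **Background anchoring.** A nucleus not brighter than background
  ($C_x \le B$) makes the ratio unstable. The pipeline treats this as an
  error identifying the cell and frame, rather than emitting an arbitrary
  number.

Across the $n$ cells of a field, each timepoint is summarized as mean
$S_x$ ± SEM, with SEM the sample standard deviation divided by $\sqrt{n}$
over all cells. Where several independent experiments contribute cells, the
pipeline pools the per-cell values and records $n$; aggregation of
per-experiment means instead is possible by calling `aggregate_curves()` per
experiment, but pooling is the default because $n$ then reflects what the
error bars actually show.

### Additive normalization to the pre-irradiation frame

Because the tagged proteins are not uniformly distributed (dark areas,
occasional bright foci), the stripe region is rarely at exactly the nuclear
mean even before damage. Curves are therefore anchored so the
pre-irradiation timepoint equals 1: the offset $\delta = \bar S(t_{pre}) - 1$
is **subtracted** from every timepoint. A pre-irradiation mean of 1.12 has
0.12 subtracted throughout; a mean of 0.9 has 0.1 added. The additive (not
multiplicative) form is unusual for ratio data but is the field's stated
convention, and `normalize_to_t0()` follows it verbatim: SEM values are
untouched (an additive shift does not alter dispersion), the operation is
idempotent, and the cumulative offset is kept as an attribute. The
normalization acts on the aggregated mean curve, not per cell, again
following the stated convention. By default the first frame is the
pre-irradiation frame; this is configurable.

### Condition comparison

At each shared timepoint the per-cell $S_x$ values of two conditions are
compared with a two-sample, two-tailed Student's t test (classical
pooled-variance form; Welch is available behind `var_equal = FALSE`).
Significance tiers follow the usual figure convention: `*` p < 0.05, `**`
p < 0.01, `***` p < 0.001. No multiple-testing correction is applied across
timepoints — the source workflow applies none, and the per-timepoint p
values are reported so a reader can apply one. Two zero-variance groups with
equal means give p = 1 by convention; with unequal means, p = 0 (the t
statistic diverges).

## The synthetic stripe movie: a stated world

No reference image data exist for this workflow, so the package carries a
generator whose defaults *are* the simulated experiment, chosen once:

| parameter | default | why |
|---|---|---|
| field | 256 × 256 px, 10 nuclei | one microscope field at 60×, a typical number of analyzable cells |
| nucleus | ellipse, semi-axes 16 × 11 px, ±10% jitter | interphase nuclei at the stated magnification |
| stripe | 5 px wide, 0.6 of the nucleus x-extent | a narrow 405 nm laser line |
| frames | t = −5 s (pre), then every 30 s to 300 s | minutes-scale recruitment; intervals are configurable because acquisition schedules vary per figure |
| intensities | nucleus 400, background 60 (camera units) | mid-range of a 12-bit camera, ~7:1 contrast |
| kinetics | $S(t) = 1 + A(1 - e^{-k(t - t_{lag})})e^{-d\,\max(0, t - t_{lag})}$, A = 1, k = 0.02 s⁻¹, lag 0, d = 0 | the simplest law reproducing the observed shapes: a saturating rise with optional mild late decay emulating diffusion of the recruited protein out of the initially narrow stripe; half-rise ≈ 35 s |
| depleted condition | A = 0.2 | a strong (~5-fold) recruitment defect |
| noise | Poisson shot noise + Gaussian read noise σ = 3 | the standard camera model; no published noise statistics exist, so shot noise dominates at these intensities (~5% relative) |
| bleaching | β = 5 × 10⁻⁴ s⁻¹ | ~14% signal loss over 5 min, typical for spinning-disk time-lapse; applied as $e^{-\beta (t - t_1)}$, i.e. bleaching accrues with illumination time from the first acquired frame |
| drift | (0, 0) px/frame | cells "sometimes move slightly"; no magnitude is stated, so the default field is stationary and drift is switched on explicitly where tracking is exercised |

Rendering follows
$I(x,t) = I_{bg} + (I_{nuc} - I_{bg})\,M_{nuc}(x,t)\,[1 + (S(t) - 1)M_{stripe}(x,t)]$,
bleached, drifted, then noised. One master seed drives everything;
per-frame and per-condition substreams are derived deterministically, so an
identical (config, seed) pair reproduces the stack bit for bit.

**What a green test establishes — and what it does not.** The returned ROI
polygons are the simulator's own drifted geometry, i.e. a perfect
annotator: measured means then equal the ground-truth means up to noise, and
parameter recovery (plateau within ±10% at 10 cells) tests the statistics,
not segmentation robustness. Real data add hand-drawing variability,
non-uniform nuclear texture, stripe widening by the PSF, and out-of-focus
drift, none of which are modeled (no optical PSF for the stripe, no
multi-channel bleed-through, 2D nuclei only). Tracking is integer-pixel
cross-correlation of the nucleus neighborhood — adequate for the slow
migration it emulates, with an ambiguous correlation peak falling back to
zero shift with a warning.

## Foci counting

Foci stacks are z-stacks (21 planes by convention) of disk nuclei whose
per-nucleus focus count is Poisson with mean $m(t) = m_0 + r\,t$ (defaults
$m_0 = 2$, $r = 2.5$ h⁻¹: mean 12 at 4 h in controls; a suppressed
condition is emulated by lowering $r$). Spots are 3D Gaussians (σ 1.5 px in
xy, 2 planes in z, amplitude 150 over a nuclear baseline of 200 — about
10× the shot-noise σ) placed with a minimum in-plane separation of 5 px by
rejection sampling; when a draw cannot honor the separation the spot is
placed anyway with a warning and the returned count stays truthful.

Detection is deliberately simple and reproducible: maximum-intensity
projection over z, single-scale Laplacian-of-Gaussian response, local
maxima whose projected brightness exceeds 1.3× the median intensity of
their nucleus (a *relative* threshold, so a global gain change cannot alter
counts), greedy minimum-separation suppression with the strongest response
winning. The brightness test uses the 3×3 neighborhood maximum of the
projection because noise can displace the LoG peak one pixel from the
intensity peak. Counting on the projection rather than in 3D is a
documented simplification, adequate at the simulated densities; at high
densities spots genuinely overlap and undercounting is the correct physical
outcome, which is why detector accuracy is specified on well-separated
spots.

The burden statistic is the percentage of nuclei with **strictly more
than** a threshold count (10 by default — nuclei at exactly 10 are
excluded), computed per experiment, then mean ± SEM across independent
experiments (SEM = sd/√n over experiments, matching the error bars of the
source workflow), with per-timepoint Student's t at p < 0.05.

## Clonogenic survival

Colony counts are binomial: each of the plated cells (250–4,000, the
standard range) forms a colony with probability
$PE \times p(d)$, with plating efficiency $PE$ (default 0.5) and a
log-linear dose response $p(d) = e^{-\lambda d}$. Analysis normalizes per
replicate by that replicate's untreated plating efficiency,
$SF(d) = \frac{\text{colonies}/\text{plated}}{PE}$, so $SF(0) = 1$ exactly
by construction, then averages replicates with a selectable dispersion
statistic (SEM default, SD available, since published panels mix both).
Doses are treated as an ordered index with agent-specific units. The
normalization convention is not written out in the source workflow; the
per-replicate form used here is the standard clonogenic practice. No
linear-quadratic fitting or IC50 estimation is attempted.

## Numerical choices

* **Rasterization**: a pixel belongs to a polygon iff its center (integer
  0-based coordinates) is strictly inside by the even-odd rule or on the
  boundary. This makes measurement exactly translation-equivariant for
  integer shifts, and is asserted against an independent winding-number
  double-loop oracle.
* **TIFF**: stacks round-trip through an in-package baseline TIFF codec
  (uncompressed little-endian grayscale; 32-bit float written, 8/16/32-bit
  unsigned also read). Interoperability is tested against an independent
  implementation. Float32 storage bounds the round-trip error at ~1e-5 of
  the stored value, irrelevant at camera-count scales.
* **Plateau estimation**: nonlinear least squares on the post-irradiation
  mean curve with the lag fixed at 0; if the fit does not converge the mean
  of the last three timepoints minus 1 is used (valid once $kt \gg 1$).
* **Degenerate statistics**: SEM requires ≥ 2 cells; comparisons require a
  shared timepoint grid; empty ROIs, out-of-bounds polygons, missing
  pre-irradiation frames, zero plating efficiency and missing dose-0 rows
  are all hard errors naming the offending unit.

## Known limitations

The generator is a statistics testbed, not an optics simulator: green tests
demonstrate that the measurement, aggregation, normalization and testing
machinery is correct on data whose ground truth is known, at the stated
noise levels — they do not validate hand-annotation practice, segmentation,
or detector performance on real point-spread functions. The headline
biological results of any particular study (which proteins are recruited,
which cell lines are sensitive) are not reproducible from synthetic data
and are not claimed; the two externally checkable numbers this package
reproduces are the normalization worked example (offset 0.12 for a
pre-irradiation mean of 1.12) and the exactness of the normalization
contract, as reported by `scripts/acceptance.R`.
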