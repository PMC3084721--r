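---
title: "Automated force-volume image analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated force-volume image analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forcemap)
```

`forcemap` turns raw AFM force-distance curves into physical parameters
of a soft, charged biological sample — per pixel, without manual region
selection. This vignette explains the models behind each stage, the
parameters a user may want to tune, the numerical choices that make the
pipeline deterministic, and what the synthetic benchmark does and does
not demonstrate.

## Coordinate conventions and preprocessing

All positions are in nm, forces in nN, stiffnesses in nN/nm (numerically
equal to N/m); the Hertz prefactor `a` is in nN/nm² (numerically GPa).
Curves are stored with `z` strictly increasing; contact lies at the
largest `z` for approach curves and the smallest `z` for retraction
curves. Raw curves are sorted (duplicate `z` averaged) and an affine
baseline, fitted by OLS on the far-from-contact end (`baseline_n = 500`
points by default, capped at a third of the curve so short records are
not swallowed), is subtracted. The unbiased sample variance of the force
over the flat quarter of the curve serves as the noise estimate that
drives later thresholds.

One subtlety matters downstream: a baseline fitted a micrometre away
from contact leaves a residual offset of order half the noise SD once
extrapolated to the contact region. An exponential with no offset term
cannot absorb this, and it measurably degrades the Debye-length
estimate. The approach pipeline therefore re-zeroes the force on a short
window just below the measurable-force onset, where the true interaction
is negligible, before any electrostatic fitting.

## Greedy change-point segmentation

Both analyses start from the same segmentation: the samples are
partitioned into contiguous index intervals, each approximated by a
polynomial of degree `r` (degree 2 for approach, 1 for retraction) in
the least-squares sense. Starting from a single interval, each iteration
inserts the one admissible breakpoint that most reduces the total SSE,
in the spirit of forward greedy selection; intervals always keep at
least `r + 2` samples so residual comparisons remain meaningful. The
iteration stops at `k_max` breakpoints (6 for approach, 20 for
retraction — approach curves have few regime changes, retraction curves
up to tens of ruptures) or when the global MSE (total SSE / n) falls to
`eps`, whichever comes first. `eps` defaults to the empirical noise
variance: segmentation refines until the smoother is within the noise.

Numerical choices:

* Candidate-split SSEs are computed *exactly* (QR residuals on a
  per-range centered basis) for intervals up to 300 samples. Longer
  intervals are scanned with a closed-form prefix-moment formula on a
  locally standardized abscissa, then polished with exact refits around
  the approximate optimum. The closed form alone is ill-conditioned for
  short sub-ranges of long intervals and must not be trusted for final
  values.
* The MSE stopping test uses `max(eps, 1e-18 * mean(F^2))`: on
  noise-free signals an exact piecewise fit leaves a residual a few ulps
  above zero, and the relative floor recognises it.
* Ties between candidate splits are broken toward the smallest index,
  so runs are deterministic.
* Stored interval SSEs come from direct refits and agree with an
  independent refit to 1e-9 relative; an exhaustive enumeration oracle
  (`exhaustive_segment_oracle`, n ≤ 300, k ≤ 2) provides the reference
  for optimality tests.

## Approach curves: electrostatics, Hertz, Hooke

Before contact, tip and cell repel through overlapping electric double
layers; within the weak-overlap (Debye–Hückel) regime the force is
`F(z) = A exp(-kappa (Z1 - z))`, where `kappa^-1` is the Debye length
and `A` — the extrapolated force at the virtual pre-contact point `Z1` —
carries the surface/volume charge information. The theoretical Debye
length of a symmetric monovalent electrolyte,
`kappa^-1 = sqrt(eps0 eps_r R T / (2 F^2 c))`, is provided for
consistency checks (`debye_length_theoretical(1e-3)` is ~9.6 nm with
`eps_r = 78.5` at 298.15 K).

Past `Z1`, the sample deforms. In the indentation coordinate
`delta = (z - Z1) - (F - F1)/k_c` the model is flat at `F1` below a
virtual contact offset `delta0`, conical-tip Hertz
`F1 + a (delta - delta0)^2` up to the transition `Delta1`, and linear
(Hooke, slope `k_cell`) beyond — continuous everywhere. The Young
modulus follows from `E = a pi (1 - nu^2) / (2 tan alpha)` with the tip
semi-angle `alpha` (35° by default) and Poisson ratio `nu` (0.5,
incompressible).

The pipeline is: segment → detect the electrostatic region → refine `Z1`
→ fit the exponential → compute indentation → fit the contact model.

* **Detection.** The onset `z_c` is the last upward crossing of a
  threshold `tau` by the smoothed force (default `3 * noise SD`, floored
  at 1e-6 nN so noise-free signals keep a finite onset). `Z0` and `Z1`
  are the consecutive breakpoints bracketing `z_c`; the next breakpoint
  initialises the Hertz-to-Hooke transition. An all-noise curve, or an
  onset collapsing onto the first sample, is reported as
  `no_electrostatic`.
* **`Z1` refinement.** Breakpoints localise `Z1` only to the nearest
  detected discontinuity, and the prefactor is biased by
  `exp(kappa * dz)` for an anchor error `dz` — a single sample spacing
  already costs several percent. `process_approach` therefore refines
  `Z1` continuously: over a fixed window around the onset, candidate
  anchors split the samples into an exponential branch and a
  Hertz-onset branch whose anchor force is the fitted `A` (continuity),
  and the total SSE is minimised by a grid-then-Brent search. The onset
  branch is evaluated by the *forward* model (solving
  `u = a (X - u/k_c)^2` analytically) so anchor errors propagate with
  unit gain rather than amplified by `1/k_c`. The refinement assumes
  `delta0 = 0` in its onset window; a genuinely nonzero offset shifts
  the anchor slightly and is re-estimated by the full contact fit. On
  noise-free curves the refined `Z1` is exact; it can be disabled with
  `refine_Z1 = FALSE` to obtain the raw breakpoint bracketing.
* **Exponential fit.** `A` is linear in the model (closed form, clipped
  to `[0, A_max]`, default `A_max` twice the window maximum); `kappa` is
  found by a deterministic log-spaced grid over `[1/200, 2] nm^-1`
  (Debye lengths 0.5–200 nm), augmented with the heuristic start
  `P'(Z1)/P(Z1)` from the smoothed polynomial, then Brent-refined. A
  fitted `A` at or below `tau` is indistinguishable from baseline noise
  and is reported as `no_electrostatic`. The fit window extends up to
  ~120 samples below `Z1` even when the detected `Z0` sits higher:
  `kappa` needs several Debye lengths of span.
* **Contact fit.** For fixed `(delta0, Delta1)` the model is linear in
  `(a, k_cell)`; the two-variable non-negative solve is closed-form
  (active sets). The outer 2-D search runs Nelder-Mead (relative
  tolerance 1e-14, restarted once) from the best of a small
  deterministic start set that includes the segmentation initialisation
  `(0, Delta1_init)` and the degenerate corner `(0, 0)` — the latter
  makes pure-Hooke data (no resolvable Hertz regime) exact. If the
  optimiser pushes `Delta1` onto the upper boundary no Hooke regime was
  seen and `k_cell` is flagged unreliable. Samples with
  `delta < delta0` are compared to the flat branch by default;
  `restrict_precontact = TRUE` excludes them instead.

### Known limitation

With a prefactor at or below the noise (A ≲ 3 sigma) the exponential
branch can imitate the early Hertz rise, and the refined `Z1` drifts
into the contact region on noisy curves; the measurability gate then
only catches clear cases. On noise-free curves the absence of an
electrostatic component is detected exactly.

## Retraction curves: FJC stretching and ruptures

Pulling the (functionalised) tip away stretches surface macromolecules;
each stretching event follows the Freely Jointed Chain extension
`x = Lc (coth(u) - 1/u)` with `u = F lk / (kB T)` (series `u/3 - u^3/45`
below `u = 1e-4` for stability), ending in a rupture jump. The analysis
is: segment (degree 1) → detect decreasing regions → fit each region →
assemble rupture statistics.

* **Region detection.** Candidate runs are the samples on which each
  interval polynomial strictly decreases (degree-2 intervals are split
  at the vertex). A run only counts as significant when its fitted drop
  exceeds twice the noise SD — flat baseline pieces whose fitted slope
  is negative by chance are neutral. Runs are chained across interval
  boundaries and short neutral gaps (up to 100 samples), because one
  pull spans several affine pieces, but never across an upward jump of
  the measured force (3-sample means on each side, threshold
  `4 * noise SD`): a rupture separates two events even when both sides
  decrease, as superposed pulls do. Each region is clipped to
  `z >= Zc + skip_nm` (default 100 nm — the first stretch past contact
  is dominated by non-specific adhesion), must keep at least
  `min_region_pts = 5` samples, and non-negative forces are trimmed at
  the attachment edge; if they reach deeper than 40% of the region the
  region is discarded as inconsistent with adhesive stretching.
* **FJC fit.** The residual is measured in extension:
  `sum ((z_i - Zc) - Lc g(|F_i|; lk))^2`, quadratic in `Lc` whose
  constrained minimiser (`Lc >= z_b - Zc`) is closed-form; `lk` is
  scanned on a log grid over `[1e-3, 5]` nm (including the small start
  0.01 nm that sits in the steep convex part of the cost valley) and
  Brent-refined. Because force noise maps into extension noise through
  `dx/dF = Lc g'(u) lk / kBT`, which varies by ~two orders of magnitude
  along a region, one Gauss–Markov reweighting pass (weights
  `1/(dx/dF)^2` from the first fit, dynamic range capped at 1e4)
  restores near-efficient estimates while keeping the problem quadratic
  in `Lc`; `reweight = FALSE` gives the plain unweighted fit.
* **Contact point.** `Zc` is taken from the paired approach fit's `Z1`
  when one exists; otherwise from the first positive-to-negative zero
  crossing of the smoothed force scanning from the contact end.
* **Statistics.** The rupture position of a region is its last sample;
  `deltaL` is the spacing between consecutive rupture positions;
  `n_ruptures = (number of regions) + 1`, the initial non-specific
  detachment counting as one; the last region supplies the
  last-adhesion-force and last-rupture-distance values used for maps.

## Whole images

`process_fvi_approach()` / `process_fvi_retract()` apply the per-curve
pipeline to every pixel sequentially with one shared configuration; no
state crosses pixels, so sub-grids reproduce the full grid exactly and
reruns are bit-identical. Topography is `max(Z1) - Z1` over the image.
Failed pixels are masked (NaN) in the maps; retraction pixels with no
detected region contribute zero adhesion (polymer absent or not
detectable). Histograms use Freedman–Diaconis binning. Outputs are plain
TSV matrices and tables plus a JSON metadata record.

## The synthetic benchmark

`simulate_approach_curve()` and `simulate_retract_curve()` evaluate the
same forward models the fitters assume and add i.i.d. Gaussian force
noise. Defaults reflect the targeted experiments: 2700 samples per
curve; a 10.4 pN/nm cantilever with a 35° conical tip; approach spans
(-1200, +300) nm around `Z1` (0.55 nm sampling, matching sub-nm
instrument resolution, with a flat far field for the 500-point
baseline); retraction spans (-40, +600) nm around `Zc`, the scale on
which rupture events are observed; reference truths A = 0.05 nN,
Debye length 10 nm, E = 1 MPa, k_cell = 0.1 N/m, Delta1 = 50 nm, and a
modal chain Lc = 312 nm, lk = 0.27 nm rupturing at 0.3 nN (mid-range of
typical adhesion forces, so the high-tension part of the extension curve
is exercised). The approach grid is aligned so `Z1` falls on a sample,
keeping ground truth free of discretisation bias. The contact branch is
generated in the indentation domain and mapped to `z` analytically; the
FJC force at a given extension is obtained by bracketed root-finding to
1e-10 nm.

`simulate_fvi()` provides two presets: `approach-demo` (a 300 nm
Gaussian dome of contact heights over uniform mechanical parameters,
noise-free so recovery is exact) and `retract-annulus` (single pulls
with randomised rupture force and contour length on a ring of pixels,
0.005 nN noise), both 8x8 by default, writing a manifest, curve files
and truth maps.

What passing the synthetic suite shows: the implementation inverts its
own forward models exactly in the noise-free limit and degrades
gracefully under Gaussian noise at realistic levels. What it does not
show: robustness to instrument artefacts absent from the generator —
drift and hysteresis, z jitter, correlated noise, virtual deflection,
tip-shape convolution, or molecules whose elasticity deviates from the
ideal FJC. Parameter maps from real data should always be read together
with the per-pixel status column and fit residuals.

## Problem sizes and runtimes

The test suite and the acceptance script use full-length curves (2700
samples) for single-curve checks, 100-replicate Monte-Carlo runs for
the noisy-recovery medians, and 8x8 images for spatial checks; smaller
grids and shorter curves are used for interface tests. On a single CPU
the whole suite runs in a few minutes; one approach curve takes ~0.2 s
and one retraction curve ~0.3 s end to end.
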