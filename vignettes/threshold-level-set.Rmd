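---
title: "Threshold-based level-set segmentation: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-based level-set segmentation: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneuseg)
```

## The segmentation problem

Contrast-enhanced CT angiography renders the blood pool of an artery and its
aneurysm as a bright, roughly homogeneous region against a darker background.
Extracting that region as a closed 3D surface is the first step of any
morphological or hemodynamic analysis, and the two classical tools both have
failure modes: region growing needs a seed point and a hand-picked intensity
window and leaks through blurred boundaries; the Chan-Vese region competition
needs no edges but knows nothing about them either, so its partition can drift
wherever the two-mean model prefers. The threshold-based level set (TLS)
implemented here combines the two sources of information in one speed
function and estimates its only data-dependent parameter — the intensity
threshold — from the image itself.

## The model

The surface is the zero level set of a scalar field $\phi$ (negative inside)
advected in its normal direction,
$\partial\phi/\partial t = F\,|\nabla\phi|$, with

$$F \;=\; \alpha\,(I - T)\;+\;\beta\,\operatorname{div}\!\Big(g\,
\frac{\nabla\phi}{|\nabla\phi|}\Big),
\qquad g(|\nabla I|) = \frac{1}{1 + c\,|\nabla I|^2}.$$

Where the image intensity $I$ exceeds the threshold $T$ the region term is
positive and the surface expands; below $T$ it contracts. With $\beta = 0$
the sign of $F$ is exactly the lower-threshold acceptance rule of region
growing; with $\alpha = 0$ what remains is the geodesic active contour term,
whose edge-stopping map $g$ falls from 1 in homogeneous tissue toward 0 on
strong gradients. Both reductions are verified in the test suite.

### Automatic threshold selection

The lumen is assumed brighter than its background. Writing
$(\mu_a, \sigma_a)$ and $(\mu_b, \sigma_b)$ for the two intensity
populations, Chebyshev's inequality bounds the mass beyond $k$ standard
deviations of any distribution, so $\mu_a - k\sigma_a$ is a defensible lower
confidence bound for lumen intensity and $\mu_b + k\sigma_b$ an upper bound
for the background. Equating the two — the lowest intensity the object can
reach is the highest the background can reach — and using one shared
multiplier gives

$$k = \frac{\mu_a - \mu_b}{\sigma_a + \sigma_b},
\qquad T = \mu_a - k\,\sigma_a = \mu_b + k\,\sigma_b .$$

The balance identity holds exactly by construction and is asserted in the
tests. A variant with $\sigma_a - \sigma_b$ in the denominator is exposed as
`kMode = "as-printed"` for comparison; it is singular when the two spreads
coincide and can be negative, so the sum form is the default
(`kMode = "balanced"`). When both spreads vanish (noise-free data) the
threshold degenerates to the midpoint $(\mu_a + \mu_b)/2$.

The pipeline (`segmentTLS`) is: (1) initialize $\phi$ as the signed distance
to a box inset 2 voxels from the ROI faces; (2) run a Chan-Vese
pre-segmentation to get a first mask; (3) alternate — statistics
$\rightarrow k \rightarrow T_i \rightarrow$ a block of TLS PDE steps
$\rightarrow$ new mask — until $|T_i - T_{i-1}|$ falls below a tolerance.
Both $k$ and $T$ are re-estimated every outer iteration: the estimator's
inputs improve as the mask improves, and on separable data the iteration
reaches its fixed point within a few rounds, so there is no advantage in
freezing $k$ at its initial value.

### Which voxels enter the statistics

Partial-volume voxels at the lumen boundary belong to neither intensity
population: their values sweep the whole range between the two means and
inflate $\sigma_a$ asymmetrically (the background, being much larger, is
barely affected). Because $T$ is the $\sigma$-weighted interpolation between
the means, an inflated $\sigma_a$ drags $T$ toward the background, the mask
dilates into the partial-volume shell, the statistics get worse, and the
update can run away — we observed exactly this divergence when the
foreground statistics were taken over the raw mask. The statistics therefore
exclude a one-voxel band on both sides of the interface: foreground = mask
eroded by one voxel, background = mask complement eroded by one voxel. With
the band excluded the fixed point sits near the intensity midpoint and the
iteration converges in a handful of outer iterations. The erosion falls back
to the raw regions when a mask is too thin to erode.

### The region of interest

All experiments run on a tight ROI around the target anatomy
(`autoRoi`: ground-truth bounding box plus a 6-voxel margin on phantoms,
standing in for the manually chosen crop on clinical data). This is not only
an economy: the threshold model's "background" is the ROI complement of the
object, and a compact ROI keeps that population local and homogeneous. It
also bounds the number of background voxels whose noise can exceed the
converged threshold. Isolated supra-threshold noise voxels are genuine
debris for any thresholded evolution: the region term holds them, and the
upwind gradient at an isolated extremum is zero, so once separated they
neither grow nor vanish. On whole 64³ grids with only ~4 % foreground this
left hundreds of one-voxel specks in the lowest-contrast case; within the
ROI protocol the effect is marginal at the default contrasts.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `alpha` | 10 | 1/HU | weight of the region term; dominates the speed on HU-scale data |
| `beta` | 3 | voxels | weight of the geodesic term; smooths and anchors to edges |
| `c` | 0.5 | (HU/voxel)⁻² | slope of $g$; the segmented volume is insensitive across 0.5–0.7 (asserted in the tests), the default is the lower end |
| `inset` | 2 | voxels | initial box retraction from the ROI faces |
| `tolT` | 0.5 | HU | stop when the threshold moves less than this |
| `maxOuter` | 30 | — | outer-iteration budget (convergence typically takes 3–6) |
| `innerSteps` | 25 | — | PDE steps per outer iteration; enough for a few voxels of interface travel |
| `smoothSigma` | 0.5 | voxels | Gaussian pre-smoothing for the gradient of $g$ only |
| CV `lambda1, lambda2` | 0.001 | 1/HU² | region-fit weights of the pre-segmentation |
| CV `beta` | 0.3 | voxels | curvature weight of the pre-segmentation |
| CV `nIter` | 2500 | — | step budget; the box-to-object sweep is slow while the interior mean is still background-dominated |
| CV `smoothSigma` (pre-seg) | 1 | voxels | the pre-segmentation runs on a smoothed copy; the standalone Chan-Vese segmenter defaults to the raw volume |

The pre-segmentation smoothing deserves a note: Chan-Vese compares each voxel
with two global means, so at low contrast-to-noise a noticeable fraction of
background noise sits closer to the foreground mean and the partition can
lock onto noise rather than anatomy. One voxel of smoothing removes that trap
without moving the boundary materially; the exact-recovery test (noise-free
two-phase image) runs unsmoothed and must recover the true partition voxel
for voxel.

## Numerical scheme

* **Discretization.** Explicit Euler in time. The advective (region) part of
  the speed multiplies the Godunov upwind gradient norm chosen by the sign of
  the local speed; curvature-derived parts (the $\beta$ term of both
  evolutions) multiply the central-difference norm. Upwinding a curvature
  term adds first-order dissipation — a shrinking-sphere experiment loses
  ~10 % of its radius to it, and the split scheme brings the closed-form law
  $R(t)^2 = R_0^2 - 4\beta t$ back within a few percent.
* **Time step.** $\Delta t = \min(0.45/\max|F|,\; 0.12/\beta_\text{eff})$:
  at most ~half a voxel of interface travel per step, plus a parabolic bound
  for the explicit curvature term.
* **Curvature.** $\kappa = \operatorname{div}(\nabla\phi/|\nabla\phi|)$ by the
  full second-derivative formula (equal to $2/R$ on a sphere),
  $\varepsilon$-regularized at $|\nabla\phi| < 10^{-8}$ and clamped to
  $\pm 1$ per voxel — curvature beyond the grid's resolution bound is noise.
* **Reinitialization.** Every 20 steps, by the relaxation PDE
  $\phi_t = \mathrm{sign}(\phi_0)(1 - |\nabla\phi|)$ with a subcell fix that
  pins interface-adjacent voxels to their interpolated distances in
  $\phi_0$. An exact-distance rebuild from the current mask would be simpler
  but quantizes the interface to voxel boundaries, erasing sub-voxel
  progress: any flow slower than half a voxel per reinitialization cycle
  stalls. The subcell scheme keeps the voxel partition bit-identical and the
  interface displacement well under half a voxel (both asserted in tests).
  Only a band of about ten voxels is restored to unit gradient; the far
  field is clamped to $\pm 6$ after each cycle, since an unbounded far field
  steepens exponentially under any persistent speed.
* **Stopping.** Chan-Vese stops when the inside/outside partition changes by
  fewer than 0.1 % of the voxels between reinitialization cycles, or at the
  step budget. The TLS outer loop stops on the threshold tolerance.
* **Boundary conditions.** One-sided differences at grid faces; no
  wraparound. Unit voxel spacing is assumed in all finite differences
  (physical spacing is carried as metadata; the validation metrics are
  reported in voxel units).
* **Degenerate inputs.** Empty or full masks, single-signed fields,
  non-positive thresholds multipliers and out-of-band thresholds all raise
  typed errors or clamp with a warning (out-of-band $T$ is pulled 5 % inside
  $(\mu_b, \mu_a)$ so the region term keeps a meaningful sign).

## The phantom generator

`makePhantom` builds a tubular parent artery (straight, or a circular arc),
a spherical aneurysm sac, and optionally a small bleb; the exact union of
the analytic solids, voxelized by the centre-inside rule, is the ground
truth. The volume is background intensity plus contrast times the
*blurred* shape indicator (Gaussian PSF, default 0.8 voxels, emulating CT
partial volume) plus white Gaussian noise (default 10 HU). Defaults — lumen
200 HU on a 100 HU background, artery radius 5 voxels, sac radius 10 at
roughly half-millimetre voxel scale — give contrast-CTA-like separation
that is not trivially separable after blur. `caseSuite` fixes four 64³
anatomies (straight + sac; curved artery + large sac; sac with a 4-voxel
bleb; small sac at 160 HU) that exercise the shapes segmentation methods
find hard.

What the phantoms do *not* emulate: spatially correlated reconstruction
noise, beam hardening and streaks, intensity inhomogeneity along the vessel,
surrounding structures (bone, veins) and vascular trees with branches.
Passing the suite therefore demonstrates correct mechanics and the method's
statistical behaviour under blur and noise, not clinical performance.

## Problem sizes

The validation suite runs at 64³ with ROI crops of roughly 50×30×40 voxels;
brute-force oracle comparisons (flood fill, all-pairs surface distances) use
8³–10³ grids where exhaustive computation is exact and cheap; closed-form
level-set checks use 32³. These sizes were chosen so the full suite
exercises every pipeline end to end in about a minute of CPU.

## Known limitations

* The converged threshold sits at the $\sigma$-weighted midpoint of the two
  populations, so the mask boundary lands where the blurred edge crosses
  that value — a fraction of a voxel outside the true surface when
  $\sigma_a > \sigma_b$. On thin vessels this is the dominant error term.
* Debris: isolated supra-threshold voxels survive the evolution (see above);
  at the default contrasts within an ROI this is rare, but heavily noised
  low-contrast data will produce speckle that a connected-component filter
  (`connectedComponents`) can remove if the application warrants it.
* Finite differences assume isotropic unit spacing; strongly anisotropic
  volumes should be resampled upstream.
* The Chan-Vese pre-segmentation is the slowest stage (a whole-box sweep);
  its budget, not the TLS iteration, bounds runtime.
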