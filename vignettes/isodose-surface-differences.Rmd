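---
title: "Comparing dose distributions by isodose surface shape"
author: "isodiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing dose distributions by isodose surface shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The method

Patient-specific QA compares a reference dose distribution against a
recalculated or measured one. The dominant tool, the gamma index, compresses
the comparison into a single passing rate and is known to conceal clinically
relevant discrepancies. `isodiff` implements an isodose-by-isodose
alternative: each isodose surface is treated as a 3D shape, reduced to a
shape signature, and compared against its counterpart, with acceptance
limits tied to the mechanical QA tolerance of the treatment machine rather
than to an arbitrary statistical band.

The pipeline, per evaluated isodose level $x$ (in percent of the maximum
dose):

1. **Surface extraction.** The isodose surface $is_x$ is the set of points
   receiving exactly $x\%$. We extract the marching-cubes vertex set: every
   crossing of the iso-value along a grid edge, positioned by linear
   interpolation. Sub-voxel geometry matters because the tolerance criterion
   is $\pm 1$ mm. A voxel-membership shell extractor is kept as an option
   (`method = "voxel"`) for sensitivity studies. Surfaces with fewer than 4
   points are rejected as missing: a histogram or median over 3 points is
   meaningless.
2. **Shape histogram.** Each surface point $p_x(n)$ is mapped to its
   Euclidean distance $d_x(n)$ from the plan isocenter. The histogram
   $his_x$ of these distances is the surface's signature. The bin count
   comes from Doane's formula,
   $\lceil 1 + \log_2 n + \log_2(1 + |g_1|/\sigma_{g_1}) \rceil$ with $g_1$
   the adjusted Fisher–Pearson sample skewness — appropriate because
   distance distributions of irregular surfaces are skewed. A floor of 4
   bins is applied; zero-spread samples collapse to a single flagged bin.
3. **Comparison.** Reference and evaluated distance samples are binned on
   shared edges (bin count from the *reference* sample, span covering the
   union of both samples) and compared with the Bray–Curtis dissimilarity
   $BC_x = \sum_i |e_i - r_i| / \sum_i (e_i + r_i)$, 0 for identical binned
   shapes, 1 for disjoint support. Counts are normalized to relative
   frequencies by default so unequal sample sizes do not masquerade as
   shape difference; raw-count mode is available.
4. **Tolerance band.** On the reference distribution alone, the equivalent
   sphere radius of every 1%-isodose volume yields a radius-vs-level curve;
   successive differences measure the local dose gradient. The level whose
   difference is closest to the midrange of these differences is the
   reference isodose ISOmr (ties break upward; a user override supports
   multi-target plans). Moving $\pm 1$ mm (the MLC QA tolerance) along the
   interpolated radius curve at ISOmr gives a fixed dose interval
   $(\delta_{low}, \delta_{up})$ that is applied at *every* level: the
   acceptance limits for level $x$ are
   $BC_{ISOup} = BC(his_{x+\delta_{up}}, his_x)$ and
   $BC_{ISOlow} = BC(his_{x-\delta_{low}}, his_x)$, both computed from the
   reference distribution. The fixed dose interval therefore expresses a
   *non-uniform* spatial criterion that adapts to the local gradient.
5. **Normalized ISD.** The signed, normalized deviation is
   $ISD\% = +100\, BC_x / BC_{ISOup}$ when the evaluated median distance is
   at least the reference one (the evaluated isodose sits farther from the
   isocenter: the plan is *hotter* there), and
   $-100\, BC_x / BC_{ISOlow}$ otherwise (*cooler*). Medians come from the
   raw distances, not the binned data, so the sign is free of binning
   artifacts. On the chart the tolerance lines sit at exactly $\pm 100\%$
   for every level; the asymmetric raw limits remain available
   (`plotRawTolerance()`). Levels above ISOmr form the PTV region, the rest
   Normal Tissue. The per-comparison summary is the mean absolute ISD.

The hotter branch is normalized by $BC_{ISOup}$ exactly as the defining
formula states, even though the hotter isodose geometrically resembles the
*lower* tolerance surface; `swapLimitPairing = TRUE` implements the
alternative pairing for sensitivity analysis. For a symmetric falloff the
two limits coincide and the choice is immaterial.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `spatialTol` | 1 mm | MLC QA tolerance mapped to the dose interval |
| `levels` | 10–100 step 5 | evaluated isodose levels (%) |
| `normalization` | `global_max` | percent scale: each grid's own maximum |
| `normalize` (BC) | `TRUE` | relative-frequency histograms |
| `isoMrOverride` | none | user ISOmr for multi-target or degenerate plans |
| gamma criteria | 3% / 2 mm / 10% cutoff / 95% | baseline gamma settings |

Percent normalization defaults to each distribution's own maximum because
isodose levels are defined up to $D_{max}$; `explicit_dose` normalization
(e.g. to a prescription dose) is exposed because verification practice
varies — values above 100% are then legal, and the grid class only
enforces non-negativity.

Fractional tolerance offsets are rounded to whole-percent isodoses for
histogram extraction, matching the 1% resolution of the radius curve. Where
the local gradient is steeper than 2 mm per percentage point the rounded
offset collapses onto the level itself; such levels are flagged unavailable
and dropped from the chart with a warning rather than given a fabricated
limit.

## The synthetic plan generator

Clinical plans cannot ship with the package, so every property is exercised
on generated fields with analytically known isodose geometry
(`makePlan()`): spheres, ellipsoids and two-lobe (dual-target analogue)
fields with linear, quadratic or sigmoid falloff on a 1 mm isotropic grid —
the grid resolution of a typical verification calculation. Defaults
(`r0 = 50` mm, `dMax = 2` Gy) are a prostate-like high-dose region and a
conventional fraction dose. Rigid shifts (`applyShift()`, tricubic
resampling, 1–10 mm) reproduce the delivery-error induction protocol used
to validate the method; `applyRotation()` and the generator's `orientation`
argument (analytic, resampling-free) exercise the rotation pre-flight.

Two generator properties deserve emphasis:

* **A perfectly centered sphere is degenerate.** All its isocentric
  distances are equal, the histogram collapses to a single bin, and any
  perturbation saturates $BC \approx 1$ immediately — the graded,
  monotone response to increasing shifts that clinical plans show cannot be
  reproduced in that geometry. The shift-sensitivity fixtures therefore
  offset the parametrization point from the dose centroid
  (`isocenterOffset = c(8, 0, 0)` for the `r0 = 25` mm sphere), which gives
  every isodose a realistic distance spread while keeping the point central
  in the distribution. This emulates the clinical situation (the isocenter
  is central but not coincident with the dose maximum) and is the
  documented study condition for those tests.
* **An exactly linear radial plan has a flat radius-difference curve**, so
  the midrange ISOmr selection is ill-posed on it (any level is equivalent;
  voxel noise decides). Where such a plan is used to verify the
  $\pm1$ mm $\to$ dose-interval mapping, ISOmr is pinned mid-range via
  `isoMrOverride = 50`; the derived interval is identical for any choice.

What the generator does *not* emulate: TPS beam models, heterogeneity,
measurement noise, multi-component disconnected isodoses of real IMRT
plans, or steep dose ridges. Passing tests demonstrate the method's
defining values and invariances, not clinical performance.

## Numerical choices

* Surface extraction uses edge-crossing interpolation (`(level - a)/(b - a)`
  along each grid axis); points are exact for fields linear along edges.
* Enclosed volumes are voxel counts of the $\ge$-level region; equivalent
  radii $(3V/4\pi)^{1/3}$ are clipped non-increasing (running minimum)
  before differencing so voxel noise cannot produce negative gradient
  estimates.
* The radius-vs-level curve is inverted piecewise-linearly; offsets hitting
  the curve ends raise an error naming the unreachable direction.
* The gamma baseline uses global normalization to the reference maximum,
  10% low-dose cutoff, a displacement search of radius 3 DTA sampled at
  DTA/10 with trilinear interpolation of the evaluated grid, and per-voxel
  early termination once the distance term alone exceeds the best gamma so
  far (offsets are scanned in order of increasing distance).
* Rigid transforms resample with Catmull–Rom tricubic interpolation,
  clipping negative overshoots to zero.
* Median ties (`medianEval == medianRef`) take the positive branch, per the
  defining formula's weak inequality.

## The rotation pre-flight and its limits

Distance histograms taken from the isocenter are invariant under any
rotation of the evaluated distribution about that point. The pre-flight
check recomputes the comparison at isodoses 50/75/80/90% from three random
non-coplanar probe points (drawn uniformly in the bounding box of the
reference 50% isodose; the probe tetrahedron must exceed 0.5% of the box
volume, because probes clustered near one line through the isocenter are
themselves blind to rotations about that line). Rotation is suspected when
some level shows $BC < \varepsilon$ at the isocenter but
$BC > \varepsilon$ at a probe.

Two honest limitations, measured on analytic rotations (no resampling
error):

* Two different voxel samplings of the *same* continuous surface do not
  give $BC = 0$: the floor is approximately $\sqrt{k/n}/2$ for $n$ surface
  points in $k$ bins — about 0.02–0.06 for the grids used here. The default
  $\varepsilon = 10^{-3}$ is therefore far below what 1 mm grids can
  attain, and at that setting the check cannot flag a rotation in
  practice; an $\varepsilon$ of about 0.07, above the measured floor, flips
  the verdict correctly for a clearly detectable (40°) rotation of a
  strongly anisotropic field. The parameter is exposed.
* Detection power is modest: Bray–Curtis between broad overlapping
  distributions responds weakly to moderate perturbations, so small-angle
  rotations (15°) of smooth fields sit near the sampling floor even from
  good probe positions.

## Problem sizes used in tests

Unit and property tests run on 45³–117³ grids (spheres with
`r0` = 20–50 mm); the tolerance-geometry and saturation checks use a
`r0` = 100 mm linear sphere on a 191³ grid, where the analytic mapping of
$\pm1$ mm is exactly $\pm1$ percentage point. These sizes keep the full
suite within a few minutes while leaving at least a factor 20 between the
falloff scale and the voxel size.

## Known limitations

* The chart reports *that* an isodose's shape deviates, not *where* on the
  surface the deviation sits.
* Limits collapse (and the level is dropped) where the gradient exceeds
  2 mm per percentage point, a consequence of whole-percent rounding.
* DICOM support covers axis-aligned RTDOSE grids (implicit/explicit VR
  little endian, uncompressed); RTDOSE stores no isocenter, so one must be
  supplied at load time.
* The gamma implementation is a baseline for context, not a certified QA
  engine.
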