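---
title: "Methods: phantoms, morphometry, micro-FE and bending mechanics in tibiamech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantoms, morphometry, micro-FE and bending mechanics in tibiamech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tibiamech)
```

tibiamech reimplements the computational core of a rodent tibial-loading
study as a reusable, tested pipeline. This vignette explains the models and
the numerical choices; the README shows the surface API.

## What the synthetic data emulate — and what they do not

No scan data ship with the package, so every pipeline stage is exercised on
synthetic inputs with *analytic* ground truth:

* **Geometric phantoms** (`generate_phantom()`): an annulus stands in for
  the cortical mid-shaft, plate and rod lattices for trabecular bone, a
  uniform block for calibration checks. A voxel is bone iff its centre lies
  inside the analytic solid (point sampling, not partial-volume), which
  makes the closed-form ground truth exact up to digitisation: the oracle is
  computed from the geometry, never from the voxelised image. Lattices are
  offset so every plate/rod is interior to the volume; only half-gaps touch
  the faces, keeping sphere-fitting free of edge bias.
* **A scaled whole tibia** (`generate_full_tibia()`): distal-to-proximal
  volume with a diaphyseal annulus, a tapering metaphyseal shell enclosing
  a trabecular plate lattice, a solid growth-plate disc (the landmark the
  VOI rules need), and two hydroxyapatite calibration inserts in the
  surrounding air. The default length is 10 mm — about a quarter of a real
  rat tibia — so that local-thickness mapping and the FE solve stay in the
  minutes range on one CPU; the scale and voxel size are ordinary knobs.
  The lattice keeps a 0.2-mm marrow clearance from the shell (so shell
  exclusion is well-posed) but touches the growth-plate disc, which keeps
  the whole bone one face-connected component for meshing.
* **Bending curves** (`generate_curve()`): bilinear loading (elastic slope
  k to the yield force, a post-yield slope to the ultimate force) followed
  by an abrupt fracture drop, sampled every 0.015 mm (0.15 mm/s crosshead,
  10 Hz acquisition), with seeded Gaussian force noise.
* **Longitudinal studies** (`generate_study()`): five groups (control,
  sham, three loaded) measured at 11/14/22/34/52 weeks; per-animal
  compound-symmetric correlation (default 0.6, a typical repeated-µCT
  value) and additive group effects expressed in SD units.

What the phantoms deliberately do **not** model: scanner physics (beam
hardening, rings, partial volume), biological remodeling, anisotropy and
curvature of real trabeculae, and marrow-grayscale texture. Passing tests
therefore demonstrate *algorithmic* correctness against known geometry and
statistics, not field performance on scanner data.

All generators are bit-reproducible under a fixed seed; noise is truncated
to the 8-bit range [0, 255].

## Calibration: two density maps, kept apart

The package carries two calibrations that must not be conflated:

* the **HU chain** HU = 18.278·g − 1000, ρ = 3.821e−3·HU − 0.062, feeding
  the quadratic modulus law E = 28.6·(ρ/1.762)² GPa used by the FE mesh;
* the **phantom map**, a two-point linear fit taking the mean grayscales of
  the 0.25 and 0.75 g/cm³ CaHA inserts to their nominal densities, used for
  BMD/TMD reporting.

They disagree by construction: grayscale 65 (the global segmentation
threshold) corresponds to 0.413 g/cm³ CaHA under the phantom map but to
≈ 0.657 g/cm³ under the HU chain. Both are kept as separate types and the
0.413 equivalence is stored as a constant, never derived. The threshold
comparison is inclusive (≥ 65), fixed so tests are bit-exact. The
displacement-for-age table (loading displacements at the 4/8/12-week
strain-gauge calibrations for 450/850/1250 µε) ships with configurable
placeholder values since the source prints no numbers; interpolation
between calibration ages is piecewise-linear with no extrapolation.

## VOI placement and shell exclusion

"0.35 mm distal to the growth plate" is read as moving from the growth
plate toward the diaphysis, into the secondary spongiosa; the trabecular
VOI then extends distally for 12 % of L (slice counts are rounded at the
voxel size). The cortical VOI spans 5 % of L centred at L/2 from the distal
bone end; an odd slice count puts the extra slice proximal. VOIs are
half-open slice ranges, and their derivation (offsets, spans, centre) is
recorded in the returned object.

The cortical-shell exclusion algorithm is our own design (the original
semiautomatic step is unpublished): per slice, the bone mask is closed with
a disc of radius 0.09 mm (≈ cortical pore scale; exposed as a parameter),
the marrow is the largest enclosed background component of the closed mask,
and trabecular bone is the original bone inside the marrow's filled hull.
Slices with no closed ring fall back to a 3D connected-component split with
a warning. On the synthetic tibia this recovers the generated lattice with
Dice 1.0; on real bone the closing radius is the parameter to revisit.

## Local thickness

Tb.Th and Tb.Sp use the model-independent definition: the value at a voxel
is the diameter of the largest sphere that contains it and fits in the
phase. The implementation computes an exact Euclidean distance transform
(Felzenszwalb–Huttenlocher, in C++), converts centre-to-centre distances to
centre-to-surface radii by subtracting half a voxel, and paints spheres in
decreasing radius order; a pure-R brute-force all-spheres oracle reproduces
the map exactly in the tests. Two conventions matter:

* **Borders.** `border = "ignore"` treats out-of-bounds as continuation of
  the structure (right for cropped VOIs and periodic phantoms);
  `"background"` ends the structure at the face. 2D inputs (single-slice
  arrays, used for Ct.Th) never pad across the plane.
* **Discretisation bias.** With sphere centres restricted to voxel centres,
  an aligned slab of *odd* voxel width measures exactly; an *even*-width
  slab reads one voxel thin. The phantom defaults therefore use odd-voxel
  plates and gaps; on unaligned geometry the bias is below one voxel and
  vanishes with resolution (tested at two voxel sizes).

## Cross-sectional geometry

Areas inside the periosteal and endocortical envelopes and their perimeters
come from marching-squares contours at the 0.5 level (`contourLines`). The
indicator field is first smoothed with a one-voxel Gaussian: raw binary
marching squares overestimates the perimeter of smooth shapes by ≈ 6 %
(staircase chamfer), while the level set of a smoothed step edge stays on
the edge, bringing a digitised circle's perimeter within 1 %. Areas are
unbiased to first order either way; bone area (Ct.Ar) is the voxel count,
so Tt.Ar ≈ Ct.Ar + Ma.Ar closes to < 1 % at 18 µm. Second moments are
summed over bone pixels (including each pixel's own a⁴/12 term, which makes
aligned rectangles exact); I_p = I_min + I_max holds identically. Because
the source does not define "mean eccentricity", we report the
ellipse-equivalent Ecc = √(1 − I_min/I_max) — an isolated, documented
choice. Tb.N likewise has no stated formula; we use the direct-model
convention Tb.N = (BV/TV)/Tb.Th, which reduces to 1/(thickness+gap) on a
plate lattice (the alternative 1/(Tb.Th+Tb.Sp) is redundant given the two
measured quantities). Sections with a broken ring are excluded per slice
(broken = a small closing re-creates an enclosed cavity; genuinely solid
sections are analysed with Ma.Ar = 0).

## Micro-FE

2×2×2 voxel blocks aggregate to cubic eight-node bricks (36 µm at native
18 µm). An element exists iff ≥ 4 of its 8 children are bone (majority
rule, configurable); its density is the mean of all eight children's
HU-chain densities, each child clamped to [0, ρ_max] *before* averaging —
clamping the mean instead would let air-grayscale children (negative
density) zero out boundary elements. Only the largest face-connected
component is meshed; marrow is not meshed. The element stiffness is the
standard trilinear brick with full 2×2×2 Gauss quadrature — symmetric, six
exact rigid-body modes, linear in E (so K(1) is cached and scaled).

Boundary conditions: the total force (default 35 N) is split equally over
the proximal-face nodes, directed −Z. The stated distal X/Y constraints
alone leave Z translation free, so the default adds full distal fixation
(standard micro-FE practice); a statically determinate variant
(`bc = "xy_plus_one_z"`) pins Z at one node instead. Note the equal split
is *not* a consistent uniform traction — verification tests that need an
exactly uniform state prescribe trapezoidal (¼/½/1) face weights instead.

The solver is Jacobi-preconditioned conjugate gradients on the eliminated
system, relative residual ≤ 1e−8 (tightening to 1e−10 moves VOI strain
summaries by < 0.5 %). Strains are evaluated from the shape-function
gradients at element centroids; principal strains are the sorted
eigenvalues, and VOI summaries report the mean maximum (tensile) and mean
|minimum| (compressive) principal strain in µε. Verification: exact affine
patch test on arbitrary uniform meshes, uniform uniaxial state to 1e−6,
series-compliance additivity to 1e−6 (run at ν ≈ 0, since with ν = 0.3 the
lateral-contraction mismatch at the interface is a real ~0.4 % 3D effect,
not an error), and linearity in load and modulus.

## Bending

Structural properties come from the curve: stiffness is the least-squares
slope over the ascending 20–80 % F_ult window, with one guard — if a
two-segment changepoint fit of that window finds a significantly better
description whose second slope is < 90 % of the first, the window straddled
the yield knee and the first segment's slope is used. (On a curve that is
linear through the window the guard never triggers; on a noiseless bilinear
curve it recovers the elastic slope exactly.) Yield is declared where the
5-sample local tangent drops below 90 % of k (offset criteria need strain,
which a force–displacement record lacks; the threshold is configurable) and
the returned point is refined by intersecting the elastic and post-knee
lines, which is exact on bilinear curves. Failure is the first post-peak
sample at ≤ 50 % F_ult. Works are trapezoidal integrals (N·mm = mJ).

Estimated tissue-level properties use Euler–Bernoulli identities with the
µCT section at the mid-diaphysis: E = kL³/48I, σ = FLc_max/4I,
resilience = σ_y²/2E, toughness = 0.75·W·b²/(L·I) — the parse of the
toughness formula that is dimensionally a stress and equals the beam-theory
identity 3Uc²/(LI) with c = b/2. Outer-fibre strains are reported
geometrically as ε = 12·c·d/L², which matches σ/E within 1 % at yield on an
ideal beam. Post-yield displacement is reported in mm (a µm reading for
values near 0.6 would be physically implausible for rat tibia). The yield
criterion, stiffness window and strain formulas are stated stand-ins —
configurable and excluded from any cross-study comparison.

## Statistics

`rm_anova()` is the classical split-plot decomposition (between-animal
stratum for the group effect, within-animal for time and interaction) via
`aov(value ~ group * week + Error(animal))`; a hand-computed
sum-of-squares oracle in the tests pins the decomposition to 1e−6. Animals
missing a timepoint are dropped listwise from the ANOVA but kept in the
per-timepoint Tukey–Kramer comparisons (`TukeyHSD`, unequal-n capable). No
sphericity correction is applied by default — the generator's compound
symmetry satisfies the assumption exactly — and a Greenhouse–Geisser flag
exists for real data. Calibration is verified by simulation: the omnibus
group test rejects at 0.05 ± 0.02 under the null (1000 replicates of the
default design), and a +2 SD group effect at n = 10 is detected by
Tukey-against-sham in ≥ 95 % of replicates. At a *single* timepoint the
analytic power of that comparison is only ≈ 0.94 (noncentral t against the
studentised-range critical value — the tests check the simulation against
this number), so the detection criterion reads a group effect the way the
study reports it: flagged at any analysed timepoint.

## Problem sizes and runtime

The shipped configurations are chosen so the whole verification runs on one
CPU in minutes: the tibia phantom at 36-µm voxels (≈ 4M voxels, ≈ 55k
elements, ≈ 220k unknowns, ~2700 PCG iterations), morphometry phantoms at
native 18 µm, 1000-replicate null simulations, 200-replicate power runs,
and 20 brute-force thickness cross-checks at 32³. All are configuration
knobs, not limits of the methods.

## Known limitations

* The shell-exclusion closing radius and the yield/stiffness settings are
  stand-ins for unpublished protocol steps; treat them as free parameters
  on real data.
* Perimeter estimates stop improving below ≈ 0.5 % error (level-set jitter
  does not average out along the contour), unlike areas and moments.
* The FE layer is linear-elastic with bone-only meshing: no contact at the
  loading platens, no marrow, no failure.
* BMD over a rectangular VOI slab includes extra-osseous air in the
  denominator; pass the compartment mask when the marrow-cavity convention
  is wanted.
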