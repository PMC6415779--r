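---
title: "Deformed alignment of SMLM ring structures: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformed alignment of SMLM ring structures: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-molecule localization microscopy (STORM/PALM) delivers, for each
imaged structure, a *molecule list*: the (x, y, z) coordinates of every
detected fluorophore, in nanometers.  Ring-shaped organelle-scale
assemblies — ciliary distal appendages, transition zones, centrioles,
nuclear pores — are prime targets for such imaging, but two properties
make naive averaging of many copies fail:

* **Under-labeling.** Only a fraction of the protein copies carry a
  working fluorophore, so single structures show an incomplete,
  asymmetric subset of the true arrangement.
* **Semi-flexibility.** The structures keep their symmetry and angular
  arrangement but vary in size and ellipticity from copy to copy (distal
  appendage rings span roughly 370–500 nm in diameter), so rigid
  registration smears the average radially.

`ringalign` implements a template-free averaging pipeline that treats
shape flexibility as an explicit degree of freedom: every structure is
*deformed to a common circle* before rigid registration, and for flat
structures tilted in 3D a tilt search replaces the deformation.

## The pipeline

### 1. Robust ellipse fit and circularization

Each structure's localizations are fitted to the general conic
$Ax^2 + Bxy + Cy^2 + Dx + Ey + F = 0$ under the ellipse constraint
$B^2 - 4AC < 0$, and the coefficients are converted to center
$(x_0, y_0)$, semi-axes $a \ge b$ and major-axis angle $\varphi$.  Note
the cross term $Bxy$: an axis-aligned conic cannot represent a rotated
ellipse, and the orientation angle is precisely what the deformation
needs, so the full six-coefficient conic is fitted.  Two estimators are
provided:

* `least_squares` — the direct constrained least-squares fit
  (Halir–Flusser's numerically stable formulation of the Fitzgibbon
  estimator), after centering and scaling the data for conditioning;
* `robust` (default) — an approximation to least-absolute-deviations on
  the algebraic residuals, realized as iteratively reweighted least
  squares around the same constrained solver (weights $1/|r_i|$, at most
  50 passes, convergence at $10^{-8}$ relative coefficient change).
  Localization data contain stray background localizations, and the LAD
  loss keeps them from twisting the fitted orientation.

Outliers are then trimmed: each point's *radial residual* — its distance
from the ellipse center minus the ellipse radius at its polar angle — is
computed, and points deviating more than $k = 1.5$ standard deviations
from the mean residual are removed (under Gaussian radial noise this
retains ≈ 86.6 % of points).  The algebraic residual or the distance to
the centroid would have been alternatives; the radial residual was
chosen because it is expressed in nanometers along the direction in
which a ring has physical thickness.  The fit–clean–refit cycle runs
once: fit on all points, trim, refit on the survivors.

With the cohort's average radius $R$ (mean of $(a+b)/2$ over
structures), each structure is centered, de-rotated by $-\varphi$, and
scaled by $R/a$ in x and $R/b$ in y:
$x_{circ} = x/a \cdot R$, $y_{circ} = y/b \cdot R$.  After this every
structure is a ring of radius $R$ and only the rigid degrees of freedom
remain.

### 2. Rendering

Registration happens in the pixel domain, so molecule lists are rendered:
a 2D histogram on a square grid followed by Gaussian smoothing.  The
defaults are a 10 nm pixel and a 640 nm field; the smoothing SD should be
set to about the localization precision of the data.  For registration
*discriminability*, the useful rule of thumb established on synthetic
data is: pixel size at or below the localization SD, smoothing SD about
equal to it.  With 18-cluster structures whose neighboring clusters sit
39 nm apart, registering 10 nm/15 nm renderings leaves a ±6° rotational
ambiguity, while 5 nm/6 nm renderings align to ≈ 0.4° — the rendering,
not the correlation machinery, sets the angular accuracy.

### 3. Rotation + subpixel translation registration

For a moving image $g$ and reference $f$, the quality metric is the
normalized root-mean-square error

$$E^2 = \min_{\alpha, x_0, y_0, \theta}
\frac{\sum_{x,y} |\alpha\, g_\theta(x-x_0, y-y_0) - f(x,y)|^2}
     {\sum_{x,y}|f(x,y)|^2},$$

whose minimization over the transform is equivalent to maximizing the
cross-correlation $r_{fg} = \sum F\,G_\theta^* e^{i2\pi(u x_0/M + v
y_0/N)}$; $\alpha$ has a closed-form optimum and is reported alongside.
The search is exhaustive in rotation and Fourier-based in translation:

* the moving image is rotated through 0–359° in 1° steps (bilinear
  interpolation about the raster center);
* at each angle, the integer-pixel correlation peak is found by FFT;
* the angle with the highest peak wins (exact ties break toward the
  smallest angle), and the translation at that angle is refined on a
  ±0.75 px neighborhood sampled at 1/100 px by a matrix-multiply DFT.

No sub-grid angle refinement is attempted: angular resolution stays at
the grid step.  Before the FFT both images are mean-subtracted and
tapered with a raised-cosine window over the outer 5 % of pixels
(disableable with `taper = FALSE`) to suppress wrap-around artifacts;
for registration of deliberately circularly-shifted test images the
taper should be off.  Rotation convention: `theta` rotates coordinates
by `[cos θ, −sin θ; sin θ, cos θ]` in the (x, y) frame in which y grows
with the row index; visually (y plotted upward) this is clockwise.

### 4. Template-free iteration

To avoid template bias, the first reference is the plain average of all
input images.  Each iteration registers every *original* image to the
current reference (so interpolation errors never accumulate) and the
average of the aligned images becomes the next reference; 10 iterations
are the 2D default, 5 in 3D.  The mean per-image NRMSE is non-increasing
across iterations up to interpolation noise.  An early-stop test (max
transform change < 0.01 px and < 1 angle step) is available but off by
default — the fixed iteration count makes runs exactly reproducible.
After the last iteration the accumulated transforms — deformation, tilt,
rotation, shift — are applied to the *coordinates*, so the output is
again a molecule list at full precision, and the reference is never
re-centered globally between iterations.

### 5. 3D: tilt search instead of deformation

A flat structure tilted out of plane projects as an ellipse, which is a
shape change the deformation step must *not* absorb (it is orientation,
not flexibility).  The 3D mode therefore skips circularization and adds
one exhaustive loop: rotation about the x axis by $\varphi$ over a preset
grid (default ±90° in 2° steps), applied about the structure centroid,
with the 2D (θ, shift) search run on the x–y projection at each trial
tilt.  By Euler's rotation theorem a y-axis tilt of a flat structure is
reachable as a z-rotation, an x-tilt and another z-rotation, so the
(φ, θ) grid covers all orientations of flat structures.  The projection
of a flat ring is invariant under φ → −φ, so recovered tilts are
identifiable up to sign; grid-boundary hits are flagged in the report.
Tilt discrimination rides on the few-nanometer y-compression of the
projected ring (the compression changes by about r·sin(φ)·Δφ per tilt
increment Δφ at ring radius r), so projections should be rendered with
*light* smoothing (well below the localization precision) when tilt
precision matters.
The z coordinate rides along through every transform and is written out,
but the registration objective only ever sees the x–y projection.

### 6. Multicolor transfer

Channels of one structure share a coordinate frame, so aligning one
channel aligns them all: the user designates a reference channel
(conventionally the one with higher resolution — this is a required
argument, not auto-detected), the pipeline aligns it, and each
structure's full transform (including the deformation scales in 2D mode,
fitted on the reference channel only) is applied verbatim to the other
channels.  Inter-channel geometry is untouched in 3D mode and scaled
exactly by the shared deformation in 2D mode.  Any number of channels is
supported.

## Quality metrics

**Rotational autocorrelation.**  The averaged image is resampled once
onto a polar grid over its inscribed disk; rotation then becomes an
integer circular shift along the angle axis, computed for all angles at
once by FFT.  The older alternative — rotating the raster for every
angle — carries an angle-dependent interpolation loss (exact at 0°, 90°,
180°, maximal near 45°) of order 1 %, which is *larger* than the real
height differences between symmetry peaks and silently biases the
dominant-peak angle; the polar form makes every angle suffer identical
interpolation.  Peaks are local maxima in (0°, 180°] above a 5 %
prominence floor.  An N-fold ring peaks at multiples of 360°/N.  Note a
statistical caveat: for a cohort of, say, 20 under-labeled rings, the
peak *heights* at the different symmetry multiples agree to within the
cluster-occupancy sampling noise, so which multiple is the tallest is
substantially a draw; the presence and location of the peaks, not the
argmax identity, is the robust readout.

**Fourier ring correlation.**  The pooled aligned localizations are
randomly halved, each half is rendered as an unsmoothed 5 nm histogram,
and the two Fourier transforms are correlated ring by ring; the
resolution is read where the (3-point smoothed) curve first drops below
1/7.  Frame numbers are not part of the data model, so the split is per
localization; the split is repeated (default 20×) and the SD over splits
is the reported uncertainty.  Smoothed rendering must not be used here —
it inflates low-frequency correlation and flatters the resolution.

## The simulator

`simulate_structures()` generates cohorts of ring structures: cluster
centers at configurable angles on one or more rings (per-channel
diameter, angular offset, z offset), labeling dropout (an exact count or
an independent per-cluster probability; structures that would lose every
cluster are redrawn), Poisson localization counts per cluster (mean 50
by default), optional intrinsic cluster spread, an area-preserving
random aspect stretch for semi-flexible 2D cohorts, uniform in-plane
rotation, bounded uniform tilt about x (two-sided: within ±range),
Gaussian translation jitter (SD 20 nm), and finally Gaussian
localization noise — lateral SD on x and y, axial SD on z, applied after
the geometric transforms because localization error lives in the imaging
frame.  Ground-truth transforms and occupancies are recorded for every
structure, and a seed makes cohorts bit-for-bit reproducible.

One interpretation choice deserves emphasis: the preset protocols
(`sim_preset()`) quote localization precision values of 15, 30 and
60 nm that originate from experiments reporting precision as a FWHM.
Treating them as Gaussian SDs makes the corresponding published outcomes
geometrically impossible — with SD = 15 nm at ring radius 150 nm the
cluster angular width is 5.7°, so autocorrelation features are ≈ 8°
wide and can never show separate 15° and 25° peaks; with SD = 60 nm the
ninefold Fourier amplitude of a single structure is
$e^{-m^2\sigma^2/2r^2} \approx 0.15\,\%$ at $m = 9$ and rotational
alignment cannot lock at all.  With SD = value/2.355 every published
behavior is reproduced (separate 15°/25°/40° peaks; the 60 nm cohort
aligns with ≈ 2° residual).  The presets therefore store value/2.355 in
the `precision_lateral`/`precision_axial` fields, which are defined as
SDs.  What the simulator does *not* model: fluorophore photophysics
(blinking, repeated localizations of one emitter), background
localizations, and camera noise — so passing tests demonstrate correct
geometry recovery under idealized Gaussian localization error, not
robustness to those real-data effects.

## Numerical choices and degenerate inputs

* Even image dimensions ≥ 8 are enforced (simple Fourier frequency
  indexing); the field size is rounded to an even pixel count.
* Correlation ties: smallest angle first, then the first peak in
  column-major scan order; tilt ties toward the smallest |φ|.
* A labeled cluster emits at least one localization (a Poisson zero is
  promoted to 1), so "5 labeled clusters" means five visible ones.
* Ellipse fits reject < 6 points, collinear sets, and non-ellipse
  conics with an error naming the structure; outlier trimming refuses to
  leave fewer than 6 points; the 2D pipeline drops structures whose fit
  fails (with a warning) and aborts only when fewer than 2 survive.
* Transform inversion in the fixed composition order exists whenever a
  transform does not combine anisotropic scaling with a tilt — true for
  every transform the pipelines emit.
* The FFT hot loop (per-angle rotate–correlate) is C++ via
  RcppArmadillo with FFTW3 providing the transforms.

## Problem sizes used by the test-suite

The shipped tests exercise the full protocols at their native sizes (20
structures, 10/5 iterations) where feasible and scaled-down cohorts
(8–12 structures, 2–3 iterations, coarser tilt grids) for the
combinatorially heavier 3D and replicate-based property checks; the
methods are linear in the number of structures, so the scaled runs probe
the same code paths.  Monte-Carlo oracles (ellipse parameter recovery,
robust-vs-LS contamination contests) use 60 paired replicates.

## Known limitations

* Deformation is global anisotropic scaling — no local warps; strongly
  bent or locally dented rings are out of model.
* Structures are treated as rigid in 3D; out-of-plane bending is not
  corrected.
* The tilt of a flat ring is recovered up to sign, and tilts outside the
  preset grid alias onto its boundary (flagged in the report).  The
  cohort-level tilt gauge is also degenerate: a residual tilt common to
  all structures leaves every projection equally self-consistent, so
  template-free 3D alignment fixes relative tilts (the net out-of-plane
  angle is shared across the cohort to a few degrees) but not the
  absolute plane.
* The FRC variant (random localization halving, 1/7 threshold, 3-point
  smoothing) is one of several in use; absolute resolutions can shift by
  a few nm across variants, comparisons within one variant are stable.
* Chromatic aberration between channels is assumed corrected upstream.
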