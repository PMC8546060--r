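---
title: "Quantifying contraction and myofibrillar structure in micropatterned cardiac muscle bundles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying contraction and myofibrillar structure in micropatterned cardiac muscle bundles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbkit)
```

## The system and the measurement problem

Micron-scale two-dimensional cardiac muscle bundles (2DMBs) are rectangular
multicellular strips of purified human pluripotent stem cell-derived
cardiomyocytes, patterned at a 7:1 aspect ratio (308 x 45 um) on soft
(8 kPa) PDMS so that myofibrils align with the long axis and the tissue
contracts uniaxially against a compliant elastic load (auxotonic
contraction). The platform's analytical questions are:

1. How much does a bundle shorten per beat, and with what velocity,
   acceleration and relaxation kinetics? (brightfield movies, no
   fluorescent reporter)
2. How well organized are its sarcomeres? (striation-marker images:
   per-unit resting length and the dispersion sigma of unit orientations)
3. How densely packed are its myofibrillar bundles? (F-actin images:
   area fraction and heterogeneity)
4. Are neighbouring bundles on one substrate mechanically independent, and
   how do substrate thickness, tissue modulus and ROI placement affect the
   shortening readout? (elastic model)

`mbkit` implements all four, plus seeded synthetic-data generators with
exact ground truth so that every algorithm is testable without microscope
data, and the reproducibility/power statistics used to compare assay
designs.

Conventions: pixel indices are 0-based, `(x, y)` = (column, row), origin
at the top-left, `y` increasing downward; units are micrometres, seconds
and kilopascals throughout.

## Displacement tracking

`track_roi()` tracks a template region of interest (ROI) through the movie
by zero-normalized cross-correlation (ZNCC): template and candidate patch
are mean-subtracted and variance-normalized, which removes sensitivity to
the slow illumination drift typical of brightfield time series. The two
ROIs are placed on the long axis at +/- L/4 from the centre
(`place_rois_inner50()`), so their separation spans the inner 50% of the
bundle length -- the placement the substrate model shows to be least
sensitive to positioning error (see below).

The integer-pixel displacement is the ZNCC argmax within
`+/- search_radius`; the FFT-accelerated evaluation is verified in the
test suite to agree exactly with an exhaustive spatial-domain argmax.
Subpixel refinement fits a least-squares paraboloid to the 3x3
correlation neighbourhood around the peak and takes its vertex, clamped
to +/- 0.5 px. We use the 9-sample paraboloid rather than two separable
3-point parabolas because both cost the same and the paraboloid is
markedly more robust to noise on the shallow ridge of a band-limited
texture's autocorrelation: on the synthetic benchmark (SNR 10) the
separable fit occasionally exceeded 0.2 px error in the quiet axis while
the paraboloid stays within 0.1 px. Peaks on the search border are
flagged (radius too small), and an exact match (correlation 1) skips
refinement, since the vertex of the texture autocorrelation need not lie
on the sample.

Quality control (`qc_trace()`) rejects a tracked pair when any frame's
peak correlation falls below 0.5, when the median symmetrical motion
index over contraction frames exceeds 0.5, or when transverse
displacement exceeds half the axial. The symmetrical motion index at a
frame is `|a_p + a_d| / (|a_p| + |a_d|)` for the two ROIs' axial
displacement components: 0 for equal-and-opposite (pure contraction), 1
for common-mode translation. Two numerical details matter. First, frames
whose total axial motion is below an absolute noise floor (0.05 um) carry
no information and are excluded. Second, the median is taken only over
contraction frames -- frames whose total motion also exceeds 25% of the
record's maximum -- because the template's own noise realization induces a
small *constant* position bias per ROI (of order 0.1 px), and on quiescent
frames that bias is the whole signal: it is equal-signed often enough to
masquerade as common-mode motion in low-amplitude recordings. Genuinely
rigid recordings still fail, because their high-motion frames are
common-mode.

## Fractional shortening and beat kinetics

The instantaneous inter-ROI length is `L(t) = L_sep + a_d(t) - a_p(t)`;
the resting length `L0` is the 90th percentile of `L(t)` (contraction only
shortens, so the baseline is the upper tail, robust to noise spikes), and
fractional shortening is `fs = (L0 - L)/L0`.

`segment_and_merge()` detects beats as `fs` peaks with topographic
prominence of at least 50% of the global maximum and at least 0.3 s apart,
windows each beat between the adjacent inter-beat valleys, aligns beats on
the interpolated upstroke crossing of half-maximum (more stable for
contraction-limb averaging than aligning on the peak itself), and
interpolates them onto a common grid. The merged beat is the pointwise
mean with a 95% band (mean +/- 1.96 SEM). Beat frequency is
`(n_beats - 1)` over the span of peak times.

`extract_kinetics()` computes, on the merged beat:

* `max_fs` -- peak fractional shortening (also as %).
* `v_con_20/50/80`, `v_rel_80/50/20` -- |d(fs)/dt| interpolated at the
  times `fs` first (contraction) or last (relaxation) crosses 20/50/80% of
  `max_fs`. Velocities are normalized (s^-1, strain rate), which makes
  them geometry-independent; multiply by `L0` for um/s.
* `peak_acceleration` -- maximum second derivative on the contraction limb.
* `deceleration_time` -- time from deviation from the linear contractile
  slope to the fs peak. The linear slope is fit where `fs` is between 30%
  and 70% of maximum; the onset is the first time after the velocity peak
  that velocity drops below 90% of that slope (tolerance configurable).
* `relaxation_time` -- fs peak to 90% recovery toward baseline
  (endpoint configurable), with the crossing linearly interpolated.

Derivatives use Savitzky-Golay smoothing (default window 7 frames, order
3, configurable and recorded) followed by centred differences; the
acceleration uses the compact 3-point second difference rather than two
nested first differences, because the wider nested stencil smears the
acceleration discontinuity at contraction onset and underestimates the
peak by ~5% at 50 frames/s. On the closed-form raised-cosine beat
(FS 5%, 0.5 s limbs, 50 fps) the velocities at 20/50/80% match
0.1257/0.1571/0.1257 s^-1 within 2% and peak acceleration matches
0.987 s^-2 within 5%; the test suite pins these.

Per-beat standard deviations come from running the identical extraction
on each aligned beat. `drug_response()` forms per-parameter paired fold
changes (after/before), flagging undefined baselines instead of emitting
infinities.

## Sarcomere structure

`segment_sarcomere_units()` segments striation bands from a
striation-marker image (MyBP-C, alpha-actinin) with a
difference-of-Gaussians band-pass tuned to periods of 1.2-3.5 um,
thresholds the response at 0.5 SD, labels connected components, and pairs
adjacent bands into sarcomere units. Pairing requires (i) band axes
parallel within 15 degrees, (ii) centroid separation *projected onto the
common myofibril axis* inside the 1.2-3.5 um detection band, and (iii) a
transverse offset below 4 um. Three estimator choices deserve note:

* **Per-band orientation comes from the gradient structure tensor summed
  over the band's own pixels**, not from blob moments: bands clipped by
  myofibril boundaries are sheared parallelograms whose principal axes are
  biased along the clip edge, while the striation gradient direction is
  exactly the myofibril axis.
* **Unit length is the projected centroid spacing.** Raw centroid
  separations of clipped bands run along the clip edge
  (`spacing / cos(theta)`), so projecting onto the axis removes a bias
  that grows quadratically with the orientation angle.
* **Pixels near myofibril ends are excluded from the tensor** (an eroded
  striation-energy mask): cut edges contribute gradients along the cut
  and would bias edge-band orientations by a degree or more. The
  anisotropic angle distortion of the discrete central-difference
  gradient (components `sin(k cos t), sin(k sin t)` instead of
  `k cos t, k sin t`) is inverted analytically per unit.

`fit_orientation_sigma()` reports the dispersion sigma of unit
orientations. Angles are axial (theta and theta+180 coincide), so the
circular mean is taken on doubled angles and deviations are unwrapped
about it before fitting -- distributions straddling +/-90 degrees are
handled correctly. The default fit is a least-squares Gaussian to the
binned histogram (bin width 2 degrees, refined automatically when the
dispersion approaches the bin width), with Poisson-motivated weights
(1/count): unweighted least squares lets the tall peak bins dominate and
inflates sigma by several percent on real, clustered unit data. A direct
standard-deviation estimate (`method = "direct"`) is also available; the
histogram fit is the default reporting route. Fits with fewer than 30
units are refused as unstable.

## Myofibrillar density

`extract_bundle_peaks()` rotates the F-actin image into the bundle frame,
averages intensity along the axis in 10 um axial windows, subtracts a
rolling-minimum background (12 um window), and detects transverse peaks
with prominence at least 20% of the profile range. Each peak's width is
measured at half *prominence* (not half maximum), which is robust to
uneven baselines between adjacent bundles; for a symmetric smoothed
stripe this width equals the underlying stripe width.
`compute_density()` reports the per-window covered fraction (summed
widths over tissue width), the area fraction (mean over windows) and the
heterogeneity (CV across windows). The original peak/width criteria of
the upstream MyoQuant implementation are not published in detail; the
defaults above are this package's declared surrogates, and all thresholds
are arguments.

## Substrate mechanics

`layer_model()` + `solve_displacement_field()` implement a quasi-static
linear-elastic surrogate for the full (unpublished) layered model: a thin
elastic strip (default 8 um thick, 8-12 kPa) with an imposed axial
contractile eigenstrain, coupled by shear lag to the surface of an
elastomer layer (default 8 kPa, nu = 0.49, 70 um) bonded to rigid glass.
The substrate surface response to tangential traction is the
Boussinesq-Cerruti half-space Green's function attenuated by a
finite-thickness factor `1/(1 + (r/h)^3)`, which recovers the half space
as `h` grows and the local Winkler-like (`u ~ tau h/E`) response of a
thin bonded layer as `h` shrinks. This captures the *qualitative*
thickness scaling and the suppression of long-range transmission; it is
not the exact layered kernel, and the package asserts only qualitative
claims about thickness effects.

The tissue couples to the surface through an explicit adhesion compliance
(`adhesion_stiffness`, default 0.015 kPa/um): tissue displacement equals
surface displacement plus traction/Y, as in standard cell-monolayer
shear-lag models. This term is physically necessary here: with a rigid
bond and the stated moduli the shear-lag length would be ~20 um, pinning
the bundle interior and concentrating all strain at the free ends --
contradicting the experimentally observed distributed interior
shortening that makes inner-50% ROI tracking meaningful in the first
place. The default places the coupling length
`sqrt(E_t t / Y)` at roughly a quarter of the bundle length; `Y = Inf`
recovers the rigid bond. The coupled system is linear and solved
directly, with an explicit self-consistency residual check (an error with
the residual is raised if it fails).

Derived analyses:

* `neighbor_coupling()` -- max surface displacement on the buffer edge
  facing a neighbour (offset by the gap, spanning the tissue footprint)
  over max displacement under the tissue. At the standard layout
  (240 um long-axis, 80 um short-axis gaps) the metric is below 0.01 and
  0.04 respectively -- the model's operationalization of "minimal force
  transmission"; the threshold 0.1 used in tests is this package's
  choice, as no number is published.
* `thickness_decoupling_sweep()` -- normalized max-norm deviation of the
  surface field from the half-space (h -> infinity) solution; it decays
  monotonically and flattens above several tens of micrometres. The
  published "40 um" decoupling threshold depends on an unpublished
  criterion, so the sweep exposes the whole curve and the tests assert
  monotonicity and plateau behaviour only.
* `fs_force_curve()` -- realized shortening vs width-normalized force,
  and the relative spread of force at fixed shortening across tissue
  moduli of 8-12 kPa (about 9% with the defaults: "minor").
* `roi_placement_sensitivity()` -- error of the ROI-pair shortening
  estimate vs the end-to-end tissue strain as a function of span. Spans
  near 50% of the length sit on the flat interior of the strain profile;
  the placement gradient there is several-fold smaller than at 80-90%
  spans, reproducing the design rationale for inner-50% ROI placement.

Forces are reported in uN and uN/mm of bundle width. Because the model is
a deliberately reduced surrogate (1-D tissue, approximate kernel, linear
constitutive law), its absolute force scale is not calibrated to
experimental traction values and no quantitative force comparison is
asserted anywhere.

## Synthetic data

`gen_contraction_movie()` renders a band-limited random texture (Gaussian
blurred white noise, correlation length 2 um) confined to the bundle
rectangle and warps it per frame with the uniform-axial-strain field
`u_x = -eps(t) (x - x_c)` (plus optional drift and common-mode
translation), resampling with a 6-tap Lanczos-3 kernel via a sparse
operator. Because the strain is uniform, the separation change of any two
material points is *analytically* `eps(t)` -- tracking tests inherit exact
ground truth rather than a numerically tracked one. Defaults emulate the
acquisition and biology of the platform: 0.4 Hz spontaneous beating,
raised-cosine limbs of 0.5/0.7 s, 5% peak shortening, 50 frames/s, and
additive Gaussian noise at 5% of texture contrast. Movies are generated
at 0.4875 um/px (a 3x binning of the 0.1625 um/px 40x-objective pitch)
over the tissue plus tracking margins; this is the package's standard
problem size for full-length (20 s, 1000-frame) recordings and leaves
tracking errors far below the shortening signal at all tested
amplitudes.

`gen_monolayer_movie()` tiles the field with independent texture domains
contracting along random directions with random amplitudes and phases -- a
surrogate for nonpatterned monolayers. It is deliberately *not* a
biophysical monolayer model; it exists to demonstrate that the pipeline's
across-ROI variability is far higher on disorganized motion than on an
organized bundle, the qualitative contrast the platform was designed to
remove. The published experimental means for bundles vs monolayers are
real-data results and are not reproduced numerically.

`gen_structure_image()` renders either striation images -- a grid of
myofibril segments (4 um across, 8 um long, separated by 3.6 um axial
gaps so segments are never paired across boundaries) each carrying a
cosine grating at its own orientation drawn from N(mu, sigma) -- or
F-actin bundle images (axial stripes of stated width/gap with 0.3 um
smoothed edges). All generators are pure functions of (truth, seed):
identical inputs give bit-identical outputs, and the caller's RNG state
is untouched.

What passing tests on these fixtures do **not** show: robustness to
optical point-spread blur, shot noise, photobleaching, focus drift,
overlapping/branching myofibrils, or non-uniform illumination. The
generators are ground-truth benchmarks, not photorealistic simulators.

## Assay statistics

`coefficient_of_variation()`, `percent_reduction()` and `fold_ratio()`
are the replicate-variability arithmetic used in platform comparisons.
`two_group_sample_size()` uses the normal-approximation two-sample
formula `n = 2 (z_{1-a/2} + z_{1-b})^2 (CV/delta)^2` with
nearest-integer rounding by default; with CV 0.21, a 20% difference,
alpha 0.05 and power 0.9 it gives 23 per group (23.17 before rounding).
A ceiling mode and an iterative t-quantile correction are available for
conservative planning. Known limitation: the published monolayer sample
size of 205 is not reproducible from the published monolayer CV of 1.58
with this (or any CV-based normal) formula, which gives ~1300; the
inputs behind that figure are not published, so the package makes no
attempt to reproduce it.

## Problem sizes used in the test suite

The suite regenerates everything it tests: 20 s, 1000-frame movies at
five shortening amplitudes for end-to-end recovery; 50 seeded stacks for
the FFT-vs-exhaustive tracking oracle; three seeded striation images per
sigma level for orientation recovery; and the default 2 um substrate
node spacing with 4 um field grids for the mechanics properties. These
sizes were chosen so the full suite regenerates all data in a few
minutes while keeping every tolerance comfortably resolvable.

## A worked example

```{r example, fig.width = 6, fig.height = 4}
mov <- gen_contraction_movie(contraction_truth(fs_max = 0.05),
                             duration = 10, seed = 1)
rois <- place_rois_inner50(mov$geometry, mov$stack$pixel_size,
                           frame_dim = dim(mov$stack)[1:2])
prox <- track_roi(mov$stack, rois$proximal,
                  tracking_params(search_radius = 12))
dist <- track_roi(mov$stack, rois$distal,
                  tracking_params(search_radius = 12))
qc_trace(prox, dist)$accept
beats <- segment_and_merge(build_waveform(prox, dist))
plot(beats)
extract_kinetics(beats)
```
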