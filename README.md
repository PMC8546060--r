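# mbkit

Contractile kinetics and myofibrillar structure quantification for
micron-scale two-dimensional cardiac muscle bundles (2DMBs) — rectangular
(308 × 45 µm, 7:1) strips of purified hPSC-derived cardiomyocytes
micropatterned on soft (8 kPa) PDMS that contract uniaxially against a
compliant elastic load.

The package is aimed at labs running (or modelling) micropatterned
cardiomyocyte contractility assays. It provides the complete desk
workflow:

* **ROI tracking** — subpixel displacement of template regions of interest
  through brightfield movies by zero-normalized cross-correlation
  (FFT-accelerated, with an exhaustive spatial-domain oracle), with
  paraboloid subpixel refinement and tracking QC (`track_roi()`,
  `qc_trace()`).
* **Contraction kinetics** — fractional shortening `fs = (L₀ − L)/L₀` from
  an ROI pair spanning the inner 50% of the bundle length; beat
  segmentation, upstroke alignment and merging with 95% bands; and the
  standard parameter set: max FS, normalized contraction/relaxation
  velocities at 20/50/80% of peak shortening (s⁻¹), peak acceleration
  (s⁻²), deceleration time (deviation from the linear contractile slope to
  the fs peak) and relaxation time (`build_waveform()`,
  `segment_and_merge()`, `extract_kinetics()`, `drug_response()`).
* **Sarcomere structure** — binary-mask segmentation of sarcomere units
  from striation-marker images, per-unit resting length and orientation,
  and a Gaussian fit to the orientation distribution reporting the
  dispersion σ (`segment_sarcomere_units()`, `fit_orientation_sigma()`).
* **Myofibrillar density** — transverse intensity-peak detection of
  myofibrillar bundles in F-actin images; area fraction = Σ peak widths ÷
  tissue width, plus along-axis heterogeneity (`extract_bundle_peaks()`,
  `compute_density()`).
* **Substrate mechanics** — a linear elastic shear-lag model of the
  contracting strip on a finite-thickness elastomer over rigid glass
  (Boussinesq–Cerruti kernel with a thickness attenuation), used to check
  neighbour decoupling at the 240/80 µm buffer gaps, thickness decoupling,
  tissue-modulus sensitivity, and ROI-placement robustness
  (`layer_model()`, `solve_displacement_field()`).
* **Synthetic data with exact ground truth** — seeded generators for
  contraction movies (strain-exact warps of band-limited texture),
  disorganized multi-domain monolayer movies, and striation / F-actin
  structure images (`gen_contraction_movie()`, `gen_structure_image()`).
* **Assay statistics** — CV, percent reduction, fold ratio, and the
  two-group sample size `n = 2(z₁₋α/₂ + z₁₋β)² (CV/δ)²`
  (`two_group_sample_size()`).

## Worked example

Simulate a 10 s brightfield recording of a bundle shortening by 5% at
0.4 Hz, track it, and extract kinetics:

```r
library(mbkit)
mov  <- gen_contraction_movie(contraction_truth(fs_max = 0.05),
                              duration = 10, seed = 1)
rois <- place_rois_inner50(mov$geometry, mov$stack$pixel_size,
                           frame_dim = dim(mov$stack)[1:2])
prox <- track_roi(mov$stack, rois$proximal, tracking_params(search_radius = 12))
dist <- track_roi(mov$stack, rois$distal,  tracking_params(search_radius = 12))
qc_trace(prox, dist)$accept
#> [1] TRUE
extract_kinetics(segment_and_merge(build_waveform(prox, dist)))
#> <kinetics_summary>
#>   max fractional shortening  4.99% (SD 0.00%)
#>   v_con 20/50/80%            0.1236 / 0.1561 / 0.1240 s^-1
#>   v_rel 80/50/20%            0.0896 / 0.1109 / 0.0884 s^-1
#>   peak acceleration          1.205 s^-2
#>   deceleration time          0.180 s
#>   relaxation time            0.548 s
#>   frequency                  0.402 Hz over 4 beat(s)
```

The recovered peak shortening (4.99%) matches the generator's imposed 5%,
the velocity at half-maximal shortening is within 1% of the closed form
`FS·π/2T_c = 0.157 s⁻¹` for the raised-cosine beat (relaxation
velocities are lower because the generated relaxation limb is slower,
0.7 s), and the beat frequency is recovered to the beat-count quantum. Structural analysis runs the same way on
`gen_structure_image()` fixtures or your own TIFFs (`read_stack()`).

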