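---
title: "marmoreg: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{marmoreg: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each
stage computes, under which assumptions, which tunable parameters
matter, what the synthetic phantom does and does not emulate, and where
the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. The registration model

Both stages estimate a 6-degree-of-freedom rigid transform
`x -> R x + t` between the CT scanner world and the MR scanner world
(millimetres throughout). Rigid is an assumption, not a limitation of
the implementation: the head, cranium and rigidly attached marker
holder move as one body between the two scans, and scanner geometric
distortion is taken as negligible at the field of view involved. No
scaling or shear is ever fitted.

### Marker-based fiducial registration (MBFR)

1. **Detection.** Each modality is binarised at a threshold
   (`mbfr_config()`): CT at 800 HU — the tungsten-solution markers sit
   near cortical-bone density — and MR at an upper intensity quantile,
   because the markers are the brightest structures in T2w. Connected
   components (26-connectivity) are filtered by a physical volume
   window, 2–20 mm³ by default, bracketing the ~6.3 mm³ cylindrical
   cavity; the window, not the threshold, is what removes the cranial
   shell on CT. The centroid is the unweighted mean of component voxel
   world-centres — a *binary* centroid, matching the
   thresholding-and-binarisation definition the MRE is built on; an
   intensity-weighted variant exists as an option.
2. **Correspondence.** Rigid motions preserve pairwise distances, so
   the two centroid constellations are matched by distance-matrix
   consistency: exhaustive non-collinear triplet seeding, greedy
   extension, best (largest, then lowest-residual) pairing wins,
   spurious detections stay unmatched. Symmetric constellations that
   admit tied pairings raise an explicit ambiguity error rather than a
   silent arbitrary choice — marker holders should be (and the
   phantom's is) asymmetric.
3. **Fit.** The Kabsch algorithm (SVD of the cross-covariance with the
   determinant correction) gives the least-squares rigid transform.
   Three markers are accepted, with a warning: three non-collinear
   points determine a rigid transform but leave no redundancy, so the
   MRE is optimistic there.

### The MRE and the failure rule

`MRE = sqrt(mean(d_i^2))` over post-registration distances between
corresponding centroids. A registration is *failed* when MRE exceeds
1 mm (configurable), and cohort failure probability is the failed
fraction. Two caveats are honoured rather than hidden: the MRE is
evaluated on the same markers the fit used, a circularity the test
suite sidesteps by always also comparing against the phantom's
ground-truth transform; and the reported MRE covers the matched subset
of markers, which the result object records.

### Boundary-based refinement

The refinement cost is *BBR-style*, not a bit-exact clone of any
existing implementation (whose vertex sets and projection details are
not public contracts). The bone mask is a direct HU threshold
(1000 HU); boundary voxels are mask voxels with a non-mask 6-neighbour;
outward normals come from the central-difference gradient of the mask,
mapped to world as covectors. For each boundary point mapped by the
candidate pose, the MR is sampled at ±`normal_offset` (0.5 mm ≈ one MR
voxel) along the normal, and the percent contrast
`Q = 100 (g_out − g_in) / (0.5 (g_out + g_in) + 1e-6)` enters the cost
`mean (1 + tanh(slope · Q / 2)) / 2` with slope −0.5, so boundaries
whose outward side is brighter (bone into brain tissue in T2w) drive
the cost toward 0 and a uniform image gives exactly 0.5.

Two design points deserve emphasis:

* **Only bone/soft-tissue interfaces are used** (default
  `tissue_adjacent_only = TRUE`, implemented by probing the CT
  2.5 voxels along the outward normal). The air-facing outer skull
  surface carries the *opposite* contrast sign in T2w, and with a fixed
  negative slope it would reward drifting the whole boundary into
  uniform air, where `Q = 0` yields the "better" value 0.5. Restricting
  to tissue-adjacent boundary mirrors removing air by thresholding the
  CT at −250 HU before segmentation.
* **The optimizer minimises `log(cost + 1e-25)`.** On high-contrast
  data the tanh saturates and the raw cost spans many orders of
  magnitude (1e-20 … 1) inside the basin; a relative-tolerance stop on
  the raw cost fires immediately there. The logarithm is a monotone
  transform — identical minimiser — that keeps Nelder–Mead's stopping
  rule meaningful; the reported `min_cost` is the raw cost.

The refinement assumes its initialisation lies within roughly
2 mm / 5° of the optimum (what MBFR delivers); a result whose
perturbation exceeds twice that basin is flagged `escaped_basin` and
reported unconverged.

## 2. Coordinate frames and the frame bias

*AC-PC native*: origin at the AC centre, +Y along the PC→AC direction,
midsagittal plane X = 0 fitted in least squares to user-supplied
midline points (at least one off the AC-PC line), +Z superior
completing the right-handed frame. Automatic midsagittal-symmetry
fitting is deliberately out of scope — the midline points are inputs.

*Image-based stereotactic*: X along the interaural line, horizontal
zero plane the least-squares plane constrained to contain the
interaural line and passing through both infra-orbital points, origin
at the interaural midpoint, +Y anterior. When the four defining points
are not exactly coplanar the constrained least-squares plane is the
symmetric, deterministic resolution.

**Angle convention.** Extrinsic fixed axes applied X then Y then Z
(`R = Rz(yaw) Ry(roll) Rx(pitch)`), right-handed RAS world, degrees.
The middle (Y) angle is the gimbal axis; decomposition within 1° of
|roll| = 90° carries a warning flag. `frame_bias(a, b)` returns
`a$to_frame ∘ b$to_frame⁻¹`; with the AC-PC frame first and the
stereotactic frame second, a positive pitch means the stereotactic
horizontal plane tips the frontal (+Y) direction downward — the sign
convention all bias reports use. Fitting the bundled cranial-landmark
cohort means (`cranial_landmark_means()`) this way yields a pitch of
+9.98°, which is what `scripts/acceptance.R` recomputes.

## 3. Statistics

* **ICC(1,1)**: one-way random-effects
  `(MSB − MSW) / (MSB + (k−1) MSW)`, with the F-based Shrout–Fleiss
  95% interval. Zero-variance tables return 0 with a warning instead of
  NaN. The point estimator is biased downward in small designs — at 5
  subjects × 5 repetitions a population ICC of 0.8 yields a Monte-Carlo
  mean near 0.72 — so recovery claims in the tests are made at large
  subject counts and the small-design bias is asserted as such.
* **Wilcoxon signed-rank**: two-sided, exact for up to 25 informative
  observations via dynamic programming over doubled midranks
  (equivalent to full 2^n enumeration, which the test suite performs
  literally as the oracle); zeros use the Pratt method, ties midranks;
  the normal approximation with tie/zero corrections and continuity
  correction applies above n = 25. A practical consequence honoured by
  the tests: with N = 5 subjects the smallest attainable two-sided
  exact p is 2/32 = 0.0625, so a real bias can only ever look
  "borderline" in that design.
* **COV and isometric ratios**: `100·sd/mean` (positive means only);
  linear measures compare as `a/b`, volumes as `(a/b)^(1/3)`.
* **Transform averaging / de-drifting**: translations average
  arithmetically; rotations by the iterated Karcher mean in
  rotation-vector space, valid and fast for the < 30° rotations this
  tool handles. Iterating to the true Fréchet mean (rather than a
  single log-average pass) is what makes de-drifted sets re-average to
  the identity at machine precision, which the tests assert per call.

## 4. The phantom: a stated world

The generator renders what the registration code needs and nothing
more: an ellipsoidal head (semi-axes 25 × 20 × 18 mm — marmoset-sized)
with a 1 mm bone shell, a brain/soft-tissue compartment, six cylindrical
marker cavities (2.0 mm diameter × 2.0 mm) on an asymmetric holder
constellation outside the shell, cranial landmarks, AC/PC points placed
so the stereotactic frame is pitched +10° (frontal down) relative to
the AC-PC frame, and a known true CT→MR transform (default: pitch 10°,
translation (2, −3, 1) mm). Intensities are plausible constants — CT
air −1000 / tissue 40 / shell 1500 / marker 1200 HU; T2w marker
brightest, tissue mid, bone and air dark — plus additive Gaussian noise
(default 15 HU CT, 0.02 on the 0–1 MR scale, roughly SNR 30 for
tissue). Shapes are rasterised through signed-distance partial-volume
ramps, so ground-truth centroids are sub-voxel exact by construction.

Deliberate departures from naive geometry, each forced by a failure
mode the naive phantom could not exercise:

* **Inner-surface bone ridges** (`inner_bumps`, default on): eight
  fixed spherical bosses protruding ~1.5 mm from the inner shell
  surface. A purely ellipsoidal inner surface moves almost tangentially
  under small rotations about the head centre, leaving any
  boundary-contrast cost rotation-blind; real crania are aspherical,
  and the ridges restore that rotational anchoring.
* **Spherical bubble pockets**: a marker air bubble is a sphere seated
  at the cavity's outer end, volume-matched to the requested fraction.
  (An axial slab of the right volume would leave a shorter but still
  point-symmetric cylinder — the asymmetry QC it exists to exercise
  would never fire.) The truth centroid shift,
  `b (H/2 − 3r/8)/(1 − b)` with `r = (1.5 b R² H)^{1/3}`, is exact
  while the pocket is narrower than the cavity (fractions ≤ ~0.33).
* **T2w bone intensity 0.35**, intermediate rather than near-zero: a
  ~1 mm shell is heavily partial-volumed at 0.36–0.48 mm MR voxels, and
  a fully saturated bone/brain contrast would additionally push the
  tanh cost into exact floating-point saturation.

Default grids are desk-scale: voxels 0.24 mm CT / 0.48 mm MR (half the
0.12 / 0.36 mm acquisition figures; `acquisition_resolution = TRUE` restores
them at ~8× cost), field of view auto-fitted to head + holder. The test
suite runs at 0.4 / 0.7 mm for speed; all geometry, noise and
thresholds there are the package defaults.

What the phantom does **not** emulate — hence what a green test does
not establish: MR physics (bias fields, distortion, Rician noise is
optional but off), CT beam hardening and reconstruction artifacts,
anatomy beyond the shell/brain/marker compartments, scalp and soft
tissue outside the shell, and real landmark-picking error. Quantities
tied to a specific animal cohort (real-scan MRE of 0.15 ± 0.04 mm,
comparative failure probabilities of intensity-based methods, per-axis
ICC values of a particular stereotactic device, the 0.2 mm surgical
target error) are *not* reproducible from synthetic data; the suite
substitutes the corresponding structural properties (ground-truth
recovery, oracle agreement, monotone degradation with noise).

Positioning-error simulation defaults
(`simulate_positionings()`): bias (1.6°, 1.1°, −0.2°, 0, 0, 0),
between-subject SDs (0.3, 1.0, 1.5, 0.8, 0.9, 0.5) and within-subject
SDs (1.0, 0.3, 0.2, 0.4, 0.4, 0.7) for (pitch, roll, yaw, tx, ty, tz).
These were chosen once so that the implied population ICCs
(σ²_b/(σ²_b+σ²_w) ≈ 0.08, 0.92, 0.98, 0.80, 0.84, 0.34) reproduce the
qualitative reproducibility pattern of a manually mounted device — poor
for pitch, excellent for roll/yaw, moderate for in-plane translation —
without tuning to any particular printed value.

## 5. Numerical choices, degenerate inputs, tolerances

* Rotations are re-orthonormalised by polar decomposition at
  construction, so long composition chains cannot drift; orthonormality
  is enforced at 1e-9.
* Euler round-trips are exact to 1e-6° away from |roll| ≥ 89°.
* Kabsch degeneracy: collinear sources (second singular value ≤ 1e-9
  relative) and n < 3 are errors, not warnings; n = 3 warns at the
  pipeline level.
* Interpolation: trilinear by default (deterministic, exact at
  grid-aligned samples), tricubic Keys convolution as `"spline"`,
  nearest for label volumes. Out-of-view voxels fill with the modality
  background (−1000 HU for CT, 0 otherwise); almost-integer voxel
  coordinates are snapped at 1e-7 so identity resampling is exact.
* Marker matching tolerance defaults to 0.5 mm of pairwise-distance
  disagreement; ambiguity requires a distinct equal-size pairing within
  1e-6 mm RMS.
* The NIfTI-1 reader/writer is intentionally minimal (single-file,
  sform preferred over qform, common datatypes, gzip) and is validated
  against an independent implementation in the test suite; files with
  neither affine, or a singular one, are rejected.
* The asymmetry QC index (1 − point-reflection overlap fraction) is
  lattice-quantised: clean markers score ~0.1–0.2 at 0.4 mm voxels and
  lower at acquisition resolution, so the default flag threshold (0.15)
  is meaningful near acquisition resolution and the tests compare
  bubble against clean markers at matched resolution instead of against
  the absolute threshold.

## 6. Known limitations

* The BBR cost is step-like on noiseless high-contrast data: its basin
  floor is flat within roughly a quarter millimetre, so refinement
  cannot improve an initialisation already better than that — it is a
  safety net for marker-centroid error, not a super-resolution
  registration.
* Marker correspondence is exhaustive over triplets and capped at 12
  candidates per modality (the 12 largest components are kept when
  noise speckle survives the size window).
* The stereotactic frame presumes identifiable ear-canal centres and
  infra-orbital points; no automatic landmark detection is attempted,
  by design — bregma in particular is reported ambiguous often enough
  that automating it would lend false confidence.
* `mean_transform` assumes rotations well inside ±180° (axis-angle
  averaging); it is not a general rotation-averaging method for widely
  scattered orientations.
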