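---
title: "Size-specific DECT material decomposition: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size-specific DECT material decomposition: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vncsim)
```

This vignette documents the model behind `vncsim`, the assumptions it
makes, the parameters that matter, and the design decisions taken where
the underlying vendor behavior is proprietary or under-determined.

## 1. What is being modeled

Dual-energy CT decomposes a co-registered low/high-energy HU image pair
into a virtual non-contrast (VNC) image and an enhancement image carrying
the removed contrast material's signal. Two size-sensitive parameters
control the result: the material's dual-energy ratio (DER), and an
optional beam-hardening correction (BHC) that adapts the decomposition to
object size but is calibrated on iodine with a head-sized reference. The
package reproduces, on synthetic phantoms, how these parameters interact
across an eight-workflow factorial (BHC on/off × head/body DER ×
head/body phantom) for iodine and calcium, under two acquisition
profiles: Dual Spiral (sequential 80/140 kVp, wide spectral separation)
and TwinBeam (split-filter, narrow separation).

## 2. Effective-HU rendering, not spectral physics

The generator never touches spectra, sinograms or reconstruction
kernels. Each material carries, per beam and per phantom size, either a
HU baseline (base materials) or a HU-per-(mg/ml) slope (contrast
materials); a voxel's HU is the occupancy-weighted sum of its regions'
values, so HU is exactly linear in concentration and the implied DER of a
contrast material is `slope_low / slope_high` by construction. Size
dependence enters only through these per-size entries. This is the level
at which the phenomenon under study lives — everything the factorial
probes is a statement about HU-space geometry — and it makes the
generator's ground truth exactly recoverable, which the test suite
exploits heavily.

Default slopes put the high-beam slope at 17 HU/(mg/ml) for iodine and
2.6 HU/(mg/ml) for calcium (plausible magnitudes; only the ratios are
constrained by the reference DER table) and derive the low-beam slope as
`DER × slope_high` from the measured DERs: TwinBeam iodine 1.40 (head) /
1.30 (body), calcium 1.19/1.14; Dual Spiral iodine 1.97/2.18, calcium
1.52/1.57.

Base-material HU pairs `(low, high)` are **modality-specific**, because
they encode spectral separation:

| material | Dual Spiral | TwinBeam |
|----------|-------------|----------|
| water    | (0, 0)      | (0, 0)   |
| fat      | (−110, −100)| (−102, −100) |
| tissue   | (55, 50)    | (51, 50) |
| CB2      | (60, 50)    | (57, 53) |

Two constraints shaped these invented defaults. First, water, tissue and
fat are exactly collinear in (low, high) HU space, so the water base of
the iodine inserts lies on the tissue–fat basis line and a size-matched
decomposition returns exactly 0 HU inside the iodine inserts — the
idealization of "all iodine removed leaves water". Second, CB2's mixed
value is exactly 55 HU in both tables, the calcium-free baseline of the
VNCa analysis. The TwinBeam pairs are compressed toward equality
(basis-line slopes ≈ 1.02–1.04 vs ≈ 1.1 for Dual Spiral): a narrow
split-filter separation cannot spread tissue HU more than it spreads
contrast-material HU, and a single shared table would place the TwinBeam
fat–CB2 basis line within 0.01 of the TwinBeam calcium DERs — a
near-degenerate geometry whose ~100-fold noise amplification is an
artifact of the shared table, not of the technique. Even with the
compressed pairs, TwinBeam calcium decomposition remains strongly
ill-conditioned (as the factorial shows), which is faithful to how badly
split-filter calcium decomposition behaves.

## 3. Phantom geometry

The head section is a 20 cm disc, the body a 35 × 26 cm ellipse. Only the
35 cm major axis is documented for the physical phantom; 26 cm is a
convention (configurable) matching the look of an abdomen section.
Inserts are 2.8 cm cylinders on a 5 cm-radius ring around the center —
the "inner head portion" placement — leaving the exact center free as a
uniform water region for noise ROIs. Insert sets default to 2, 5, 10,
15 mg/ml iodine on a water base and 0, 50, 100, 300 mg/ml calcium on a
CB2 base (the 0 mg/ml insert is the calcium-free CB2 reference that
defines the 55 HU baseline).

Rasterization is by area sampling: each 1 mm pixel is split into
`supersample² = 16` sub-pixels, each assigned to exactly one region
(insert ≻ body ≻ background), so per-pixel occupancy fractions sum to 1
exactly and edges are anti-aliased. Arrays are laid out `(row, col,
slice)` — the idiomatic R/NIfTI order — with the in-plane origin at the
phantom center; user-facing positions are always metric (cm).

Default depth is 5 slices of 3 mm for the noise-free factorial (the ROI
protocol uses 5 slices, so more buys nothing) and 35 slices for the noise
study (§7).

## 4. Noise and the iterative-reconstruction emulation

Acquisition noise is zero-mean Gaussian with per-beam SD
`σ_ref / sqrt(mAs fraction)`; `σ_ref` defaults to 10 HU (head) and
`10·sqrt(10) ≈ 31.6` HU (body), so matching body-level noise in the head
requires a tube-current fraction of 0.10 — the design of the low-dose
arm. The standard-normal draws depend only on the seed, not on the dose,
so comparing dose arms under one seed compares scaled versions of the
same noise realization, as a paired design intends. All stochastic
outputs are pure functions of (inputs, seed); the global RNG state is
left untouched.

Iterative noise reduction is emulated per slice and beam as a convex
blend with a 3 × 3 box filter, `out = α x + (1 − α) box(x)` (replicated
edges). For white noise,
`var(α n + (1 − α) box(n)) = σ² (8 α² + 1) / 9`, so choosing
`α = sqrt((9 f² − 1) / 8)` makes the uniform-region SD multiplier exactly
`f(strength) = 1 − 0.09 · strength`: `f(0) = 1` (identity), `f(5) = 0.55`
(a 45% reduction, the middle of the reported 40–50% band). Constant
regions pass through unchanged and region means are preserved in
expectation. Because the decomposition is linear and both beams are
filtered identically, the same multiplier carries through to the VNC
image, which is what the noise-study assertions measure.

## 5. The decomposition and its conventions

In (low, high) HU space a voxel is decomposed as
`voxel = b1 + t (b2 − b1) + c (d, 1)`, solved exactly per voxel by
Cramer's rule (vectorized). Conventions that deserve a note:

- **Pair ordering** is `(low, high)` everywhere; beam labels ride in the
  metadata so a silent swap cannot survive a round-trip.
- **Contrast direction** is `(d, 1)` with `c` in high-beam HU. Since
  `d = s_low / s_high`, a concentration ρ displaces a voxel by
  `(ρ s_low, ρ s_high) = ρ s_high (d, 1)`; any other orientation
  contradicts either the DER definition or the enhancement identity
  `enhancement = c (w d + 1 − w)`, which this convention makes exact.
- **VNC is reported on the mixed scale** (`w = 0.5` for both modalities;
  the weighting of the 120 kVp-equivalent image is not documented, so a
  symmetric default is used and exposed). Per-beam VNC volumes are kept
  internally for testing.
- **Degeneracy**: the solve refuses configurations with
  `|det| = |Δ_low − d Δ_high| < 10⁻⁶ × basis scale` with a classed
  error rather than returning NaNs. Values are never clipped; VNC voxels
  beyond ±3000 HU (the regime where the real system saturates) are
  counted and reported in a message, not altered.

## 6. The emulated size correction

The vendor BHC is proprietary; it is emulated as a multiplicative
remapping `d → d · r(D_w)`, where `D_w` is the water-equivalent diameter
of the mixed image,
`D_w = 2 sqrt(A_w / π)`, `A_w = Σ pixel_area (1 + HU/1000)` over voxels
above −600 HU averaged over slices, and `r(D) = DER_iodine(D) /
DER_iodine(D_ref)` interpolates the *iodine* DER piecewise-linearly
between anchors (clamped outside). This is the simplest model that
reproduces all reported qualitative behavior: exact for iodine at any
size when the head DER is supplied (workflows 1–2), a no-op at the head
reference (workflow 1 ≡ 5), an over-correction when the body DER is
supplied with the correction active (workflows 3–4), and a wrong —
iodine-ratio — rescaling of calcium (workflow 2). Whether the real
correction is multiplicative or affine in HU is unknowable from the
outside; only sign and structure claims are asserted anywhere.

Anchors are `(water-equivalent diameter, iodine DER)` pairs. Nominal
phantom diameters are *not* WEDs — the water-filled 35 × 26 cm ellipse
has `D_w = 2 sqrt(17.5 · 13) ≈ 30.2` cm — so `run_grid()` calibrates the
anchors at the measured WEDs of its own rendered head and body mixed
images (reference = head), mirroring a correction "designed against a
head-sized phantom". `default_bhc_model()` uses the water-phantom values
(20, 30.17 cm) for standalone use.

## 7. The factorial and the noise study

`run_grid()` closes the loop generator → estimator → decomposition: the
DERs each workflow applies are re-estimated from the rendered images via
`estimate_der()` (OLS of low on high across insert ROI means, *with*
intercept — raw insert HU include the base-material offset, which the
intercept absorbs; a through-origin fit would be wrong for calcium).
ROI protocol: circular ROI of 60% of the insert diameter at the insert
center, central slice ± 2 (5 slices, configurable), mean and SD over all
included voxels. Concentrations come from the "manual method": an OLS
calibration of concentration on enhancement HU (prediction direction,
with intercept) fitted on workflow 5 and applied to all head-phantom
workflows {1, 3, 5, 7}, and on workflow 8 for the body workflows
{2, 4, 6, 8}. A workflow is flagged accurate when its largest absolute
VNC error across inserts is ≤ τ; τ defaults to 20 HU, sitting between
the accurate (≈0 HU here; single-digit in the physical study) and
inaccurate (≥ 40 HU) clusters, and the test suite asserts the accurate
sets are unchanged for any τ in [10, 30] HU — the flag is not
knife-edged.

`run_noise_study()` compares three seeded arms, each decomposed with its
size-correct BHC-off workflow: body at reference dose, the same body
acquisition through the strength-5 noise-reduction emulation, and the
head phantom at 10% tube current. Its phantoms default to 35 slices
(10.5 cm, covering the full length of the physical insert rods) with the
ROI copied across all of them: the quantities under test are
insert-*mean* shifts of a few HU, and the per-insert ROI mean of the
amplified decomposition noise must be estimated from enough voxels
(~19 000) that sampling scatter does not masquerade as a systematic
shift — a power consideration, fixed before the arms are compared.

## 8. What the synthetic data does and does not show

The generator reproduces the *structure* the analysis assumes: exact
linearity in concentration, per-size DERs, dose-scaled Gaussian noise,
and a mean-preserving noise-reduction operator. It does not model
polychromatic beam hardening, scatter, reconstruction kernels, partial
spectral overlap, insert texture, or the vendor's saturation behavior.
Consequently, passing tests establish that the pipeline's estimators and
decomposition are correct and that the factorial's accuracy pattern is a
necessary consequence of the DER/BHC geometry — they do not certify the
HU magnitudes of any physical scanner's tables, which depend on
proprietary processing the package deliberately does not imitate.
Matching magnitudes was a non-goal; matching which workflows succeed,
the error signs and growth with concentration, and the noise findings,
is the point.

## 9. Numerical notes

- Occupancy fractions are exact rationals (`k/16`) and sum to 1 per pixel.
- The conservation identity `vnc + enhancement = mixed` holds to
  arithmetic round-off (asserted at 10⁻⁶ HU).
- DER and calibration fits use `stats::lm`; interpolation uses
  `stats::approx` (clamped); NIfTI IO uses `RNifti` (float32, lossless
  round-trip at that precision plus a JSON sidecar carrying acquisition
  metadata).
- The projection solve is validated in tests against a QR least-squares
  oracle and a brute-force residual grid around the oracle solution; the
  two routes agree to 10⁻⁹ even for the worst-conditioned TwinBeam
  calcium geometry.
- Errors are classed conditions (`vncsim_error_geometry`,
  `_validation`, `_config`, `_format`, `_fit`, `_degenerate`,
  `_report`), so callers can distinguish a bad phantom from a bad fit.
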