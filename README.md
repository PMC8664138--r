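# vncsim

Simulation and analysis of **size-specific dual-energy CT (DECT) material
decomposition** — who gets hurt when an iodine-specific size correction is
applied to non-iodine materials, and how to configure the decomposition so
that it does not happen.

## The problem

Vendor DECT software decomposes a co-registered low/high-energy image pair
into a *virtual non-contrast* (VNC) image and a complementary *enhancement*
image holding the removed material's signal. Two parameters govern the
decomposition of a material:

- the **dual-energy ratio** (DER), the slope *d* of the linear fit of
  low-energy CT numbers against high-energy CT numbers across
  concentrations of the material — specific to material, technique
  (TwinBeam split-filter vs Dual Spiral 80/140 kVp) and object size; and
- an optional **beam-hardening correction** (BHC) that remaps the
  decomposition for object size — but is calibrated on *iodine* in a
  *head-sized* phantom.

For iodine the BHC works as designed. For calcium (e.g. virtual
non-calcium imaging of bone marrow) the iodine-based size correction
rescales the calcium DER by the *iodine* size ratio and corrupts the
result. `vncsim` reproduces this whole mechanism in an open, testable
pipeline: a synthetic head (20 cm disc) / body (35 × 26 cm ellipse)
phantom generator with concentration-graded iodine (2–15 mg/ml) and
calcium (50–300 mg/ml) inserts, dose-scaled noise and an
iterative-reconstruction emulation; a two-basis projection decomposition
with an emulated size correction; DER estimation, ROI statistics,
size-specific concentration calibration and bias/total-error metrics; and
the eight-workflow factorial crossing BHC on/off × head/body DER ×
head/body phantom.

## The model

In (low, high) HU space each voxel is written as

```
voxel = b1 + t (b2 - b1) + c (d, 1)
```

with `b1`, `b2` the basis-material HU pairs (tissue/fat for iodine,
fat/CB2 for calcium), `d` the applied DER and `c` the contrast
displacement in high-beam HU. The 2×2 system is solved exactly per voxel;
the VNC image is the mixed-image value (`w·low + (1-w)·high`, `w = 0.5`)
of the basis-line point, and

```
enhancement = mixed - VNC = c (w d + 1 - w)
```

holds as an exact identity. With the BHC active the applied DER is
`d · r(D_w)`, where `D_w` is the water-equivalent diameter of the mixed
image and `r` interpolates the iodine DER between head- and body-sized
anchors (`r = 1` at the head reference — which is exactly why the
correction is harmless at head size and wrong for calcium at body size).

## Worked example

```r
library(vncsim)

grid <- run_grid("DualSpiral", "calcium", tau = 20)
grid
#> <vnc_grid> DualSpiral calcium, noise-free: baseline 55.0 HU, tau = 20 HU
#>   measured DERs: head 1.5200, body 1.5700
#>   accurate workflows: {1, 5, 8}
#> # A tibble: 8 x 8
#>   workflow bhc_active der_source phantom_size applied_der largest_error_hu
#>      <int> <lgl>      <chr>      <chr>              <dbl>            <dbl>
#> 1        1 TRUE       head       head                1.52         9.24e-13
#> 2        2 TRUE       head       body                1.68         1.70e+ 2
#> 3        3 TRUE       body       head                1.57         9.53e+ 1
#> 4        4 TRUE       body       body                1.74         2.31e+ 2
#> 5        5 FALSE      head       head                1.52         9.24e-13
#> 6        6 FALSE      head       body                1.52        -1.08e+ 2
#> 7        7 FALSE      body       head                1.57         9.53e+ 1
#> 8        8 FALSE      body       body                1.57         3.55e-13
```

Reading the table: the head/body calcium DERs measured from the rendered
images are 1.52/1.57. Workflows 5 and 8 (BHC off, size-matched DER)
remove the calcium exactly, leaving the 55 HU calcium-free CB2 baseline
(largest error ~1e-13 HU). Workflow 1 is also exact because the BHC is a
no-op at head size. Every other workflow mis-scales the DER — e.g.
workflow 2's head DER 1.52 is remapped by the *iodine* size ratio to 1.68
instead of the correct 1.57, leaving up to 170 HU of residual error at
300 mg/ml. The same run for iodine returns accurate workflows
{1, 2, 5, 8}: with iodine the BHC size correction is the right one.

Per-insert tables, concentration errors via the size-specific calibration
("manual method"), and figures:

```r
tidy(grid)          # workflow x insert VNC / enhancement / concentration
glance(grid)        # per-workflow summary (shown above)
autoplot(grid)      # concentration-error bar chart
render_report(grid, "report/")   # CSVs + montage figure

ns <- run_noise_study("DualSpiral", seed = 1)
ns
#> <noise_study> DualSpiral calcium (seed 1)
#>   noise-reduction arm: uniform-ROI SD down 45.1%, max insert-mean shift 0.17 HU
#>   10%-dose head arm: max insert-mean shift 1.50 HU
```

The noise study isolates noise from size: strength-5 iterative noise
reduction cuts VNC noise SD by ~45% while moving insert means by well
under 3 HU, and re-acquiring the head phantom at 10% tube current (noise
matched to the body) moves them by under 6 HU — so noise does not explain
the size-specific errors above.

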