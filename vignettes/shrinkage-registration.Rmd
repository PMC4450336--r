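---
title: "Registering shrinking head-and-neck tumors: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registering shrinking head-and-neck tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shrinkreg)
```

## The problem

Most head-and-neck cancer patients undergoing fractionated radiotherapy
show substantial anatomic change over the treatment course, and the primary
tumor itself loses both density and volume as irradiated cells die. When a
posttreatment CT is registered deformably to the planning CT, this breaks
the assumption every intensity-based algorithm rests on: that each voxel of
one image has a physical counterpart in the other. Intensity mass present
in the planning tumor simply no longer exists at the later time point.
Around such regions a Demons-type registration produces erratic, physically
meaningless displacement vectors and mis-places the tumor contour.

`shrinkreg` implements a pipeline that restores approximate intensity
correspondence *before* deformable registration, by predicting the
radiation-induced intensity loss of every planning-CT tumor voxel from the
planned dose:

1. **Preprocessing** — couch removal, clamping of sub-air voxels
   (below -500 HU to -1000 HU), cropping, and resampling of both scans to a
   common 2 x 2 x 3 mm grid (nearest interpolation).
2. **Rigid initialization** — a translation-only registration driven by the
   bony skeleton (both images floored at 500 HU; exhaustive correlation
   search plus parabolic sub-step refinement).
3. **Intensity-modification procedure (IMP)** — the package's core. Each
   planning tumor voxel's CT number $I_0$ is converted to a linear
   attenuation coefficient $\mu_0 = I_0\,\mu_W/1000 + \mu_W$, which is
   proportional to the number of intact cells in the voxel. The
   linear-quadratic (LQ) model predicts the surviving fraction after a
   total voxel dose $D$ delivered in $n$ fractions of $d = D/n$:
   $$\mathrm{SF} = \exp\!\left[-\alpha D \left(1 + \frac{d}{\alpha/\beta}\right)\right],$$
   and the modified intensity is
   $I_S = (\mu_0\,\mathrm{SF} - \mu_W)\cdot 1000/\mu_W$, algebraically
   $(I_0 + 1000)\,\mathrm{SF} - 1000$. A final scale step multiplies every
   tumor voxel's offset value $I_S + 1000$ by $S/S_0$, where $S_0$ is the
   modified tumor's offset sum and $S$ the posttreatment sum over the same
   region, absorbing the (large) uncertainty in the radiobiological
   parameters.
4. **Deformable registration** — a single-resolution symmetric-force
   ("active force") Demons iteration,
   $$D_n = G_\sigma * \left( D_{n-1} + (I - I')\left[
      \frac{\nabla I}{|\nabla I|^2 + k^2 (I-I')^2} +
      \frac{\nabla I'}{|\nabla I'|^2 + k^2 (I-I')^2} \right]\right),$$
   where $I$ is the static (posttreatment) intensity, $I'$ the currently
   warped moving (planning) intensity, and $G_\sigma$ a Gaussian smoother.
5. **Evaluation** — Dice similarity (DSC, %) of propagated tumor masks,
   displacement-field statistics, and displacement-recovery scoring
   against analytic ground truth.

## Conventions

* Volumes are column-major (x, y, z) arrays with per-axis spacing (mm) and
  a world origin at the center of the first voxel, in the DICOM patient
  (LPS) frame; axes are assumed axis-aligned.
* Displacement fields live on the static grid, in millimeters, and are
  **backward-mapping**: warping samples the moving image at
  $x + u(x)$. Out-of-volume samples read as air (-1000 HU). Because voxels
  are anisotropic, millimeters are the only unambiguous unit; fields are
  converted to voxel units internally at interpolation time.
* With this convention the Demons force must carry the sign $(I - I')$;
  the force published for forward-push fields has the opposite sign. The
  two conventions describe the same update. Our sign is fixed by a
  consistency requirement: on a translated ramp the update must point
  toward the true correspondence (it does; this is unit-tested).
* Gradients are central differences in the interior, one-sided at faces,
  in HU/mm. The smoothing kernel is truncated at $3\sigma$ with
  nearest-edge replication, and $\sigma$ is in voxel units, as is usual
  for grid-based Demons regularization.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| $\alpha$ | 0.33 | Gy$^{-1}$ | nominal LQ radiosensitivity for head-and-neck tumors |
| $\alpha/\beta$ | 10 | Gy | nominal for most tumors |
| fractions $n$ | 35 | — | a 70 Gy prescription at 2 Gy/fraction |
| $\mu_W$ | 0.1928 | cm$^{-1}$ | attenuation of water; cancels in the HU round trip, so any consistent unit works |
| $\sigma$ | 1 | voxels | Demons field smoothing |
| $k$ | 0.4 | — | force normalization; caps the per-iteration step at $1/2k = 1.25$ mm per force term |
| iterations | 200 | — | full budget by default (see below) |
| bone threshold | 500 | HU | isolates the skeleton for the rigid stage |
| air clamp | -500 | HU | strictly below goes to -1000 |
| working grid | 2 x 2 x 3 | mm | standard resolution for all registrations |

The scale step makes the pipeline remarkably insensitive to $\alpha$ and
$\alpha/\beta$: with a near-uniform in-tumor dose the survival fraction is
close to spatially constant, so changing the parameters rescales all tumor
voxels by a common factor that the sum-matching step removes almost
exactly. The sensitivity test in the acceptance suite sweeps
$\alpha \in \{0.1, 0.33, 1.0\}$ Gy$^{-1}$ and
$\alpha/\beta \in \{3, 10, 40\}$ Gy and verifies the final DSC moves by no
more than 2 percentage points.

**Stopping.** An MSD-based early-stopping rule
(`convergence_tol`) is available but disabled by default. The reason is a
genuine failure mode we observed: when two scans are already well aligned
everywhere except a small tumor region, the *global* mean squared
difference reaches its noise floor within ~10 iterations while the tumor
region is still evolving, so any rule keyed on global MSD improvement
quits long before the clinically interesting part of the field has
converged. The default therefore runs the full 200-iteration budget
(about 10-15 s at the standard phantom size with the compiled kernels).

**Numerical details.** Force denominators below $10^{-9}$ zero their term
(flat-region guard). Nearest-neighbor ties round half away from zero.
The intensity scale step works on offset values $I + 1000$ (proportional
to attenuation): raw HU sums can be negative or zero, which would make a
multiplicative match ill-defined; $S_0$ sums the *LQ-modified* values, so
the scale corrects exactly the residual radiobiological uncertainty it is
meant to absorb. Contours rasterize by the even-odd rule at voxel centers;
multiple contours on a slice combine by XOR so holes work.

## The synthetic phantom: what it emulates, and what it does not

All tests and validation experiments run on a seeded synthetic head
phantom (default 96 x 96 x 40 voxels at 2 x 2 x 3 mm): an ellipsoidal
cranium shell at ~1200 HU, soft-tissue interior at ~40 HU, a spherical
tumor at ~60 HU, a couch slab at ~300 HU, and Gaussian noise (sd 10 HU) on
all non-air voxels.

Two design points deserve emphasis because they were forced by
well-posedness, not convenience:

* **Bone texture.** Real bone is heterogeneous (cortical vs trabecular).
  The phantom skull carries a smooth sinusoidal HU modulation (+/-450 HU,
  wavelengths 35-50 mm). A constant-HU shell would make the rigid stage's
  Pearson objective degenerate — the static bone values would have no
  variance beyond noise, and no translation could be distinguished at
  sub-voxel offsets.
* **Soft-tissue texture.** Real soft tissue has anatomic structure at many
  scales. The phantom adds a smooth two-scale modulation (about +/-25 HU,
  wavelengths 11-41 mm) under the white noise. White noise alone has a
  correlation length of one voxel, so an intensity-based registration has
  no basin of attraction beyond ~2 voxels and *no* algorithm of this class
  could recover a 5 mm deformation from it.

The shrinkage study (`make_shrinkage_study()`) renders the same anatomy
twice with independent noise (two scans are independent acquisitions),
then replaces the tumor with a concentric residual of 67% volume at
markedly reduced density (20 HU against 40 HU soft tissue) and applies a
smooth one-sided inward collapse of the tumor bed (3 mm amplitude toward
a fixed left-posterior direction by default; `deform_amplitude_mm`,
`deform_anisotropy`, `deform_direction`). The collapse
is what gives the deformable stage something physically real to recover;
the concentric replacement is what creates the no-correspondence defect.
Both are needed: without a true deformation, "do nothing" is the optimal
field for both pipeline arms and the method has nothing to demonstrate;
without the replacement there is no correspondence defect and plain
Demons suffices.

What the phantom does **not** emulate: airways, vertebrae and skull-base
anatomy, beam-hardening and scatter artifacts, weight loss and posture
change, multi-organ deformation, partial-volume effects of real scanners.
Passing the phantom suite therefore demonstrates the algorithmic
machinery — geometric fidelity of warps, correctness of the LQ intensity
model, recoverability of smooth deformations, and the qualitative benefit
of intensity modification under tumor shrinkage — not clinical-grade
accuracy on patient data.

## Validation experiments

* **Deformable:** a full 2nd-order polynomial displacement field (all ten
  monomials per component, coefficients seeded, rescaled so the mean
  in-body magnitude is 5.5 mm) warps the phantom; the Demons stage must
  recover at least 90% of body voxels to within 2 mm of the analytic
  truth. `validate_deformable()` reruns this end to end.
* **Rigid:** twenty seeded random translations with components up to
  10 mm (sub-voxel fractions included) must be recovered with a mean
  residual of at most 1.1 mm. `validate_rigid()` reruns this.
* **Ablation:** on the standard shrinkage suite, tumor DSC with IMP must
  exceed tumor DSC without IMP on every seed. This is the package-level
  restatement of the clinical finding (a 21% mean DSC improvement on ten
  patients), scaled to what synthetic data can support.

Problem sizes were chosen so the full test suite and the validation
scripts run in minutes on a single CPU: the standard phantom has ~370k
voxels, and each 200-iteration Demons run takes ~10-15 s.

## Known limitations

* Translation-only rigid initialization; no rotations (patients are
  assumed masked/immobilized).
* Single-resolution Demons; no multiresolution pyramid, no diffeomorphic
  or inverse-consistent variant. Very large deformations (beyond ~10 mm
  locally) may not be fully recovered.
* The LQ model ignores proliferation, hypoxia, chemotherapy and
  time-dependence; the scale step absorbs much, but not all, of this.
* The DICOM layer reads only explicit-VR little-endian files of the kinds
  the package itself writes (CT series, RT-DOSE, RT-STRUCT); it is a
  fixture-grade implementation, not a clinical parser.
* Dose is trilinearly resampled; strong dose gradients at the tumor
  boundary are mildly smoothed at the 4 mm dose-grid scale.
* The global mean squared difference is not strictly monotone over
  iterations: near the optimum the fixed normalized step overshoots at
  strong bone edges and the MSD settles into a small limit cycle (about
  1% relative on the standard validation run). This is intrinsic to
  fixed-step Demons without a line search; it does not affect the
  recovered fields, but it means MSD alone cannot certify convergence.
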