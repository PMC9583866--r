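---
title: "The peripheral-dose model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The peripheral-dose model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peridose)
```

## The model and its assumptions

Peripheral photon dose (PPD) — the absorbed dose outside the treatment
field — has three sources: scatter generated inside the patient,
scatter from the collimators and head, and leakage through the head
shielding.  Close to the field edge patient scatter dominates; far away
only leakage matters.  `peridose` models the sum with a single closed
form in the isocenter-origin frame (x anterior–posterior, y left–right,
z caudal–cranial, cm):

$$\mathrm{PPD}(x,y,z) = \begin{cases}
\varepsilon\, F\,\dfrac{(A_1 - A_2 |z|)\, e^{-A_3 r}}{r^2} + (L_u - L_r)
  & r \le 40\ \mathrm{cm}\\[1ex]
L_u & r > 40\ \mathrm{cm}
\end{cases}$$

with $r = \sqrt{x^2+y^2+z^2}$, in mGy per monitor unit (MU).  The form
encodes the model's assumptions:

- **Spherical symmetry of the scatter term** apart from the linear
  $|z|$ gradient.  This fits treatments whose beams are spread around
  the isocenter (VMAT, IMRT, multi-field plans); plans with few beams
  produce non-symmetric isodoses the model cannot follow.
- **Water-equivalence.**  No electron-density information enters; doses
  in lung or bone are correspondingly less accurate.
- **A hard 40 cm cutoff** below which scatter and leakage are modelled
  together and beyond which only the leakage plateau $L_u$ remains.
  The piecewise form is applied exactly as written, with its
  discontinuity at $r = 40$ cm; no blending is applied, because the
  calibration data for the scatter branch only extends to 40 cm and
  smoothing would invent information neither branch has.
- **Validity only outside the 5 % isodose.**  Planning systems are
  accurate inside; the model is undefined there.  Querying within
  `r_min` = 1 cm of the isocenter raises an out-of-validity error
  rather than returning the diverging $1/r^2$ value.

## Parameters

| parameter | units | default | meaning |
|---|---|---|---|
| `A1` | mGy·cm²/MU | 37.890 | scatter amplitude |
| `A2` | mGy·cm/MU | 0.679 | craniocaudal gradient |
| `A3` | cm⁻¹ | 0.007 | effective attenuation of scattered photons |
| `E_R` | mGy/MU | 2000/278 ≈ 7.194 | reference treatment efficiency |
| `F_R` | cm² | 149.2 | reference field area |
| `L_r` | mGy/MU | 0.001 | reference head leakage |
| `r_cut` | cm | 40 | leakage-only radius |
| `r_min` | cm | 1 | validity guard |
| `isodose_exclusion` | — | 0.05 | in-field exclusion fraction |

The user supplies the treatment efficiency `E_U` (prescription / total
MU), the field area `F_U`, and — when measured — the leakage `L_u`.
When `L_u` is unknown it defaults to `L_r`, so the leakage-difference
term vanishes.

Two display conventions are worth spelling out.  All ratios are carried
at full floating precision; values like 7.2 mGy/MU, F = 0.35/0.36 or
ε = 1.04 are two-digit display roundings of the exact quotients, and
`E_R` defaults to the exact quotient 2000/278 rather than the rounded
7.2.  One published worked example prints ε = 0.48 for a plan whose own
quotient is 3.6/7.2 = 0.50; `efficiency_factor()` computes the
quotient, so it returns 0.50 for those inputs.

The coefficient invariant `A1 − A2·r_cut > 0` is enforced at
construction: since $|z| \le r \le 40$, it guarantees the scatter
bracket never goes negative where the scatter branch applies.  The
model output is additionally clamped at zero — possible only when
`L_u < L_r` and the scatter term is tiny — because absorbed dose cannot
be negative.

## Field-size extraction

`F_U` is defined as the mean of the areas inside the 50 % isodose on
the coronal and sagittal planes through the isocenter.
`plane_isodose_area()` counts plane pixels at or above the threshold
(inclusive `>=`) and multiplies by the pixel area: reproducible, and no
contouring algorithm to tune.  The plane is the voxel slab nearest the
isocenter coordinate — a known half-voxel bias documented rather than
interpolated away.  The threshold is relative to the dose trilinearly
interpolated *at the isocenter position*, not at the nearest voxel,
since the isocenter rarely coincides with a voxel center.

A second recipe — the product of the 50 % full widths of the two 1D
profiles through the isocenter — exists in the field and is exposed as
`field_area_profile()`; the area-based recipe is the default
everywhere.

## Calibration

`fit_coefficients()` fits $(A_1, A_2, A_3)$ to a reference 3D dose
distribution (per MU, reference conditions $\varepsilon = F = 1$,
$L_u = L_r$) by Nelder–Mead simplex.  Voxels eligible for fitting
(`calibration_mask()`) are those inside the body with the one-voxel
surface shell eroded away (electron contamination at the surface is not
modelled), outside the 5 % isodose, and at radii between `r_min` and
40 cm.  Erosion uses 6-connectivity — the most conservative definition
of "surface voxel"; the choice is not critical since it removes only a
one-voxel shell.

Design choices the original procedure leaves open, fixed here:

- **Loss.**  Sum of squared *relative* residuals
  $((\mathrm{model} - \mathrm{ref})/\mathrm{ref})^2$.  Peripheral dose
  spans about two orders of magnitude between the field edge and 40 cm;
  absolute least squares would be dominated by the innermost voxels.
  Absolute-residual loss is available via `loss = "absolute"`, and the
  `.3ddose` relative-error array can be converted to
  inverse-variance weights (`weights =`), off by default.
- **Start and convergence.**  Default simplex start `(20, 0.3, 0.02)`,
  relative tolerance `1e-8`, at most 5000 iterations, and `parscale`
  set to the start so the simplex moves on comparable scales for
  parameters four orders of magnitude apart.  After the first optimum a
  second simplex is started from it — a standard guard against
  premature simplex collapse.  The whole fit is deterministic for a
  fixed start.
- **The 5 % isodose is relative to the isocenter dose**, not the global
  maximum.  For isocentric plans the two usually agree; the fraction
  and the reference point are arguments if another convention is
  needed.

On a noiseless synthetic cube generated by the model itself the fit
recovers the generating coefficients to well under 0.1 % relative from
any start within ±50 % of the truth; with 5 % multiplicative noise on a
41³ grid the recovered values stay well inside the published
coefficient uncertainties.  Reproducing the original coefficients from
the original Monte Carlo cube is *not* claimed: that cube is not
shipped, and the original objective and convergence settings are
unpublished.

## Dose cubes, sentinels and DVHs

`compute_ppd_cube()` evaluates the model at every voxel center.
Voxels inside the exclusion mask or closer than `r_min` carry `NA` plus
a companion `valid` mask — never silent zeros, which would corrupt
organ means.  DVHs (`cumulative_dvh()`) report
$V(d) = 100\,\%\times$ (fraction of organ voxels with dose $\ge d$) at
the left edge of each bin; bins default to 0.1 mGy width (peripheral
doses are small and fine bins are cheap) spanning $[0, d_{max} +$ one
bin$]$.  Organs straddling the 5 % isodose are truncated: the
not-computed voxels are dropped and their fraction reported, with a
warning above 10 %.  Only relative (percent) volume is binned; the
absolute organ volume in cm³ is reported alongside.  The exported
ASCII DVH is a two-column table with `#` headers and C-locale decimal
points.

## I/O conventions

All internal geometry is cm; NIfTI pixel dimensions (mm) are divided by
10 on read and multiplied on write, and `.3ddose` boundary coordinates
are taken as cm (the EGSnrc convention) with an `mm = TRUE` override
for nonstandard exports.  The `.3ddose` reader derives voxel centers
from boundary midpoints, checks monotonicity and uniformity, and
attaches the relative-error array from the file's last block.  DICOM
and MetaImage volumes are not read; convert to NIfTI upstream.  The
canonical axis order is (AP, LR, craniocaudal) with the isocenter at
the origin; `isocenter_frame()` maps any signed grid-axis permutation
onto it.

## The synthetic generator

`generate_phantom()` voxelizes a body ellipsoid (default semi-axes
12 × 17 × 40 cm — an adult trunk — on a 2 cm isotropic grid) with a few
ellipsoidal organs; `generate_reference_dose()` emulates a Monte Carlo
reference distribution as model × (1 + cv·N(0,1)) per voxel, plus an
in-field Gaussian blob (default amplitude 7.2 mGy/MU — the isocenter
dose per MU of the reference plan — with σ = 2 cm) so that a 5 %
isodose region exists; `generate_tld_points()` scatters pseudo
point-dosimeter measurements uniformly over an annulus.  The noise is
multiplicative because Monte Carlo uncertainty is reported as relative
error; the blob σ is chosen so its tail is negligible at the radii
where calibration voxels begin.  All randomness sits behind one integer
seed.

What the synthetic data does *not* emulate: anatomical realism, tissue
heterogeneity, asymmetric isodoses from few-beam plans, the collimator
shielding drop seen in measured profiles around 21–22 cm for small
fields, and detector-specific effects.  Tests passing on synthetic data
therefore demonstrate the *internal* consistency of the pipeline
(calibration recovers generating coefficients; cube, DVH and statistics
agree with brute-force oracles) — not clinical accuracy, which the
original validation against thermoluminescent dosimeters and
independent Monte Carlo simulations addresses.

## Problem sizes and numerical details

The verification suite uses a 41³ voxel, 2 cm isotropic grid (±40 cm)
for calibration-recovery checks — about 33 000 fittable voxels, which a
fit completes in well under a second — and the default 17 × 21 × 45
phantom for pipeline checks.  Quantiles use R's default (type 7)
definition.  Areas and widths use inclusive thresholds; ties at exactly
the threshold count as inside.  Degenerate inputs (empty masks, empty
organs, zero isocenter dose, non-monotone grid boundaries, truncated
files) raise typed errors naming the offending input rather than
propagating NaNs.

## Known limitations

- Accuracy degrades for few-beam, strongly asymmetric plans and in
  tissues far from water equivalence (lung, bone).
- The sharp dose drop from primary-collimator shielding at ~21 cm for
  small fields is not representable by the smooth exponential form.
- Skin dose, electron contamination and neutron dose (relevant above
  10 MV) are out of scope.
- The leakage plateau treats $L_u$ as constant; linacs with strongly
  position-dependent leakage need a measured map instead.
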