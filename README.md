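# shrinkreg

Deformable registration of planning and posttreatment head-and-neck CT in
the presence of radiation-induced tumor shrinkage.

## The problem

When a tumor responds to fractionated radiotherapy, irradiated cells die
and the tumor loses density and volume. Between the planning CT and a
posttreatment CT there is then no one-to-one correspondence for many tumor
voxels — intensity mass in the planning image simply no longer exists —
and intensity-based deformable registration (the Demons family included)
produces erratic displacement fields exactly where accuracy matters most
for adaptive radiotherapy.

`shrinkreg` restores approximate correspondence *before* registering. For
every planning-CT tumor voxel it converts the CT number I0 to a linear
attenuation coefficient mu0 = I0 * muW/1000 + muW (proportional to the
number of intact cells), predicts the surviving cell fraction from the
planned voxel dose D (delivered in n fractions of d = D/n) with the
linear-quadratic model

    SF = exp( -alpha * D * (1 + d / (alpha/beta)) ),

reduces the voxel intensity accordingly, IS = (I0 + 1000) * SF - 1000, and
finally rescales the tumor region so its offset-intensity sum matches the
posttreatment scan over the same region (absorbing radiobiological
parameter uncertainty). The modified pair is registered with a
single-resolution symmetric-force ("active force") Demons iteration

    D_n = G_sigma * ( D_{n-1} + (I - I') [ grad I  / (|grad I |^2 + k^2 (I-I')^2)
                                         + grad I' / (|grad I'|^2 + k^2 (I-I')^2) ] ),

with sigma = 1 voxel, k = 0.4, initialized by a bone-driven
translation-only rigid registration. Accuracy is reported as the Dice
similarity coefficient (DSC, %) of propagated tumor masks and as
displacement-recovery statistics against analytic ground truth.

The package includes readers/writers for DICOM CT series, RT-DOSE and
RT-STRUCT (explicit VR little endian), NIfTI and MetaImage volumes, and a
seeded synthetic head-phantom generator that replaces patient data in all
tests and validation experiments.

## Worked example

```r
library(shrinkreg)

# A complete synthetic study: planning CT, posttreatment CT with a shrunken
# tumor, planned dose, tumor mask, and ground truth.
st <- make_shrinkage_study(seed = 1)

# Intensity-modification procedure, then Demons.
modified <- apply_imp(st$planning, st$dose, st$tumor, st$post,
                      radiobiology_params(alpha = 0.33, alpha_beta = 10))
reg <- demons_register(st$post, modified)
summary(reg)
#> Demons registration (sigma = 1 voxels, k = 0.4)
#>   iterations: 200 (budget reached)
#>   MSD: 1.983e+04 -> 892.8
#>   displacement: mean 0.383 mm, max 5.805 mm

# Propagate the planning tumor contour and score it against ground truth.
prop <- propagate_mask(st$tumor, reg$field)
dice_coefficient(prop, st$tumor_post)
#> [1] 83.51776
# the same registration without intensity modification:
dice_coefficient(propagate_mask(st$tumor,
                                demons_register(st$post, st$planning)$field),
                 st$tumor_post)
#> [1] 77.24583
```

The two DSC values restate the package's central claim: with the
intensity-modification procedure the propagated tumor contour matches the
true shrunken tumor substantially better than plain Demons does.

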