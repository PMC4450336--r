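#' Radiobiology parameters for the intensity-modification procedure
#'
#' Parameters of the linear-quadratic (LQ) cell-survival model and the
#' HU-attenuation conversion. `alpha` (Gy^-1) and `alpha_beta` (the
#' alpha/beta ratio, Gy) are the LQ radiosensitivity parameters; the
#' defaults (0.33 Gy^-1, 10 Gy) are nominal literature values for
#' head-and-neck tumors. The per-voxel dose per fraction is
#' `d = D / n_fractions`. `mu_water` is the linear attenuation coefficient
#' of water; it cancels in the HU round trip, so any consistent unit works.
#'
#' @param alpha LQ alpha, Gy^-1, default 0.33.
#' @param alpha_beta alpha/beta ratio, Gy, default 10.
#' @param n_fractions number of treatment fractions, default 35.
#' @param mu_water attenuation coefficient of water, default 0.1928.
#' @return An object of class `radiobiology_params`.
#' @export
radiobiology_params <- function(alpha = 0.33, alpha_beta = 10,
                                n_fractions = 35, mu_water = 0.1928) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (!is.numeric(alpha_beta) || alpha_beta <= 0)
    stop("alpha_beta must be > 0", call. = FALSE)
  if (!is.numeric(n_fractions) || n_fractions < 1)
    stop("n_fractions must be >= 1", call. = FALSE)
  if (!is.numeric(mu_water) || mu_water <= 0)
    stop("mu_water must be > 0", call. = FALSE)
  structure(list(alpha = alpha, alpha_beta = alpha_beta,
                 n_fractions = n_fractions, mu_water = mu_water),
            class = "radiobiology_params")
}

#' @export
print.radiobiology_params <- function(x, ...) {
  cat(sprintf("<radiobiology_params> alpha = %g Gy^-1, alpha/beta = %g Gy, %g fractions, mu_W = %g\n",
              x$alpha, x$alpha_beta, x$n_fractions, x$mu_water))
  invisible(x)
}

#' Convert CT numbers to linear attenuation coefficients
#'
#' `mu = I0 * mu_W / 1000 + mu_W`: air (-1000 HU) maps to 0 and water
#' (0 HU) maps to `mu_W`.
#'
#' @param I0 CT numbers (HU), any shape.
#' @param p a [radiobiology_params()].
#' @return Attenuation coefficients, same shape.
#' @export
hu_to_mu <- function(I0, p = radiobiology_params()) {
  I0 * p$mu_water / 1000 + p$mu_water
}

#' Convert attenuation coefficients to CT numbers
#'
#' Exact inverse of [hu_to_mu()]: `I = 1000 * (mu - mu_W) / mu_W`.
#'
#' @param mu attenuation coefficients.
#' @param p a [radiobiology_params()].
#' @return CT numbers (HU).
#' @export
mu_to_hu <- function(mu, p = radiobiology_params()) {
  1000 * (mu - p$mu_water) / p$mu_water
}

#' LQ cell survival fraction
#'
#' `SF = exp(-alpha * D * (1 + d / (alpha/beta)))` with dose per fraction
#' `d = D / n_fractions`; cell proliferation over the treatment course is
#' neglected. Strictly decreasing in dose, with `SF(0) = 1`.
#'
#' @param D total absorbed dose per voxel, Gy (non-negative).
#' @param p a [radiobiology_params()].
#' @return Survival fractions in (0, 1].
#' @export
survival_fraction <- function(D, p = radiobiology_params()) {
  if (any(!is.finite(D)) || any(D < 0))
    stop("dose must be finite and non-negative", call. = FALSE)
  d <- D / p$n_fractions
  exp(-p$alpha * D * (1 + d / p$alpha_beta))
}

#' LQ intensity modification of a tumor voxel
#'
#' Converts the CT number to attenuation, scales by the survival fraction
#' (attenuation is proportional to the surviving cell count), and converts
#' back: `IS = ((I0 * mu_W/1000 + mu_W) * SF - mu_W) * 1000 / mu_W`, which
#' is algebraically `(I0 + 1000) * SF - 1000`. Total kill (`SF = 0`) maps
#' any voxel to air.
#'
#' @param I0 CT numbers (HU).
#' @param SF survival fractions (same shape or scalar).
#' @param p a [radiobiology_params()].
#' @return Modified CT numbers (HU).
#' @export
modify_intensity <- function(I0, SF, p = radiobiology_params()) {
  mu_to_hu(hu_to_mu(I0, p) * SF, p)
}

#' Resample a dose grid onto a CT grid
#'
#' Trilinear interpolation in world (DICOM patient) coordinates, so that
#' each CT voxel receives the planned dose at its own position; positions
#' outside the dose extent receive 0 Gy.
#'
#' @param dose a [volume_image()] of absorbed dose (Gy), possibly on a
#'   coarser offset grid.
#' @param ct a [volume_image()] providing the target grid.
#' @return A [volume_image()] of dose (Gy) on the CT grid.
#' @export
resample_dose_to_ct <- function(dose, ct) {
  stopifnot(inherits(dose, "volume_image"), inherits(ct, "volume_image"))
  q <- world_to_voxel(dose, voxel_world_coords(ct))
  vals <- cpp_sample3(as.numeric(dose$values), dim(dose$values), q, 1L, 0)
  volume_image(array(pmax(vals, 0), dim(ct$values)), ct$spacing, ct$origin)
}

#' Scale tumor intensities to match the posttreatment intensity sum
#'
#' Works on the offset scale `value + 1000` (proportional to attenuation,
#' on which the HU conversion is linear; raw HU sums can be negative or
#' zero, which would make a multiplicative match ill-defined). With
#' `S0 = sum(modified + 1000)` over the tumor mask and
#' `S = sum(static + 1000)` over the same mask, every tumor voxel's offset
#' value is multiplied by `S / S0`, so the tumor-region offset sum equals
#' `S` exactly. Non-tumor voxels are untouched. This absorbs residual
#' discrepancy from uncertain radiobiology parameters.
#'
#' @param modified LQ-modified planning image ([volume_image()]).
#' @param tumor_mask non-empty [binary_mask()] on the same grid.
#' @param static posttreatment image on the same grid (after rigid
#'   alignment).
#' @return A [volume_image()].
#' @export
scale_tumor <- function(modified, tumor_mask, static) {
  stopifnot(inherits(modified, "volume_image"), inherits(tumor_mask, "binary_mask"),
            inherits(static, "volume_image"))
  stop_if_incompatible(modified, tumor_mask, "image and tumor mask")
  stop_if_incompatible(modified, static, "planning and posttreatment images")
  sel <- tumor_mask$values
  if (!any(sel)) stop("tumor mask is empty", call. = FALSE)
  S0 <- sum(modified$values[sel] + 1000)
  if (S0 <= 0)
    stop("degenerate tumor region: modified offset intensity sum is not positive",
         call. = FALSE)
  S <- sum(static$values[sel] + 1000)
  modified$values[sel] <- (modified$values[sel] + 1000) * (S / S0) - 1000
  modified
}

#' Intensity-modification procedure (IMP)
#'
#' The full per-voxel pipeline restoring intensity correspondence between a
#' planning CT and a posttreatment CT in the presence of radiation-induced
#' tumor shrinkage: the planned dose is resampled onto the CT grid, each
#' tumor voxel's survival fraction is computed with the LQ model, its
#' intensity is reduced accordingly, and the tumor region is rescaled so
#' its offset intensity sum matches the posttreatment image over the same
#' region. All non-tumor voxels are unchanged.
#'
#' @param planning planning CT ([volume_image()], rigidly aligned to
#'   `static`).
#' @param dose planned dose ([volume_image()], Gy, own geometry).
#' @param tumor planning tumor [binary_mask()] on the planning grid.
#' @param static posttreatment CT on the planning grid.
#' @param p a [radiobiology_params()].
#' @return The modified planning CT ([volume_image()]).
#' @export
apply_imp <- function(planning, dose, tumor, static, p = radiobiology_params()) {
  stopifnot(inherits(planning, "volume_image"), inherits(tumor, "binary_mask"))
  stop_if_incompatible(planning, tumor, "planning image and tumor mask")
  stop_if_incompatible(planning, static, "planning and posttreatment images")
  dose_ct <- resample_dose_to_ct(dose, planning)
  sel <- tumor$values
  if (!any(sel)) stop("tumor mask is empty", call. = FALSE)
  SF <- survival_fraction(dose_ct$values[sel], p)
  # Work on the offset scale throughout: converting the LQ-modified values
  # back to HU before scaling would round tiny surviving fractions into
  # exactly -1000 HU (offset 0) and lose the relative weights the scale
  # step needs. o0 = (I0 + 1000) * SF is the attenuation-proportional
  # offset value; the sum match then fixes the absolute level.
  o0 <- hu_to_mu(planning$values[sel], p) * SF * (1000 / p$mu_water)
  S0 <- sum(o0)
  if (S0 <= 0)
    stop("degenerate tumor region: modified offset intensity sum is not positive",
         call. = FALSE)
  S <- sum(static$values[sel] + 1000)
  modified <- planning
  modified$values[sel] <- o0 * (S / S0) - 1000
  modified
}
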