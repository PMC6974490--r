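# Standardized uptake value maps from the late static window.

#' SUV map from a static activity image
#'
#' \code{SUV = C / (ID / BW)} with C in kBq/ml, injected dose ID in MBq and
#' body weight BW in kg, as conventionally printed. With the implicit
#' 1 g/ml tissue density this equals the usual dimensionless SUV (the
#' kBq/MBq and kg/g factors of 1000 cancel). The static image is typically
#' the 70-90 min window average of the decay-corrected dynamic scan
#' (see [windowAverage()]).
#'
#' @param static 3D activity array (kBq/ml).
#' @param injectedDoseMBq injected dose in MBq (> 0).
#' @param bodyWeightKg body weight in kg (> 0).
#' @param window optional window bounds (minutes) recorded in provenance.
#' @return A [ParametricMap-class] with quantity "SUV".
#' @export
suvMap <- function(static, injectedDoseMBq, bodyWeightKg, window = c(70, 90)) {
  if (injectedDoseMBq <= 0) stop("injected dose must be > 0")
  if (bodyWeightKg <= 0) stop("body weight must be > 0")
  stopifnot(length(dim(static)) == 3L)
  new("ParametricMap", values = static / (injectedDoseMBq / bodyWeightKg),
      quantity = "SUV", units = "unitless",
      provenance = list(stage = "suv", injected_dose_MBq = injectedDoseMBq,
                        body_weight_kg = bodyWeightKg,
                        window_min = window, density_g_per_ml = 1))
}

#' SUVR map: SUV relative to a reference region
#'
#' Divides the SUV map by its mean over the reference mask. Provided for
#' completeness: a reference-normalized SUVR is only meaningful when the
#' reference region's uptake is comparable across the groups being studied,
#' which must be checked beforehand; the provenance carries a warning flag
#' to that effect.
#'
#' @param suv a [ParametricMap-class] with quantity "SUV".
#' @param refMask 3D logical array, nonempty, with positive mean SUV.
#' @return A [ParametricMap-class] with quantity "SUVR".
#' @export
suvrMap <- function(suv, refMask) {
  stopifnot(is(suv, "ParametricMap"), suv@quantity == "SUV")
  if (!any(refMask)) stop("reference mask is empty")
  m <- mean(suv@values[refMask], na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stop("reference region mean SUV must be > 0")
  new("ParametricMap", values = suv@values / m, quantity = "SUVR",
      units = "unitless",
      provenance = c(suv@provenance,
                     list(stage = "suvr", ref_mean_suv = m,
                          ref_n_voxels = sum(refMask),
                          caveat = "verify reference-region comparability between groups before using SUVR")))
}
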