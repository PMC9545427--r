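#' Erythrocyte water fraction of whole blood
#'
#' Fraction of whole-blood water residing in erythrocytes:
#' `f_e = W_RBC * Hct / (W_RBC * Hct + W_plasma * (1 - Hct))`. Strictly
#' increasing in hematocrit, 0 at Hct = 0 and 1 at Hct = 1.
#'
#' @param hct Hematocrit, 0-1 (vectorised).
#' @param w_rbc Water volume fraction of erythrocytes (default 0.70).
#' @param w_plasma Water volume fraction of plasma (default 0.95).
#' @return Water fraction in \[0, 1\].
#' @export
erythrocyte_water_fraction <- function(hct, w_rbc = 0.70, w_plasma = 0.95) {
  stopifnot(all(hct >= 0), all(hct <= 1), w_rbc > 0, w_rbc <= 1,
            w_plasma > 0, w_plasma <= 1)
  w_rbc * hct / (w_rbc * hct + w_plasma * (1 - hct))
}

#' Field-dependent blood model parameters
#'
#' Evaluates the four affine-in-B0 blood model parameters at a field strength.
#'
#' @param b0 Main magnetic field, tesla.
#' @param coeffs A [blood_coefficients()] object.
#' @return A list of class `"field_params"` with `r1_eox`, `r1_p` (s^-1),
#'   `r1_dhb` (s^-1 L mmol^-1), `r1_pox` (s^-1 mmHg^-1) and `b0`.
#' @export
field_params <- function(b0, coeffs) {
  stopifnot(is.numeric(b0), length(b0) == 1L, b0 >= 0)
  vals <- list(
    r1_eox = coeffs$r1eox_b0 + coeffs$r1eox_b1 * b0,
    r1_p   = coeffs$r1p_b0 + coeffs$r1p_b1 * b0,
    r1_dhb = coeffs$r1dhb_b0 + coeffs$r1dhb_b1 * b0,
    r1_pox = coeffs$r1pox_b0 + coeffs$r1pox_b1 * b0
  )
  neg <- names(vals)[unlist(vals) < 0]
  if (length(neg) > 0) {
    stop("blood model parameter(s) ", paste(neg, collapse = ", "),
         " evaluate negative at b0 = ", b0, " T", call. = FALSE)
  }
  structure(c(vals, list(b0 = b0)), class = "field_params")
}

#' Longitudinal relaxation rate of whole blood
#'
#' Two-compartment (erythrocyte / plasma) blood R1 model:
#' `R1_b = f_e * (R1eox + r1dHb * [Hb] * (1 - SO2)) +
#'  (1 - f_e) * (R1p + r1pOx * PO2)`,
#' where the saturation follows the blood-model Hill curve
#' (`p50_blood`, `hill_n_blood` from the coefficient set) and `[Hb]` is the
#' mean corpuscular hemoglobin concentration (`hb_molar`, 5.15 mmol
#' tetramer/L). Deoxyhemoglobin raises R1 (paramagnetic), so oxygenation
#' lowers the erythrocyte term while dissolved oxygen raises the plasma term.
#'
#' @param po2 Blood oxygen tension, mmHg (vectorised, >= 0).
#' @param hct Hematocrit, 0-1.
#' @param b0 Main magnetic field, tesla.
#' @param coeffs A [blood_coefficients()] object.
#' @param constants Constant set from [ox_constants()] (supplies `w_rbc`,
#'   `w_plasma`, `hb_molar`).
#' @return Blood R1 in s^-1.
#' @export
blood_r1 <- function(po2, hct, b0, coeffs, constants = ox_constants()) {
  if (any(po2 < 0)) stop("po2 must be non-negative", call. = FALSE)
  fp <- field_params(b0, coeffs)
  fe <- erythrocyte_water_fraction(hct, constants$w_rbc, constants$w_plasma)
  so2 <- hill_saturation(po2, coeffs$p50_blood, coeffs$hill_n_blood)
  fe * (fp$r1_eox + fp$r1_dhb * constants$hb_molar * (1 - so2)) +
    (1 - fe) * (fp$r1_p + fp$r1_pox * po2)
}

#' Hyperoxia-induced change in blood R1
#'
#' `delta_r1_blood = blood_r1(po2_ox) - blood_r1(po2_air)`: antisymmetric
#' under swapping the states. The sign balances two competing effects -
#' falling deoxyhemoglobin (negative contribution) against rising dissolved
#' oxygen (positive) - so venous blood with a modest tension change typically
#' shows a negative change.
#'
#' @param po2_air,po2_ox Blood oxygen tensions in the air and hyperoxic
#'   states, mmHg.
#' @inheritParams blood_r1
#' @return Change in R1, s^-1.
#' @export
delta_r1_blood <- function(po2_air, po2_ox, hct, b0, coeffs,
                           constants = ox_constants()) {
  blood_r1(po2_ox, hct, b0, coeffs, constants) -
    blood_r1(po2_air, hct, b0, coeffs, constants)
}

#' Longitudinal relaxivity of dissolved oxygen
#'
#' Lorentzian-plus-temperature model
#' `r1_Ox = c1 / (1 + c2 * B0^2) + c3 + c_temp * T`; with physically fitted
#' coefficients it decreases with field strength.
#'
#' @param b0 Main magnetic field, tesla (> 0, vectorised).
#' @param temperature Temperature, degrees C (default 37).
#' @param coeffs A [relaxivity_coefficients()] object.
#' @return r1_Ox in s^-1 mmHg^-1.
#' @export
oxygen_relaxivity <- function(b0, temperature = 37, coeffs) {
  if (any(b0 <= 0)) stop("b0 must be positive", call. = FALSE)
  out <- coeffs$c1 / (1 + coeffs$c2 * b0^2) + coeffs$c3 +
    coeffs$c_temp * temperature
  if (any(out <= 0)) {
    stop("r1_Ox evaluates non-positive at b0 = ", b0[which(out <= 0)[1]],
         " T, temperature = ", temperature, " C", call. = FALSE)
  }
  out
}

#' Hyperoxia-induced change in tissue R1
#'
#' In the tissue compartment the only paramagnetic species changing between
#' gas states is dissolved oxygen, so
#' `delta_r1_tissue = r1_Ox(B0, T) * delta_po2_t`.
#'
#' @param delta_po2_t Change in mean tissue oxygen tension, mmHg.
#' @param b0 Main magnetic field, tesla.
#' @param temperature Temperature, degrees C (default 37).
#' @param coeffs A [relaxivity_coefficients()] object.
#' @return Change in tissue R1, s^-1 (linear in `delta_po2_t`).
#' @export
delta_r1_tissue <- function(delta_po2_t, b0, temperature = 37, coeffs) {
  oxygen_relaxivity(b0, temperature, coeffs) * delta_po2_t
}
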