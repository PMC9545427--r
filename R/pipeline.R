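#' Define a model scenario
#'
#' One evaluation of the voxel model is described by the five independent
#' physiological/experimental variables (field strength, hematocrit, oxygen
#' extraction fraction, blood volume fraction, critical tension) plus the gas
#' challenge (arterial tensions on air and on supplemental oxygen, default
#' 90 -> 600 mmHg) and the arterial share of the blood volume (default 0.5,
#' i.e. equal arterial and venous fractions).
#'
#' @param b0 Main magnetic field, tesla.
#' @param hct Hematocrit, 0-1.
#' @param oef Oxygen extraction fraction, \[0, 1).
#' @param bv Blood volume fraction, (0, 1\].
#' @param p_crit Critical tension for Michaelis-Menten consumption, mmHg.
#'   May be `NA` for pure-blood scenarios (no tissue compartment).
#' @param pao2_air Arterial PO2 breathing air, mmHg (default 90).
#' @param pao2_ox Arterial PO2 on the hyperoxic gas, mmHg (default 600; must
#'   be >= `pao2_air`).
#' @param arterial_fraction Arterial share of the blood volume, 0-1
#'   (default 0.5).
#' @param tissue_type Label, either a preset name or `"custom"`.
#' @return A one-row tibble of class `"ox_scenario"`.
#' @examples
#' scenario(b0 = 1.5, hct = 0.42, oef = 0.34, bv = 0.045, p_crit = 2.5)
#' @export
scenario <- function(b0, hct, oef, bv, p_crit = 1,
                     pao2_air = 90, pao2_ox = 600,
                     arterial_fraction = 0.5, tissue_type = "custom") {
  check_scalar <- function(x, nm, lo, hi, lo_open = FALSE, hi_open = FALSE,
                           na_ok = FALSE) {
    if (na_ok && is.na(x)) return(invisible())
    ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
      (if (lo_open) x > lo else x >= lo) &&
      (if (hi_open) x < hi else x <= hi)
    if (!ok) {
      stop(sprintf("scenario field '%s' = %s outside its domain [%g, %g]",
                   nm, format(x), lo, hi), call. = FALSE)
    }
  }
  check_scalar(b0, "b0", 0, Inf, lo_open = TRUE)
  check_scalar(hct, "hct", 0, 1)
  check_scalar(oef, "oef", 0, 1, hi_open = TRUE)
  check_scalar(bv, "bv", 0, 1, lo_open = TRUE)
  check_scalar(p_crit, "p_crit", 0, Inf, na_ok = TRUE)
  check_scalar(pao2_air, "pao2_air", 0, Inf)
  check_scalar(pao2_ox, "pao2_ox", pao2_air, Inf)
  check_scalar(arterial_fraction, "arterial_fraction", 0, 1)
  out <- tibble::tibble(
    b0 = b0, hct = hct, oef = oef, bv = bv, p_crit = p_crit,
    pao2_air = pao2_air, pao2_ox = pao2_ox,
    arterial_fraction = arterial_fraction, tissue_type = tissue_type
  )
  class(out) <- c("ox_scenario", class(out))
  out
}

#' Blood-volume-weighted voxel R1 change
#'
#' Combines compartment R1 changes with blood-volume weights:
#' `delta_r1_voxel = BV * f_A * dR1_A + (1 - BV) * dR1_T +
#'  BV * (1 - f_A) * dR1_V` with `f_A` the arterial fraction - a convex
#' combination of the three compartment changes. Compartments with zero
#' weight may be `NA` (e.g. no tissue compartment when `bv = 1`).
#'
#' @param bv Blood volume fraction, 0-1.
#' @param d_arterial,d_tissue,d_venous Compartment R1 changes, s^-1.
#' @param arterial_fraction Arterial share of blood volume (default 0.5).
#' @return Voxel R1 change, s^-1.
#' @examples
#' delta_r1_voxel(0.1, 0.1, 0.02, -0.04)  # 0.021
#' @export
delta_r1_voxel <- function(bv, d_arterial, d_tissue, d_venous,
                           arterial_fraction = 0.5) {
  stopifnot(all(bv >= 0), all(bv <= 1),
            all(arterial_fraction >= 0), all(arterial_fraction <= 1))
  w_a <- bv * arterial_fraction
  w_t <- 1 - bv
  w_v <- bv * (1 - arterial_fraction)
  term <- function(w, d) ifelse(w == 0, 0, w * d)
  term(w_a, d_arterial) + term(w_t, d_tissue) + term(w_v, d_venous)
}

#' Run the four-step voxel model for one scenario
#'
#' Executes the full pipeline: (1) capillary oxygen profiles for the air and
#' hyperoxic states, holding the *absolute* extraction fixed at the
#' normoxic value `OEF * CaO2(air)` (tissue consumption is unchanged by the
#' gas challenge); (2) Krogh cylinder geometry from blood volume, maximum
#' consumption rate from the normoxic OEF, tissue oxygen fields in both
#' states and their mean-tension difference; (3) blood R1 changes at the
#' arterial-end (z = 0) and venous-end (z = L) tensions plus the tissue R1
#' change via the oxygen relaxivity; (4) the blood-volume-weighted voxel R1
#' change. Deterministic: identical inputs give identical outputs.
#'
#' For `bv = 1` (pure blood, e.g. the vascular periphery preset) the tissue
#' path is skipped and the tissue change is `NA` with weight zero.
#'
#' @param scn A [scenario()] (one row).
#' @param constants Constant set from [ox_constants()].
#' @param blood_coeffs A [blood_coefficients()] object.
#' @param relax_coeffs A [relaxivity_coefficients()] object.
#' @param n_z,n_r Axial and radial grid sizes (defaults 51 and 101).
#' @param profile_mode Capillary decline mode, `"content_linear"` (default)
#'   or `"so2_linear"`; see [capillary_profile()].
#' @return An object of class `"voxel_result"`: a list with the per-
#'   compartment changes (`delta_r1_arterial`, `delta_r1_venous`,
#'   `delta_r1_tissue`, `delta_r1_voxel`, s^-1), `delta_po2_tissue` (mmHg),
#'   venous tensions in both states, `m0`, `r_t`, diagnostics (clamped
#'   fraction, solver iterations) and the scenario. Use [tidy()] for a
#'   one-row tibble or [glance()] for the headline numbers.
#' @export
run_scenario <- function(scn, constants = ox_constants(),
                         blood_coeffs, relax_coeffs,
                         n_z = 51, n_r = 101,
                         profile_mode = c("content_linear", "so2_linear")) {
  profile_mode <- match.arg(profile_mode)
  stopifnot(inherits(scn, "ox_scenario"), nrow(scn) == 1L)
  s <- as.list(scn)

  step <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop("step ", label, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # Step 1: capillary profiles, air and oxygen, fixed absolute extraction
  sao2_air <- hill_saturation(s$pao2_air, constants$p50_tissue, constants$hill_n)
  ca_o2_air <- o2_content(s$pao2_air, sao2_air, s$hct, constants)
  extraction <- s$oef * ca_o2_air
  prof_air <- step("1 (air capillary profile)", capillary_profile(
    s$pao2_air, s$hct, extraction = extraction, n_z = n_z,
    constants = constants, mode = profile_mode, state_label = "air"))
  prof_ox <- step("1 (oxygen capillary profile)", capillary_profile(
    s$pao2_ox, s$hct, extraction = extraction, n_z = n_z,
    constants = constants, mode = profile_mode, state_label = "oxygen"))

  venous_po2_air <- prof_air$po2_mmhg[n_z]
  venous_po2_ox <- prof_ox$po2_mmhg[n_z]

  # Step 2: tissue oxygenation (skipped for pure-blood voxels)
  has_tissue <- s$bv < 1
  if (has_tissue) {
    geometry <- step("2 (geometry)", capillary_geometry(s$bv, constants))
    m0 <- step("2 (consumption)", max_consumption_from_oef(
      s$oef, s$hct, sao2_air, geometry, constants))
    p_crit <- if (is.na(s$p_crit)) 0 else s$p_crit
    consumption <- consumption_model(m0, p_crit, constants = constants)
    field_air <- step("2 (air tissue field)",
                      tissue_field(prof_air, consumption, geometry, n_r = n_r))
    field_ox <- step("2 (oxygen tissue field)",
                     tissue_field(prof_ox, consumption, geometry, n_r = n_r))
    d_po2_t <- as.numeric(delta_tissue_po2(field_air, field_ox))
    clamped <- max(field_air$clamped_fraction, field_ox$clamped_fraction)
    iters <- max(field_air$iterations, field_ox$iterations)
    r_t <- geometry$r_t
  } else {
    m0 <- NA_real_
    d_po2_t <- NA_real_
    clamped <- NA_real_
    iters <- NA_real_
    r_t <- NA_real_
  }

  # Step 3: compartment R1 changes
  d_arterial <- step("3 (arterial blood)", delta_r1_blood(
    s$pao2_air, s$pao2_ox, s$hct, s$b0, blood_coeffs, constants))
  d_venous <- step("3 (venous blood)", delta_r1_blood(
    venous_po2_air, venous_po2_ox, s$hct, s$b0, blood_coeffs, constants))
  d_tissue <- if (has_tissue) {
    step("3 (tissue)", delta_r1_tissue(
      d_po2_t, s$b0, constants$temperature, relax_coeffs))
  } else {
    NA_real_
  }

  # Step 4: blood-volume weighting
  d_voxel <- step("4 (voxel weighting)", delta_r1_voxel(
    s$bv, d_arterial, d_tissue, d_venous, s$arterial_fraction))

  structure(
    list(
      delta_r1_arterial = d_arterial,
      delta_r1_venous = d_venous,
      delta_r1_tissue = d_tissue,
      delta_r1_voxel = d_voxel,
      delta_po2_tissue = d_po2_t,
      venous_po2_air = venous_po2_air,
      venous_po2_ox = venous_po2_ox,
      m0 = m0, r_t = r_t,
      clamped_fraction = clamped,
      solver_iterations = iters,
      scenario = scn,
      profile_mode = profile_mode
    ),
    class = "voxel_result"
  )
}

#' @export
print.voxel_result <- function(x, ...) {
  s <- as.list(x$scenario)
  cat(sprintf(
    "<voxel_result> %s at %g T (Hct %.3g, OEF %.3g, BV %.3g, PaO2 %g -> %g mmHg)\n",
    s$tissue_type, s$b0, s$hct, s$oef, s$bv, s$pao2_air, s$pao2_ox))
  cat(sprintf("  dR1 arterial %+.5f  venous %+.5f  tissue %s  voxel %+.5f s^-1\n",
              x$delta_r1_arterial, x$delta_r1_venous,
              if (is.na(x$delta_r1_tissue)) "    NA   " else
                sprintf("%+.5f", x$delta_r1_tissue),
              x$delta_r1_voxel))
  if (!is.na(x$delta_po2_tissue)) {
    cat(sprintf("  tissue dPO2 %.3f mmHg, venous PO2 %.2f -> %.2f mmHg\n",
                x$delta_po2_tissue, x$venous_po2_air, x$venous_po2_ox))
  }
  invisible(x)
}

#' Tidy a voxel result into a one-row tibble
#'
#' @param x A `"voxel_result"` from [run_scenario()].
#' @param ... Unused.
#' @return A one-row tibble: scenario fields followed by all result fields.
#' @export
tidy.voxel_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::as_tibble(x$scenario),
    tibble::tibble(
      delta_r1_arterial = x$delta_r1_arterial,
      delta_r1_venous = x$delta_r1_venous,
      delta_r1_tissue = x$delta_r1_tissue,
      delta_r1_voxel = x$delta_r1_voxel,
      delta_po2_tissue = x$delta_po2_tissue,
      venous_po2_air = x$venous_po2_air,
      venous_po2_ox = x$venous_po2_ox,
      m0 = x$m0, r_t = x$r_t,
      clamped_fraction = x$clamped_fraction,
      solver_iterations = x$solver_iterations
    )
  )
}

#' Headline numbers of a voxel result
#'
#' @param x A `"voxel_result"` from [run_scenario()].
#' @param ... Unused.
#' @return A one-row tibble with the voxel R1 change, its three compartment
#'   contributions and the tissue tension change.
#' @export
glance.voxel_result <- function(x, ...) {
  tibble::tibble(
    delta_r1_voxel = x$delta_r1_voxel,
    delta_r1_arterial = x$delta_r1_arterial,
    delta_r1_venous = x$delta_r1_venous,
    delta_r1_tissue = x$delta_r1_tissue,
    delta_po2_tissue = x$delta_po2_tissue
  )
}
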