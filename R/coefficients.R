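#' Blood relaxometry model coefficients
#'
#' The two-compartment blood R1 model expresses four field-dependent
#' parameters as straight lines in B0: the relaxation rate of fully
#' oxygenated erythrocytes `R1eox`, the plasma relaxation rate `R1p`, the
#' molar relaxivity of deoxyhemoglobin `r1dHb`, and the relaxivity of oxygen
#' dissolved in plasma `r1pOx`. The slopes and intercepts were fitted in a
#' separate relaxometry study and are therefore *inputs* to this package:
#' transcribe them from that publication into your configuration. A clearly
#' labelled synthetic placeholder set is available for testing via
#' [placeholder_blood_coefficients()].
#'
#' @param r1eox_b0,r1eox_b1 Intercept (s^-1) and slope (s^-1 T^-1) of R1eox(B0).
#' @param r1p_b0,r1p_b1 Intercept and slope of R1p(B0), same units.
#' @param r1dhb_b0,r1dhb_b1 Intercept (s^-1 L mmol^-1) and slope
#'   (s^-1 L mmol^-1 T^-1) of r1dHb(B0).
#' @param r1pox_b0,r1pox_b1 Intercept (s^-1 mmHg^-1) and slope
#'   (s^-1 mmHg^-1 T^-1) of r1pOx(B0).
#' @param p50_blood Half-saturation tension of the hemoglobin dissociation
#'   curve *as used inside the blood model fit*, mmHg. May legitimately differ
#'   from the tissue-transport `p50_tissue`.
#' @param hill_n_blood Hill exponent of the blood-model dissociation curve.
#' @param provenance Either `"user"` or `"placeholder"`; recorded in output
#'   manifests so that placeholder-driven results are never mistaken for
#'   science-grade output.
#'
#' @details Validation requires each of the four lines to evaluate strictly
#' positive for B0 in \[1.5, 7\] T (it suffices to check the interval
#' endpoints of a straight line).
#'
#' @return A named list of class `"blood_coefficients"`.
#' @export
blood_coefficients <- function(r1eox_b0, r1eox_b1,
                               r1p_b0, r1p_b1,
                               r1dhb_b0, r1dhb_b1,
                               r1pox_b0, r1pox_b1,
                               p50_blood = 37, hill_n_blood = 2.7,
                               provenance = "user") {
  betas <- list(
    r1eox_b0 = r1eox_b0, r1eox_b1 = r1eox_b1,
    r1p_b0 = r1p_b0, r1p_b1 = r1p_b1,
    r1dhb_b0 = r1dhb_b0, r1dhb_b1 = r1dhb_b1,
    r1pox_b0 = r1pox_b0, r1pox_b1 = r1pox_b1
  )
  for (nm in names(betas)) {
    v <- betas[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("blood coefficient '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  if (!is.numeric(p50_blood) || p50_blood <= 0) {
    stop("p50_blood must be positive", call. = FALSE)
  }
  if (!is.numeric(hill_n_blood) || hill_n_blood <= 0) {
    stop("hill_n_blood must be positive", call. = FALSE)
  }
  coeffs <- structure(
    c(betas, list(p50_blood = p50_blood, hill_n_blood = hill_n_blood,
                  provenance = provenance)),
    class = "blood_coefficients"
  )
  # each parameter is affine in b0, so its sign on [1.5, 7] T is decided at
  # the endpoints; relaxation rates must be positive, relaxivities may
  # degenerate to zero (po2-independent model) but never negative
  for (par in c("r1eox", "r1p", "r1dhb", "r1pox")) {
    b0i <- coeffs[[paste0(par, "_b0")]]
    b1i <- coeffs[[paste0(par, "_b1")]]
    vals <- b0i + b1i * c(1.5, 7)
    floor_excl <- par %in% c("r1eox", "r1p")
    if (any(if (floor_excl) vals <= 0 else vals < 0)) {
      bad <- c(1.5, 7)[if (floor_excl) vals <= 0 else vals < 0][1]
      stop(sprintf(
        "blood model parameter %s(B0) is %s at B0 = %g T (%.4g); parameters must be %s over [1.5, 7] T",
        par, if (floor_excl) "non-positive" else "negative", bad, min(vals),
        if (floor_excl) "positive" else "non-negative"), call. = FALSE)
    }
  }
  coeffs
}

#' Load blood model coefficients from configuration
#'
#' Reads the `blood_coefficients` section of a JSON configuration (or a named
#' list). All eight slope/intercept values must be present: they are
#' scientific inputs transcribed from the blood relaxometry publication and
#' have no silent defaults.
#'
#' @param config_source Path to a JSON file or a named list.
#' @return A `"blood_coefficients"` object.
#' @export
load_blood_coefficients <- function(config_source) {
  cfg <- read_config_section(config_source, "blood_coefficients")
  required <- c("r1eox_b0", "r1eox_b1", "r1p_b0", "r1p_b1",
                "r1dhb_b0", "r1dhb_b1", "r1pox_b0", "r1pox_b1")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop("missing blood model coefficient(s): ",
         paste(missing, collapse = ", "),
         ". Transcribe the slope/intercept values from the cited blood ",
         "relaxometry publication into the 'blood_coefficients' section, ",
         "or use placeholder_blood_coefficients() for testing only.",
         call. = FALSE)
  }
  cfg$provenance <- cfg$provenance %||% "user"
  keep <- intersect(c(required, "p50_blood", "hill_n_blood", "provenance"),
                    names(cfg))
  do.call(blood_coefficients, cfg[keep])
}

#' Synthetic placeholder blood coefficients (testing only)
#'
#' Returns a blood coefficient set constructed from public literature anchors
#' (deoxyhemoglobin relaxivity at 1.5 and 4.7 T, field-dependent plasma and
#' erythrocyte relaxation rates, oxygen relaxivity in the 1.5-4e-4
#' s^-1 mmHg^-1 envelope). These values are *synthetic placeholders*: they
#' reproduce the qualitative physics (positive, dHb relaxivity rising and
#' everything else falling with B0) but are not the fitted coefficients of the
#' blood relaxometry publication. A warning marks every use.
#'
#' @param quiet Suppress the provenance warning (used internally by code that
#'   has already warned once).
#' @return A `"blood_coefficients"` object with `provenance = "placeholder"`.
#' @export
placeholder_blood_coefficients <- function(quiet = FALSE) {
  if (!quiet) {
    warning("using synthetic placeholder blood coefficients - for testing only, ",
            "not for science-grade predictions", call. = FALSE)
  }
  blood_coefficients(
    r1eox_b0 = 0.87, r1eox_b1 = -0.080,
    r1p_b0   = 0.82, r1p_b1   = -0.053,
    r1dhb_b0 = 0.00, r1dhb_b1 = 0.075,
    r1pox_b0 = 3.5e-4, r1pox_b1 = -3.0e-5,
    p50_blood = 37, hill_n_blood = 2.7,
    provenance = "placeholder"
  )
}

#' Oxygen relaxivity model coefficients
#'
#' The longitudinal relaxivity of dissolved molecular oxygen follows a
#' Lorentzian-plus-temperature model,
#' `r1_Ox(B0, T) = c1 / (1 + c2 * B0^2) + c3 + c_temp * T`, fitted in a
#' separate compilation study. As with the blood model, the fitted constants
#' are configuration inputs; [placeholder_relaxivity_coefficients()] provides
#' a synthetic set for tests.
#'
#' @param c1,c2,c3,c_temp Fitted constants; units such that `r1_Ox` is
#'   s^-1 mmHg^-1 with B0 in tesla and temperature in degrees C.
#' @param provenance `"user"` or `"placeholder"`.
#' @details Validation requires the resulting relaxivity at 37 C to be
#'   positive and non-increasing in B0 over \[1.5, 7\] T.
#' @return A named list of class `"relaxivity_coefficients"`.
#' @export
relaxivity_coefficients <- function(c1, c2, c3, c_temp, provenance = "user") {
  for (nm in c("c1", "c2", "c3", "c_temp")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("relaxivity coefficient '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  coeffs <- structure(
    list(c1 = c1, c2 = c2, c3 = c3, c_temp = c_temp, provenance = provenance),
    class = "relaxivity_coefficients"
  )
  b0_grid <- seq(1.5, 7, by = 0.25)
  vals <- c1 / (1 + c2 * b0_grid^2) + c3 + c_temp * 37
  if (any(vals <= 0)) {
    stop("r1_Ox evaluates non-positive at B0 = ",
         b0_grid[which(vals <= 0)[1]], " T (37 C); check coefficients",
         call. = FALSE)
  }
  if (any(diff(vals) > 1e-15)) {
    stop("r1_Ox must be monotonically non-increasing in B0 over [1.5, 7] T",
         call. = FALSE)
  }
  coeffs
}

#' Load oxygen relaxivity coefficients from configuration
#'
#' @param config_source Path to a JSON file or a named list with a
#'   `relaxivity_coefficients` section (or the four constants at top level).
#' @return A `"relaxivity_coefficients"` object.
#' @export
load_relaxivity_coefficients <- function(config_source) {
  cfg <- read_config_section(config_source, "relaxivity_coefficients")
  required <- c("c1", "c2", "c3", "c_temp")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop("missing oxygen relaxivity coefficient(s): ",
         paste(missing, collapse = ", "),
         ". Transcribe c1, c2, c3, c_temp from the cited oxygen relaxivity ",
         "publication, or use placeholder_relaxivity_coefficients() for ",
         "testing only.", call. = FALSE)
  }
  cfg$provenance <- cfg$provenance %||% "user"
  do.call(relaxivity_coefficients, cfg[c(required, "provenance")])
}

#' Synthetic placeholder oxygen relaxivity coefficients (testing only)
#'
#' @inheritParams placeholder_blood_coefficients
#' @return A `"relaxivity_coefficients"` object with
#'   `provenance = "placeholder"`. Yields r1_Ox of ~3.1e-4 s^-1 mmHg^-1 at
#'   1.5 T and 37 C, decreasing to ~1.8e-4 at 7 T - inside the envelope of
#'   published oxygen relaxivities, but synthetic.
#' @export
placeholder_relaxivity_coefficients <- function(quiet = FALSE) {
  if (!quiet) {
    warning("using synthetic placeholder oxygen relaxivity coefficients - ",
            "for testing only, not for science-grade predictions",
            call. = FALSE)
  }
  relaxivity_coefficients(
    c1 = 2.2e-4, c2 = 0.21, c3 = 2.4e-4, c_temp = -2.2e-6,
    provenance = "placeholder"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
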