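# Shared fixtures: quiet placeholder coefficient sets and preset-midpoint
# scenarios.

`%||%` <- function(a, b) if (is.null(a)) b else a

test_blood_coeffs <- placeholder_blood_coefficients(quiet = TRUE)
test_relax_coeffs <- placeholder_relaxivity_coefficients(quiet = TRUE)
test_constants <- ox_constants()

midpoint_scenario <- function(name, b0 = 1.5, ...) {
  p <- preset(name)
  mid <- function(lo, hi) if (is.na(lo)) NA_real_ else (lo + hi) / 2
  scenario(
    b0 = b0,
    hct = mid(p$hct_lo_total, p$hct_hi_total),
    oef = mid(p$oef_lo, p$oef_hi),
    bv = mid(p$bv_lo, p$bv_hi),
    p_crit = mid(p$pcrit_lo, p$pcrit_hi),
    tissue_type = name,
    ...
  )
}

run_midpoint <- function(name, b0 = 1.5, ...) {
  run_scenario(midpoint_scenario(name, b0),
               constants = test_constants,
               blood_coeffs = test_blood_coeffs,
               relax_coeffs = test_relax_coeffs, ...)
}
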