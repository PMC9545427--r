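#' Tissue-type presets
#'
#' Parameter ranges for the six simulated tissue types: healthy brain tissue,
#' tumour vascular periphery (pure blood, no tissue compartment), hypoxic
#' tumour tissue with low and with high blood volume, tumour tissue with
#' normal metabolism, and necrotic tumour tissue (essentially no blood
#' compartment). Ranges are the published values adopted for the reference
#' simulation: OEF and blood volume from peer-reviewed measurements and
#' computational tumour oxygenation models, critical PO2 1-4 mmHg for healthy
#' tissue and 0.5-2 mmHg for tumour tissue, hematocrit 0.36-0.48 (female),
#' 0.41-0.50 (male), 0.36-0.50 (total).
#'
#' @return A tibble with one row per tissue type and columns:
#'   `name`, `oef_lo`, `oef_hi`, `bv_lo`, `bv_hi`, `pcrit_lo`, `pcrit_hi`
#'   (NA where the tissue has no consuming compartment),
#'   `hct_lo_female`, `hct_hi_female`, `hct_lo_male`, `hct_hi_male`,
#'   `hct_lo_total`, `hct_hi_total`, `has_tissue_compartment`,
#'   `has_blood_compartment`.
#' @examples
#' tissue_presets()
#' preset("necrotic")
#' @export
tissue_presets <- function() {
  out <- tibble::tribble(
    ~name,                 ~oef_lo, ~oef_hi, ~bv_lo, ~bv_hi, ~pcrit_lo, ~pcrit_hi, ~has_tissue_compartment, ~has_blood_compartment,
    "healthy_brain",       0.31,    0.37,    0.02,   0.07,   1,         4,         TRUE,                    TRUE,
    "vascular_periphery",  0.24,    0.44,    1.0,    1.0,    NA_real_,  NA_real_,  FALSE,                   TRUE,
    "hypoxic_low_bv",      0.02,    0.20,    0.047,  0.059,  0.5,       2,         TRUE,                    TRUE,
    "hypoxic_high_bv",     0.02,    0.20,    0.09,   0.17,   0.5,       2,         TRUE,                    TRUE,
    "normal_metabolism",   0.02,    0.05,    0.047,  0.059,  0.5,       2,         TRUE,                    TRUE,
    "necrotic",            0.02,    0.05,    0.001,  0.001,  0.5,       2,         TRUE,                    FALSE
  )
  out$hct_lo_female <- 0.36
  out$hct_hi_female <- 0.48
  out$hct_lo_male   <- 0.41
  out$hct_hi_male   <- 0.50
  out$hct_lo_total  <- 0.36
  out$hct_hi_total  <- 0.50
  out
}

#' Look up one tissue-type preset
#'
#' @param name One of `"healthy_brain"`, `"vascular_periphery"`,
#'   `"hypoxic_low_bv"`, `"hypoxic_high_bv"`, `"normal_metabolism"`,
#'   `"necrotic"`.
#' @return A one-row tibble (see [tissue_presets()] for columns).
#' @export
preset <- function(name) {
  presets <- tissue_presets()
  if (!is.character(name) || length(name) != 1L || !name %in% presets$name) {
    stop("unknown tissue type ", deparse(name), "; valid identifiers are: ",
         paste(presets$name, collapse = ", "), call. = FALSE)
  }
  presets[presets$name == name, ]
}

# Hematocrit range columns for a given mode ("female", "male", "total").
hct_range <- function(preset_row, hct_mode = c("total", "female", "male")) {
  hct_mode <- match.arg(hct_mode)
  c(preset_row[[paste0("hct_lo_", hct_mode)]],
    preset_row[[paste0("hct_hi_", hct_mode)]])
}
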