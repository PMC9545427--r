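#' Physiological constants for the voxel oxygenation model
#'
#' Builds the validated set of physical and physiological constants used
#' throughout the model. Defaults are the literature values adopted for the
#' reference simulation (hemoglobin half-saturation tension 37 mmHg, Hill
#' exponent 2.7, 1 mm capillaries of 3.5 um radius, etc.). Any field can be
#' overridden.
#'
#' @param ... Named overrides of individual constants (see Details).
#'
#' @details Fields and units:
#' * `p50_tissue` hemoglobin half-saturation tension used for capillary/tissue
#'   oxygen transport, mmHg (default 37).
#' * `hill_n` Hill exponent, unitless (default 2.7).
#' * `alpha_p` plasma O2 solubility, mlO2 ml^-1 mmHg^-1 (default 3.1e-5).
#' * `c_hb` Hüffner factor, mlO2 per g hemoglobin (default 1.36).
#' * `c0` O2 capacity per unit erythrocyte volume at full saturation,
#'   mlO2 ml^-1 (default 0.5, the adopted literature value).
#' * `hb_molar` mean corpuscular hemoglobin concentration, mmol tetramer L^-1
#'   (default 5.15).
#' * `hb_mass` mean corpuscular hemoglobin concentration, g mL^-1 (default 0.43).
#' * `alpha_t` tissue O2 solubility, mlO2 ml^-1 mmHg^-1 (default 2.8e-5).
#' * `d_t` tissue O2 diffusivity, m^2 s^-1 (default 2.41e-9).
#' * `cap_length` capillary length L, m (default 1e-3).
#' * `cap_radius` capillary radius R_c, m (default 3.5e-6).
#' * `cap_velocity` capillary blood velocity v, m s^-1 (default 7.9e-4).
#' * `w_rbc`, `w_plasma` water volume fractions of erythrocytes and plasma
#'   (defaults 0.70 and 0.95).
#' * `temperature` tissue temperature, degrees C (default 37).
#'
#' Note that the adopted `c0 = 0.5` is not the arithmetic product
#' `c_hb * hb_mass = 0.5848`; `c0` is carried as an independent constant and a
#' message flags the inconsistency when both defaults are in force.
#'
#' @return A named list of class `"ox_constants"`.
#' @seealso [load_constants()] to read the same fields from a JSON config.
#' @examples
#' ox_constants()
#' ox_constants(p50_tissue = 26)
#' @export
ox_constants <- function(...) {
  defaults <- list(
    p50_tissue   = 37,
    hill_n       = 2.7,
    alpha_p      = 3.1e-5,
    c_hb         = 1.36,
    c0           = 0.5,
    hb_molar     = 5.15,
    hb_mass      = 0.43,
    alpha_t      = 2.8e-5,
    d_t          = 2.41e-9,
    cap_length   = 1e-3,
    cap_radius   = 3.5e-6,
    cap_velocity = 7.9e-4,
    w_rbc        = 0.70,
    w_plasma     = 0.95,
    temperature  = 37
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) && is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown constant(s): ", paste(unknown, collapse = ", "),
         "; valid names are: ", paste(names(defaults), collapse = ", "),
         call. = FALSE)
  }
  constants <- utils::modifyList(defaults, overrides)
  validate_constants(constants)
  structure(constants, class = "ox_constants")
}

validate_constants <- function(x) {
  numeric_fields <- names(x)
  for (nm in numeric_fields) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("constant '", nm, "' must be a single finite number", call. = FALSE)
    }
    if (v <= 0) {
      stop("constant '", nm, "' must be strictly positive (got ", v, ")",
           call. = FALSE)
    }
  }
  if (x$hill_n <= 1) {
    stop("hill_n must exceed 1 (got ", x$hill_n, ")", call. = FALSE)
  }
  for (nm in c("w_rbc", "w_plasma")) {
    if (x[[nm]] > 1) {
      stop(nm, " must lie in (0, 1] (got ", x[[nm]], ")", call. = FALSE)
    }
  }
  if (x$cap_radius >= x$cap_length) {
    stop("cap_radius must be smaller than cap_length", call. = FALSE)
  }
  invisible(x)
}

#' Load model constants from a configuration source
#'
#' Reads the `constants` section of a JSON configuration file (or an already
#' parsed list) and returns a validated constant set. Omitted fields fall back
#' to the package defaults (see [ox_constants()]).
#'
#' @param config_source Path to a JSON file, or a named list. A file may
#'   either contain the constants at top level or under a `constants` key.
#' @return A named list of class `"ox_constants"`.
#' @examples
#' load_constants(list(p50_tissue = 26))
#' @export
load_constants <- function(config_source = list()) {
  cfg <- read_config_section(config_source, "constants")
  out <- do.call(ox_constants, cfg)
  # c0 is adopted independently of c_hb * hb_mass; flag when they disagree.
  prod_c0 <- out$c_hb * out$hb_mass
  if (abs(prod_c0 - out$c0) > 1e-3 * out$c0) {
    message(sprintf(
      "note: c0 = %.4g mlO2/ml is carried independently of c_hb * hb_mass = %.4g mlO2/ml",
      out$c0, prod_c0))
  }
  out
}

# Shared helper: accept a path or list, optionally descend into a named section.
read_config_section <- function(config_source, section) {
  if (is.character(config_source)) {
    if (!file.exists(config_source)) {
      stop("configuration file not found: ", config_source, call. = FALSE)
    }
    cfg <- tryCatch(
      jsonlite::read_json(config_source, simplifyVector = TRUE),
      error = function(e) {
        stop("failed to parse configuration '", config_source, "': ",
             conditionMessage(e), call. = FALSE)
      }
    )
  } else if (is.list(config_source)) {
    cfg <- config_source
  } else {
    stop("config_source must be a file path or a named list", call. = FALSE)
  }
  if (!is.null(cfg[[section]]) && is.list(cfg[[section]])) {
    cfg <- cfg[[section]]
  }
  cfg
}

#' Tabulate the model constants
#'
#' @param constants A constant set from [ox_constants()].
#' @return A tibble with one row per constant (`name`, `value`, `units`).
#' @export
constants_table <- function(constants = ox_constants()) {
  units <- c(
    p50_tissue = "mmHg", hill_n = "unitless",
    alpha_p = "mlO2 ml^-1 mmHg^-1", c_hb = "mlO2 g^-1", c0 = "mlO2 ml^-1",
    hb_molar = "mmol tetramer L^-1", hb_mass = "g mL^-1",
    alpha_t = "mlO2 ml^-1 mmHg^-1", d_t = "m^2 s^-1",
    cap_length = "m", cap_radius = "m", cap_velocity = "m s^-1",
    w_rbc = "fraction", w_plasma = "fraction", temperature = "degC"
  )
  tibble::tibble(
    name = names(unclass(constants)),
    value = unlist(unclass(constants), use.names = FALSE),
    units = unname(units[names(unclass(constants))])
  )
}

#' @export
print.ox_constants <- function(x, ...) {
  cat("<ox_constants>\n")
  print(constants_table(x), n = Inf)
  invisible(x)
}

#' Krogh diffusion constant
#'
#' K = D_T * alpha_T, the product of tissue oxygen diffusivity and solubility,
#' in mlO2 m^2 ml^-1 s^-1 mmHg^-1.
#'
#' @param constants A constant set from [ox_constants()].
#' @return Scalar K.
#' @export
krogh_diffusion_constant <- function(constants = ox_constants()) {
  constants$d_t * constants$alpha_t
}
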