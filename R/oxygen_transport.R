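#' Hill oxyhemoglobin dissociation curve
#'
#' `hill_saturation()` maps oxygen tension to hemoglobin saturation,
#' `SO2 = PO2^n / (PO2^n + P50^n)`; `hill_tension()` is its exact inverse,
#' `PO2 = P50 * (SO2 / (1 - SO2))^(1/n)`.
#'
#' @param po2 Oxygen tension, mmHg (vectorised, must be >= 0).
#' @param so2 Hemoglobin saturation in \[0, 1) (vectorised).
#' @param p50 Half-saturation tension, mmHg (> 0).
#' @param n Hill exponent (> 0).
#' @return Saturation in \[0, 1) for `hill_saturation()`; tension in mmHg for
#'   `hill_tension()`.
#' @examples
#' hill_saturation(37, 37, 2.7)   # 0.5 by definition of P50
#' hill_tension(0.5, 37, 2.7)     # 37
#' @export
hill_saturation <- function(po2, p50 = 37, n = 2.7) {
  stopifnot(p50 > 0, n > 0)
  if (any(po2 < 0)) {
    stop("po2 must be non-negative", call. = FALSE)
  }
  # ratio form is robust for large po2 (po2^n may overflow for extreme n)
  ratio <- (po2 / p50)^n
  ifelse(is.infinite(ratio), 1, ratio / (1 + ratio))
}

#' @rdname hill_saturation
#' @export
hill_tension <- function(so2, p50 = 37, n = 2.7) {
  stopifnot(p50 > 0, n > 0)
  if (any(so2 < 0)) {
    stop("so2 must be non-negative", call. = FALSE)
  }
  if (any(so2 >= 1)) {
    stop("so2 must be below 1 (saturation 1 corresponds to infinite tension)",
         call. = FALSE)
  }
  p50 * (so2 / (1 - so2))^(1 / n)
}

#' Total blood oxygen content
#'
#' Sum of dissolved and hemoglobin-bound oxygen:
#' `c = alpha_p * PO2 + Hct * c0 * SO2`, in mlO2 per ml blood.
#'
#' @param po2 Oxygen tension, mmHg.
#' @param so2 Hemoglobin saturation, 0-1.
#' @param hct Hematocrit, 0-1.
#' @param constants Constant set from [ox_constants()].
#' @return Oxygen content, mlO2 ml^-1.
#' @examples
#' o2_content(90, hill_saturation(90), 0.42)
#' @export
o2_content <- function(po2, so2, hct, constants = ox_constants()) {
  if (any(po2 < 0) || any(so2 < 0) || any(so2 > 1) || any(hct < 0) || any(hct > 1)) {
    stop("arguments outside domain: need po2 >= 0, so2 and hct in [0, 1]",
         call. = FALSE)
  }
  constants$alpha_p * po2 + hct * constants$c0 * so2
}

#' Invert total oxygen content to a blood gas state
#'
#' Solves `alpha_p * PO2 + hct * c0 * hill_saturation(PO2)` = `content` for
#' PO2. The left side is strictly increasing in PO2, so the solution is
#' unique. A safeguarded Newton iteration (bisection fallback) drives the
#' content residual below 1e-12 mlO2/ml.
#'
#' @param content Total oxygen content, mlO2 ml^-1 (vectorised).
#' @param hct Hematocrit, 0-1.
#' @param constants Constant set from [ox_constants()]. The tissue-transport
#'   Hill parameters (`p50_tissue`, `hill_n`) are used.
#' @param p_max Upper solver bracket, mmHg (default 5000).
#' @return A tibble with columns `po2`, `so2`, `content`, `hct` (one row per
#'   input content).
#' @examples
#' invert_content(o2_content(600, hill_saturation(600), 0.42), 0.42)
#' @export
invert_content <- function(content, hct, constants = ox_constants(),
                           p_max = 5000) {
  stopifnot(length(hct) == 1L, hct >= 0, hct <= 1)
  cmax <- constants$alpha_p * p_max +
    hct * constants$c0 * hill_saturation(p_max, constants$p50_tissue, constants$hill_n)
  if (any(content < 0) || any(content >= cmax)) {
    stop(sprintf(
      "content outside invertible range [0, %.5g) for hct = %.3g and p_max = %g mmHg",
      cmax, hct, p_max), call. = FALSE)
  }
  po2 <- vapply(content, solve_po2_from_content, numeric(1),
                hct = hct, constants = constants, p_max = p_max)
  so2 <- hill_saturation(po2, constants$p50_tissue, constants$hill_n)
  tibble::tibble(po2 = po2, so2 = so2,
                 content = o2_content(po2, so2, hct, constants), hct = hct)
}

# Scalar solver: safeguarded Newton on f(P) = alpha_p P + hct c0 S(P) - content.
solve_po2_from_content <- function(content, hct, constants, p_max = 5000,
                                   tol = 1e-13, max_iter = 100) {
  if (content == 0) return(0)
  ap <- constants$alpha_p
  hc0 <- hct * constants$c0
  p50 <- constants$p50_tissue
  n <- constants$hill_n
  f <- function(p) ap * p + hc0 * hill_saturation(p, p50, n) - content

  lo <- 0
  hi <- p_max
  # initial guess: bound-only inversion if feasible, else dissolved-only
  s_guess <- if (hc0 > 0) min(content / hc0, 0.999) else NA
  p <- if (!is.na(s_guess) && s_guess > 1e-12) {
    hill_tension(s_guess, p50, n)
  } else {
    content / ap
  }
  p <- min(max(p, 1e-9), p_max * 0.999)
  for (i in seq_len(max_iter)) {
    fp <- f(p)
    if (abs(fp) < tol) return(p)
    if (fp > 0) hi <- p else lo <- p
    s <- hill_saturation(p, p50, n)
    dsdp <- if (p > 0) n * s * (1 - s) / p else 0
    deriv <- ap + hc0 * dsdp
    p_new <- p - fp / deriv
    if (!is.finite(p_new) || p_new <= lo || p_new >= hi) {
      p_new <- (lo + hi) / 2  # bisection safeguard
    }
    p <- p_new
  }
  if (abs(f(p)) > 1e-10) {
    stop(sprintf(
      "content inversion did not converge: bracket [%.6g, %.6g] mmHg, residual %.3g",
      lo, hi, f(p)), call. = FALSE)
  }
  p
}

#' Mean capillary hemoglobin saturation
#'
#' Under the assumption that oxygen extraction rises linearly along the
#' capillary, the capillary-average saturation is
#' `SO2_cap,mean = SaO2 * (1 - OEF / 2)`.
#'
#' @param sao2 Arterial saturation, 0-1.
#' @param oef Oxygen extraction fraction, 0-1.
#' @return Mean saturation, 0-1.
#' @export
mean_capillary_saturation <- function(sao2, oef) {
  stopifnot(all(sao2 >= 0), all(sao2 <= 1), all(oef >= 0), all(oef <= 1))
  sao2 * (1 - oef / 2)
}

#' Oxygen saturation, tension and content along a capillary
#'
#' Step 1 of the voxel pipeline: propagate arterial blood down a capillary of
#' length L given the amount of oxygen the surrounding tissue extracts.
#' Extraction is assumed to accumulate linearly with axial distance.
#'
#' Two profile modes are available. The default, `"content_linear"`, declines
#' *total* oxygen content linearly from the arterial value by the extraction
#' amount and recovers (PO2, SO2) at each position by numerically inverting
#' the content equation together with the Hill curve; this conserves oxygen
#' exactly even under hyperoxia, where dissolved oxygen is a non-negligible
#' share of content. `"so2_linear"` declines *saturation* linearly (the
#' classical bound-oxygen formulation), so the venous saturation equals
#' `SaO2 * (1 - OEF)` exactly; total content then deviates slightly from
#' linearity by the dissolved share.
#'
#' @param pao2 Arterial oxygen tension, mmHg.
#' @param hct Hematocrit, 0-1.
#' @param oef Oxygen extraction fraction applied to the arterial content of
#'   *this* state (give either `oef` or `extraction`).
#' @param extraction Absolute content extracted over the capillary,
#'   mlO2 ml^-1. Use this to impose the normoxic-state consumption on a
#'   hyperoxic profile.
#' @param n_z Number of axial grid points (>= 2, endpoints inclusive).
#' @param constants Constant set from [ox_constants()].
#' @param mode `"content_linear"` (default) or `"so2_linear"`.
#' @param state_label Label stored with the profile, e.g. `"air"` or
#'   `"oxygen"`.
#' @return A tibble of class `"capillary_profile"` with columns `z_m`, `so2`,
#'   `po2_mmhg`, `content_mlo2_per_ml`, and attributes `state_label`,
#'   `oef_effective` (content actually extracted as a fraction of arterial
#'   content), `extraction` (mlO2/ml), `pao2`, `hct`, `mode`.
#' @examples
#' capillary_profile(90, 0.42, oef = 0.34, state_label = "air")
#' @export
capillary_profile <- function(pao2, hct, oef = NULL, extraction = NULL,
                              n_z = 51, constants = ox_constants(),
                              mode = c("content_linear", "so2_linear"),
                              state_label = "air") {
  mode <- match.arg(mode)
  stopifnot(pao2 >= 0, hct >= 0, hct <= 1, n_z >= 2)
  if (is.null(oef) == is.null(extraction)) {
    stop("give exactly one of 'oef' or 'extraction'", call. = FALSE)
  }
  sao2 <- hill_saturation(pao2, constants$p50_tissue, constants$hill_n)
  ca_o2 <- o2_content(pao2, sao2, hct, constants)
  if (!is.null(oef)) {
    stopifnot(oef >= 0, oef < 1)
    extraction <- oef * ca_o2
  }
  if (extraction > ca_o2) {
    stop(sprintf(
      "infeasible extraction: %.5g mlO2/ml exceeds arterial content %.5g mlO2/ml",
      extraction, ca_o2), call. = FALSE)
  }
  z <- seq(0, constants$cap_length, length.out = n_z)
  frac <- z / constants$cap_length

  if (mode == "content_linear") {
    content <- ca_o2 - extraction * frac
    st <- invert_content(content, hct, constants)
    so2 <- st$so2
    po2 <- st$po2
  } else {
    # saturation-linear: venous SO2 = SaO2 * (1 - OEF) exactly, with OEF the
    # nominal content fraction
    oef_nominal <- extraction / ca_o2
    so2 <- sao2 * (1 - oef_nominal * frac)
    if (any(so2 < 0)) {
      stop("infeasible extraction: saturation would fall below zero",
           call. = FALSE)
    }
    po2 <- hill_tension(so2, constants$p50_tissue, constants$hill_n)
    content <- o2_content(po2, so2, hct, constants)
  }

  out <- tibble::tibble(
    z_m = z, so2 = so2, po2_mmhg = po2, content_mlo2_per_ml = content
  )
  attr(out, "state_label") <- state_label
  attr(out, "oef_effective") <- (content[1] - content[n_z]) / content[1]
  attr(out, "extraction") <- content[1] - content[n_z]
  attr(out, "pao2") <- pao2
  attr(out, "hct") <- hct
  attr(out, "mode") <- mode
  class(out) <- c("capillary_profile", class(out))
  out
}

#' @export
print.capillary_profile <- function(x, ...) {
  cat(sprintf(
    "<capillary_profile> state = %s, mode = %s, PaO2 = %g mmHg, Hct = %.3g, effective OEF = %.4g\n",
    attr(x, "state_label"), attr(x, "mode"), attr(x, "pao2"), attr(x, "hct"),
    attr(x, "oef_effective")))
  NextMethod()
}
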