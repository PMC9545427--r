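#' Factorial sweep of the voxel model over a tissue preset
#'
#' Evaluates [run_scenario()] on the full Cartesian product of uniformly
#' spaced grids over a preset's hematocrit, OEF, blood volume and critical
#' tension ranges, crossed with a list of field strengths. Single-point
#' ranges contribute one grid point. Rows are emitted in deterministic
#' lexicographic order of (b0, hct, oef, bv, p_crit). Physically infeasible
#' combinations (extraction exceeding arterial content) are flagged rather
#' than fatal.
#'
#' @param preset A preset name (see [tissue_presets()]) or a one-row preset
#'   tibble.
#' @param b0 Field strengths to evaluate, tesla (default all four of 1.5, 3,
#'   4.7, 7).
#' @param hct_mode Which hematocrit range to sweep: `"total"` (default),
#'   `"female"` or `"male"`.
#' @param steps Grid points per varying range (default 5). Either a single
#'   number or a named vector with any of `hct`, `oef`, `bv`, `p_crit`.
#' @param grids Optional named list of explicit grid vectors overriding the
#'   preset ranges (any of `hct`, `oef`, `bv`, `p_crit`).
#' @param constants,blood_coeffs,relax_coeffs Model inputs as in
#'   [run_scenario()].
#' @param pao2_air,pao2_ox,arterial_fraction Gas challenge and blood split.
#' @param n_z,n_r,profile_mode Numerical settings, see [run_scenario()].
#' @return A `"sweep_table"` tibble: one row per combination with all
#'   scenario fields, all voxel-result fields and a `feasible` flag.
#'   Attributes record the preset, grids, steps and hematocrit mode.
#' @export
run_sweep <- function(preset, b0 = c(1.5, 3, 4.7, 7),
                      hct_mode = c("total", "female", "male"),
                      steps = 5, grids = list(),
                      constants = ox_constants(),
                      blood_coeffs, relax_coeffs,
                      pao2_air = 90, pao2_ox = 600, arterial_fraction = 0.5,
                      n_z = 51, n_r = 101,
                      profile_mode = c("content_linear", "so2_linear")) {
  hct_mode <- match.arg(hct_mode)
  profile_mode <- match.arg(profile_mode)
  if (is.character(preset)) preset <- preset(preset)
  stopifnot(nrow(preset) == 1L)
  steps_for <- function(var) {
    if (length(steps) == 1L && is.null(names(steps))) return(steps)
    if (var %in% names(steps)) steps[[var]] else 5
  }
  hr <- hct_range(preset, hct_mode)
  grid <- list(
    hct = grids$hct %||% range_grid(hr[1], hr[2], steps_for("hct")),
    oef = grids$oef %||% range_grid(preset$oef_lo, preset$oef_hi, steps_for("oef")),
    bv = grids$bv %||% range_grid(preset$bv_lo, preset$bv_hi, steps_for("bv")),
    p_crit = grids$p_crit %||%
      range_grid(preset$pcrit_lo, preset$pcrit_hi, steps_for("p_crit"))
  )
  combos <- tidyr::expand_grid(
    b0 = b0, hct = grid$hct, oef = grid$oef, bv = grid$bv,
    p_crit = grid$p_crit
  )

  # the physiology (steps 1-2) does not depend on b0: compute it once per
  # unique physiological combination, then apply relaxometry per field
  phys_key <- combos |>
    dplyr::distinct(.data$hct, .data$oef, .data$bv, .data$p_crit)
  phys <- purrr::pmap(phys_key, function(hct, oef, bv, p_crit) {
    scenario_physiology(hct, oef, bv, p_crit, pao2_air, pao2_ox,
                        constants, n_z, n_r, profile_mode)
  })
  phys_key$.phys <- phys

  rows <- combos |>
    dplyr::left_join(phys_key, by = c("hct", "oef", "bv", "p_crit")) |>
    purrr::pmap(function(b0, hct, oef, bv, p_crit, .phys) {
      assemble_sweep_row(b0, hct, oef, bv, p_crit, .phys,
                         pao2_air, pao2_ox, arterial_fraction,
                         preset$name, constants, blood_coeffs, relax_coeffs)
    }) |>
    dplyr::bind_rows()

  attr(rows, "preset") <- preset$name
  attr(rows, "grids") <- grid
  attr(rows, "b0") <- b0
  attr(rows, "hct_mode") <- hct_mode
  attr(rows, "profile_mode") <- profile_mode
  attr(rows, "coefficient_provenance") <- c(
    blood = blood_coeffs$provenance %||% "user",
    relaxivity = relax_coeffs$provenance %||% "user"
  )
  class(rows) <- c("sweep_table", class(rows))
  rows
}

# Uniformly spaced grid over [lo, hi]; a degenerate or NA range is one point.
range_grid <- function(lo, hi, steps) {
  if (is.na(lo) || is.na(hi)) return(NA_real_)
  if (lo == hi || steps <= 1) return(lo)
  seq(lo, hi, length.out = steps)
}

# Steps 1-2 for one physiological combination (independent of b0).
scenario_physiology <- function(hct, oef, bv, p_crit, pao2_air, pao2_ox,
                                constants, n_z, n_r, profile_mode) {
  out <- tryCatch({
    sao2_air <- hill_saturation(pao2_air, constants$p50_tissue, constants$hill_n)
    ca_o2_air <- o2_content(pao2_air, sao2_air, hct, constants)
    extraction <- oef * ca_o2_air
    prof_air <- capillary_profile(pao2_air, hct, extraction = extraction,
                                  n_z = n_z, constants = constants,
                                  mode = profile_mode, state_label = "air")
    prof_ox <- capillary_profile(pao2_ox, hct, extraction = extraction,
                                 n_z = n_z, constants = constants,
                                 mode = profile_mode, state_label = "oxygen")
    if (bv < 1) {
      geometry <- capillary_geometry(bv, constants)
      m0 <- max_consumption_from_oef(oef, hct, sao2_air, geometry, constants)
      consumption <- consumption_model(m0, if (is.na(p_crit)) 0 else p_crit,
                                       constants = constants)
      field_air <- tissue_field(prof_air, consumption, geometry, n_r = n_r)
      field_ox <- tissue_field(prof_ox, consumption, geometry, n_r = n_r)
      d_po2_t <- as.numeric(delta_tissue_po2(field_air, field_ox))
      clamped <- max(field_air$clamped_fraction, field_ox$clamped_fraction)
      iters <- max(field_air$iterations, field_ox$iterations)
      r_t <- geometry$r_t
    } else {
      m0 <- NA_real_; d_po2_t <- NA_real_; clamped <- NA_real_
      iters <- NA_real_; r_t <- NA_real_
    }
    n <- nrow(prof_air)
    list(feasible = TRUE,
         venous_po2_air = prof_air$po2_mmhg[n],
         venous_po2_ox = prof_ox$po2_mmhg[n],
         d_po2_t = d_po2_t, m0 = m0, r_t = r_t,
         clamped_fraction = clamped, iterations = iters)
  }, error = function(e) list(feasible = FALSE, message = conditionMessage(e)))
  out
}

# Step 3-4 for one grid row.
assemble_sweep_row <- function(b0, hct, oef, bv, p_crit, phys,
                               pao2_air, pao2_ox, arterial_fraction,
                               tissue_type, constants, blood_coeffs,
                               relax_coeffs) {
  base <- tibble::tibble(
    b0 = b0, hct = hct, oef = oef, bv = bv, p_crit = p_crit,
    pao2_air = pao2_air, pao2_ox = pao2_ox,
    arterial_fraction = arterial_fraction, tissue_type = tissue_type
  )
  if (!isTRUE(phys$feasible)) {
    return(dplyr::bind_cols(base, tibble::tibble(
      delta_r1_arterial = NA_real_, delta_r1_venous = NA_real_,
      delta_r1_tissue = NA_real_, delta_r1_voxel = NA_real_,
      delta_po2_tissue = NA_real_, venous_po2_air = NA_real_,
      venous_po2_ox = NA_real_, m0 = NA_real_, r_t = NA_real_,
      clamped_fraction = NA_real_, solver_iterations = NA_real_,
      feasible = FALSE
    )))
  }
  d_arterial <- delta_r1_blood(pao2_air, pao2_ox, hct, b0, blood_coeffs,
                               constants)
  d_venous <- delta_r1_blood(phys$venous_po2_air, phys$venous_po2_ox, hct, b0,
                             blood_coeffs, constants)
  d_tissue <- if (bv < 1) {
    delta_r1_tissue(phys$d_po2_t, b0, constants$temperature, relax_coeffs)
  } else {
    NA_real_
  }
  d_voxel <- delta_r1_voxel(bv, d_arterial, d_tissue, d_venous,
                            arterial_fraction)
  dplyr::bind_cols(base, tibble::tibble(
    delta_r1_arterial = d_arterial, delta_r1_venous = d_venous,
    delta_r1_tissue = d_tissue, delta_r1_voxel = d_voxel,
    delta_po2_tissue = phys$d_po2_t, venous_po2_air = phys$venous_po2_air,
    venous_po2_ox = phys$venous_po2_ox, m0 = phys$m0, r_t = phys$r_t,
    clamped_fraction = phys$clamped_fraction,
    solver_iterations = phys$iterations,
    feasible = TRUE
  ))
}

#' Sex-stratified hematocrit comparison
#'
#' Runs the factorial sweep of each preset separately over the female and the
#' male hematocrit range and summarises, per preset and field strength, the
#' mean voxel R1 change of each sweep and their absolute difference. The
#' largest difference across all (preset, field) cells and its location are
#' attached as attributes and shown by the print method.
#'
#' @param presets Character vector of preset names (default: all six).
#' @param b0 Field strengths, tesla (default 1.5, 3, 4.7, 7).
#' @param steps Grid points per varying range (default 5).
#' @param ... Passed on to [run_sweep()] (constants, coefficients, numerical
#'   settings).
#' @return A `"sex_comparison"` tibble with columns `tissue_type`, `b0`,
#'   `mean_delta_r1_female`, `mean_delta_r1_male`, `abs_difference`, plus
#'   attributes `max_difference`, `max_tissue_type`, `max_b0`.
#' @export
sex_comparison <- function(presets = tissue_presets()$name,
                           b0 = c(1.5, 3, 4.7, 7), steps = 5, ...) {
  cells <- purrr::map(presets, function(p) {
    f <- run_sweep(p, b0 = b0, hct_mode = "female", steps = steps, ...)
    m <- run_sweep(p, b0 = b0, hct_mode = "male", steps = steps, ...)
    fsum <- f |>
      dplyr::filter(.data$feasible) |>
      dplyr::group_by(.data$b0) |>
      dplyr::summarise(mean_delta_r1_female = mean(.data$delta_r1_voxel),
                       .groups = "drop")
    msum <- m |>
      dplyr::filter(.data$feasible) |>
      dplyr::group_by(.data$b0) |>
      dplyr::summarise(mean_delta_r1_male = mean(.data$delta_r1_voxel),
                       .groups = "drop")
    dplyr::inner_join(fsum, msum, by = "b0") |>
      dplyr::mutate(tissue_type = p, .before = 1)
  })
  out <- dplyr::bind_rows(cells) |>
    dplyr::mutate(abs_difference = abs(.data$mean_delta_r1_male -
                                         .data$mean_delta_r1_female))
  i_max <- which.max(out$abs_difference)
  attr(out, "max_difference") <- out$abs_difference[i_max]
  attr(out, "max_tissue_type") <- out$tissue_type[i_max]
  attr(out, "max_b0") <- out$b0[i_max]
  class(out) <- c("sex_comparison", class(out))
  out
}

#' @export
print.sex_comparison <- function(x, ...) {
  NextMethod()
  cat(sprintf(
    "largest male/female difference: %.5g s^-1 (%s at %g T)\n",
    attr(x, "max_difference"), attr(x, "max_tissue_type"), attr(x, "max_b0")))
  invisible(x)
}

#' Draw a random scenario within a preset's ranges
#'
#' Uniform draws within the preset's total hematocrit, OEF, blood volume and
#' critical tension ranges and a random choice among the standard field
#' strengths. The draw is fully determined by `seed` and does not disturb the
#' session RNG state. Intended as a property-test and demonstration fixture.
#'
#' @param seed Integer seed.
#' @param preset Preset name or one-row preset tibble.
#' @param b0_choices Candidate field strengths (default 1.5, 3, 4.7, 7 T).
#' @param ... Additional fields passed to [scenario()] (e.g. `pao2_ox`).
#' @return A one-row [scenario()] tibble.
#' @export
random_scenario <- function(seed, preset, b0_choices = c(1.5, 3, 4.7, 7),
                            ...) {
  if (is.character(preset)) preset <- preset(preset)
  withr::with_seed(seed, {
    runif_range <- function(lo, hi) {
      if (is.na(lo) || is.na(hi)) NA_real_ else stats::runif(1, lo, hi)
    }
    scenario(
      b0 = sample(b0_choices, 1),
      hct = runif_range(preset$hct_lo_total, preset$hct_hi_total),
      oef = runif_range(preset$oef_lo, preset$oef_hi),
      bv = runif_range(preset$bv_lo, preset$bv_hi),
      p_crit = runif_range(preset$pcrit_lo, preset$pcrit_hi),
      tissue_type = preset$name,
      ...
    )
  })
}
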