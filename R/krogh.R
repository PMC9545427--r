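#' Krogh cylinder geometry from blood volume
#'
#' Each capillary is modelled as a cylinder of radius `R_c` and length `L`
#' supplying a coaxial tissue cylinder of radius `R_t`. The capillary count in
#' a voxel follows from the blood volume fraction,
#' `N_cap = BV * V_voxel / (pi R_c^2 L)`, and with capillaries spaced on a
#' sqrt(N) x sqrt(N) grid across the voxel cross-section,
#' `R_t = voxel_width / (2 sqrt(N_cap))`, which reduces to the
#' voxel-size-independent identity `R_t = (R_c / 2) * sqrt(pi / BV)`.
#' `N_cap` is kept continuous to avoid discretisation artifacts in sweeps.
#'
#' @param bv Blood volume fraction, strictly inside (0, 1).
#' @param constants Constant set from [ox_constants()].
#' @param voxel_volume Voxel volume, m^3 (default 1e-9, i.e. 1 mm^3).
#' @return A list of class `"krogh_geometry"` with fields `r_c`, `r_t`,
#'   `cap_length`, `n_cap`, `voxel_width`, `bv`.
#' @examples
#' capillary_geometry(0.05)
#' @export
capillary_geometry <- function(bv, constants = ox_constants(),
                               voxel_volume = 1e-9) {
  stopifnot(length(bv) == 1L, is.finite(bv))
  if (bv <= 0 || bv >= 1) {
    stop("degenerate geometry: bv must lie strictly inside (0, 1); ",
         "bv = 1 voxels are pure blood (no tissue cylinder) and bv = 0 ",
         "voxels are pure tissue (no capillary) - use the corresponding ",
         "compartment-only pipeline paths", call. = FALSE)
  }
  if (bv >= pi / 4) {
    stop("degenerate geometry: with capillaries on a square grid the tissue ",
         "radius falls below the capillary radius for bv >= pi/4 (~0.785); ",
         "voxels this blood-rich have no tissue annulus - use the pure-blood ",
         "path", call. = FALSE)
  }
  r_c <- constants$cap_radius
  l <- constants$cap_length
  v_cap <- pi * r_c^2 * l
  n_cap <- bv * voxel_volume / v_cap
  voxel_width <- sqrt(voxel_volume / l)
  r_t <- voxel_width / (2 * sqrt(n_cap))
  structure(
    list(r_c = r_c, r_t = r_t, cap_length = l, n_cap = n_cap,
         voxel_width = voxel_width, bv = bv),
    class = "krogh_geometry"
  )
}

#' @export
print.krogh_geometry <- function(x, ...) {
  cat(sprintf(
    "<krogh_geometry> bv = %.4g: R_c = %.4g m, R_t = %.4g m, N_cap = %.1f, L = %g m\n",
    x$bv, x$r_c, x$r_t, x$n_cap, x$cap_length))
  invisible(x)
}

#' Maximum tissue oxygen consumption rate from OEF
#'
#' Relates the oxygen extraction fraction to the maximum Michaelis-Menten
#' consumption rate M0 by mass balance over one Krogh cylinder: the oxygen
#' delivered per capillary, `v * pi * R_c^2 * Hct * c0 * SaO2 * OEF`, equals
#' the oxygen consumed in its tissue annulus, `M0 * pi * (R_t^2 - R_c^2) * L`.
#' M0 must be derived in the normoxic (air-breathing) state.
#'
#' @param oef Oxygen extraction fraction in \[0, 1).
#' @param hct Hematocrit, 0-1.
#' @param sao2_air Arterial saturation in the normoxic state, 0-1.
#' @param geometry A [capillary_geometry()] object.
#' @param constants Constant set from [ox_constants()].
#' @return M0 in mlO2 ml^-1 s^-1 (linear in `oef`).
#' @export
max_consumption_from_oef <- function(oef, hct, sao2_air, geometry,
                                     constants = ox_constants()) {
  stopifnot(oef >= 0, oef < 1, hct >= 0, hct <= 1,
            sao2_air >= 0, sao2_air <= 1)
  if (geometry$r_t <= geometry$r_c) {
    stop("invalid geometry: r_t must exceed r_c", call. = FALSE)
  }
  oef * sao2_air * hct * constants$c0 * constants$cap_velocity *
    geometry$r_c^2 / ((geometry$r_t^2 - geometry$r_c^2) * geometry$cap_length)
}

#' Michaelis-Menten oxygen consumption rate
#'
#' `M(PO2) = M0 * PO2 / (PO2 + P_crit)`: approximately constant at `M0` well
#' above the critical tension and falling to zero below it. For `p_crit = 0`
#' the rate is `M0` for any positive tension and 0 at zero tension.
#'
#' @param po2 Tissue oxygen tension, mmHg (>= 0, vectorised).
#' @param m0 Maximum consumption rate, mlO2 ml^-1 s^-1.
#' @param p_crit Critical tension, mmHg (>= 0).
#' @return Consumption rate, mlO2 ml^-1 s^-1.
#' @export
michaelis_menten_rate <- function(po2, m0, p_crit) {
  stopifnot(m0 >= 0, p_crit >= 0)
  if (any(po2 < 0)) stop("po2 must be non-negative", call. = FALSE)
  ifelse(po2 > 0, m0 * po2 / (po2 + p_crit), 0)
}

#' Krogh-Erlang radial oxygen tension
#'
#' Closed-form steady-state tissue PO2 at radius `r` from the capillary axis
#' for uniform consumption `m_rate`:
#' `PO2(r) = P_cap + (m/4K)(r^2 - R_c^2) - (m R_t^2 / 2K) ln(r / R_c)`.
#' The radial gradient vanishes at `r = R_t` (no flux into neighbouring
#' cylinders). Tensions are clamped at zero by default since the formula can
#' go negative at large `R_t` or low capillary tension.
#'
#' @param r Radius, m (vectorised, must lie in `[R_c, R_t]`).
#' @param p_cap Capillary-wall oxygen tension, mmHg.
#' @param m_rate Uniform consumption rate, mlO2 ml^-1 s^-1.
#' @param geometry A [capillary_geometry()] object.
#' @param k_diff Krogh diffusion constant `K = D_T * alpha_T` (defaults from
#'   `constants`).
#' @param constants Constant set, used only for the default `k_diff`.
#' @param clamp Clamp negative tensions at 0 (default TRUE).
#' @return Tissue PO2 at `r`, mmHg.
#' @export
krogh_radial_po2 <- function(r, p_cap, m_rate, geometry,
                             k_diff = krogh_diffusion_constant(constants),
                             constants = ox_constants(), clamp = TRUE) {
  tol <- 1e-12 * geometry$r_t
  if (any(r < geometry$r_c - tol) || any(r > geometry$r_t + tol)) {
    stop(sprintf("radius outside tissue annulus [%.4g, %.4g] m",
                 geometry$r_c, geometry$r_t), call. = FALSE)
  }
  po2 <- p_cap + (m_rate / (4 * k_diff)) * (r^2 - geometry$r_c^2) -
    (m_rate * geometry$r_t^2 / (2 * k_diff)) * log(r / geometry$r_c)
  if (clamp) pmax(po2, 0) else po2
}

#' Solve one tissue slice with Michaelis-Menten consumption
#'
#' Couples the Krogh-Erlang closed form (exact for uniform consumption) with
#' the tension-dependent Michaelis-Menten rate through a fixed point on the
#' slice-average tension: starting from `m = M0`, the radial profile is
#' evaluated, its volume-weighted mean tension computed, and the effective
#' uniform rate updated to `M(mean PO2)` until successive means differ by
#' less than `tol_mean` (default 1e-6 mmHg). If the iteration oscillates the
#' update is damped by a factor 0.5. With `p_crit = 0` and positive mean
#' tension this reduces exactly to the closed form at `m = M0`.
#'
#' @param p_cap Capillary-wall oxygen tension for this slice, mmHg (>= 0).
#' @param consumption List with `m0` (mlO2 ml^-1 s^-1), `p_crit` (mmHg) and
#'   optionally `k_diff`; see [consumption_model()].
#' @param geometry A [capillary_geometry()] object.
#' @param n_r Radial grid size (>= 3, default 101, uniform in r).
#' @param tol_mean Convergence tolerance on the mean tension, mmHg.
#' @param max_iter Iteration cap (default 100).
#' @return A list with `r` (grid), `po2` (clamped radial profile), `m_eff`
#'   (converged effective rate), `mean_po2` (volume-weighted), `iterations`,
#'   `clamped_fraction` (volume fraction of the annulus clamped at 0).
#' @export
solve_tissue_slice <- function(p_cap, consumption, geometry, n_r = 101,
                               tol_mean = 1e-6, max_iter = 100) {
  stopifnot(p_cap >= 0, n_r >= 3)
  k_diff <- consumption$k_diff
  m0 <- consumption$m0
  p_crit <- consumption$p_crit
  r <- seq(geometry$r_c, geometry$r_t, length.out = n_r)
  w <- radial_volume_weights(r)

  evaluate <- function(m) {
    po2 <- krogh_radial_po2(r, p_cap, m, geometry, k_diff = k_diff)
    list(po2 = po2, mean = sum(w * po2))
  }

  m <- m0
  prev_mean <- NA_real_
  prev_delta <- NA_real_
  damped <- FALSE
  for (iter in seq_len(max_iter)) {
    sol <- evaluate(m)
    if (!is.na(prev_mean)) {
      delta <- sol$mean - prev_mean
      if (abs(delta) < tol_mean) {
        po2 <- sol$po2
        return(list(
          r = r, po2 = po2, m_eff = m, mean_po2 = sol$mean,
          iterations = iter,
          clamped_fraction = sum(w[po2 <= 0])
        ))
      }
      # oscillation: successive mean updates flip sign without shrinking
      if (!is.na(prev_delta) && delta * prev_delta < 0 &&
          abs(delta) >= abs(prev_delta) && !damped) {
        damped <- TRUE
      }
      prev_delta <- delta
    }
    prev_mean <- sol$mean
    m_target <- michaelis_menten_rate(max(sol$mean, 0), m0, p_crit)
    m <- if (damped) 0.5 * (m + m_target) else m_target
  }
  stop(sprintf(
    "tissue slice did not converge after %d iterations (last mean change %.3g mmHg)",
    max_iter, if (is.na(prev_delta)) NA else prev_delta), call. = FALSE)
}

# Volume weights proportional to r (cylindrical shells), trapezoidal in r,
# normalised to sum to 1.
radial_volume_weights <- function(r) {
  n <- length(r)
  dr <- diff(r)
  w <- numeric(n)
  w[1] <- r[1] * dr[1] / 2
  w[n] <- r[n] * dr[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- r[2:(n - 1)] * (dr[-(n - 1)] + dr[-1]) / 2
  w / sum(w)
}

# Trapezoidal weights on a uniform-or-not 1-D grid, normalised to sum to 1.
axial_weights <- function(z) {
  n <- length(z)
  dz <- diff(z)
  w <- numeric(n)
  w[1] <- dz[1] / 2
  w[n] <- dz[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dz[-(n - 1)] + dz[-1]) / 2
  w / sum(w)
}

#' Bundle a consumption model
#'
#' @param m0 Maximum consumption rate, mlO2 ml^-1 s^-1 (>= 0).
#' @param p_crit Critical tension, mmHg (>= 0).
#' @param k_diff Krogh diffusion constant (defaults from `constants`).
#' @param constants Constant set used for the default `k_diff`.
#' @return A list of class `"consumption_model"`.
#' @export
consumption_model <- function(m0, p_crit,
                              k_diff = krogh_diffusion_constant(constants),
                              constants = ox_constants()) {
  stopifnot(m0 >= 0, p_crit >= 0, k_diff >= 0)
  structure(list(m0 = m0, p_crit = p_crit, k_diff = k_diff),
            class = "consumption_model")
}

#' Tissue oxygen field over the Krogh cylinder
#'
#' Step 2 of the voxel pipeline: solves [solve_tissue_slice()] at every axial
#' position of a capillary profile, giving tissue PO2 over radius x axial
#' position, with volume-weighted mean and minimum summaries.
#'
#' @param profile A [capillary_profile()].
#' @param consumption A [consumption_model()].
#' @param geometry A [capillary_geometry()].
#' @param n_r Radial grid size (default 101).
#' @return An object of class `"tissue_field"`: list with `r_grid`, `z_grid`,
#'   `po2` (matrix `n_r x n_z`, clamped at 0), `mean_po2` (volume-weighted
#'   over the annulus and capillary length), `min_po2`, `clamped_fraction`,
#'   `m_eff` (effective rate per slice), `iterations` (per slice),
#'   `state_label`.
#' @export
tissue_field <- function(profile, consumption, geometry, n_r = 101) {
  z <- profile$z_m
  n_z <- length(z)
  slices <- vector("list", n_z)
  for (j in seq_len(n_z)) {
    slices[[j]] <- tryCatch(
      solve_tissue_slice(profile$po2_mmhg[j], consumption, geometry, n_r = n_r),
      error = function(e) {
        stop("tissue slice solve failed at z index ", j, " (z = ", z[j],
             " m): ", conditionMessage(e), call. = FALSE)
      }
    )
  }
  po2 <- vapply(slices, `[[`, numeric(n_r), "po2")
  r <- slices[[1]]$r
  wr <- radial_volume_weights(r)
  wz <- axial_weights(z)
  mean_po2 <- as.numeric(t(wr) %*% po2 %*% wz)
  clamped_fraction <- as.numeric(t(wr) %*% (po2 <= 0) %*% wz)
  structure(
    list(
      r_grid = r, z_grid = z, po2 = po2,
      mean_po2 = mean_po2, min_po2 = min(po2),
      clamped_fraction = clamped_fraction,
      m_eff = vapply(slices, `[[`, numeric(1), "m_eff"),
      iterations = vapply(slices, `[[`, numeric(1), "iterations"),
      state_label = attr(profile, "state_label")
    ),
    class = "tissue_field"
  )
}

#' @export
print.tissue_field <- function(x, ...) {
  cat(sprintf(
    "<tissue_field> state = %s: %d x %d grid, mean PO2 = %.3f mmHg, min PO2 = %.3f mmHg, clamped fraction = %.3g\n",
    x$state_label, length(x$r_grid), length(x$z_grid), x$mean_po2, x$min_po2,
    x$clamped_fraction))
  invisible(x)
}

#' Tidy a tissue oxygen field into a long tibble
#'
#' @param x A [tissue_field()] object.
#' @param ... Unused.
#' @return Tibble with columns `r_m`, `z_m`, `po2_mmhg`, `state`.
#' @export
tidy.tissue_field <- function(x, ...) {
  tibble::tibble(
    r_m = rep(x$r_grid, times = length(x$z_grid)),
    z_m = rep(x$z_grid, each = length(x$r_grid)),
    po2_mmhg = as.vector(x$po2),
    state = x$state_label
  )
}

#' Change in mean tissue oxygen tension between gas states
#'
#' @param field_air,field_ox [tissue_field()] objects on identical grids for
#'   the air and hyperoxic states.
#' @return Scalar `mean_po2(ox) - mean_po2(air)` in mmHg, with the pointwise
#'   difference matrix attached as attribute `"delta_field"`.
#' @export
delta_tissue_po2 <- function(field_air, field_ox) {
  if (!isTRUE(all.equal(field_air$r_grid, field_ox$r_grid)) ||
      !isTRUE(all.equal(field_air$z_grid, field_ox$z_grid))) {
    stop("tissue fields are on different grids", call. = FALSE)
  }
  out <- field_ox$mean_po2 - field_air$mean_po2
  attr(out, "delta_field") <- field_ox$po2 - field_air$po2
  out
}
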