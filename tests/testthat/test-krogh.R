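test_that("capillary geometry follows the grid construction and its identities", {
  g <- capillary_geometry(0.05)
  expect_equal(g$n_cap, 1299.22402520832, tolerance = 1e-10)
  expect_equal(g$r_t, 1.38716455416210e-5, tolerance = 1e-10)
  # algebraic identity of the construction: bv = pi r_c^2 / (4 r_t^2)
  for (bv in c(0.001, 0.02, 0.07, 0.17, 0.5)) {
    gi <- capillary_geometry(bv)
    expect_equal(pi * gi$r_c^2 / (4 * gi$r_t^2), bv, tolerance = 1e-12)
    expect_true(gi$r_t > gi$r_c)
  }
  # r_t is independent of the voxel volume
  expect_equal(capillary_geometry(0.05, voxel_volume = 8e-9)$r_t, g$r_t,
               tolerance = 1e-12)
  expect_error(capillary_geometry(1.0), "degenerate")
  expect_error(capillary_geometry(0), "degenerate")
  # above bv = pi/4 the square-grid construction has no tissue annulus
  expect_error(capillary_geometry(0.9), "degenerate")
})

test_that("maximum consumption rate from OEF is the mass-balance form", {
  g <- capillary_geometry(0.05)
  sao2 <- hill_saturation(90)
  expect_equal(max_consumption_from_oef(0, 0.42, sao2, g), 0)
  m1 <- max_consumption_from_oef(0.17, 0.42, sao2, g)
  m2 <- max_consumption_from_oef(0.34, 0.42, sao2, g)
  expect_equal(m2, 2 * m1, tolerance = 1e-14)  # linear in OEF
  expect_equal(m2, 3.51609487021812e-3, tolerance = 1e-10)
  # independent check: per-capillary O2 flux over annulus volume
  k <- ox_constants()
  flux <- k$cap_velocity * pi * g$r_c^2 * 0.42 * k$c0 * sao2 * 0.34
  vol <- pi * (g$r_t^2 - g$r_c^2) * g$cap_length
  expect_equal(m2, flux / vol, tolerance = 1e-12)
})

test_that("Krogh-Erlang radial solution honours its boundary conditions", {
  g <- capillary_geometry(0.05)
  kd <- krogh_diffusion_constant()
  # capillary wall tension is reproduced exactly
  expect_equal(krogh_radial_po2(g$r_c, 90, 2.4e-4, g, kd), 90)
  # zero consumption: flat profile
  r <- seq(g$r_c, g$r_t, length.out = 11)
  expect_equal(krogh_radial_po2(r, 55, 0, g, kd), rep(55, 11))
  # frozen derived value at the outer radius
  g2 <- structure(list(r_c = 3.5e-6, r_t = 1.387e-5), class = "krogh_geometry")
  expect_equal(krogh_radial_po2(1.387e-5, 90, 2.4e-4, g2, k_diff = 6.748e-14),
               89.6890939076793, tolerance = 1e-10)
  # zero radial gradient at r_t (second-order one-sided finite difference)
  eps <- g$r_t * 1e-4
  grad <- (3 * krogh_radial_po2(g$r_t, 90, 2.4e-4, g, kd) -
             4 * krogh_radial_po2(g$r_t - eps, 90, 2.4e-4, g, kd) +
             krogh_radial_po2(g$r_t - 2 * eps, 90, 2.4e-4, g, kd)) / (2 * eps)
  expect_lt(abs(grad), 1e-2)  # mmHg per metre, vanishing at the outer rim
  expect_error(krogh_radial_po2(g$r_t * 1.01, 90, 2.4e-4, g, kd), "annulus")
  # clamping: low capillary tension with strong consumption floors at 0
  v <- krogh_radial_po2(r, 1, 3e-3, g, kd)
  expect_true(all(v >= 0))
  expect_true(any(krogh_radial_po2(r, 1, 3e-3, g, kd, clamp = FALSE) < 0))
})

test_that("Michaelis-Menten rate has the textbook shape", {
  expect_equal(michaelis_menten_rate(2.5, 1e-3, 2.5), 0.5e-3)
  expect_equal(michaelis_menten_rate(0, 1e-3, 2.5), 0)
  expect_equal(michaelis_menten_rate(9 * 2.5, 1e-3, 2.5), 0.9e-3)
  # p_crit = 0: full rate for any positive tension, zero at zero
  expect_equal(michaelis_menten_rate(c(0, 1e-9, 50), 1e-3, 0),
               c(0, 1e-3, 1e-3))
})

test_that("tissue slice fixed point is self-consistent and reduces to the closed form", {
  g <- capillary_geometry(0.05)
  k <- ox_constants()
  m0 <- max_consumption_from_oef(0.34, 0.42, hill_saturation(90), g)

  # p_crit = 0, no clamping: identical to the closed form at m = m0
  cons0 <- consumption_model(m0, 0)
  sl <- solve_tissue_slice(90, cons0, g)
  expect_equal(sl$m_eff, m0)
  expect_equal(sl$po2, krogh_radial_po2(sl$r, 90, m0, g), tolerance = 1e-12)
  expect_equal(sl$clamped_fraction, 0)

  # m0 = 0: uniform profile at the capillary tension
  slu <- solve_tissue_slice(72.5, consumption_model(0, 2), g)
  expect_equal(unique(slu$po2), 72.5)

  # converged solutions satisfy the self-consistency residual
  for (p_crit in c(0.5, 2, 4)) {
    for (p_cap in c(43, 60, 90)) {
      s <- solve_tissue_slice(p_cap, consumption_model(m0, p_crit), g)
      target <- michaelis_menten_rate(s$mean_po2, m0, p_crit)
      expect_lt(abs(s$m_eff - target), 1e-9 * m0)
    }
  }
})

test_that("tissue slice agrees with the finite-volume oracle with spatially varying consumption", {
  kd <- krogh_diffusion_constant()
  withr::with_seed(7, {
    for (i in 1:12) {
      bv <- runif(1, 0.02, 0.17)
      oef <- runif(1, 0.05, 0.37)
      p_crit <- runif(1, 0.5, 4)
      p_cap <- runif(1, 40, 90)
      g <- capillary_geometry(bv)
      m0 <- max_consumption_from_oef(oef, 0.42, hill_saturation(90), g)
      mine <- solve_tissue_slice(p_cap, consumption_model(m0, p_crit), g)
      oracle <- oracle_tissue_slice(p_cap, m0, p_crit, g, kd)
      expect_lt(abs(mine$mean_po2 - oracle_radial_mean(mine$r, oracle)), 0.5)
    }
  })
})

test_that("tissue field assembles slices with correct summaries", {
  g <- capillary_geometry(0.045)
  k <- ox_constants()
  prof <- capillary_profile(90, 0.42, oef = 0.34, n_z = 21)
  m0 <- max_consumption_from_oef(0.34, 0.42, hill_saturation(90), g)

  # m0 = 0: mean tissue PO2 equals the length-average of the capillary tension
  f0 <- tissue_field(prof, consumption_model(0, 2), g, n_r = 41)
  wz <- diff(prof$z_m)
  trap <- sum((prof$po2_mmhg[-1] + prof$po2_mmhg[-21]) / 2 * wz) / sum(wz)
  expect_equal(f0$mean_po2, trap, tolerance = 1e-10)

  # monotone capillary input: minimum attained at (r_t, L)
  f <- tissue_field(prof, consumption_model(m0, 2.5), g, n_r = 41)
  expect_equal(f$min_po2, f$po2[41, 21])
  expect_equal(f$po2[1, ], prof$po2_mmhg)  # wall condition, exact
  # radially non-increasing at fixed z
  expect_true(all(apply(f$po2, 2, function(col) all(diff(col) <= 1e-12))))
  expect_true(f$min_po2 <= f$mean_po2)
  expect_equal(f$clamped_fraction, 0)
})

test_that("tissue tension change is a telescoping mean-field difference", {
  g <- capillary_geometry(0.045)
  m0 <- max_consumption_from_oef(0.34, 0.42, hill_saturation(90), g)
  cons <- consumption_model(m0, 2.5)
  ca_air <- o2_content(90, hill_saturation(90), 0.42)
  ext <- 0.34 * ca_air
  mk_field <- function(pao2) {
    tissue_field(capillary_profile(pao2, 0.42, extraction = ext, n_z = 11),
                 cons, g, n_r = 41)
  }
  fa <- mk_field(90)
  fb <- mk_field(200)
  fc <- mk_field(600)
  expect_equal(delta_tissue_po2(fa, fa), 0, ignore_attr = TRUE)
  expect_equal(as.numeric(delta_tissue_po2(fa, fc)),
               as.numeric(delta_tissue_po2(fa, fb)) +
                 as.numeric(delta_tissue_po2(fb, fc)),
               tolerance = 1e-12)
  d <- delta_tissue_po2(fa, fc)
  expect_equal(dim(attr(d, "delta_field")), c(41, 11))

  # grid mismatch is an error
  fe <- tissue_field(capillary_profile(90, 0.42, extraction = ext, n_z = 13),
                     cons, g, n_r = 41)
  expect_error(delta_tissue_po2(fa, fe), "grids")
})
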