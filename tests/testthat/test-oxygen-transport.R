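test_that("Hill curve hits its anchor points and inverts exactly", {
  expect_equal(hill_saturation(37, 37, 2.7), 0.5, tolerance = 1e-15)
  expect_equal(hill_tension(0.5, 37, 2.7), 37, tolerance = 1e-12)
  expect_equal(hill_saturation(0, 37, 2.7), 0)
  expect_equal(hill_tension(0, 37, 2.7), 0)
  # frozen value cross-checked with 30-digit arithmetic
  expect_equal(hill_saturation(90, 37, 2.7), 0.916827894156506,
               tolerance = 1e-12)

  # exact inverse over the full domain
  po2 <- c(10, 50, 200, 600, exp(seq(log(0.5), log(3000), length.out = 50)))
  expect_equal(hill_tension(hill_saturation(po2, 37, 2.7), 37, 2.7), po2,
               tolerance = 1e-9)
  so2 <- seq(0.001, 0.999, length.out = 60)
  expect_equal(hill_saturation(hill_tension(so2, 26, 2.2), 26, 2.2), so2,
               tolerance = 1e-12)

  # strictly increasing
  expect_true(all(diff(hill_saturation(seq(0, 800, by = 2), 37, 2.7)) > 0))

  expect_error(hill_saturation(-1), "non-negative")
  expect_error(hill_tension(1), "below 1")
  expect_error(hill_tension(-0.1), "non-negative")
})

test_that("oxygen content sums dissolved and bound fractions", {
  expect_equal(o2_content(90, hill_saturation(90), 0.42), 0.195323857772866,
               tolerance = 1e-12)
  expect_equal(o2_content(600, hill_saturation(600), 0.42), 0.228486467365189,
               tolerance = 1e-12)
  expect_equal(o2_content(0, 0, 0.42), 0)
  expect_equal(o2_content(0, 0, 0.9), 0)
  expect_error(o2_content(90, 1.2, 0.4), "domain")
})

test_that("content inversion solves Eq-4-plus-Hill uniquely and precisely", {
  k <- ox_constants()
  # round trip at hyperoxic tension
  ct <- o2_content(600, hill_saturation(600), 0.42)
  st <- invert_content(ct, 0.42)
  expect_equal(st$po2, 600, tolerance = 1e-6 / 600)
  expect_equal(st$so2, hill_saturation(st$po2), tolerance = 1e-12)

  # zero content maps to the zero state
  st0 <- invert_content(0, 0.42)
  expect_equal(st0$po2, 0)
  expect_equal(st0$so2, 0)

  # frozen derived value (independent bisection oracle)
  expect_equal(invert_content(0.16208, 0.42)$po2, 57.0960574860911,
               tolerance = 1e-8)

  # residual below 1e-10 absolute across a content range, vs uniroot oracle
  contents <- seq(0.001, 0.22, length.out = 25)
  st <- invert_content(contents, 0.42)
  expect_true(all(abs(st$content - contents) < 1e-10))
  oracle <- vapply(contents, function(ct) {
    stats::uniroot(function(p) o2_content(p, hill_saturation(p), 0.42) - ct,
                   c(0, 5000), tol = 1e-12)$root
  }, numeric(1))
  expect_equal(st$po2, oracle, tolerance = 1e-7)

  # out-of-range content is a range error
  expect_error(invert_content(1, 0.42), "range")
  expect_error(invert_content(-0.01, 0.42), "range")
})

test_that("mean capillary saturation follows the linear-extraction identity", {
  expect_equal(mean_capillary_saturation(1.0, 0.4), 0.8)
  expect_equal(mean_capillary_saturation(0.73, 0), 0.73)
  expect_equal(mean_capillary_saturation(hill_saturation(90), 0.34),
               0.760967152149900, tolerance = 1e-12)
})

test_that("saturation-linear capillary profile reproduces the classical venous state", {
  prof <- capillary_profile(90, 0.42, oef = 0.34, mode = "so2_linear",
                            state_label = "air")
  n <- nrow(prof)
  sao2 <- hill_saturation(90)
  # venous SO2 = SaO2 * (1 - OEF) exactly in this mode
  expect_equal(prof$so2[n], sao2 * (1 - 0.34), tolerance = 1e-12)
  expect_equal(prof$so2[n], 0.605106410143294, tolerance = 1e-12)
  expect_equal(prof$po2_mmhg[n], 43.3361664400617, tolerance = 1e-9)
  # mean saturation equals the analytic capillary mean (linear -> trapezoid exact)
  expect_equal(mean(prof$so2), mean_capillary_saturation(sao2, 0.34),
               tolerance = 1e-12)
  # dissolved fraction is small at normoxia
  dissolved <- ox_constants()$alpha_p * prof$po2_mmhg
  expect_true(all(dissolved / prof$content_mlo2_per_ml < 0.02))
})

test_that("content-linear capillary profile conserves oxygen exactly", {
  # seeded random scenarios: content(0) - content(L) equals the requested
  # extraction to 1e-12 relative
  withr::with_seed(42, {
    for (i in 1:50) {
      pao2 <- runif(1, 60, 600)
      hct <- runif(1, 0.2, 0.6)
      oef <- runif(1, 0, 0.9)
      prof <- capillary_profile(pao2, hct, oef = oef, n_z = 21)
      n <- nrow(prof)
      extraction <- oef * prof$content_mlo2_per_ml[1]
      expect_equal(prof$content_mlo2_per_ml[1] - prof$content_mlo2_per_ml[n],
                   extraction, tolerance = 1e-12)
      expect_equal(attr(prof, "oef_effective"), oef, tolerance = 1e-12)
      # monotone decline whenever extraction > 0
      if (extraction > 0) {
        expect_true(all(diff(prof$po2_mmhg) < 0))
        expect_true(all(diff(prof$so2) < 0))
        expect_true(all(diff(prof$content_mlo2_per_ml) < 0))
      }
    }
  })
})

test_that("capillary profile handles degenerate and infeasible extraction", {
  # zero extraction: constant profile at the arterial state
  prof <- capillary_profile(90, 0.42, extraction = 0)
  expect_equal(unique(round(prof$po2_mmhg, 9)), 90)
  expect_equal(unique(round(prof$so2, 12)), round(hill_saturation(90), 12))
  expect_equal(attr(prof, "oef_effective"), 0)

  # extraction above arterial content is infeasible
  ca <- o2_content(90, hill_saturation(90), 0.42)
  expect_error(capillary_profile(90, 0.42, extraction = 1.01 * ca),
               "infeasible")
  expect_error(capillary_profile(90, 0.42), "exactly one")
  expect_error(capillary_profile(90, 0.42, oef = 0.3, extraction = 0.01),
               "exactly one")
})

test_that("hyperoxic profile under fixed normoxic extraction matches the root-solve oracle", {
  ca_air <- o2_content(90, hill_saturation(90), 0.42)
  prof <- capillary_profile(600, 0.42, extraction = 0.34 * ca_air,
                            state_label = "oxygen")
  n <- nrow(prof)
  expect_equal(prof$po2_mmhg[n], 57.0940604579629, tolerance = 1e-7)
  # venous content equals arterial(oxygen) minus the air-state extraction
  ca_ox <- o2_content(600, hill_saturation(600), 0.42)
  expect_equal(prof$content_mlo2_per_ml[n], ca_ox - 0.34 * ca_air,
               tolerance = 1e-14)
})
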