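test_that("erythrocyte water fraction is a strictly increasing bijection of hematocrit", {
  expect_equal(erythrocyte_water_fraction(0), 0)
  expect_equal(erythrocyte_water_fraction(1), 1)
  expect_equal(erythrocyte_water_fraction(0.42), 0.347928994082840,
               tolerance = 1e-12)
  hct <- seq(0, 1, length.out = 101)
  fe <- erythrocyte_water_fraction(hct)
  expect_true(all(diff(fe) > 0))
  expect_true(all(fe >= 0 & fe <= 1))
})

test_that("field parameters evaluate the affine field dependence", {
  bc <- test_blood_coeffs
  p0 <- field_params(0, bc)
  expect_equal(p0$r1_eox, bc$r1eox_b0)
  expect_equal(p0$r1_pox, bc$r1pox_b0)
  # affine: equal increments per tesla
  p1 <- field_params(1, bc); p2 <- field_params(2, bc); p3 <- field_params(3, bc)
  for (f in c("r1_eox", "r1_p", "r1_dhb", "r1_pox")) {
    expect_equal(p2[[f]] - p1[[f]], p3[[f]] - p2[[f]], tolerance = 1e-12)
  }
  # exact affine evaluation at 3 T vs independent arithmetic
  expect_equal(p3$r1_eox, 0.87 - 0.08 * 3)
  expect_equal(p3$r1_p, 0.82 - 0.053 * 3)
  expect_equal(p3$r1_dhb, 0.075 * 3)
  expect_equal(p3$r1_pox, 3.5e-4 - 3e-5 * 3)
  # a parameter going negative at the requested field is named
  bad <- blood_coefficients(1, 0, 0.8, 0, 0.1, 0, 3e-4, -3e-5)
  expect_error(field_params(20, bad), "r1_pox")
})

test_that("blood R1 has the two-compartment structure and limits", {
  bc <- test_blood_coeffs
  k <- ox_constants()
  # hct = 0: pure plasma line R1p + r1pOx * PO2
  fp <- field_params(3, bc)
  po2 <- c(0, 40, 90, 600)
  expect_equal(blood_r1(po2, 0, 3, bc), fp$r1_p + fp$r1_pox * po2,
               tolerance = 1e-14)
  # degenerate relaxivities: po2-independent mixture
  flat <- blood_coefficients(1, 0, 0.8, 0, 0, 0, 0, 0)
  fe <- erythrocyte_water_fraction(0.42)
  expect_equal(unique(round(blood_r1(po2, 0.42, 3, flat), 12)),
               round(fe * 1 + (1 - fe) * 0.8, 12))
  # high-tension asymptote of the erythrocyte term: deoxyhemoglobin vanishes
  r1_hi <- blood_r1(1e7, 0.42, 3, bc)
  expect_equal(fe * fp$r1_eox,
               r1_hi - (1 - fe) * (fp$r1_p + fp$r1_pox * 1e7),
               tolerance = 1e-6)
  expect_error(blood_r1(-5, 0.42, 3, bc), "non-negative")
})

test_that("blood R1 differences decompose into opposing oxygen and deoxyhemoglobin terms", {
  bc <- test_blood_coeffs
  k <- ox_constants()
  withr::with_seed(11, {
    for (i in 1:25) {
      p1 <- runif(1, 10, 300)
      p2 <- p1 + runif(1, 1, 300)
      hct <- runif(1, 0.2, 0.6)
      b0 <- runif(1, 1.5, 7)
      fp <- field_params(b0, bc)
      fe <- erythrocyte_water_fraction(hct, k$w_rbc, k$w_plasma)
      s1 <- hill_saturation(p1, bc$p50_blood, bc$hill_n_blood)
      s2 <- hill_saturation(p2, bc$p50_blood, bc$hill_n_blood)
      oxy_term <- (1 - fe) * fp$r1_pox * (p2 - p1)
      dhb_term <- fe * fp$r1_dhb * k$hb_molar * (s1 - s2)
      expect_gt(oxy_term, 0)
      expect_lt(dhb_term, 0)
      expect_equal(delta_r1_blood(p1, p2, hct, b0, bc),
                   oxy_term + dhb_term, tolerance = 1e-12)
    }
  })
})

test_that("blood R1 change is null for a null challenge and antisymmetric", {
  bc <- test_blood_coeffs
  expect_equal(delta_r1_blood(90, 90, 0.42, 1.5, bc), 0)
  expect_equal(delta_r1_blood(43, 57, 0.42, 1.5, bc),
               -delta_r1_blood(57, 43, 0.42, 1.5, bc), tolerance = 1e-15)
  # venous-range tensions with a modest change: deoxyhemoglobin dominates,
  # net change negative
  expect_lt(delta_r1_blood(43, 57, 0.42, 1.5, bc), 0)
})

test_that("oxygen relaxivity follows the Lorentzian-plus-temperature model", {
  rc <- test_relax_coeffs
  # exact formula at (3 T, 37 C)
  expect_equal(oxygen_relaxivity(3, 37, rc),
               rc$c1 / (1 + rc$c2 * 9) + rc$c3 + rc$c_temp * 37,
               tolerance = 1e-15)
  # c2 = 0: field-independent value
  rc0 <- relaxivity_coefficients(2e-4, 0, 2e-4, -2e-6)
  expect_equal(oxygen_relaxivity(c(1.5, 7), 37, rc0),
               rep(2e-4 + 2e-4 - 2e-6 * 37, 2))
  # high-field asymptote c3 + c_temp * T
  expect_equal(oxygen_relaxivity(1e8, 37, rc), rc$c3 + rc$c_temp * 37,
               tolerance = 1e-12)
  # strictly decreasing across the standard fields
  expect_true(all(diff(oxygen_relaxivity(c(1.5, 3, 4.7, 7), 37, rc)) < 0))
  expect_error(oxygen_relaxivity(0, 37, rc), "positive")
})

test_that("tissue R1 change is linear in the tension change", {
  rc <- test_relax_coeffs
  expect_equal(delta_r1_tissue(0, 1.5, 37, rc), 0)
  d1 <- delta_r1_tissue(25, 1.5, 37, rc)
  expect_equal(delta_r1_tissue(50, 1.5, 37, rc), 2 * d1, tolerance = 1e-15)
  expect_equal(delta_r1_tissue(50, 3, 37, rc),
               50 * oxygen_relaxivity(3, 37, rc), tolerance = 1e-15)
})
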