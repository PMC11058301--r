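test_that("viscosity polynomials reproduce hand-evaluated values", {
  ## raw polynomial values in Pa.s (cP x 1e-3)
  expect_equal(mu_zero(0, raw = TRUE), -0.129e-3)
  expect_equal(mu_zero(0.45, raw = TRUE), 133.366605e-3, tolerance = 1e-12)
  expect_equal(mu_inf(0), 14.439e-3)
  expect_equal(mu_inf(0.45), 10.5351825e-3, tolerance = 1e-12)
  expect_equal(mu_inf(0.2), 11.31032e-3, tolerance = 1e-12)
  ## floor engages where the raw polynomial is negative
  expect_gt(mu_zero(0), 0)
  expect_equal(mu_zero(0), rheology_coefficients()$mu_floor)
  expect_error(mu_zero(-0.1), "phi")
  expect_error(mu_inf(1.2), "phi")
})

test_that("unit round-trip cP -> Pa.s -> cP reproduces printed coefficients", {
  co <- rheology_coefficients()
  phis <- c(0, 0.2, 0.45, 0.6)
  back <- mu_zero(phis, co, raw = TRUE) / co$output_unit_scale
  expect_equal(back, co$mu0_poly[1] * phis^2 + co$mu0_poly[2] * phis +
                 co$mu0_poly[3], tolerance = 1e-12)
})

test_that("generalized shear rate matches closed forms", {
  expect_equal(generalized_shear_rate(tensor_field(0, 0, 0)), 0)
  ## simple shear du/dy = 10/s: D off-diagonals 5
  expect_equal(generalized_shear_rate(tensor_field(0, 5, 0)), 10)
  ## pure stretch diag(1, -1): sqrt(2 * 2) = 2
  expect_equal(generalized_shear_rate(tensor_field(1, 0, -1)), 2)
  ## hoop component enters the trace
  expect_equal(generalized_shear_rate(tensor_field(0, 0, 0, tt = 3)),
               sqrt(2 * 9))
})

test_that("RBC viscosity limits, frozen value, and bracketing hold", {
  co <- rheology_coefficients()
  phis <- seq(0.05, 0.6, by = 0.05)
  ## zero-shear limit: mu0 (1 + phi) / 2 exactly
  expect_equal(rbc_viscosity(phis, 0),
               0.5 * mu_zero(phis, raw = TRUE) * (1 + phis))
  ## infinite-shear limit approached from above
  expect_equal(rbc_viscosity(phis, 1e12),
               0.5 * mu_inf(phis, raw = TRUE) * (1 + phis),
               tolerance = 1e-8)
  ## independently hand-computed scalar value (phi = 0.45, 10/s, k = 11 s)
  expect_equal(rbc_viscosity(0.45, 10), 12.218634e-3, tolerance = 1e-7)
  ## bracketing between the zero- and infinite-shear limits; note the
  ## printed fits cross near phi = 0.11 (mu0 < mu_inf below it), so the
  ## bounds are ordered per phi
  for (ph in phis) {
    gd <- 10^seq(-3, 6, by = 0.5)
    v <- rbc_viscosity(ph, gd)
    b1 <- 0.5 * mu_zero(ph, raw = TRUE) * (1 + ph)
    b2 <- 0.5 * mu_inf(ph, raw = TRUE) * (1 + ph)
    expect_true(all(v <= max(b1, b2) * (1 + 1e-12)))
    expect_true(all(v >= min(b1, b2) * (1 - 1e-12)))
  }
  expect_error(rbc_viscosity(0.2, -1), "gamma_dot")
})

test_that("RBC viscosity is non-increasing in shear rate where mu0 > muinf", {
  ## shear-thinning holds above the fit crossover (phi > ~0.11)
  gd <- 10^seq(-3, 6, by = 0.1)
  for (ph in c(0.15, 0.2, 0.45, 0.6)) {
    expect_gt(mu_zero(ph, raw = TRUE), mu_inf(ph, raw = TRUE))
    v <- rbc_viscosity(ph, gd)
    expect_true(all(diff(v) <= 1e-12 * v[1]))
  }
})

test_that("phase stresses match hand evaluations and sum to -pI at rest", {
  ## hydrostatic limit
  Ts <- plasma_stress(p = 100, phi = 0, Dp = tensor_field(0, 0, 0))
  expect_equal(c(Ts$xx, Ts$yy, Ts$tt), rep(-100, 3))
  expect_equal(Ts$xy, 0)
  ## plasma absent
  Ts <- plasma_stress(p = 100, phi = 1, Dp = tensor_field(1, 2, 3))
  expect_equal(max(abs(c(Ts$xx, Ts$xy, Ts$yy, Ts$tt))), 0)
  ## simple shear 100/s, phi = 0.2: shear stress 2 * mu_p * 0.8 * 50
  Ts <- plasma_stress(p = 0, phi = 0.2, Dp = tensor_field(0, 50, 0))
  expect_equal(Ts$xy, 0.0768, tolerance = 1e-12)
  ## RBC phase absent
  Tr <- rbc_stress(p = 50, phi = 0, Dr = tensor_field(1, 2, 3))
  expect_equal(max(abs(c(Tr$xx, Tr$xy, Tr$yy, Tr$tt))), 0)
  ## Dr = 0 -> -p phi I
  Tr <- rbc_stress(p = 50, phi = 0.3, Dr = tensor_field(0, 0, 0))
  expect_equal(c(Tr$xx, Tr$yy, Tr$tt), rep(-15, 3))
  ## chains the rbc_viscosity value: 2 mu_r phi gamma/2
  Tr <- rbc_stress(p = 0, phi = 0.45, Dr = tensor_field(0, 5, 0))
  expect_equal(Tr$xy, 2 * 12.218634e-3 * 0.45 * 5, tolerance = 1e-6)
  ## pressure shared by volume fraction sums to the total at rest
  for (ph in c(0, 0.2, 0.45, 0.68)) {
    Tp <- plasma_stress(p = 77, phi = ph, Dp = tensor_field(0, 0, 0))
    Tr <- rbc_stress(p = 77, phi = ph, Dr = tensor_field(0, 0, 0))
    expect_equal(Tp$xx + Tr$xx, -77)
    expect_equal(Tp$tt + Tr$tt, -77)
  }
})
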