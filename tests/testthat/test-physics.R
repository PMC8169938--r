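test_that("Young's modulus follows the single-point secant formula", {
  # strain = 1 and stress = 1 N/m^2
  t1 <- tensile_test(mass = 1 / 9.81, strip_length = 1, cross_section = 1,
                     elongation = 1)
  expect_equal(young_modulus(t1), 1)
  t2 <- tensile_test(0.010, 0.05, 1e-5, 0.005)
  expect_equal(young_modulus(t2), 98100)  # g m L / (A dL) by hand
  t3 <- tensile_test(0.020, 0.05, 1e-5, 0.005)
  expect_equal(young_modulus(t3), 2 * young_modulus(t2))
  expect_error(tensile_test(-1, 0.05, 1e-5, 0.005), "mass")
  expect_error(tensile_test(0.01, 0.05, 0, 0.005), "cross_section")
})

test_that("compression frequency reproduces the experimental protocol grid", {
  expect_equal(compression_frequency(0.2, 1.8), 0.5)
  expect_equal(compression_frequency(0.2, 0.2), 2.5)
  expect_equal(compression_frequency(0.5, 0.5), 1.0)
  expect_equal(sapply(c(0.2, 0.3, 0.8, 1.8),
                      function(toff) compression_frequency(0.2, toff)),
               c(2.5, 2, 1, 0.5))
  expect_error(compression_frequency(0, 0.2), "time_on")
  expect_error(compression_frequency(0.2, -1), "time_off")
})

test_that("Womersley number matches direct formula evaluation and scaling", {
  geom <- tube_geometry(5e-3, 0.5e-3, 38e-3)
  glyc <- fluid_properties(1000, 2.26e-3)
  wo <- womersley_number(geom, glyc, protocol_hz(0.5))
  expect_equal(wo, 2.5e-3 * sqrt(1000 * 2 * pi * 0.5 / 2.26e-3),
               tolerance = 1e-12)
  expect_equal(wo, 2.95, tolerance = 0.01)
  thick <- fluid_properties(1000, 4 * 2.26e-3)
  expect_equal(womersley_number(geom, thick, protocol_hz(0.5)), wo / 2)
  # the experimental grid lands mostly in the 2-8 range
  grid <- expand.grid(r = c(1.5e-3, 2.5e-3, 4e-3), f = c(0.5, 1, 1.5, 2, 2.5),
                      mu = c(0.95e-3, 2.26e-3))
  wos <- mapply(function(r, f, mu) {
    womersley_number(tube_geometry(2 * r, 0.5e-3, 38e-3),
                     fluid_properties(1000, mu), protocol_hz(f))
  }, grid$r, grid$f, grid$mu)
  expect_gt(mean(wos >= 2 & wos <= 8), 0.6)
})

test_that("oscillatory velocity profile has the right limits", {
  # no-slip at the wall for any Wo
  for (wo in c(0, 0.1, 1, 5, 20)) {
    expect_equal(womersley_profile(wo, 1), 0, tolerance = 1e-10)
  }
  # Poiseuille limit
  xi <- seq(0, 1, by = 0.05)
  expect_lt(max(abs(womersley_profile(0.1, xi) - (1 - xi^2))), 1e-2)
  # flattening at high Wo
  expect_gt(womersley_profile(10, 0.5), 0.75)
  expect_gt(womersley_profile(50, 0.9), 0.5)
  expect_error(womersley_profile(5, 1.2), "positions")
  expect_error(womersley_profile(-1, 0.5), "wo")
})

test_that("k_w correction is bounded, monotone, and matches quadrature", {
  expect_equal(kw_correction(0), 0.5, tolerance = 1e-3)
  expect_equal(kw_correction(0.1), 0.5, tolerance = 1e-3)
  expect_gt(kw_correction(200), 0.95)
  grid <- kw_correction(c(0.1, 0.5, 1, 2, 5, 10, 20, 50))
  expect_true(all(diff(grid) >= 0))
  expect_true(all(grid >= 0.5 & grid <= 1))
  expect_equal(kw_correction(5), oracle_kw(5), tolerance = 1e-3)
  expect_error(kw_correction(-0.5), "wo")
})

test_that("Moens-Korteweg speed reproduces the worked compliant-tube case", {
  geom <- tube_geometry(5e-3, 0.4e-3, 38e-3)
  water <- fluid_properties(1000, 0.95e-3)
  c0 <- moens_korteweg_speed(47e3, geom, water)
  expect_equal(c0, 2, tolerance = 0.05)      # ~2 m/s
  expect_equal(moens_korteweg_speed(4 * 47e3, geom, water), 2 * c0)
  geom2 <- tube_geometry(5e-3, 0.5e-3, 38e-3)
  expect_equal(moens_korteweg_speed(47e3, geom2, water), 2.168,
               tolerance = 1e-3)
  expect_error(moens_korteweg_speed(-1, geom, water), "young_modulus")
})

test_that("natural frequency is c / 2L", {
  geom <- tube_geometry(5e-3, 0.4e-3, 38e-3)
  water <- fluid_properties(1000, 0.95e-3)
  c0 <- moens_korteweg_speed(47e3, geom, water)
  expect_equal(natural_frequency(c0, geom), 25, tolerance = 0.1 * 25)
  long <- tube_geometry(5e-3, 0.4e-3, 2 * 38e-3)
  expect_equal(natural_frequency(c0, long), natural_frequency(c0, geom) / 2)
  expect_equal(natural_frequency(60, geom), 60 / 0.076, tolerance = 1e-10)
})

test_that("peristaltic reference flowrate is F A P", {
  q <- peristaltic_flowrate(protocol_hz(2.5), compliant_geom())
  expect_equal(flow_m3s_to_ulps(q), 172, tolerance = 0.005)
  q2 <- peristaltic_flowrate(protocol_hz(1), tube_geometry(3e-3, 0.5e-3, 38e-3))
  expect_equal(flow_m3s_to_ulps(q2), 24.7, tolerance = 0.005)
})

test_that("glycerol-water viscosity reproduces the six printed values", {
  printed <- c(0.95, 1.10, 1.31, 1.56, 1.87, 2.26)
  fractions <- c(0, 0.05, 0.10, 0.15, 0.20, 0.25)
  got <- viscosity_pas_to_cp(glycerin_water_viscosity(fractions, 22))
  expect_true(all(abs(got - printed) / printed < 0.02))
  expect_lt(viscosity_pas_to_cp(glycerin_water_viscosity(0.10, 22)),
            viscosity_pas_to_cp(glycerin_water_viscosity(0.20, 22)))
  expect_error(glycerin_water_viscosity(1.5, 22), "fraction")
  expect_error(glycerin_water_viscosity(0.1, 150), "temperature")
})

test_that("Poiseuille resistance scales as mu L / r^4", {
  geom <- tygon_geom()
  base <- poiseuille_resistance_scaling(fluid_properties(1000, 0.95e-3), geom)
  expect_equal(poiseuille_resistance_scaling(fluid_properties(1000, 1.9e-3),
                                             geom) / base, 2)
  half_r <- tube_geometry(1.5e-3, 0.5e-3, 38e-3)
  expect_equal(poiseuille_resistance_scaling(fluid_properties(1000, 0.95e-3),
                                             half_r) / base, 16)
  expect_equal(2.26 / 0.95, 2.38, tolerance = 0.005)
  r226 <- poiseuille_resistance_scaling(fluid_properties(1000, 2.26e-3), geom)
  expect_equal(r226 / base, 2.26 / 0.95, tolerance = 1e-12)
})

test_that("calculators obey exact power-law scaling in every argument", {
  set.seed(101)
  for (i in 1:20) {
    k <- exp(stats::runif(1, -1, 1))
    E <- stats::runif(1, 1e4, 1e6)
    d <- stats::runif(1, 1e-3, 8e-3)
    h <- stats::runif(1, 2e-4, 1e-3)
    L <- stats::runif(1, 0.01, 0.05)
    rho <- stats::runif(1, 900, 1200)
    mu <- stats::runif(1, 5e-4, 5e-3)
    f <- stats::runif(1, 0.3, 2.4)
    g0 <- tube_geometry(d, h, L)
    fl0 <- fluid_properties(rho, mu)
    p0 <- protocol_hz(f)
    # Moens-Korteweg: c ~ E^1/2 h^1/2 rho^-1/2 d^-1/2
    c0 <- moens_korteweg_speed(E, g0, fl0)
    expect_equal(moens_korteweg_speed(k * E, g0, fl0), sqrt(k) * c0)
    expect_equal(moens_korteweg_speed(E, g0, fluid_properties(k * rho, mu)),
                 c0 / sqrt(k))
    # natural frequency ~ c / L
    expect_equal(natural_frequency(k * c0, g0), k * natural_frequency(c0, g0))
    # peristaltic ~ F A P: doubling d quadruples A
    q0 <- peristaltic_flowrate(p0, g0)
    g2 <- tube_geometry(k * d, h, L)
    expect_equal(peristaltic_flowrate(p0, g2), k^2 * q0, tolerance = 1e-12)
    # Womersley number ~ r rho^1/2 F^1/2 mu^-1/2
    w0 <- womersley_number(g0, fl0, p0)
    expect_equal(womersley_number(g0, fluid_properties(rho, k * mu), p0),
                 w0 / sqrt(k))
    expect_equal(womersley_number(g0, fluid_properties(k * rho, mu), p0),
                 w0 * sqrt(k))
  }
})

test_that("complex Bessel J0 agrees with base besselJ on the real axis", {
  # covers both the series branch (|z| <= 12) and the asymptotic branch
  z <- c(0.3, 1, 4, 8, 11.9, 12.1, 20, 40)
  got <- liebauflow:::.besselJ0_complex(complex(real = z))
  expect_equal(Re(got), besselJ(z, 0), tolerance = 1e-7)
  expect_true(all(abs(Im(got)) < 1e-7))
})
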