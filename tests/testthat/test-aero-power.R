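# Power model: Reynolds number, drag modes, induced/profile power,
# mechanical power, isolines, bounding power.

test_that("Reynolds number matches hand evaluation and scales linearly", {
  m <- fixture_morph()
  kin <- kinematic_state(200, 2.8, unit = "rad")
  # S*n*Phi/nu = 3.6e-6 * 200 * 2.8 / 1.5e-5
  expect_equal(reynolds_number(kin, m), 3.6e-6 * 200 * 2.8 / 1.5e-5)
  expect_equal(reynolds_number(kin, m), 134.4)
  kin2 <- kinematic_state(400, 2.8, unit = "rad")
  expect_equal(reynolds_number(kin2, m) / reynolds_number(kin, m), 2)
  # degrees interface agrees with radians
  expect_equal(reynolds_number(kinematic_state(200, 2.8 * 180 / pi), m),
               reynolds_number(kin, m))
  expect_error(kinematic_state(-1, 2.8, unit = "rad"), "positive")
  expect_error(kinematic_state(200, 0, unit = "rad"), "amplitude")
})

test_that("profile drag coefficient: Re-based and fixed modes", {
  m <- fixture_morph()
  expect_identical(profile_drag_coefficient(100, m), 0.7)
  expect_equal(profile_drag_coefficient(131.7, m), 7 / sqrt(131.7))
  expect_equal(profile_drag_coefficient(131.7, m), 0.610, tolerance = 1e-3)
  m136 <- fixture_morph(cd_pro_fixed = 1.36)
  expect_identical(profile_drag_coefficient(50, m136), 1.36)
  expect_identical(profile_drag_coefficient(5000, m136), 1.36)
  expect_error(profile_drag_coefficient(0, m), "positive")
})

test_that("induced power matches the closed form and its symmetries", {
  m <- fixture_morph()
  kin <- kinematic_state(200, 2.8, unit = "rad")
  # independent scalar evaluation of kappa*(F_t/m_M)*sqrt(F_t/(2 rho Phi R^2))
  expected <- 1.2 * (1.2e-5 / 3e-7) *
    sqrt(1.2e-5 / (2 * 1.2 * 2.8 * (2.4e-3)^2))
  expect_equal(induced_power(kin, m), expected)
  # zero flight force
  m0 <- morphometrics(F_t = 0, R = 2.4e-3, S = 3.6e-6, m_M = 3e-7)
  expect_identical(induced_power(kin, m0), 0)
  # linear in kappa
  m2 <- fixture_morph(kappa = 2.4)
  expect_equal(induced_power(kin, m2), 2 * induced_power(kin, m))
  # monotone decreasing in amplitude
  phis <- seq(1, 3, by = 0.25)
  p <- induced_power(kinematic_state(rep(200, length(phis)), phis,
                                     unit = "rad"), m)
  expect_true(all(diff(p) < 0))
})

test_that("profile power obeys the exact frequency scaling laws", {
  kin1 <- kinematic_state(100, 2.5, unit = "rad")
  kin2 <- kinematic_state(200, 2.5, unit = "rad")
  m_fix <- fixture_morph(cd_pro_fixed = 1.36)
  expect_equal(profile_power(kin2, m_fix) / profile_power(kin1, m_fix), 8)
  m_re <- fixture_morph()
  expect_equal(profile_power(kin2, m_re) / profile_power(kin1, m_re),
               2^2.5)
  # independent evaluation with fixed cd
  expected <- 1.2 * 3.6e-6 * 100^3 * 2.5^3 * (2.4e-3)^3 * 0.2 * 100 *
    1.36 / (16 * 3e-7)
  expect_equal(profile_power(kin1, m_fix), expected)
  # vanishing amplitude
  tiny <- profile_power(kinematic_state(100, 1e-6, unit = "rad"), m_fix)
  expect_lt(tiny, 1e-12)
})

test_that("log-log slope of profile power vs n*Phi is exactly 3 / 2.5", {
  n <- seq(150, 260, length.out = 12)
  phi <- seq(2, 3, length.out = 12)
  kin <- kinematic_state(n, phi, unit = "rad")
  for (spec in list(list(m = fixture_morph(cd_pro_fixed = 1.36), s = 3),
                    list(m = fixture_morph(), s = 2.5))) {
    y <- log(profile_power(kin, spec$m))
    x <- log(n * phi)
    sl <- coef(lm(y ~ x))[2]
    expect_equal(unname(sl), spec$s, tolerance = 1e-10)
  }
})

test_that("mechanical power is the exact sum of its parts", {
  m <- fixture_morph()
  kin <- kinematic_state(c(180, 212, 240), c(150, 160, 170))
  pb <- mechanical_power(kin, m)
  expect_identical(pb$P_mech, pb$P_ind + pb$P_pro)
  expect_true(all(pb$P_mech >= pmax(pb$P_ind, pb$P_pro)))
  # kappa = 0 with fixed cd removes the induced term entirely
  m0 <- fixture_morph(cd_pro_fixed = 1.36, kappa = 0)
  pb0 <- mechanical_power(kin, m0)
  expect_identical(pb0$P_mech, pb0$P_pro)
  expect_identical(pb0$P_ind, rep(0, 3))
  # default fixture at the flight-typical operating point: independent
  # arithmetic evaluation of the full closed form
  dm <- default_morphometrics()
  k1 <- kinematic_state(212, 160)
  phi <- 160 * pi / 180
  Re <- 3.6e-6 * 212 * phi / 1.5e-5
  expect_equal(
    mechanical_power(k1, dm)$P_mech,
    1.2 * (1e-5 / 3e-7) * sqrt(1e-5 / (2 * 1.2 * phi * (2.4e-3)^2)) +
      1.2 * 3.6e-6 * 212^3 * phi^3 * (2.4e-3)^3 * 0.195 *
      (32 * pi^2 / 3) * (7 / sqrt(Re)) / (16 * 3e-7))
})

test_that("results are invariant to consistent unit rescaling", {
  # express lengths in mm with compensating conversions: R' = R*1e3 with
  # rho' = rho*1e-9 (kg/mm^3), S' = S*1e6, nu' = nu*1e6 leaves Re and the
  # power per kg unchanged except for the explicit W = kg m^2 s^-3 scale
  m <- fixture_morph()
  kin <- kinematic_state(200, 2.8, unit = "rad")
  m_mm <- morphometrics(F_t = m$F_t * 1e3, # kg mm s^-2
                        R = m$R * 1e3, S = m$S * 1e6, m_M = m$m_M,
                        rho = m$rho * 1e-9, g = m$g * 1e3,
                        kappa = m$kappa, r3_hat_cubed = m$r3_hat_cubed,
                        mean_abs_angvel_cubed = m$mean_abs_angvel_cubed,
                        nu = m$nu * 1e6)
  expect_equal(reynolds_number(kin, m_mm), reynolds_number(kin, m))
  # powers come out in kg mm^2 s^-3 = 1e-6 W
  expect_equal(induced_power(kin, m_mm) * 1e-6, induced_power(kin, m))
  expect_equal(profile_power(kin, m_mm) * 1e-6, profile_power(kin, m))
})

test_that("isolines satisfy the solver contract and the closed form", {
  # profile-only limit with fixed cd: n * Phi is constant along the curve
  m0 <- fixture_morph(cd_pro_fixed = 1.36, kappa = 0)
  P0 <- 60
  n_grid <- seq(150, 300, length.out = 50)
  iso <- solve_isoline(P0, n_grid, m0)
  expect_equal(nrow(iso), 50)
  expect_true(all(abs(iso$residual) <= 1e-9 * P0))
  const <- (16 * m0$m_M * P0 /
              (m0$rho * m0$S * m0$R^3 * m0$r3_hat_cubed *
                 m0$mean_abs_angvel_cubed * 1.36))^(1 / 3)
  expect_equal(iso$n_hz * iso$phi_rad, rep(const, 50), tolerance = 1e-6)
  expect_true(all(diff(iso$phi_deg) < 0))

  # full model with induced power: contract still holds
  m <- fixture_morph()
  iso2 <- solve_isoline(80, seq(160, 280, by = 10), m)
  expect_true(all(abs(iso2$residual) <= 1e-9 * 80))
  expect_true(all(diff(iso2$phi_deg) < 0))
  kin <- kinematic_state(iso2$n_hz, iso2$phi_rad, unit = "rad")
  expect_equal(mechanical_power(kin, m)$P_mech, rep(80, nrow(iso2)),
               tolerance = 1e-9)
})

test_that("unreachable power levels are omitted or rejected", {
  m <- fixture_morph()
  # a level below the minimum power at high frequency: low-n points only
  iso <- solve_isoline(40, seq(150, 400, by = 25), m)
  expect_true(length(attr(iso, "omitted_n")) > 0)
  expect_true(all(attr(iso, "omitted_n") > max(iso$n_hz)))
  expect_error(solve_isoline(1e-3, seq(150, 400, by = 50), m),
               "no isoline in range")
})

test_that("induced/profile ratio falls as amplitude grows", {
  m <- fixture_morph()
  phis <- seq(100, 200, by = 10)
  kin <- kinematic_state(rep(212, length(phis)), phis)
  pb <- mechanical_power(kin, m)
  expect_true(all(diff(pb$P_ind / pb$P_pro) < 0))
})

test_that("bounding power finds the isoline level of its own curve", {
  m <- fixture_morph()
  iso <- solve_isoline(75, seq(170, 260, by = 10), m)
  kin <- kinematic_state(iso$n_hz, iso$phi_rad, unit = "rad")
  bp <- bounding_power(kin, m)
  expect_equal(bp$P_max, 75, tolerance = 1e-8)
  # singleton trajectory
  one <- kinematic_state(212, 160)
  expect_equal(bounding_power(one, m)$P_max,
               mechanical_power(one, m)$P_mech)
  # adding a dominated point (lower n and Phi) never changes the max
  kin2 <- kinematic_state(c(iso$n_hz, 150), c(iso$phi_rad, 1),
                          unit = "rad")
  expect_equal(bounding_power(kin2, m)$P_max, bp$P_max)
  expect_error(bounding_power(structure(list(n = numeric(0),
                                             phi_rad = numeric(0)),
                                        class = "kinematic_state"), m),
               "empty")
})

test_that("morphometrics validate and round-trip through YAML", {
  expect_error(morphometrics(F_t = 1e-5, R = -1, S = 3.6e-6, m_M = 3e-7),
               "positive")
  expect_error(morphometrics(F_t = 1e-5, R = 2.4e-3, S = 3.6e-6,
                             m_M = 3e-7, cd_pro_fixed = -2), "cd_pro_fixed")
  expect_warning(fixture_morph(kappa = 0.5), "kappa")
  p <- tempfile(fileext = ".yaml")
  m <- fixture_morph(cd_pro_fixed = 1.36)
  write_morphometrics(m, p)
  m2 <- read_morphometrics(p)
  expect_equal(unclass(m2), unclass(m))
  # Re-based default survives the round trip too
  write_morphometrics(fixture_morph(), p)
  expect_null(read_morphometrics(p)$cd_pro_fixed)
})

test_that("isoline CSV round-trips with its power level", {
  m <- fixture_morph()
  iso <- solve_isoline(80, seq(170, 250, by = 20), m)
  p <- tempfile(fileext = ".csv")
  write_isoline(iso, p)
  back <- read_isoline(p)
  expect_equal(back$n_hz, iso$n_hz)
  expect_equal(back$phi_deg, iso$phi_deg)
  expect_equal(attr(back, "P_level"), 80)
})
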