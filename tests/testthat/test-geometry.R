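# Probed wave vectors for the three scattering geometries and the
# shift <-> velocity conversion.

test_that("transmission wave vector matches (4 pi / lambda) sin(theta/2)", {
  expect_equal(q_transmission(scattering_config(532, 90))$q_nm_inv,
               0.0167, tolerance = 5e-3)
  # theta -> 0 closes the scattering triangle: q -> 0
  expect_equal(q_transmission(scattering_config(532, 1e-9))$q_nm_inv, 0,
               tolerance = 1e-12)
  # theta = 180 gives the vacuum backscattering value 4 pi / lambda
  expect_equal(q_transmission(scattering_config(532, 180))$q_nm_inv,
               4 * pi / 532, tolerance = 1e-12)
  expect_equal(4 * pi / 532, 0.02362, tolerance = 2e-4)
  expect_false(q_transmission(scattering_config(532, 90))$index_dependent)
})

test_that("reflection wave vector matches (4 pi / lambda) sqrt(n^2 - cos^2(theta/2))", {
  expect_equal(q_reflection(scattering_config(532, 120, 1.54, "reflection"))$q_nm_inv,
               0.0344, tolerance = 2e-3)
  expect_equal(q_reflection(scattering_config(532, 120, 1.0, "reflection"))$q_nm_inv,
               (4 * pi / 532) * sqrt(1 - 0.25), tolerance = 1e-12)
  expect_equal((4 * pi / 532) * sqrt(1 - 0.25), 0.02046, tolerance = 2e-4)
  expect_true(q_reflection(scattering_config(532, 120, 1.54, "reflection"))$index_dependent)
})

test_that("backscattering wave vector is 4 pi n / lambda", {
  expect_equal(q_backscatter(scattering_config(532, n = 1.54,
                                               geometry = "backscattering"))$q_nm_inv,
               4 * pi * 1.54 / 532, tolerance = 1e-12)
  expect_equal(4 * pi * 1.54 / 532, 0.03638, tolerance = 2e-4)
  # vacuum limit reduces to the transmission theta = 180 value
  expect_equal(q_backscatter(scattering_config(532, n = 1,
                                               geometry = "backscattering"))$q_nm_inv,
               4 * pi / 532, tolerance = 1e-12)
  # halves when the wavelength doubles
  expect_equal(q_backscatter(scattering_config(1064, n = 1.54,
                                               geometry = "backscattering"))$q_nm_inv,
               0.01819, tolerance = 2e-3)
})

test_that("reflection at theta = 180 coincides with backscattering", {
  qr <- q_reflection(scattering_config(532, 180, 1.54, "reflection"))$q_nm_inv
  qb <- q_backscatter(scattering_config(532, n = 1.54,
                                        geometry = "backscattering"))$q_nm_inv
  expect_equal(qr, qb, tolerance = 1e-14)
})

test_that("transmission q is independent of n; all magnitudes scale as 1/lambda", {
  for (n in c(1, 1.33, 1.54, 2.4)) {
    expect_equal(q_transmission(scattering_config(532, 75, n))$q_nm_inv,
                 q_transmission(scattering_config(532, 75, 1))$q_nm_inv,
                 tolerance = 1e-14)
  }
  for (k in c(0.5, 2, 3.7)) {
    expect_equal(q_transmission(scattering_config(532 * k, 90))$q_nm_inv,
                 q_transmission(scattering_config(532, 90))$q_nm_inv / k,
                 tolerance = 1e-12)
    expect_equal(q_reflection(scattering_config(532 * k, 120, 1.54, "reflection"))$q_nm_inv,
                 q_reflection(scattering_config(532, 120, 1.54, "reflection"))$q_nm_inv / k,
                 tolerance = 1e-12)
  }
})

test_that("shift <-> velocity conversion matches the printed velocities and round-trips", {
  q <- q_transmission(scattering_config(532, 90))
  expect_equal(velocity_from_shift(13.18, q), 4958, tolerance = 5e-4)
  expect_equal(velocity_from_shift(8.60, q), 3235, tolerance = 5e-4)
  expect_identical(velocity_from_shift(0, q), 0)
  for (c0 in c(1590, 1860, 3235, 4960)) {
    expect_equal(velocity_from_shift(shift_from_velocity(c0, q), q), c0,
                 tolerance = 1e-13)
  }
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(scattering_config(-532, 90), "lambda_nm")
  expect_error(scattering_config(532, 190), "theta_deg")
  expect_error(scattering_config(532, 90, n = 0.8), ">= 1")
  expect_error(scattering_config(532, 0), "theta_deg")
  expect_error(velocity_from_shift(10, 0), "q = 0")
  expect_error(q_transmission(cfg_refl()), "transmission")
})

test_that("leakage-angle helper implements arcsin(sin(theta)/n)", {
  expect_equal(leakage_alpha(90, 1.54), asin(1 / 1.54) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(leakage_alpha(30, 1), 30, tolerance = 1e-12)
})
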