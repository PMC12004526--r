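# Lorentzian peak extraction and branch labelling.

make_noiseless <- function(center = 13.2, fwhm = 0.8, amp = 1000, base = 10,
                           f = seq(5, 20, by = 0.02)) {
  bls_spectrum(f, base + amp * (fwhm / 2)^2 / ((f - center)^2 + (fwhm / 2)^2),
               cfg_trans())
}

test_that("a noiseless Lorentzian is recovered essentially exactly", {
  fit <- fit_peaks(make_noiseless(), n_peaks = 1)
  expect_lt(abs(fit$peaks$center_f - 13.2), 1e-6)
  expect_lt(abs(fit$peaks$fwhm - 0.8), 1e-5)
  expect_lt(abs(fit$peaks$amplitude - 1000) / 1000, 1e-5)
  expect_lt(fit$chi2_dof, 1e-10)
})

test_that("center uncertainties are calibrated: about 95% coverage under Poisson noise", {
  hits <- 0L
  for (s in 1:50) {
    m <- spectrum_model(
      data.frame(branch = "L_par", c_mps = velocity_from_shift(
        13.2, q_transmission(cfg_trans())), fwhm_ghz = 0.8, amplitude = 1000),
      baseline = 10, noise = "poisson", seed = s)
    sp <- generate_spectrum(m, cfg_trans(), f_max_ghz = 20, df_ghz = 0.02)
    anti <- bls_spectrum(sp$frequency_ghz, sp$intensity, sp$config,
                         mask = list(c(-20, 5)))
    fit <- fit_peaks(anti, n_peaks = 1,
                     init = data.frame(center = 13.0, fwhm = 1, amplitude = 800))
    if (abs(fit$peaks$center_f - 13.2) <= 2 * fit$peaks$sigma_f) hits <- hits + 1L
  }
  expect_gte(hits, 47L)
})

test_that("three-peak spectrum emulating a fiber transmission measurement is resolved in rank order", {
  # QT, L_par and leakage QL as seen in VV transmission at theta = 90
  cfg <- cfg_trans()
  a_leak <- leakage_alpha(90, 1.54)
  v <- velocities_ti(silkworm, c(a_leak, 0))
  m <- spectrum_model(
    data.frame(branch = c("QT", "L_par", "QL"),
               c_mps = c(v$c_QT[1], v$c_QL[2], v$c_QL[1]),
               fwhm_ghz = c(0.6, 0.6, 1.2),
               amplitude = c(300, 1000, 800)),
    baseline = 10, noise = "poisson", seed = 99)
  sp <- generate_spectrum(m, cfg, f_max_ghz = 35, df_ghz = 0.03)
  anti <- bls_spectrum(sp$frequency_ghz, sp$intensity, cfg, mask = list(c(-35, 2)))
  fit <- fit_peaks(anti, n_peaks = 3)
  truth <- sort(attr(sp, "truth")$center_ghz)
  expect_equal(fit$peaks$center_f, truth, tolerance = 0.02)
  # branch labels via the q_par / q_bs dispersion test
  lab <- classify_branch(fit$peaks$center_f, cfg, alpha_deg = 0,
                         c_long = v$c_QL[2])
  expect_equal(lab, c("QT", "L_par", "QL"))
})

test_that("fits are equivariant under intensity rescaling", {
  sp <- make_noiseless()
  fit1 <- fit_peaks(sp, 1)
  sp2 <- bls_spectrum(sp$frequency_ghz, sp$intensity * 7, sp$config)
  fit2 <- fit_peaks(sp2, 1)
  expect_equal(fit2$peaks$center_f, fit1$peaks$center_f, tolerance = 1e-9)
  expect_equal(fit2$peaks$amplitude, 7 * fit1$peaks$amplitude, tolerance = 1e-6)
})

test_that("a spectrum mirrored to the Stokes side yields a negated center", {
  sp <- make_noiseless()
  fitA <- fit_peaks(sp, 1)
  spS <- bls_spectrum(rev(-sp$frequency_ghz), rev(sp$intensity), sp$config)
  fitS <- fit_peaks(spS, 1)
  expect_equal(fitS$peaks$center_f, -fitA$peaks$center_f, tolerance = 1e-8)
})

test_that("recovered-center bias is below 5% of the FWHM at SNR >= 20", {
  centers <- numeric(40)
  for (s in 1:40) {
    m <- spectrum_model(
      data.frame(branch = "L_par",
                 c_mps = velocity_from_shift(13.2, q_transmission(cfg_trans())),
                 fwhm_ghz = 0.8, amplitude = 200), # SNR = 200/sqrt(200+10) ~ 14 above baseline sd
      baseline = 10, noise = "poisson", seed = 1000 + s)
    sp <- generate_spectrum(m, cfg_trans(), f_max_ghz = 20, df_ghz = 0.02)
    anti <- bls_spectrum(sp$frequency_ghz, sp$intensity, sp$config,
                         mask = list(c(-20, 5)))
    fit <- fit_peaks(anti, 1, init = data.frame(center = 13, fwhm = 1,
                                                amplitude = 150))
    centers[s] <- fit$peaks$center_f
  }
  expect_lt(abs(mean(centers) - 13.2), 0.05 * 0.8)
})

test_that("overlapping peaks are flagged and failure modes are informative", {
  f <- seq(5, 20, by = 0.02)
  y <- 10 + 1000 * 0.16 / ((f - 12.9)^2 + 0.16) + 900 * 0.16 / ((f - 13.15)^2 + 0.16)
  sp <- bls_spectrum(f, y, cfg_trans())
  expect_warning(
    fit <- fit_peaks(sp, 2, init = data.frame(center = c(12.8, 13.2),
                                              fwhm = c(0.8, 0.8),
                                              amplitude = c(900, 900))),
    "half a FWHM")
  expect_true(all(fit$peaks$overlap))
  expect_error(fit_peaks(sp, 2, init = data.frame(center = c(1, 13),
                                                  fwhm = c(1, 1),
                                                  amplitude = c(10, 10))),
               "inside")
})

test_that("branch labelling follows the polarization and geometry selection rules", {
  cfg_vh <- cfg_trans(pol = "VH")
  expect_equal(classify_branch(4.94, cfg_vh, alpha_deg = 0), "PT")
  # 4.94 GHz at q_par = 0.0167 nm^-1 is the 1860 m/s transverse velocity
  expect_equal(velocity_from_shift(4.94, q_transmission(cfg_vh)), 1860,
               tolerance = 2e-3)
  expect_equal(classify_branch(10, cfg_refl(), alpha_deg = 90), "L_perp")
  # a frequency consistent with c * q_bs rather than c * q_par is leakage QL
  cfg <- cfg_trans()
  q_bs <- 4 * pi * 1.54 / 532
  f_ql <- shift_from_velocity(4960, q_bs)
  expect_equal(classify_branch(f_ql, cfg, alpha_deg = 0, c_long = 4960), "QL")
  f_par <- shift_from_velocity(4960, q_transmission(cfg))
  expect_equal(classify_branch(f_par, cfg, alpha_deg = 0, c_long = 4960), "L_par")
  expect_equal(classify_branch(0.55 * f_par, cfg, alpha_deg = 0, c_long = 4960), "QT")
  # no reference velocity: ambiguous, with an explanation
  out <- classify_branch(f_par, cfg, alpha_deg = 0)
  expect_equal(unclass(out)[1], "unassigned")
  expect_match(attr(out, "reason")[1], "c_long")
})

test_that("the Voigt (Gaussian-convolution) option broadens but keeps the center", {
  fit <- fit_peaks(make_noiseless(), 1, resolution_ghz = 0.2,
                   init = data.frame(center = 13.2, fwhm = 0.6, amplitude = 1000))
  expect_lt(abs(fit$peaks$center_f - 13.2), 1e-3)
  expect_lt(fit$peaks$fwhm, 0.8) # Lorentzian share shrinks when convolved
})
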