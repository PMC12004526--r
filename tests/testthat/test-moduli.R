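# Engineering moduli from stiffness constants and sound velocities.

test_that("silkworm 0% stiffness constants give the published moduli", {
  m <- moduli_from_tensor(silkworm)
  expect_equal(m$E_axial, 23.4, tolerance = 0.05 / 23.4)
  expect_equal(m$E_lateral, 10.4, tolerance = 0.05 / 10.4)
  expect_equal(m$K, 8.5, tolerance = 0.05 / 8.5)
  expect_equal(m$nu31, 0.51, tolerance = 0.005 / 0.51)
  expect_equal(m$nu12, 0.16, tolerance = 0.005 / 0.16)
  expect_equal(m$G13, 4.5, tolerance = 1e-12)
  expect_equal(m$G12, 4.5, tolerance = 1e-12)
})

test_that("spider 0% stiffness constants (C66 != C44) give the published moduli", {
  m <- moduli_from_tensor(spider)
  expect_equal(m$E_axial, 20.9, tolerance = 0.05 / 20.9)
  expect_equal(m$E_lateral, 9.2, tolerance = 0.05 / 9.2)
  expect_equal(m$K, 10.8, tolerance = 0.05 / 10.8)
  expect_equal(m$nu31, 0.35, tolerance = 0.005 / 0.35)
  expect_equal(m$nu12, 0.48, tolerance = 0.005 / 0.48)
  expect_equal(m$G13, 4.1, tolerance = 1e-12)
  expect_equal(m$G12, 3.1, tolerance = 1e-12)
})

test_that("isotropic tensors reduce to the isotropic formulas and match isotropic_moduli", {
  M0 <- 12.244; G0 <- 2.958; rho <- 1170
  iso <- ti_tensor(C11 = M0, C33 = M0, C44 = G0, C13 = M0 - 2 * G0, C66 = G0,
                   rho = rho)
  m <- moduli_from_tensor(iso)
  K0 <- M0 - 4 * G0 / 3
  expect_equal(m$E_axial, 9 * K0 * G0 / (3 * K0 + G0), tolerance = 1e-12)
  expect_equal(m$E_lateral, m$E_axial, tolerance = 1e-12)
  expect_equal(m$nu31, m$nu12, tolerance = 1e-12)
  # same numbers through the velocity route
  c_L <- sqrt(M0 * 1e9 / rho); c_T <- sqrt(G0 * 1e9 / rho)
  im <- isotropic_moduli(c_L, c_T, rho)
  expect_equal(im$E, m$E_axial, tolerance = 1e-9)
  expect_equal(im$nu, m$nu31, tolerance = 1e-9)
  expect_equal(im$K, m$K, tolerance = 1e-9)
})

test_that("film velocities give M = 12.2 GPa, G = 3.0 GPa, nu = 0.34", {
  im <- isotropic_moduli(film$c_L, film$c_T, film$rho)
  expect_equal(im$M, 12.2, tolerance = 0.05 / 12.2)
  expect_equal(im$G, 3.0, tolerance = 0.05 / 3.0)
  expect_equal(im$nu, 0.34, tolerance = 0.005 / 0.34)
})

test_that("Poisson's ratio limits: zero at c_L = sqrt(2) c_T, 1/2 as c_L/c_T -> inf", {
  expect_equal(isotropic_moduli(sqrt(2) * 1590, 1590, 1170)$nu, 0,
               tolerance = 1e-12)
  expect_equal(isotropic_moduli(1860 * 1e4, 1860, 1350)$nu, 0.5,
               tolerance = 1e-6)
  expect_error(isotropic_moduli(1500, 1590, 1170), "c_L")
  expect_error(isotropic_moduli(1600, 1590, 1170), "bulk")
})

test_that("single-phonon modulus rho c^2 reproduces the printed G and C11", {
  q <- q_transmission(scattering_config(532, 90))
  f_T <- shift_from_velocity(1860, q)
  expect_equal(longitudinal_modulus(f_T, q, 1350), 4.7, tolerance = 0.05 / 4.7)
  f_L <- shift_from_velocity(3100, q)
  expect_equal(longitudinal_modulus(f_L, q, 1350), 1350 * 3100^2 / 1e9,
               tolerance = 1e-9)
  expect_lt(abs(longitudinal_modulus(f_L, q, 1350) - 13.0), 0.05)
  expect_identical(longitudinal_modulus(0, q, 1350), 0)
})

test_that("{E3, E1, nu31, nu12, G13} reconstruct {C11, C13, C33} for C66 = C44 tensors", {
  set.seed(11)
  for (i in 1:20) {
    t0 <- random_ti_tensor()
    # impose C66 = C44 keeping validity
    t1 <- tryCatch(
      ti_tensor(C11 = t0$C11, C33 = t0$C33, C44 = min(t0$C44, 0.45 * t0$C11),
                C13 = t0$C13 * 0.9, rho = t0$rho),
      error = function(e) NULL)
    if (is.null(t1)) next
    m <- moduli_from_tensor(t1)
    # standard compliance inversion of a transversely isotropic solid
    S11 <- 1 / m$E_lateral; S33 <- 1 / m$E_axial
    S12 <- -m$nu12 / m$E_lateral; S13 <- -m$nu31 / m$E_axial
    S <- matrix(c(S11, S12, S13,
                  S12, S11, S13,
                  S13, S13, S33), 3, 3, byrow = TRUE)
    C <- solve(S)
    expect_rel_equal(C[1, 1], t1$C11, rtol = 1e-9)
    expect_rel_equal(C[3, 3], t1$C33, rtol = 1e-9)
    if (abs(t1$C13) > 1e-6) expect_rel_equal(C[1, 3], t1$C13, rtol = 1e-8)
  }
})

test_that("delta-method uncertainties scale linearly with input standard errors", {
  V1 <- diag(c(0.3, 1.0, 0.1, 0.3)^2)
  dimnames(V1) <- list(c("C11", "C33", "C44", "C13"), c("C11", "C33", "C44", "C13"))
  se1 <- moduli_from_tensor(silkworm, V1)$se
  se2 <- moduli_from_tensor(silkworm, V1 / 4)$se
  expect_equal(unname(se2), unname(se1) / 2, tolerance = 1e-6)
  expect_true(all(se1[c("E_axial", "E_lateral", "K")] > 0))
  # the axial Young's modulus error should be of order the published +/- 1.0
  expect_lt(abs(se1[["E_axial"]] - 1.0), 0.7)
})

test_that("unphysical tensors are caught in the moduli layer", {
  bad <- silkworm
  bad$C13 <- 21 # bypass constructor to hit the moduli-layer guard
  expect_error(moduli_from_tensor(bad), "not physical")
})
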