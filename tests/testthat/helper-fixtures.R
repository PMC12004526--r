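# Shared fixtures for the test suite.

silkworm <- silk_fixtures()$silkworm_0
spider <- silk_fixtures()$spider_0
film <- silk_fixtures()$film

cfg_trans <- function(theta = 90, pol = "VV") {
  scattering_config(532, theta, 1.54, "transmission", pol)
}
cfg_refl <- function(theta = 120, pol = "VV") {
  scattering_config(532, theta, 1.54, "reflection", pol)
}

# deterministic stream of random-but-valid transversely isotropic tensors
random_ti_tensor <- function() {
  repeat {
    C11 <- runif(1, 2, 60)
    C33 <- runif(1, 2, 60)
    C66 <- runif(1, 0.05, 0.95) * C11 # keeps C11 > |C12|
    C44 <- runif(1, 0.5, 15)
    C12 <- C11 - 2 * C66
    c13max <- sqrt((C11 + C12) * C33 / 2)
    C13 <- runif(1, -0.95, 0.95) * c13max
    t <- tryCatch(
      ti_tensor(C11 = C11, C33 = C33, C44 = C44, C13 = C13, C66 = C66,
                rho = runif(1, 800, 3000)),
      error = function(e) NULL)
    if (!is.null(t)) return(t)
  }
}

expect_rel_equal <- function(object, expected, rtol) {
  expect_lt(max(abs(object - expected) / abs(expected)), rtol)
}
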