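# Synthetic BLS spectra and velocity datasets with the statistical structure
# the analysis assumes: Lorentzian doublets at +/- c q / (2 pi) on a flat
# baseline with counting noise, and Christoffel-model velocities with
# Gaussian errors.

#' Synthetic-spectrum model
#'
#' Describes the peaks and noise of a synthetic BLS spectrum. Each peak is
#' specified by its acoustic branch and sound velocity; the frequency
#' position follows from the scattering geometry at generation time
#' (Brillouin doublet at +/- c q / (2 pi), with the backscattering-leakage
#' wave vector q_bs used for QL peaks in transmission spectra).
#'
#' @param peaks Data frame with columns `branch` (L_par, L_perp, QL, QT,
#'   PT), `c_mps`, `fwhm_ghz`, `amplitude` (peak height in counts).
#' @param baseline Flat background level (counts).
#' @param noise `"poisson"` (counting noise, default), `"gaussian"`, or
#'   `"none"`.
#' @param noise_sd Gaussian noise standard deviation (counts), used only for
#'   `noise = "gaussian"`.
#' @param seed Integer master seed; generation is bitwise reproducible for a
#'   fixed seed. Each generator operation draws from its own substream
#'   derived from the master seed.
#' @return An object of class `"spectrum_model"`.
#' @export
spectrum_model <- function(peaks, baseline = 10,
                           noise = c("poisson", "gaussian", "none"),
                           noise_sd = 5, seed = NULL) {
  noise <- match.arg(noise)
  peaks <- as.data.frame(peaks)
  req <- c("branch", "c_mps", "fwhm_ghz", "amplitude")
  if (!all(req %in% names(peaks)) || nrow(peaks) == 0) {
    abort_validation("`peaks` must have columns branch, c_mps, fwhm_ghz, amplitude")
  }
  if (any(peaks$fwhm_ghz <= 0) || any(peaks$amplitude <= 0) || any(peaks$c_mps <= 0)) {
    abort_validation("peak velocities, FWHMs and amplitudes must be > 0")
  }
  if (baseline < 0) abort_validation("`baseline` must be >= 0")
  structure(list(peaks = peaks, baseline = baseline, noise = noise,
                 noise_sd = noise_sd, seed = seed),
            class = "spectrum_model")
}

#' Generate a synthetic BLS spectrum
#'
#' Places a symmetric Brillouin doublet at +/- c q / (2 pi) for every peak
#' of the model on a flat baseline and adds the requested noise. The wave
#' vector of each peak follows the scattering geometry of `config`; QL peaks
#' in a transmission configuration are placed at the backscattering-leakage
#' wave vector q_bs = 4 pi n / lambda, emulating the strong oblique QL mode
#' seen in fiber transmission spectra.
#'
#' @param model A [spectrum_model()].
#' @param config A [scattering_config()].
#' @param f_max_ghz Half-width of the symmetric frequency grid (GHz).
#' @param df_ghz Channel spacing (GHz).
#' @return A [bls_spectrum()] whose `"truth"` attribute records the placed
#'   peak table (branch, q, center frequency).
#' @examples
#' m <- spectrum_model(data.frame(branch = "L_par", c_mps = 4960,
#'                                fwhm_ghz = 0.8, amplitude = 1000),
#'                     noise = "none")
#' s <- generate_spectrum(m, scattering_config(532, 90, n = 1.54))
#' @export
generate_spectrum <- function(model, config, f_max_ghz = 35, df_ghz = 0.05) {
  stopifnot(inherits(model, "spectrum_model"), inherits(config, "scattering_config"))
  f <- seq(-f_max_ghz, f_max_ghz, by = df_ghz)
  q_geom <- config_wave_vector(config)$q_nm_inv
  q_bs <- 4 * pi * config$n / config$lambda_nm
  pk <- model$peaks
  pk$q_nm_inv <- ifelse(pk$branch == "QL" & config$geometry == "transmission",
                        q_bs, q_geom)
  pk$center_ghz <- shift_from_velocity(pk$c_mps, pk$q_nm_inv)
  outside <- pk$center_ghz + pk$fwhm_ghz > f_max_ghz
  if (any(outside)) {
    abort_validation(sprintf(
      "peak(s) outside the frequency grid (|f| <= %g GHz): %s",
      f_max_ghz,
      paste(sprintf("%s at %.3g GHz", pk$branch[outside], pk$center_ghz[outside]),
            collapse = ", ")))
  }
  y <- rep(model$baseline, length(f))
  for (i in seq_len(nrow(pk))) {
    y <- y + lorentzian(f, pk$center_ghz[i], pk$fwhm_ghz[i], pk$amplitude[i]) +
      lorentzian(f, -pk$center_ghz[i], pk$fwhm_ghz[i], pk$amplitude[i])
  }
  if (model$noise != "none") {
    if (!is.null(model$seed)) set.seed(derive_seed(model$seed, "spectrum"))
    y <- switch(model$noise,
      poisson = rpois(length(y), lambda = y),
      gaussian = pmax(y + rnorm(length(y), sd = model$noise_sd), 0)
    )
  }
  out <- bls_spectrum(f, y, config = config)
  attr(out, "truth") <- pk
  out
}

#' Generate a synthetic angle-dependent velocity dataset
#'
#' Evaluates the Christoffel forward model [velocities_ti()] on an angle
#' grid and adds i.i.d. Gaussian noise of standard deviation `sigma_c`,
#' which is recorded per datum. PT data are restricted to alpha = 0 by
#' default (`pt_alpha_max`), matching the observability of the
#' pure-transverse mode in fiber measurements.
#'
#' @param tensor A [ti_tensor()].
#' @param alpha_deg Angle grid (degrees).
#' @param branches Branches to include.
#' @param sigma_c Gaussian noise standard deviation (m/s); a scalar, or a
#'   named vector per branch. Use 0 for noiseless forward-model values.
#' @param pt_alpha_max Maximum alpha at which PT data are generated;
#'   `Inf` generates PT on the whole grid (needed to identify C66 when it is
#'   fitted freely).
#' @param seed Integer master seed (substream-derived; reproducible).
#' @return Data frame with columns `alpha_deg`, `branch`, `c_mps`,
#'   `sigma_c_mps`.
#' @examples
#' tw <- ti_tensor(13.0, 32.1, 4.5, 8.6, rho = 1350)
#' generate_velocity_dataset(tw, sigma_c = 0)
#' @export
generate_velocity_dataset <- function(tensor, alpha_deg = seq(0, 90, by = 10),
                                      branches = c("QL", "QT", "PT"),
                                      sigma_c = 50, pt_alpha_max = 0,
                                      seed = NULL) {
  stopifnot(inherits(tensor, "ti_tensor"))
  if (length(alpha_deg) == 0) abort_validation("`alpha_deg` grid is empty")
  check_alpha(alpha_deg)
  branches <- match.arg(branches, c("QL", "QT", "PT"), several.ok = TRUE)
  v <- velocities_ti(tensor, alpha_deg)
  rows <- list()
  for (b in branches) {
    a <- if (b == "PT") alpha_deg[alpha_deg <= pt_alpha_max] else alpha_deg
    if (b == "QT") a <- a[a > 0 & a < 90] # QT degenerates with PT at the pure-mode ends
    if (length(a) == 0) next
    cb <- v[match(a, v$alpha_deg), paste0("c_", b)]
    sb <- if (length(sigma_c) > 1) sigma_c[[b]] else sigma_c
    rows[[b]] <- data.frame(alpha_deg = a, branch = b, c_mps = cb,
                            sigma_c_mps = rep(sb, length(a)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$sigma_c_mps > 0)) {
    if (!is.null(seed)) set.seed(derive_seed(seed, "velocity"))
    out$c_mps <- out$c_mps + rnorm(nrow(out), sd = out$sigma_c_mps)
  }
  # zero-sigma data still need positive weights downstream
  out$sigma_c_mps[out$sigma_c_mps == 0] <- 1e-6
  out
}

#' Reference material fixtures
#'
#' Stiffness tensors for silkworm (Bombyx mori) and spider (Nephila pilipes
#' major ampullate) silk at 0% and 10% tensile strain, and the isotropic
#' regenerated silk fibroin film, together with the standard measurement
#' constants (532 nm laser, refractive index 1.54). Stiffness values are
#' stored at full printed precision. The silkworm tensors use C66 = C44; the
#' spider tensors have independently determined C66.
#'
#' @return Named list with [ti_tensor()] entries `silkworm_0`,
#'   `silkworm_10`, `spider_0`, `spider_10`, a list `film` (`c_L`, `c_T` in
#'   m/s, `rho` in kg/m^3), and a list `optics` (`lambda_nm`, `n`).
#' @examples
#' silk_fixtures()$silkworm_0$C33 # 32.1 GPa
#' @export
silk_fixtures <- function() {
  list(
    silkworm_0 = ti_tensor(C11 = 13.0, C33 = 32.1, C44 = 4.5, C13 = 8.6,
                            rho = 1350),
    silkworm_10 = ti_tensor(C11 = 13.2, C33 = 32.5, C44 = 4.6, C13 = 8.9,
                             rho = 1350),
    spider_0 = ti_tensor(C11 = 14.4, C33 = 26.6, C44 = 4.1, C13 = 8.0,
                          C66 = 3.1, rho = 1350),
    spider_10 = ti_tensor(C11 = 13.8, C33 = 30.3, C44 = 4.2, C13 = 6.9,
                           C66 = 3.9, rho = 1350),
    film = list(c_L = 3235, c_T = 1590, rho = 1170),
    optics = list(lambda_nm = 532, n = 1.54)
  )
}
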