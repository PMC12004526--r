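# End-to-end pipeline drivers: simulate -> fit spectra -> velocities ->
# stiffness tensor -> moduli. These back the command-line interface
# (inst/cli/silkbls) and keep it a thin argument-parsing layer.

manifest_write <- function(out_dir, inputs, config, seed) {
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "silkbls",
    version = as.character(utils::packageVersion("silkbls")),
    seed = seed,
    inputs = inputs,
    config = config,
    config_md5 = unname(tools::md5sum(cfg_file))
  )
  unlink(cfg_file)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate a BLS measurement campaign to files
#'
#' Generates, for a fixture material or a user tensor, (i) a polarized (VV)
#' transmission spectrum including the backscattering-leakage QL peak,
#' (ii) a depolarized (VH) transmission spectrum with the PT peak, and
#' (iii) an angle-dependent velocity table, and writes them with a
#' reproducibility manifest (inputs, configuration hash, seed, version) to
#' `out_dir`. Deterministic under a fixed seed.
#'
#' The isotropic `film` fixture is simulated as the equivalent isotropic
#' tensor (C11 = C33 = rho c_L^2, C44 = C66 = rho c_T^2), giving
#' angle-independent branches.
#'
#' @param out_dir Output directory (created if needed).
#' @param fixture Name of a [silk_fixtures()] entry, ignored when `tensor`
#'   is given.
#' @param tensor Optional [ti_tensor()] to simulate instead of a fixture.
#' @param seed Integer master seed.
#' @param lambda_nm,n,theta_deg Optics of the simulated measurement.
#' @param sigma_c Velocity noise (m/s) for the velocity table.
#' @param fwhm_ghz,amplitude,baseline Peak shape of the simulated spectra.
#' @param alpha_deg Angle grid of the velocity table.
#' @return Invisibly, a named character vector of the written files.
#' @export
run_simulate <- function(out_dir, fixture = "silkworm_0", tensor = NULL,
                         seed = 1, lambda_nm = 532, n = 1.54, theta_deg = 90,
                         sigma_c = 50, fwhm_ghz = 0.8, amplitude = 1000,
                         baseline = 10, alpha_deg = seq(0, 90, by = 10)) {
  fx <- silk_fixtures()
  if (is.null(tensor)) {
    if (!fixture %in% names(fx)) {
      abort_validation(sprintf("unknown fixture `%s`; available: %s", fixture,
                               paste(names(fx), collapse = ", ")))
    }
    tensor <- if (fixture == "film") {
      f <- fx$film
      M <- f$rho * f$c_L^2 / GPA
      G <- f$rho * f$c_T^2 / GPA
      ti_tensor(C11 = M, C33 = M, C44 = G, C13 = M - 2 * G, C66 = G, rho = f$rho)
    } else {
      fx[[fixture]]
    }
  }
  stopifnot(inherits(tensor, "ti_tensor"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    abort_runtime(sprintf("cannot create output directory %s", out_dir))
  }

  cfg_vv <- scattering_config(lambda_nm, theta_deg, n, "transmission", "VV")
  cfg_vh <- scattering_config(lambda_nm, theta_deg, n, "transmission", "VH")
  v0 <- velocities_ti(tensor, 0)
  a_leak <- leakage_alpha(theta_deg, n)
  v_leak <- velocities_ti(tensor, a_leak)

  pk_vv <- data.frame(
    branch = c("L_par", "QL"),
    c_mps = c(v0$c_QL, v_leak$c_QL),
    fwhm_ghz = fwhm_ghz, amplitude = c(amplitude, 0.6 * amplitude))
  pk_vh <- data.frame(branch = "PT", c_mps = v0$c_PT,
                      fwhm_ghz = fwhm_ghz, amplitude = 0.3 * amplitude)

  files <- c(
    spectrum_vv = file.path(out_dir, "spectrum_vv.csv"),
    spectrum_vh = file.path(out_dir, "spectrum_vh.csv"),
    velocities = file.path(out_dir, "velocities.csv")
  )
  write_spectrum_csv(
    generate_spectrum(spectrum_model(pk_vv, baseline, seed = seed), cfg_vv),
    files[["spectrum_vv"]])
  write_spectrum_csv(
    generate_spectrum(spectrum_model(pk_vh, baseline, seed = seed + 1), cfg_vh),
    files[["spectrum_vh"]])
  write_velocity_csv(
    generate_velocity_dataset(tensor, alpha_deg, sigma_c = sigma_c, seed = seed),
    files[["velocities"]])
  manifest_write(out_dir,
                 inputs = list(fixture = fixture,
                               tensor_GPa = unclass(tensor)),
                 config = list(lambda_nm = lambda_nm, n = n,
                               theta_deg = theta_deg, sigma_c = sigma_c,
                               fwhm_ghz = fwhm_ghz, amplitude = amplitude,
                               baseline = baseline, alpha_deg = alpha_deg),
                 seed = seed)
  invisible(c(files, manifest = file.path(out_dir, "manifest.json")))
}

#' Fit peaks in a spectrum file and convert them to sound velocities
#'
#' Reads a spectrum CSV (with its JSON metadata sidecar), masks the
#' elastic-line vicinity, fits Lorentzian peaks on the anti-Stokes side,
#' labels the branches from the scattering geometry, and converts centers
#' to sound velocities with the wave vector the branch implies (q_bs for
#' leakage QL peaks in transmission, the geometry wave vector otherwise).
#'
#' @param path Spectrum CSV (sidecar at `<path>.json`).
#' @param n_peaks Number of peaks to fit on the anti-Stokes side.
#' @param alpha_deg Angle between the probed wave vector and the fiber axis.
#' @param c_long Optional reference longitudinal velocity (m/s) for
#'   L_par/QL disambiguation in transmission spectra.
#' @param mask_ghz Half-width of the elastic-line mask around zero shift.
#' @param out Optional output CSV path for the peak table.
#' @return Data frame with columns `branch`, `f_GHz`, `sigma_f_GHz`,
#'   `fwhm_GHz`, `amplitude`, `q_nm_inv`, `c_mps`, `sigma_c_mps`.
#' @export
run_fit_spectrum <- function(path, n_peaks = 1, alpha_deg = 0, c_long = NULL,
                             mask_ghz = 2, out = NULL) {
  sp <- read_spectrum_csv(path)
  if (is.null(sp$config)) {
    abort_validation(sprintf("spectrum %s has no metadata sidecar; geometry unknown", path))
  }
  # fit the anti-Stokes side only (masking the Stokes side and elastic line)
  anti <- bls_spectrum(sp$frequency_ghz, sp$intensity, sp$config,
                       mask = list(c(-Inf, mask_ghz)))
  fit <- fit_peaks(anti, n_peaks = n_peaks)
  pk <- fit$peaks
  pk$branch <- classify_branch(pk$center_f, sp$config, alpha_deg, c_long = c_long)
  q_geom <- config_wave_vector(sp$config)$q_nm_inv
  q_bs <- 4 * pi * sp$config$n / sp$config$lambda_nm
  pk$q_nm_inv <- ifelse(pk$branch == "QL" & sp$config$geometry == "transmission",
                        q_bs, q_geom)
  pk$c_mps <- velocity_from_shift(pk$center_f, pk$q_nm_inv)
  pk$sigma_c_mps <- velocity_from_shift(pmax(pk$sigma_f, 1e-12), pk$q_nm_inv)
  res <- data.frame(branch = pk$branch, f_GHz = pk$center_f,
                    sigma_f_GHz = pk$sigma_f, fwhm_GHz = pk$fwhm,
                    amplitude = pk$amplitude, q_nm_inv = pk$q_nm_inv,
                    c_mps = pk$c_mps, sigma_c_mps = pk$sigma_c_mps)
  if (!is.null(out)) write.csv(res, out, row.names = FALSE, quote = FALSE)
  res
}

#' Fit the stiffness tensor to a velocity table file
#'
#' Reads a velocity CSV, runs [fit_elastic_tensor()], and writes a JSON fit
#' report (constants with standard errors, chi^2/dof, engineering moduli)
#' plus a residual CSV next to it.
#'
#' @param path Velocity-table CSV.
#' @param rho Density (kg/m^3).
#' @param constraint `"C66_equals_C44"` or `"C66_free"`.
#' @param out Optional JSON report path; a residual table is written to
#'   `<out>_residuals.csv`.
#' @return The `"tensor_fit"` object, invisibly when `out` is given.
#' @export
run_fit_tensor <- function(path, rho, constraint = "C66_equals_C44",
                           out = NULL) {
  data <- read_velocity_csv(path)
  fit <- fit_elastic_tensor(data, rho = rho, constraint = constraint)
  if (!is.null(out)) {
    write_fit_report(fit, out)
    write.csv(fit$residuals, paste0(sub("\\.json$", "", out), "_residuals.csv"),
              row.names = FALSE, quote = FALSE)
    return(invisible(fit))
  }
  fit
}
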