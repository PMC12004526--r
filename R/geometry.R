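# Scattering geometry: probed wave vectors and shift <-> velocity conversion.
#
# With f in GHz and q in nm^-1, c = 2*pi*f/q comes out directly in m/s
# (the 1e9 factors cancel), so no explicit unit constants appear below.

#' Scattering configuration
#'
#' Bundles the optical parameters of a BLS measurement: vacuum laser
#' wavelength, scattering angle between incident and scattered wave vectors,
#' refractive index of the medium, scattering geometry and polarization.
#'
#' @param lambda_nm Laser wavelength in vacuum/air (nm), e.g. 532.
#' @param theta_deg Scattering angle between k_i and k_s (degrees), in
#'   (0, 180]. Defaults to 180 for backscattering.
#' @param n Refractive index of the medium (>= 1). Only the reflection and
#'   backscattering wave vectors depend on it.
#' @param geometry One of `"transmission"`, `"reflection"`,
#'   `"backscattering"`.
#' @param polarization Polarization configuration, `"VV"` (selects
#'   longitudinal-type modes) or `"VH"` (transverse-type modes).
#'
#' @return An object of class `"scattering_config"`.
#' @examples
#' scattering_config(532, 90, n = 1.54, geometry = "transmission")
#' @export
scattering_config <- function(lambda_nm, theta_deg = NULL, n = 1,
                              geometry = c("transmission", "reflection",
                                           "backscattering"),
                              polarization = c("VV", "VH")) {
  geometry <- match.arg(geometry)
  polarization <- match.arg(polarization)
  check_scalar(lambda_nm, "lambda_nm")
  if (is.null(theta_deg)) {
    if (geometry == "backscattering") theta_deg <- 180
    else abort_validation("`theta_deg` is required for transmission/reflection geometry")
  }
  check_scalar(theta_deg, "theta_deg")
  if (theta_deg > 180) {
    abort_validation(sprintf("`theta_deg` must lie in (0, 180] (got %g)", theta_deg))
  }
  check_scalar(n, "n")
  if (n < 1) abort_validation(sprintf("refractive index `n` must be >= 1 (got %g)", n))
  structure(
    list(lambda_nm = lambda_nm, theta_deg = theta_deg, n = n,
         geometry = geometry, polarization = polarization),
    class = "scattering_config"
  )
}

#' @export
print.scattering_config <- function(x, ...) {
  cat(sprintf("BLS scattering config: %s, %s, lambda = %g nm, theta = %g deg, n = %g\n",
              x$geometry, x$polarization, x$lambda_nm, x$theta_deg, x$n))
  invisible(x)
}

new_wave_vector <- function(q_nm_inv, alpha_deg, index_dependent, geometry) {
  structure(
    list(q_nm_inv = q_nm_inv, alpha_deg = alpha_deg,
         index_dependent = index_dependent, geometry = geometry),
    class = "wave_vector"
  )
}

#' @export
print.wave_vector <- function(x, ...) {
  cat(sprintf("wave vector: q = %.5g nm^-1 (%s%s), alpha = %s deg\n",
              x$q_nm_inv, x$geometry,
              if (x$index_dependent) ", n-dependent" else "",
              if (is.na(x$alpha_deg)) "NA" else format(x$alpha_deg)))
  invisible(x)
}

q_magnitude <- function(q) {
  if (inherits(q, "wave_vector")) q$q_nm_inv
  else if (is.numeric(q)) q
  else abort_validation("`q` must be a wave_vector or a numeric magnitude in nm^-1")
}

#' Transmission-geometry phonon wave vector
#'
#' In the transmission geometry the probed wave vector lies in the sample
#' plane with magnitude q = (4 pi / lambda) sin(theta / 2), independent of
#' the refractive index. For a fiber mounted with its axis along q this
#' probes phonons at alpha = 0.
#'
#' @param config A [scattering_config()] with `geometry = "transmission"`.
#' @param alpha_deg Angle between q and the fiber symmetry axis (degrees);
#'   defaults to 0 (q parallel to the axis).
#' @return A `"wave_vector"` with fields `q_nm_inv`, `alpha_deg`,
#'   `index_dependent` (FALSE here) and `geometry`.
#' @examples
#' q_transmission(scattering_config(532, 90))$q_nm_inv # 0.0167 nm^-1
#' @export
q_transmission <- function(config, alpha_deg = 0) {
  stopifnot(inherits(config, "scattering_config"))
  if (config$geometry != "transmission") {
    abort_validation("q_transmission() requires a transmission-geometry config")
  }
  check_alpha(alpha_deg)
  q <- (4 * pi / config$lambda_nm) * sin(deg2rad(config$theta_deg) / 2)
  new_wave_vector(q, alpha_deg, index_dependent = FALSE, geometry = "transmission")
}

#' Reflection-geometry phonon wave vector
#'
#' In the reflection geometry the probed wave vector is normal to the sample
#' surface with magnitude q = (4 pi / lambda) sqrt(n^2 - cos^2(theta / 2)),
#' which depends on the refractive index n. For a fiber lying in the surface
#' this probes phonons normal to the axis (alpha = 90).
#'
#' @inheritParams q_transmission
#' @param alpha_deg Angle between q and the fiber axis (degrees); defaults
#'   to 90.
#' @return A `"wave_vector"`; `index_dependent` is TRUE.
#' @examples
#' q_reflection(scattering_config(532, 120, n = 1.54,
#'                                geometry = "reflection"))$q_nm_inv # 0.0344
#' @export
q_reflection <- function(config, alpha_deg = 90) {
  stopifnot(inherits(config, "scattering_config"))
  if (config$geometry != "reflection") {
    abort_validation("q_reflection() requires a reflection-geometry config")
  }
  check_alpha(alpha_deg)
  c2 <- cos(deg2rad(config$theta_deg) / 2)^2
  if (config$n^2 < c2) {
    abort_validation(sprintf(
      "physically impossible reflection configuration: n^2 = %.4g < cos^2(theta/2) = %.4g",
      config$n^2, c2))
  }
  q <- (4 * pi / config$lambda_nm) * sqrt(config$n^2 - c2)
  new_wave_vector(q, alpha_deg, index_dependent = TRUE, geometry = "reflection")
}

#' Backscattering phonon wave vector
#'
#' The backscattering wave vector q_bs = 4 pi n / lambda. In transmission
#' spectra of fibers a spurious backscattering path produces a strong
#' leakage peak at this q (assigned to the QL branch), propagating at an
#' oblique angle to the fiber axis.
#'
#' @inheritParams q_transmission
#' @param alpha_deg Angle between q_bs and the fiber axis (degrees). The
#'   leakage-mode angle depends on how the fiber is oriented in the
#'   scattering plane, so it is user-supplied; see [leakage_alpha()] for the
#'   refraction-based estimate.
#' @return A `"wave_vector"`; `index_dependent` is TRUE.
#' @examples
#' q_backscatter(scattering_config(532, n = 1.54,
#'                                 geometry = "backscattering"))
#' @export
q_backscatter <- function(config, alpha_deg = NA_real_) {
  stopifnot(inherits(config, "scattering_config"))
  if (!is.na(alpha_deg)) check_alpha(alpha_deg)
  q <- 4 * pi * config$n / config$lambda_nm
  new_wave_vector(q, alpha_deg, index_dependent = TRUE, geometry = "backscattering")
}

#' Refraction estimate of the backscattering-leakage propagation angle
#'
#' Estimates the oblique angle between the leaked backscattering wave vector
#' and the fiber axis as alpha = arcsin(sin(theta) / n). The actual angle
#' also depends on the fiber-axis orientation relative to the scattering
#' plane, so pipeline functions accept a user-supplied alpha instead of
#' asserting this value.
#'
#' @param theta_deg Scattering angle (degrees).
#' @param n Refractive index.
#' @return Angle in degrees.
#' @examples
#' leakage_alpha(90, 1.54) # about 40.5 deg
#' @export
leakage_alpha <- function(theta_deg, n) {
  check_scalar(theta_deg, "theta_deg")
  check_scalar(n, "n")
  s <- sin(deg2rad(theta_deg)) / n
  if (s > 1) abort_validation("sin(theta)/n exceeds 1; no real refraction angle")
  rad2deg(asin(s))
}

check_alpha <- function(alpha_deg) {
  if (any(!is.finite(alpha_deg)) || any(alpha_deg < 0) || any(alpha_deg > 90)) {
    abort_validation("`alpha_deg` must lie in [0, 90]")
  }
  invisible(alpha_deg)
}

#' Convert a Brillouin frequency shift to a sound velocity
#'
#' c = 2 pi f / q. With f in GHz and q in nm^-1 the result is in m/s.
#'
#' @param f_ghz Frequency shift(s) in GHz (>= 0).
#' @param q A [q_transmission()]-style wave vector, or a numeric magnitude
#'   in nm^-1.
#' @return Sound velocity in m/s (vectorized over `f_ghz`).
#' @examples
#' q <- q_transmission(scattering_config(532, 90))
#' velocity_from_shift(13.18, q) # about 4958 m/s
#' @export
velocity_from_shift <- function(f_ghz, q) {
  qm <- q_magnitude(q)
  if (any(!is.finite(qm)) || any(qm <= 0)) {
    abort_validation(
      "wave-vector magnitude must be > 0: cannot convert a frequency shift at q = 0 (velocity c = 2*pi*f/q is undefined)")
  }
  if (any(!is.finite(f_ghz)) || any(f_ghz < 0)) {
    abort_validation("`f_ghz` must be finite and >= 0")
  }
  2 * pi * f_ghz / qm
}

#' Convert a sound velocity to a Brillouin frequency shift
#'
#' Inverse of [velocity_from_shift()]: f = c q / (2 pi), in GHz for c in m/s
#' and q in nm^-1.
#'
#' @param c_mps Sound velocity in m/s (>= 0).
#' @param q Wave vector (see [velocity_from_shift()]).
#' @return Frequency shift in GHz.
#' @export
shift_from_velocity <- function(c_mps, q) {
  qm <- q_magnitude(q)
  if (any(!is.finite(qm)) || any(qm <= 0)) {
    abort_validation("wave-vector magnitude must be > 0")
  }
  if (any(!is.finite(c_mps)) || any(c_mps < 0)) {
    abort_validation("`c_mps` must be finite and >= 0")
  }
  c_mps * qm / (2 * pi)
}

# dispatch on geometry; used by the pipeline drivers
config_wave_vector <- function(config, alpha_deg = NULL) {
  switch(config$geometry,
    transmission = q_transmission(config, alpha_deg %||% 0),
    reflection = q_reflection(config, alpha_deg %||% 90),
    backscattering = q_backscatter(config, alpha_deg %||% NA_real_)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
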