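# Lorentzian peak extraction from BLS spectra and acoustic-branch labelling.

#' BLS spectrum container
#'
#' @param frequency_ghz Strictly increasing grid of signed frequency shifts
#'   (GHz); negative values are the Stokes side.
#' @param intensity Non-negative, finite counts per channel.
#' @param config Optional [scattering_config()] recorded with the spectrum.
#' @param mask Optional list of `c(lo, hi)` frequency intervals (GHz) to
#'   exclude from fitting, typically the elastic-line vicinity around zero.
#' @return An object of class `"bls_spectrum"`.
#' @export
bls_spectrum <- function(frequency_ghz, intensity, config = NULL, mask = NULL) {
  if (length(frequency_ghz) != length(intensity) || length(frequency_ghz) < 5) {
    abort_validation("`frequency_ghz` and `intensity` must be equal-length vectors (>= 5 points)")
  }
  if (any(!is.finite(frequency_ghz)) || any(diff(frequency_ghz) <= 0)) {
    abort_validation("`frequency_ghz` must be finite and strictly increasing")
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    abort_validation("`intensity` must be finite and >= 0")
  }
  if (!is.null(config)) stopifnot(inherits(config, "scattering_config"))
  if (!is.null(mask)) {
    if (!is.list(mask)) mask <- list(mask)
    ok <- vapply(mask, function(m) is.numeric(m) && length(m) == 2 && m[1] < m[2],
                 logical(1))
    if (!all(ok)) abort_validation("`mask` must be a list of c(lo, hi) intervals")
  }
  structure(list(frequency_ghz = frequency_ghz, intensity = intensity,
                 config = config, mask = mask),
            class = "bls_spectrum")
}

#' @export
print.bls_spectrum <- function(x, ...) {
  cat(sprintf("BLS spectrum: %d channels, %.3g to %.3g GHz%s\n",
              length(x$frequency_ghz), min(x$frequency_ghz), max(x$frequency_ghz),
              if (is.null(x$config)) "" else paste0(" (", x$config$geometry, ", ",
                                                    x$config$polarization, ")")))
  invisible(x)
}

# Lorentzian parameterized by peak height (amplitude at center)
lorentzian <- function(f, center, fwhm, amplitude) {
  hw2 <- (fwhm / 2)^2
  amplitude * hw2 / ((f - center)^2 + hw2)
}

# Faddeeva function w(z) for Im(z) > 0, Humlicek (1982) w4 rational
# approximation (relative accuracy ~1e-4, stable for all |z|).
faddeeva_w <- function(x, y) {
  t <- y - 1i * x
  s <- abs(x) + y
  u <- t * t
  w <- complex(length.out = length(x))
  r1 <- s >= 15
  r2 <- !r1 & s >= 5.5
  r3 <- !r1 & !r2 & (y >= 0.195 * abs(x) - 0.176)
  r4 <- !(r1 | r2 | r3)
  if (any(r1)) w[r1] <- t[r1] * 0.5641896 / (0.5 + u[r1])
  if (any(r2)) {
    w[r2] <- t[r2] * (1.410474 + u[r2] * 0.5641896) /
      (0.75 + u[r2] * (3 + u[r2]))
  }
  if (any(r3)) {
    tt <- t[r3]
    w[r3] <- (16.4955 + tt * (20.20933 + tt * (11.96482 +
               tt * (3.778987 + tt * 0.5642236)))) /
             (16.4955 + tt * (38.82363 + tt * (39.27121 +
               tt * (21.69274 + tt * (6.699398 + tt)))))
  }
  if (any(r4)) {
    tt <- t[r4]; uu <- u[r4]
    w[r4] <- exp(uu) - tt * (36183.31 - uu * (3321.9905 - uu * (1540.787 -
      uu * (219.0313 - uu * (35.76683 - uu * (1.320522 - uu * 0.56419)))))) /
      (32066.6 - uu * (24322.84 - uu * (9022.228 - uu * (2186.181 -
        uu * (364.2191 - uu * (61.57037 - uu * (1.841439 - uu)))))))
  }
  w
}

# Voigt profile (Lorentzian convolved with a Gaussian of sd sigma_g),
# normalized to unit peak height.
voigt_unit <- function(f, center, fwhm, sigma_g) {
  y <- (fwhm / 2) / (sigma_g * sqrt(2))
  x <- (f - center) / (sigma_g * sqrt(2))
  Re(faddeeva_w(x, rep(y, length(x)))) / Re(faddeeva_w(0, y))
}

peak_profile <- function(f, center, fwhm, amplitude, resolution_ghz = 0) {
  if (resolution_ghz > 0) {
    amplitude * voigt_unit(f, center, fwhm, resolution_ghz)
  } else {
    lorentzian(f, center, fwhm, amplitude)
  }
}

spectrum_modelfun <- function(f, par, n_peaks, resolution_ghz = 0) {
  y <- par[1] + par[2] * f
  for (k in seq_len(n_peaks)) {
    i <- 2 + 3 * (k - 1)
    y <- y + peak_profile(f, par[i + 1], par[i + 2], par[i + 3], resolution_ghz)
  }
  y
}

# initial guesses from local maxima of a median-filtered spectrum
guess_peaks <- function(f, y, n_peaks) {
  k <- min(5L, length(y) - (1 - length(y) %% 2)) # odd, <= length
  if (k %% 2 == 0) k <- k - 1
  ys <- runmed(y, k)
  b0 <- as.numeric(quantile(ys, 0.1))
  i <- which(ys > c(-Inf, ys[-length(ys)]) & ys >= c(ys[-1], Inf) & ys > b0)
  if (length(i) == 0) i <- which.max(ys)
  i <- i[order(ys[i], decreasing = TRUE)]
  # enforce separation of a few channels between accepted guesses
  sel <- integer(0)
  for (j in i) {
    if (all(abs(j - sel) > 5)) sel <- c(sel, j)
    if (length(sel) == n_peaks) break
  }
  if (length(sel) < n_peaks) {
    # deterministic fallback: pad with evenly spaced channels
    pad <- round(seq(1, length(f), length.out = n_peaks + 2))[-c(1, n_peaks + 2)]
    sel <- unique(c(sel, pad))[seq_len(n_peaks)]
  }
  df <- median(diff(f))
  data.frame(center = f[sel],
             fwhm = rep(max(8 * df, diff(range(f)) / 40), n_peaks),
             amplitude = pmax(ys[sel] - b0, max(ys) * 0.01))
}

#' Fit Lorentzian peaks to a BLS spectrum
#'
#' Least-squares fit of a first-order (linear) baseline plus `n_peaks`
#' Lorentzian line shapes to the spectrum, using Levenberg-Marquardt with
#' bounds. Residuals are weighted by 1/sqrt(counts) by default (Poisson
#' counting statistics); parameter uncertainties come from the fit
#' covariance scaled by chi^2/dof so that over- or under-dispersed counts
#' are absorbed into the errors.
#'
#' @param spectrum A [bls_spectrum()]. Masked intervals are excluded.
#' @param n_peaks Number of peaks to fit (>= 1).
#' @param init Optional data frame of starting values with columns `center`,
#'   `fwhm`, `amplitude` (one row per peak). If omitted, guesses are taken
#'   from local maxima of a median-filtered (window 5) copy of the spectrum.
#' @param resolution_ghz Instrument resolution as the standard deviation of
#'   a Gaussian convolved with each Lorentzian (Voigt profile). 0 (default)
#'   fits plain Lorentzians.
#' @param weights `"poisson"` (default, 1/sqrt(max(counts, 1))) or `"none"`.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return An object of class `"bls_peakfit"`: list with `peaks` (data frame
#'   `center_f`, `sigma_f`, `fwhm`, `amplitude`, `branch`, `overlap`),
#'   `baseline` (intercept, slope), `chi2_dof`, `niter`, and `model` (a
#'   function of frequency returning fitted counts). Peaks are sorted by
#'   center frequency; pairs of peaks closer than half their mean FWHM are
#'   flagged `overlap = TRUE` with a warning.
#' @examples
#' cfg <- scattering_config(532, 90)
#' f <- seq(5, 20, by = 0.02)
#' y <- 10 + lorentzian(f, 13.2, 0.8, 1000)
#' fit <- fit_peaks(bls_spectrum(f, y, cfg), n_peaks = 1)
#' fit$peaks$center_f
#' @export
fit_peaks <- function(spectrum, n_peaks = 1, init = NULL, resolution_ghz = 0,
                      weights = c("poisson", "none"), max_iter = 500) {
  stopifnot(inherits(spectrum, "bls_spectrum"))
  weights <- match.arg(weights)
  if (n_peaks < 1) abort_validation("`n_peaks` must be >= 1")
  f <- spectrum$frequency_ghz
  y <- spectrum$intensity
  if (!is.null(spectrum$mask)) {
    keep <- rep(TRUE, length(f))
    for (m in spectrum$mask) keep <- keep & !(f >= m[1] & f <= m[2])
    f <- f[keep]; y <- y[keep]
  }
  if (length(f) < 3 * n_peaks + 2 + 1) {
    abort_validation("too few unmasked channels for the requested number of peaks")
  }
  if (is.null(init)) {
    init <- guess_peaks(f, y, n_peaks)
  } else {
    init <- as.data.frame(init)
    if (nrow(init) != n_peaks || !all(c("center", "fwhm", "amplitude") %in% names(init))) {
      abort_validation("`init` needs columns center, fwhm, amplitude and one row per peak")
    }
  }
  if (any(init$center < min(f)) || any(init$center > max(f))) {
    abort_validation("initial peak centers must lie inside the (unmasked) frequency grid")
  }
  w <- if (weights == "poisson") 1 / sqrt(pmax(y, 1)) else rep(1, length(y))
  df <- median(diff(f))
  par0 <- c(b0 = as.numeric(quantile(y, 0.1)), b1 = 0,
            as.vector(rbind(init$center, init$fwhm, init$amplitude)))
  lower <- c(-Inf, -Inf, rep(c(min(f), df / 2, 0), n_peaks))
  upper <- c(Inf, Inf, rep(c(max(f), diff(range(f)), Inf), n_peaks))
  resid_fn <- function(p) w * (y - spectrum_modelfun(f, p, n_peaks, resolution_ghz))
  res <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ftol = 1e-12, ptol = 1e-12))
  if (!(res$info %in% 1:4)) {
    abort_runtime(
      sprintf("peak fit did not converge (%s)", res$message),
      class = "silkbls_convergence_error", last_par = res$par)
  }
  p <- res$par
  dof <- length(y) - length(p)
  chi2_dof <- sum(resid_fn(p)^2) / dof
  J <- num_jacobian(resid_fn, p)
  JtJ <- crossprod(J)
  cov <- tryCatch(solve(JtJ) * chi2_dof, error = function(e) {
    warning("singular Jacobian in peak fit; uncertainties set to NA", call. = FALSE)
    matrix(NA_real_, length(p), length(p))
  })
  idx <- 2 + 3 * (seq_len(n_peaks) - 1)
  peaks <- data.frame(
    center_f = p[idx + 1],
    sigma_f = sqrt(pmax(diag(cov)[idx + 1], 0)),
    fwhm = p[idx + 2],
    amplitude = p[idx + 3],
    branch = "unassigned",
    overlap = FALSE,
    stringsAsFactors = FALSE
  )
  ord <- order(peaks$center_f)
  peaks <- peaks[ord, , drop = FALSE]
  rownames(peaks) <- NULL
  if (n_peaks > 1) {
    for (k in seq_len(n_peaks - 1)) {
      sep <- peaks$center_f[k + 1] - peaks$center_f[k]
      half_fwhm <- mean(peaks$fwhm[k:(k + 1)]) / 2
      if (sep < half_fwhm) {
        peaks$overlap[k:(k + 1)] <- TRUE
        warning(sprintf(
          "peaks at %.3g and %.3g GHz are closer than half a FWHM; parameters may be degenerate",
          peaks$center_f[k], peaks$center_f[k + 1]), call. = FALSE)
      }
    }
  }
  structure(
    list(peaks = peaks, baseline = c(intercept = p[[1]], slope = p[[2]]),
         chi2_dof = chi2_dof, niter = res$niter,
         model = function(fx) spectrum_modelfun(fx, p, n_peaks, resolution_ghz)),
    class = "bls_peakfit"
  )
}

#' @export
print.bls_peakfit <- function(x, ...) {
  cat(sprintf("Lorentzian peak fit: %d peak(s), chi2/dof = %.3g\n",
              nrow(x$peaks), x$chi2_dof))
  print(x$peaks, digits = 4)
  invisible(x)
}

#' Assign acoustic-branch labels to fitted peaks
#'
#' Labels peaks by the selection rules of the scattering geometry and
#' polarization: VH at alpha = 0 selects the pure-transverse (PT) mode; VV
#' in reflection probes the longitudinal mode normal to the fiber axis
#' (L_perp); VV in backscattering is quasi-longitudinal (QL). For VV
#' transmission spectra a peak may arise either from the in-plane wave
#' vector q_par (the axial longitudinal mode L_par) or from the
#' backscattering-leakage wave vector q_bs (QL): given a reference
#' longitudinal velocity `c_long`, the peak is assigned to whichever wave
#' vector predicts its frequency within `rtol`; a lower-frequency remainder
#' is labelled QT. Ambiguous or unmatched peaks return `"unassigned"` with
#' the reason in the `"reason"` attribute.
#'
#' @param f_ghz Fitted peak center frequencies (GHz); vectorized.
#' @param config The [scattering_config()] of the measurement.
#' @param alpha_deg Angle between the probed wave vector and the fiber axis.
#' @param c_long Optional reference longitudinal velocity (m/s, the axial
#'   value) used to test q_par vs q_bs consistency in transmission spectra.
#' @param rtol Relative velocity tolerance for a dispersion match.
#' @param ql_range Acceptance window for the leakage-QL velocity at q_bs, as
#'   fractions of `c_long`: the oblique QL branch propagates slower than the
#'   axial longitudinal velocity but faster than `ql_range[1] * c_long`
#'   (default 0.55, below the lateral/axial velocity ratio of silks).
#' @return Character vector of branch labels among `L_par`, `L_perp`, `QL`,
#'   `QT`, `PT`, `unassigned`.
#' @examples
#' cfg <- scattering_config(532, 90, n = 1.54, polarization = "VH")
#' classify_branch(4.94, cfg, alpha_deg = 0) # "PT"
#' @export
classify_branch <- function(f_ghz, config, alpha_deg, c_long = NULL,
                            rtol = 0.10, ql_range = c(0.55, NA)) {
  stopifnot(inherits(config, "scattering_config"))
  check_alpha(alpha_deg)
  out <- character(length(f_ghz))
  reason <- character(length(f_ghz))
  if (config$polarization == "VH") {
    if (alpha_deg <= 5) {
      out[] <- "PT"
    } else {
      out[] <- "unassigned"
      reason[] <- "VH peak at oblique alpha: PT/QT selection depends on mode mixing"
    }
  } else if (config$geometry == "reflection") {
    out[] <- "L_perp"
  } else if (config$geometry == "backscattering") {
    out[] <- "QL"
  } else {
    q_par <- q_transmission(config)$q_nm_inv
    q_bs <- 4 * pi * config$n / config$lambda_nm
    if (is.null(c_long)) {
      out[] <- "unassigned"
      reason[] <- "transmission VV peak needs a reference velocity `c_long` to separate L_par from backscattering-leakage QL"
    } else {
      f_par <- shift_from_velocity(c_long, q_par)
      for (i in seq_along(f_ghz)) {
        # velocity implied by each candidate wave vector
        c_par <- velocity_from_shift(f_ghz[i], q_par)
        c_bs <- velocity_from_shift(f_ghz[i], q_bs)
        m_par <- abs(c_par - c_long) / c_long <= rtol
        # the oblique leakage QL velocity lies between the lateral and axial
        # longitudinal velocities, i.e. below c_long but not arbitrarily so
        m_bs <- c_bs >= ql_range[1] * c_long && c_bs <= (1 + rtol) * c_long
        if (m_par && !m_bs) out[i] <- "L_par"
        else if (m_bs && !m_par) out[i] <- "QL"
        else if (m_par && m_bs) {
          out[i] <- "unassigned"
          reason[i] <- "frequency consistent with both q_par and q_bs dispersion"
        } else if (f_ghz[i] < f_par) out[i] <- "QT"
        else {
          out[i] <- "unassigned"
          reason[i] <- "frequency above the L_par prediction but inconsistent with q_bs"
        }
      }
    }
  }
  if (any(nzchar(reason))) attr(out, "reason") <- reason
  out
}
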