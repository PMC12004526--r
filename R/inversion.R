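# Weighted nonlinear least-squares inversion of angle-dependent sound
# velocities to the transversely isotropic stiffness constants.
#
# Free parameters: (C11, C33, C44, C13) under the C66 = C44 constraint, or
# five constants when C66 is free (requires PT/QT data away from alpha = 0).
# Positive definiteness of the fitted tensor is maintained by bounding the
# diagonal constants and by fitting C13 through
#   C13 = tanh(u) * sqrt((C11 + C12) C33 / 2),
# which keeps (C11 + C12) C33 - 2 C13^2 > 0 for any real u.

normalize_branch <- function(branch) {
  b <- as.character(branch)
  b[b == "L_par" | b == "L_perp"] <- "QL" # pure-mode limits of the QL branch
  bad <- !(b %in% c("QL", "QT", "PT"))
  if (any(bad)) {
    abort_validation(sprintf("unknown branch label(s): %s",
                             paste(unique(b[bad]), collapse = ", ")))
  }
  b
}

check_velocity_data <- function(data) {
  req <- c("alpha_deg", "branch", "c_mps")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    abort_validation("velocity data must be a data frame with columns alpha_deg, branch, c_mps (and optionally sigma_c_mps)")
  }
  if (nrow(data) == 0) abort_validation("velocity data are empty")
  check_alpha(data$alpha_deg)
  if (any(!is.finite(data$c_mps)) || any(data$c_mps <= 0)) {
    abort_validation("velocities `c_mps` must be finite and > 0")
  }
  data$branch <- normalize_branch(data$branch)
  if (is.null(data$sigma_c_mps)) {
    # default per-datum weight when no uncertainties are supplied: 1% of c
    data$sigma_c_mps <- 0.01 * data$c_mps
  }
  if (any(!is.finite(data$sigma_c_mps)) || any(data$sigma_c_mps <= 0)) {
    abort_validation("`sigma_c_mps` must be finite and > 0")
  }
  data
}

model_velocities <- function(par, data, constraint, rho) {
  C11 <- par[["C11"]]; C33 <- par[["C33"]]; C44 <- par[["C44"]]
  C66 <- if (constraint == "C66_free") par[["C66"]] else C44
  C12 <- C11 - 2 * C66
  c13max <- sqrt(pmax((C11 + C12) * C33, 1e-12) / 2) * (1 - 1e-9)
  C13 <- tanh(par[["u13"]]) * c13max
  a <- deg2rad(data$alpha_deg)
  s2 <- sin(a)^2; c2 <- cos(a)^2
  P11 <- C11 * GPA; P33 <- C33 * GPA; P44 <- C44 * GPA
  P66 <- C66 * GPA; P13 <- C13 * GPA
  X <- P11 * s2 + P33 * c2 + P44
  D <- sqrt((P11 * s2 - P33 * c2 + P44 * cos(2 * a))^2 +
              4 * (P13 + P44)^2 * s2 * c2)
  cmod <- numeric(nrow(data))
  iQL <- data$branch == "QL"; iQT <- data$branch == "QT"; iPT <- data$branch == "PT"
  cmod[iQL] <- sqrt((X[iQL] + D[iQL]) / (2 * rho))
  cmod[iQT] <- sqrt(pmax(X[iQT] - D[iQT], 0) / (2 * rho))
  cmod[iPT] <- sqrt((P66 * s2[iPT] + P44 * c2[iPT]) / rho)
  cmod
}

par_to_tensor <- function(par, constraint, rho) {
  C11 <- par[["C11"]]; C33 <- par[["C33"]]; C44 <- par[["C44"]]
  C66 <- if (constraint == "C66_free") par[["C66"]] else C44
  C12 <- C11 - 2 * C66
  C13 <- tanh(par[["u13"]]) * sqrt(pmax((C11 + C12) * C33, 1e-12) / 2) * (1 - 1e-9)
  ti_tensor(C11 = C11, C33 = C33, C44 = C44, C13 = C13, C66 = C66, rho = rho)
}

default_init <- function(data, rho, constraint) {
  ql <- data[data$branch == "QL", ]
  pt <- data[data$branch == "PT", ]
  c0 <- ql$c_mps[which.min(ql$alpha_deg)]
  c90 <- ql$c_mps[which.max(ql$alpha_deg)]
  C33 <- rho * c0^2 / GPA
  C11 <- rho * c90^2 / GPA
  C44 <- if (nrow(pt) > 0) rho * mean(pt$c_mps)^2 / GPA else rho * min(data$c_mps)^2 / GPA
  C13 <- 0.9 * sqrt(C11 * C33) - C44
  init <- c(C11 = C11, C33 = C33, C44 = C44, C13 = C13)
  if (constraint == "C66_free") {
    pt90 <- pt[pt$alpha_deg >= 45, ]
    init["C66"] <- if (nrow(pt90) > 0) rho * mean(pt90$c_mps)^2 / GPA else C44
  }
  init
}

pack_par <- function(init, constraint) {
  C66 <- if (constraint == "C66_free") init[["C66"]] else init[["C44"]]
  C12 <- init[["C11"]] - 2 * C66
  c13max <- sqrt(pmax((init[["C11"]] + C12) * init[["C33"]], 1e-12) / 2)
  t <- max(min(init[["C13"]] / c13max, 0.995), -0.995)
  p <- c(C11 = init[["C11"]], C33 = init[["C33"]], C44 = init[["C44"]],
         u13 = atanh(t))
  if (constraint == "C66_free") p["C66"] <- C66
  p
}

#' Fit the transversely isotropic stiffness tensor to velocity data
#'
#' Minimizes the inverse-variance-weighted sum of squares
#' sum(((c_obs - c_model(alpha; C)) / sigma_c)^2) over the free stiffness
#' constants using bounded Levenberg-Marquardt, where c_model follows the
#' Christoffel closed form of [velocities_ti()]. Under the default
#' `C66_equals_C44` constraint four constants (C11, C33, C44, C13) are free;
#' with `C66_free` the fifth constant is identified from pure/quasi
#' transverse data away from alpha = 0. Initialization uses the pure-mode
#' limits of the data (C33 from QL near alpha = 0, C11 from QL near 90, C44
#' from PT); on failure up to `n_starts` deterministically perturbed starts
#' are tried.
#'
#' Identifiability requires at least one QL point near alpha = 0, one near
#' alpha = 90, and two QL/QT points at oblique angles (otherwise C13 does
#' not enter the model and an identifiability error is raised).
#'
#' @param data Data frame with columns `alpha_deg`, `branch` (QL/QT/PT, or
#'   the pure-mode labels L_par/L_perp, treated as QL), `c_mps` and
#'   optionally `sigma_c_mps`. When uncertainties are absent a default of 1%
#'   of each velocity is used.
#' @param rho Density (kg/m^3).
#' @param constraint `"C66_equals_C44"` (default) or `"C66_free"`.
#' @param init Optional [ti_tensor()] or named vector of starting constants
#'   (GPa).
#' @param n_starts Number of perturbed restarts on convergence failure.
#' @param resolve_crossing If TRUE (default), QT/PT data whose two model
#'   velocities lie within 2 sigma of each other are re-fit with the labels
#'   swapped and the lower-chi^2 assignment is kept (the datum is flagged).
#' @return An object of class `"tensor_fit"`: list with `tensor` (a
#'   [ti_tensor()]), `se` and `covariance` over the free constants (GPa,
#'   Jacobian-based, scaled by chi^2/dof), `chi2_dof`, `constraint`,
#'   `residuals` (data frame with model velocities and residuals in m/s),
#'   `n_data`, and `flagged` (row indices relabelled at a QT/PT crossing).
#' @examples
#' tw <- ti_tensor(13.0, 32.1, 4.5, 8.6, rho = 1350)
#' d <- generate_velocity_dataset(tw, sigma_c = 0)
#' fit_elastic_tensor(d, rho = 1350)$tensor
#' @export
fit_elastic_tensor <- function(data, rho,
                               constraint = c("C66_equals_C44", "C66_free"),
                               init = NULL, n_starts = 10,
                               resolve_crossing = TRUE) {
  constraint <- match.arg(constraint)
  check_scalar(rho, "rho")
  data <- check_velocity_data(data)

  ql <- data[data$branch == "QL", ]
  oblique <- data$branch %in% c("QL", "QT") &
    data$alpha_deg > 10 & data$alpha_deg < 80
  if (nrow(ql) == 0 || min(ql$alpha_deg) > 20 || max(ql$alpha_deg) < 70) {
    abort_validation(
      "need QL data near both alpha = 0 and alpha = 90 to identify C33 and C11",
      class = "silkbls_identifiability_error")
  }
  if (sum(oblique) < 2) {
    abort_validation(
      "C13 is unidentifiable: need at least two QL or QT data at oblique angles (10 < alpha < 80 deg)",
      class = "silkbls_identifiability_error")
  }
  if (constraint == "C66_free" &&
      !any(data$branch == "PT" & data$alpha_deg > 10)) {
    abort_validation(
      "C66 is unidentifiable under C66_free: need PT data away from alpha = 0",
      class = "silkbls_identifiability_error")
  }

  init_c <- if (is.null(init)) {
    default_init(data, rho, constraint)
  } else if (inherits(init, "ti_tensor")) {
    unlist(init[c("C11", "C33", "C44", "C13", "C66")])
  } else {
    init
  }
  if (constraint == "C66_free" && is.na(init_c["C66"])) init_c["C66"] <- init_c[["C44"]]

  npar <- if (constraint == "C66_free") 5L else 4L
  lower <- c(1e-3, 1e-3, 1e-3, -Inf, if (npar == 5) 1e-3)
  upper <- c(200, 200, 200, Inf, if (npar == 5) 200)
  make_resid <- function(dd) {
    function(p) {
      names(p) <- c("C11", "C33", "C44", "u13", if (npar == 5) "C66")
      (dd$c_mps - model_velocities(p, dd, constraint, rho)) / dd$sigma_c_mps
    }
  }

  run_fit <- function(start, dd = data) {
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = make_resid(dd),
                       control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  # deterministic multiplicative perturbations for restarts (no RNG)
  perturb <- c(1, 0.7, 1.4, 0.5, 2, 0.85, 1.2, 0.6, 1.7, 0.9, 1.1)
  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    start_c <- init_c
    start_c[c("C11", "C33", "C44")] <- start_c[c("C11", "C33", "C44")] *
      perturb[((s - 1) %% length(perturb)) + 1]
    if (constraint == "C66_free") {
      start_c["C66"] <- start_c[["C66"]] * perturb[((s - 1) %% length(perturb)) + 1]
    }
    start <- tryCatch(pack_par(start_c, constraint), error = function(e) NULL)
    if (is.null(start)) next
    res <- tryCatch(run_fit(start), error = function(e) NULL)
    if (!is.null(res) && res$info %in% 1:4 && is.finite(res$deviance)) {
      if (is.null(best) || res$deviance < best$deviance) best <- res
      if (s == 1) break # first start converged; no need for restarts
    }
  }
  if (is.null(best)) {
    abort_runtime("tensor fit failed to converge from all perturbed starts",
                  class = "silkbls_convergence_error", init = init_c)
  }

  finalize <- function(res, data, flagged) {
    p <- res$par
    names(p) <- c("C11", "C33", "C44", "u13", if (npar == 5) "C66")
    tensor <- par_to_tensor(p, constraint, rho)
    dof <- max(nrow(data) - npar, 1L)
    chi2_dof <- res$deviance / dof
    free <- c("C11", "C33", "C44", "C13", if (npar == 5) "C66")
    # covariance in C-space: numeric Jacobian of the weighted residuals
    resid_c <- function(cc) {
      C66 <- if (npar == 5) cc[["C66"]] else cc[["C44"]]
      t2 <- list(C11 = cc[["C11"]], C12 = cc[["C11"]] - 2 * C66,
                 C13 = cc[["C13"]], C33 = cc[["C33"]], C44 = cc[["C44"]],
                 C66 = C66, rho = rho)
      class(t2) <- "ti_tensor"
      v <- velocities_ti(t2, data$alpha_deg)
      cmod <- v$c_QL
      cmod[data$branch == "QT"] <- v$c_QT[data$branch == "QT"]
      cmod[data$branch == "PT"] <- v$c_PT[data$branch == "PT"]
      (data$c_mps - cmod) / data$sigma_c_mps
    }
    chat <- unlist(tensor[free])
    J <- num_jacobian(resid_c, chat)
    cov <- tryCatch(solve(crossprod(J)) * chi2_dof, error = function(e) {
      warning("near-singular design; covariance set to NA", call. = FALSE)
      matrix(NA_real_, npar, npar)
    })
    dimnames(cov) <- list(free, free)
    cmod <- data$c_mps - resid_c(chat) * data$sigma_c_mps
    structure(
      list(tensor = tensor,
           se = setNames(sqrt(pmax(diag(cov), 0)), free),
           covariance = cov, chi2_dof = chi2_dof, constraint = constraint,
           residuals = data.frame(data,
                                  c_model_mps = cmod,
                                  residual_mps = data$c_mps - cmod),
           n_data = nrow(data), flagged = flagged, deviance = res$deviance),
      class = "tensor_fit"
    )
  }

  fit <- finalize(best, data, integer(0))

  if (resolve_crossing) {
    v <- velocities_ti(fit$tensor, data$alpha_deg)
    tr <- which(data$branch %in% c("QT", "PT"))
    gap <- abs(v$c_QT[tr] - v$c_PT[tr])
    near <- tr[gap < 2 * data$sigma_c_mps[tr] & gap > 1e-6]
    flagged <- integer(0)
    for (i in utils::head(near, 5)) {
      d2 <- data
      d2$branch[i] <- if (data$branch[i] == "QT") "PT" else "QT"
      res2 <- tryCatch(run_fit(best$par, d2), error = function(e) NULL)
      if (!is.null(res2) && res2$info %in% 1:4) {
        dev2 <- res2$deviance
        if (dev2 < fit$deviance - 1e-9) {
          data <- d2
          best <- res2
          flagged <- c(flagged, i)
          fit <- finalize(best, data, flagged)
        }
      }
    }
    if (length(flagged)) {
      warning(sprintf("relabelled %d QT/PT datum(s) near the branch crossing (rows: %s)",
                      length(flagged), paste(flagged, collapse = ", ")), call. = FALSE)
    }
  }
  fit
}

#' @export
print.tensor_fit <- function(x, ...) {
  cat(sprintf("Stiffness-tensor fit (%s): %d data, chi2/dof = %.3g\n",
              x$constraint, x$n_data, x$chi2_dof))
  free <- names(x$se)
  est <- unlist(x$tensor[free])
  cat(paste(sprintf("  %s = %.4g +/- %.2g GPa", free, est, x$se), collapse = "\n"),
      "\n")
  invisible(x)
}

#' Residual-resampling bootstrap intervals for the stiffness constants
#'
#' Refits the tensor to `n_boot` datasets built by adding resampled fit
#' residuals to the fitted model velocities, and returns percentile
#' intervals per constant. This is an alternative to the covariance-based
#' standard errors of [fit_elastic_tensor()] that makes no local-linearity
#' assumption.
#'
#' @inheritParams fit_elastic_tensor
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed; fixed seed gives identical intervals.
#' @param level Confidence level for the percentile intervals.
#' @return Data frame with one row per free constant: `estimate`, `se_boot`,
#'   `lower`, `upper`, plus attributes `n_boot` and `level`. Degenerate
#'   (all-zero) residuals give zero-width intervals with a warning.
#' @export
bootstrap_uncertainty <- function(data, rho,
                                  constraint = c("C66_equals_C44", "C66_free"),
                                  n_boot = 200, seed = NULL, level = 0.95,
                                  init = NULL) {
  constraint <- match.arg(constraint)
  if (n_boot < 100) abort_validation("`n_boot` must be >= 100")
  fit <- fit_elastic_tensor(data, rho, constraint, init = init,
                            resolve_crossing = FALSE)
  free <- names(fit$se)
  est <- unlist(fit$tensor[free])
  r <- fit$residuals$residual_mps
  if (all(abs(r) < 1e-9)) {
    warning("residuals are degenerate (all zero); bootstrap intervals have zero width",
            call. = FALSE)
    out <- data.frame(constant = free, estimate = est, se_boot = 0,
                      lower = est, upper = est, row.names = NULL)
    attr(out, "n_boot") <- n_boot; attr(out, "level") <- level
    return(out)
  }
  if (!is.null(seed)) set.seed(derive_seed(seed, "bootstrap"))
  d <- fit$residuals
  draws <- matrix(NA_real_, n_boot, length(free), dimnames = list(NULL, free))
  for (b in seq_len(n_boot)) {
    db <- d[, c("alpha_deg", "branch", "sigma_c_mps")]
    db$c_mps <- pmax(d$c_model_mps + sample(r, nrow(d), replace = TRUE), 1)
    fb <- tryCatch(
      fit_elastic_tensor(db, rho, constraint, init = fit$tensor,
                         n_starts = 3, resolve_crossing = FALSE),
      error = function(e) NULL)
    if (!is.null(fb)) draws[b, ] <- unlist(fb$tensor[free])
  }
  ok <- stats::complete.cases(draws)
  if (sum(ok) < 0.8 * n_boot) {
    warning(sprintf("only %d/%d bootstrap refits converged", sum(ok), n_boot),
            call. = FALSE)
  }
  a <- (1 - level) / 2
  out <- data.frame(
    constant = free,
    estimate = est,
    se_boot = apply(draws[ok, , drop = FALSE], 2, sd),
    lower = apply(draws[ok, , drop = FALSE], 2, quantile, probs = a),
    upper = apply(draws[ok, , drop = FALSE], 2, quantile, probs = 1 - a),
    row.names = NULL
  )
  attr(out, "n_boot") <- n_boot
  attr(out, "level") <- level
  out
}
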