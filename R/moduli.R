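# Engineering moduli from stiffness constants.
#
# Transversely isotropic compliance relations (fiber axis = 3):
#   E3   = C33 - 2 C13^2 / (C11 + C12)
#   E1   = (C11 - C12) [(C11 + C12) C33 - 2 C13^2] / (C11 C33 - C13^2)
#   nu31 = C13 / (C11 + C12)            (= C13 / [2 (C11 - C66)])
#   nu12 = (C12 C33 - C13^2) / (C11 C33 - C13^2)
#   G13  = C44, G12 = C66
#   K    = [(C11 + C12) C33 - 2 C13^2] / (C11 + C12 + 2 C33 - 4 C13)
# K is the Reuss (uniform-stress) bulk modulus of the aggregate.

moduli_names <- c("E_axial", "E_lateral", "anisotropy_ratio",
                  "G13", "G12", "K", "nu31", "nu12")

moduli_values <- function(C11, C12, C13, C33, C44, C66) {
  den <- C11 * C33 - C13^2
  s <- C11 + C12
  if (den <= 0 || s <= 0) {
    abort_validation(sprintf(
      "tensor not physical: require C11 C33 - C13^2 > 0 (got %g) and C11 + C12 > 0 (got %g)",
      den, s))
  }
  num <- s * C33 - 2 * C13^2
  E3 <- C33 - 2 * C13^2 / s
  E1 <- (C11 - C12) * num / den
  c(E_axial = E3,
    E_lateral = E1,
    anisotropy_ratio = E3 / E1,
    G13 = C44,
    G12 = C66,
    K = num / (s + 2 * C33 - 4 * C13),
    nu31 = C13 / s,
    nu12 = (C12 * C33 - C13^2) / den)
}

#' Engineering moduli of a transversely isotropic stiffness tensor
#'
#' Converts stiffness constants into the engineering mechanical properties
#' of the fiber: axial and lateral Young's moduli E_axial (along the fiber)
#' and E_lateral (normal to it), their anisotropy ratio, the shear moduli
#' G13 (= G23 = C44) and G12 (= C66), the Reuss bulk modulus K, and the
#' Poisson's ratios nu31 (= nu32) and nu12. When a covariance matrix over
#' the free stiffness constants is supplied (e.g. from
#' [fit_elastic_tensor()]), first-order delta-method standard errors are
#' propagated to every modulus.
#'
#' Note that nu31 = C13 / (C11 + C12) can exceed the isotropic bound of 0.5
#' for strongly anisotropic fibers (anisotropic Poisson's ratios are not
#' bounded); the value is reported without clamping.
#'
#' @param tensor A [ti_tensor()].
#' @param covariance Optional symmetric covariance matrix (GPa^2) with
#'   dimnames naming a subset of `C11, C33, C44, C13, C66`.
#' @return An object of class `"engineering_moduli"`: a list with the eight
#'   moduli (GPa; ratios dimensionless) and, if `covariance` was given, a
#'   named numeric vector `se` of standard errors.
#' @examples
#' tw <- ti_tensor(13.0, 32.1, 4.5, 8.6, rho = 1350)
#' moduli_from_tensor(tw) # E_axial 23.4, E_lateral 10.4 GPa, ...
#' @export
moduli_from_tensor <- function(tensor, covariance = NULL) {
  stopifnot(inherits(tensor, "ti_tensor"))
  vals <- moduli_values(tensor$C11, tensor$C12, tensor$C13, tensor$C33,
                        tensor$C44, tensor$C66)
  se <- NULL
  if (!is.null(covariance)) {
    pn <- colnames(covariance)
    if (is.null(pn) || !all(pn %in% c("C11", "C33", "C44", "C13", "C66"))) {
      abort_validation("`covariance` must have dimnames among C11, C33, C44, C13, C66")
    }
    base <- unlist(tensor[c("C11", "C33", "C44", "C13", "C66")])
    f <- function(p) {
      cc <- base
      cc[pn] <- p
      # under the C66 = C44 constraint the shared value varies jointly
      if (!("C66" %in% pn) && tensor$C66 == tensor$C44 && "C44" %in% pn) {
        cc["C66"] <- cc["C44"]
      }
      moduli_values(cc["C11"], cc["C11"] - 2 * cc["C66"], cc["C13"],
                    cc["C33"], cc["C44"], cc["C66"])
    }
    J <- num_jacobian(f, base[pn])
    V <- J %*% covariance %*% t(J)
    se <- setNames(sqrt(pmax(diag(V), 0)), moduli_names)
  }
  structure(c(as.list(vals), list(se = se, tensor = tensor)),
            class = "engineering_moduli")
}

#' @export
print.engineering_moduli <- function(x, digits = 3, ...) {
  cat("Engineering moduli (GPa; ratios dimensionless)\n")
  fmt <- function(nm) {
    v <- format(signif(x[[nm]], digits))
    if (!is.null(x$se)) v <- paste0(v, " +/- ", format(signif(x$se[[nm]], 2)))
    v
  }
  cat(sprintf("  E_axial  = %s   E_lateral = %s   E_axial/E_lateral = %s\n",
              fmt("E_axial"), fmt("E_lateral"), fmt("anisotropy_ratio")))
  cat(sprintf("  G13 = G23 = %s   G12 = %s   K = %s\n",
              fmt("G13"), fmt("G12"), fmt("K")))
  cat(sprintf("  nu31 = nu32 = %s   nu12 = %s\n", fmt("nu31"), fmt("nu12")))
  invisible(x)
}

#' Isotropic elastic moduli from longitudinal and transverse sound velocities
#'
#' For an elastically isotropic material (e.g. a regenerated silk fibroin
#' film) the longitudinal modulus is M = rho c_L^2 and the shear modulus
#' G = rho c_T^2. Poisson's ratio follows from the velocity ratio
#' r = c_L / c_T as nu = (r^2 - 2) / (2 (r^2 - 1)), Young's modulus as
#' E = 2 G (1 + nu), and the bulk modulus as K = M - 4 G / 3.
#'
#' @param c_L Longitudinal sound velocity (m/s).
#' @param c_T Transverse sound velocity (m/s); must satisfy c_L > c_T, and
#'   c_L > sqrt(4/3) c_T for a positive bulk modulus.
#' @param rho Density (kg/m^3).
#' @return An object of class `"isotropic_elastic"`: list with `c_L`, `c_T`,
#'   `rho`, and `M`, `G`, `E`, `K` in GPa plus dimensionless `nu`.
#' @examples
#' isotropic_moduli(3235, 1590, 1170) # M = 12.2 GPa, G = 3.0 GPa, nu = 0.34
#' @export
isotropic_moduli <- function(c_L, c_T, rho) {
  check_scalar(c_L, "c_L"); check_scalar(c_T, "c_T"); check_scalar(rho, "rho")
  if (c_L <= c_T) {
    abort_validation(sprintf(
      "c_L (%g) must exceed c_T (%g) for a physical isotropic solid", c_L, c_T))
  }
  M <- rho * c_L^2 / GPA
  G <- rho * c_T^2 / GPA
  K <- M - 4 * G / 3
  if (K <= 0) {
    abort_validation(sprintf(
      "c_L = %g, c_T = %g imply a non-positive bulk modulus (need c_L > sqrt(4/3) c_T)",
      c_L, c_T))
  }
  r2 <- (c_L / c_T)^2
  nu <- (r2 - 2) / (2 * (r2 - 1))
  structure(
    list(c_L = c_L, c_T = c_T, rho = rho,
         M = M, G = G, nu = nu, E = 2 * G * (1 + nu), K = K),
    class = "isotropic_elastic"
  )
}

#' @export
print.isotropic_elastic <- function(x, digits = 3, ...) {
  cat(sprintf("Isotropic elasticity: c_L = %g, c_T = %g m/s, rho = %g kg/m^3\n",
              x$c_L, x$c_T, x$rho))
  cat(sprintf("  M = %.*g GPa, G = %.*g GPa, E = %.*g GPa, K = %.*g GPa, nu = %.*g\n",
              digits, x$M, digits, x$G, digits, x$E, digits, x$K, digits, x$nu))
  invisible(x)
}

#' Longitudinal modulus from a single phonon
#'
#' M = rho (2 pi f / q)^2: the longitudinal modulus probed by one phonon
#' mode, e.g. M parallel/normal to the fiber axis as a function of tensile
#' strain.
#'
#' @param f_ghz Frequency shift (GHz).
#' @param q Wave vector (object or magnitude in nm^-1).
#' @param rho Density (kg/m^3).
#' @return Modulus in GPa.
#' @examples
#' q <- q_transmission(scattering_config(532, 90))
#' longitudinal_modulus(13.18, q, 1350)
#' @export
longitudinal_modulus <- function(f_ghz, q, rho) {
  check_scalar(rho, "rho")
  c_mps <- velocity_from_shift(f_ghz, q)
  rho * c_mps^2 / GPA
}
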