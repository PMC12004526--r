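# Transversely isotropic stiffness tensor and the Christoffel forward model.
#
# Convention: Voigt notation with the fiber symmetry axis as the "3" axis.
# Stiffness constants are stored in GPa and converted to Pa inside the
# rho*c^2 arithmetic.

#' Transversely isotropic stiffness tensor
#'
#' Constructs a transversely isotropic (hexagonal) stiffness tensor with the
#' fiber axis along Voigt axis 3. The five independent constants are C11,
#' C33, C44, C13 and C66; C12 is fixed by the hexagonal identity
#' C12 = C11 - 2 C66. Positive definiteness is enforced: C44 > 0, C66 > 0,
#' C11 > |C12| and (C11 + C12) C33 > 2 C13^2.
#'
#' @param C11,C33,C44,C13 Stiffness constants in GPa.
#' @param C66 Stiffness constant in GPa; defaults to C44 (the assumption used
#'   when the pure-transverse branch is only observable at alpha = 0).
#' @param rho Mass density in kg/m^3.
#' @return An object of class `"ti_tensor"` with fields `C11, C12, C13,
#'   C33, C44, C66, rho`.
#' @examples
#' ti_tensor(C11 = 13.0, C33 = 32.1, C44 = 4.5, C13 = 8.6, rho = 1350)
#' @export
ti_tensor <- function(C11, C33, C44, C13, C66 = C44, rho) {
  for (nm in c("C11", "C33", "C44", "C66", "rho")) {
    check_scalar(get(nm), nm)
  }
  check_scalar(C13, "C13", positive = FALSE)
  C12 <- C11 - 2 * C66
  if (C11 <= abs(C12)) {
    abort_validation(sprintf(
      "tensor not positive definite: C11 = %g must exceed |C12| = |C11 - 2 C66| = %g",
      C11, abs(C12)))
  }
  if ((C11 + C12) * C33 <= 2 * C13^2) {
    abort_validation(sprintf(
      "tensor not positive definite: (C11 + C12) C33 = %g must exceed 2 C13^2 = %g",
      (C11 + C12) * C33, 2 * C13^2))
  }
  structure(
    list(C11 = C11, C12 = C12, C13 = C13, C33 = C33, C44 = C44, C66 = C66,
         rho = rho),
    class = "ti_tensor"
  )
}

#' @export
print.ti_tensor <- function(x, ...) {
  cat("Transversely isotropic stiffness tensor (GPa), fiber axis = 3\n")
  cat(sprintf("  C11 = %-6.4g C12 = %-6.4g C13 = %-6.4g\n", x$C11, x$C12, x$C13))
  cat(sprintf("  C33 = %-6.4g C44 = %-6.4g C66 = %-6.4g\n", x$C33, x$C44, x$C66))
  cat(sprintf("  rho = %g kg/m^3\n", x$rho))
  invisible(x)
}

#' 6x6 Voigt stiffness matrix
#'
#' @param tensor A [ti_tensor()].
#' @return A symmetric 6x6 matrix in GPa.
#' @export
voigt_matrix <- function(tensor) {
  stopifnot(inherits(tensor, "ti_tensor"))
  C <- matrix(0, 6, 6)
  C[1, 1] <- C[2, 2] <- tensor$C11
  C[3, 3] <- tensor$C33
  C[4, 4] <- C[5, 5] <- tensor$C44
  C[6, 6] <- tensor$C66
  C[1, 2] <- C[2, 1] <- tensor$C12
  C[1, 3] <- C[3, 1] <- C[2, 3] <- C[3, 2] <- tensor$C13
  C
}

#' Closed-form Christoffel phase velocities for a transversely isotropic medium
#'
#' For propagation at angle alpha to the symmetry axis the three acoustic
#' branch velocities are
#' \deqn{\rho c_{PT}^2 = C_{66}\sin^2\alpha + C_{44}\cos^2\alpha}
#' \deqn{\rho c_{QL,QT}^2 = \tfrac12\big[C_{11}\sin^2\alpha +
#'   C_{33}\cos^2\alpha + C_{44} \pm \sqrt{(C_{11}\sin^2\alpha -
#'   C_{33}\cos^2\alpha + C_{44}\cos 2\alpha)^2 +
#'   4 (C_{13}+C_{44})^2 \sin^2\alpha \cos^2\alpha}\big]}
#' with QL taking the + root. At alpha = 0 and 90 degrees the quasi-modes
#' become pure (c_QL = sqrt(C33/rho) and sqrt(C11/rho) respectively).
#'
#' @param tensor A [ti_tensor()].
#' @param alpha_deg Propagation angle(s) to the fiber axis, in [0, 90]
#'   degrees.
#' @return A data frame with columns `alpha_deg`, `c_QL`, `c_QT`, `c_PT`
#'   (velocities in m/s).
#' @examples
#' tw <- ti_tensor(13.0, 32.1, 4.5, 8.6, rho = 1350)
#' velocities_ti(tw, c(0, 45, 90))
#' @export
velocities_ti <- function(tensor, alpha_deg) {
  stopifnot(inherits(tensor, "ti_tensor"))
  check_alpha(alpha_deg)
  a <- deg2rad(alpha_deg)
  s2 <- sin(a)^2
  c2 <- cos(a)^2
  rho <- tensor$rho
  C11 <- tensor$C11 * GPA; C33 <- tensor$C33 * GPA
  C44 <- tensor$C44 * GPA; C66 <- tensor$C66 * GPA
  C13 <- tensor$C13 * GPA
  pt <- sqrt((C66 * s2 + C44 * c2) / rho)
  X <- C11 * s2 + C33 * c2 + C44
  D <- sqrt((C11 * s2 - C33 * c2 + C44 * cos(2 * a))^2 +
              4 * (C13 + C44)^2 * s2 * c2)
  ql <- sqrt((X + D) / (2 * rho))
  qt <- sqrt(pmax(X - D, 0) / (2 * rho))
  data.frame(alpha_deg = alpha_deg, c_QL = ql, c_QT = qt, c_PT = pt)
}

# full rank-4 stiffness from the Voigt matrix (GPa)
stiffness_tetradic <- function(tensor) {
  Cv <- voigt_matrix(tensor)
  vmap <- matrix(c(1, 6, 5,
                   6, 2, 4,
                   5, 4, 3), 3, 3, byrow = TRUE)
  C4 <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    C4[i, j, k, l] <- Cv[vmap[i, j], vmap[k, l]]
  }
  C4
}

#' Acoustic-tensor eigensolver (brute-force Christoffel solution)
#'
#' Builds the full stiffness tensor from the Voigt matrix, contracts it to
#' the 3x3 acoustic (Christoffel) tensor Gamma_ik = C_ijkl n_j n_l / rho for
#' a propagation direction n, and returns the square roots of its
#' eigenvalues. This is the generic-oracle route against which the closed
#' form [velocities_ti()] is validated.
#'
#' @param tensor A [ti_tensor()].
#' @param direction Unit 3-vector of propagation (component 3 along the
#'   fiber axis). A non-unit vector is normalized with a warning.
#' @return Numeric vector of the three phase velocities in m/s, sorted
#'   decreasing (QL first).
#' @examples
#' tw <- ti_tensor(13.0, 32.1, 4.5, 8.6, rho = 1350)
#' christoffel_eigensolve(tw, c(0, 0, 1)) # largest = sqrt(C33/rho)
#' @export
christoffel_eigensolve <- function(tensor, direction) {
  stopifnot(inherits(tensor, "ti_tensor"))
  if (!is.numeric(direction) || length(direction) != 3L || any(!is.finite(direction))) {
    abort_validation("`direction` must be a finite numeric 3-vector")
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) abort_validation("`direction` must be non-zero")
  if (abs(nrm - 1) > 1e-8) {
    warning("`direction` is not a unit vector; normalizing", call. = FALSE)
    direction <- direction / nrm
  }
  C4 <- stiffness_tetradic(tensor) * GPA
  G <- matrix(0, 3, 3)
  for (i in 1:3) for (k in 1:3) {
    G[i, k] <- sum(C4[i, , k, ] * outer(direction, direction))
  }
  ev <- eigen(G / tensor$rho, symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(ev, 0))
}
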