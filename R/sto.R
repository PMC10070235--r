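# Two-center integrals over normalized 1s Slater-type orbitals,
# chi(r) = (zeta^3/pi)^(1/2) exp(-zeta |r - R|).
# These provide the orbital overlaps and the electron repulsion integrals that
# feed the fragment-orbital couplings and the charged-pair interaction energy.

#' Overlap of two 1s Slater orbitals
#'
#' Computes \eqn{\langle \chi_{\zeta_1}(0) | \chi_{\zeta_2}(R) \rangle} for
#' normalized 1s Slater functions separated by `R` bohr. For equal exponents
#' the closed form \eqn{e^{-\rho}(1+\rho+\rho^2/3)} with \eqn{\rho = \zeta R}
#' is used; unequal exponents are handled by radial quadrature in prolate
#' spheroidal coordinates.
#'
#' @param zeta1,zeta2 orbital exponents in bohr^-1 (must be positive).
#' @param R internuclear distance in bohr (>= 0).
#' @return overlap value in (0, 1].
#' @examples
#' sto_overlap(1, 1, 0)   # 1
#' sto_overlap(1, 1, 1)   # exp(-1) * 7/3
#' @export
sto_overlap <- function(zeta1, zeta2, R) {
  if (!is.numeric(zeta1) || !is.numeric(zeta2) || zeta1 <= 0 || zeta2 <= 0)
    diabex_error("Slater exponents must be positive", "invalid_parameter")
  if (R < 0)
    diabex_error("distance R must be non-negative", "invalid_parameter")
  if (R == 0) {
    # full 3-D integral collapses to a single radial one
    return(8 * (zeta1 * zeta2)^1.5 / (zeta1 + zeta2)^3)
  }
  if (isTRUE(all.equal(zeta1, zeta2))) {
    rho <- zeta1 * R
    return(exp(-rho) * (1 + rho + rho^2 / 3))
  }
  # prolate spheroidal coordinates: overlap separates into products of the
  # auxiliary integrals A_n(p) = int_1^Inf mu^n e^(-p mu) dmu and
  # B_n(q) = int_-1^1 nu^n e^(-q nu) dnu, evaluated by quadrature.
  p <- (zeta1 + zeta2) * R / 2
  q <- (zeta1 - zeta2) * R / 2
  A <- function(n) {
    stats::integrate(function(mu) mu^n * exp(-p * mu), 1, Inf,
                     rel.tol = 1e-12)$value
  }
  B <- function(n) {
    stats::integrate(function(nu) nu^n * exp(-q * nu), -1, 1,
                     rel.tol = 1e-12)$value
  }
  2 * (zeta1 * zeta2)^1.5 * (R / 2)^3 * (A(2) * B(0) - A(0) * B(2))
}

#' Two-center Coulomb repulsion of 1s Slater charge clouds
#'
#' Electron-electron Coulomb integral \eqn{J = \int\int \rho_1(r_1)
#' \rho_2(r_2) / r_{12}} between two unit 1s charge clouds whose centres are
#' `R` bohr apart. For equal exponents the closed form
#' \deqn{J = 1/R - e^{-2\zeta R}(1/R + 11\zeta/8 + 3\zeta^2 R/4 + \zeta^3 R^2/6)}
#' is used; unequal exponents fall back to radial quadrature of one cloud over
#' the exact electrostatic potential of the other. `J < 1/R` always, and
#' `J -> 1/R` as `R -> Inf` (point-charge limit).
#'
#' At `R = 0` the finite self-energy branch is returned (equal exponents:
#' \eqn{5\zeta/8}), marked with attribute `branch = "self-energy"`.
#'
#' @param zeta orbital exponent of the first cloud (bohr^-1, positive).
#' @param R centre separation in bohr (>= 0).
#' @param zeta2 exponent of the second cloud; defaults to `zeta`.
#' @return Coulomb energy in hartree for unit charges.
#' @examples
#' sto_coulomb(1, 2)           # ~0.4260
#' 50 * sto_coulomb(1, 50)     # ~1 (point-charge limit)
#' @export
sto_coulomb <- function(zeta, R, zeta2 = zeta) {
  if (zeta <= 0 || zeta2 <= 0)
    diabex_error("Slater exponents must be positive", "invalid_parameter")
  if (R < 0)
    diabex_error("distance R must be non-negative", "invalid_parameter")
  if (R == 0) {
    val <- zeta * zeta2 * (zeta^2 + 3 * zeta * zeta2 + zeta2^2) /
      (zeta + zeta2)^3
    attr(val, "branch") <- "self-energy"
    return(val)
  }
  if (isTRUE(all.equal(zeta, zeta2))) {
    return(1 / R - exp(-2 * zeta * R) *
             (1 / R + 11 * zeta / 8 + 3 * zeta^2 * R / 4 + zeta^3 * R^2 / 6))
  }
  # rho_2 shell-averaged over the potential of cloud 1:
  # J = int_0^Inf rho2(r) r^2 (2 pi/(r R)) [F(R + r) - F(|R - r|)] dr,
  # with F the antiderivative of s * phi1(s) and phi1 the cloud potential.
  phi_int <- function(s) {
    # antiderivative of s * phi1(s) = 1 - exp(-2 zeta s)(1 + zeta s)
    s + exp(-2 * zeta * s) * (3 / (4 * zeta) + s / 2)
  }
  rho2 <- function(r) (zeta2^3 / pi) * exp(-2 * zeta2 * r)
  f <- function(r) {
    rho2(r) * r^2 * (2 * pi / (r * R)) * (phi_int(R + r) - phi_int(abs(R - r)))
  }
  stats::integrate(f, 0, Inf, rel.tol = 1e-11)$value
}

#' Electrostatic potential of a unit 1s Slater charge cloud
#'
#' Potential at distance `R` from the centre of a normalized 1s cloud:
#' \eqn{\phi(R) = [1 - e^{-2\zeta R}(1 + \zeta R)]/R}. Used for the
#' electron-nucleus attraction terms of the charged-pair interaction energy.
#' `zeta = Inf` gives the bare point-charge potential `1/R`.
#'
#' @param zeta orbital exponent in bohr^-1 (positive, may be `Inf`).
#' @param R distance in bohr (> 0).
#' @return potential in hartree per unit charge.
#' @export
sto_potential <- function(zeta, R) {
  if (any(R <= 0))
    diabex_error("potential requested at zero distance", "singularity")
  if (is.infinite(zeta)) return(1 / R)
  if (zeta <= 0)
    diabex_error("Slater exponent must be positive", "invalid_parameter")
  (1 - exp(-2 * zeta * R) * (1 + zeta * R)) / R
}
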