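# LE block: site-energy container and Forster-type Coulomb couplings between
# localized transitions, evaluated from discrete transition charges, with the
# point-dipole approximation available for comparison.

#' Site-energy container for the four LE diabats
#'
#' Holds the Qy/Qx excitation energies of the two fragments in eV with a
#' provenance tag. Toy-provenance energies must satisfy `Qx >= Qy` per
#' fragment (the Qx band lies above Qy) and be positive.
#'
#' @param qy1,qx1,qy2,qx2 energies in eV (fragment 1 = A, fragment 2 = B).
#' @param provenance `"toy"`, `"file"` or `"external"`.
#' @return named numeric vector of class `site_energies`.
#' @export
site_energies <- function(qy1, qx1, qy2, qx2, provenance = "toy") {
  e <- c(Qy1 = qy1, Qx1 = qx1, Qy2 = qy2, Qx2 = qx2)
  if (any(!is.finite(e)) || any(e <= 0))
    diabex_error("site energies must be positive and finite", "configuration")
  if (provenance == "toy" && (e["Qx1"] < e["Qy1"] || e["Qx2"] < e["Qy2"]))
    diabex_error("toy site energies must satisfy Qx >= Qy per fragment",
                 "configuration")
  structure(e, provenance = provenance, class = "site_energies")
}

#' Toy site energies from fragment frontier gaps
#'
#' Qy = `eps_L - eps_H`, Qx = `eps_L - eps_Hp` for each fragment, in eV.
#'
#' @param dimer a [build_dimer()] result.
#' @return a [site_energies()] object.
#' @export
toy_site_energies <- function(dimer) {
  g <- function(frag) c(
    qy = hartree_to_ev(frag$orbital_energies[frag$frontier$L] -
                         frag$orbital_energies[frag$frontier$H]),
    qx = hartree_to_ev(frag$orbital_energies[frag$frontier$L] -
                         frag$orbital_energies[frag$frontier$Hp]))
  a <- g(dimer$fragA); b <- g(dimer$fragB)
  site_energies(a[["qy"]], a[["qx"]], b[["qy"]], b[["qx"]],
                provenance = "toy")
}

#' Coulomb coupling between two transition-charge sets
#'
#' Forster-type coupling between localized transitions, evaluated from the
#' discrete transition charges:
#' \deqn{V = \sum_{s \in A, t \in B} q_s q_t / |r_s - r_t|}
#' Symmetric in A and B, and converges to [pda_coupling()] when the
#' separation is large compared to the charge-set extent.
#'
#' @param tqA,tqB [make_transition_charges()] results (or data.frames with
#'   columns `x`, `y`, `z` in bohr and `q` in e) on disjoint fragments.
#' @param unit `"hartree"` (default) or `"eV"`.
#' @return coupling in the requested unit.
#' @export
coulomb_coupling <- function(tqA, tqB, unit = "hartree") {
  pA <- as.matrix(tqA[, c("x", "y", "z")])
  pB <- as.matrix(tqB[, c("x", "y", "z")])
  d2 <- outer(rowSums(pA^2), rowSums(pB^2), `+`) - 2 * pA %*% t(pB)
  if (min(d2) < 1e-16)
    diabex_error("coincident charge sites across fragments", "singularity")
  V <- sum(outer(tqA$q, tqB$q) / sqrt(d2))
  as_unit(V, unit)
}

#' Point-dipole approximation to the transition coupling
#'
#' \deqn{V = [\mu_A \cdot \mu_B - 3 (\mu_A \cdot \hat R)(\mu_B \cdot \hat R)]
#'       / R^3}
#'
#' @param muA,muB transition dipoles in e bohr.
#' @param Rvec displacement vector from A to B in bohr (nonzero).
#' @param unit `"hartree"` (default) or `"eV"`.
#' @return coupling in the requested unit.
#' @examples
#' pda_coupling(c(1, 0, 0), c(1, 0, 0), c(0, 0, 10))  # 1e-3 hartree
#' @export
pda_coupling <- function(muA, muB, Rvec, unit = "hartree") {
  R <- sqrt(sum(Rvec^2))
  if (R <= 0)
    diabex_error("zero separation in point-dipole coupling", "singularity")
  rhat <- Rvec / R
  V <- (sum(muA * muB) - 3 * sum(muA * rhat) * sum(muB * rhat)) / R^3
  as_unit(V, unit)
}
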