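# Toy fragments: a minimal chromophore model with 1s Slater basis functions on
# point sites, orthonormal molecular orbitals with energies, and a frontier
# orbital map (HOMO-1, HOMO, LUMO). Stands in for a subsystem-DFT fragment.

#' Construct a toy chromophore fragment
#'
#' A fragment is a set of sites (positions in bohr, with core charges), a 1s
#' Slater basis attached to the sites, and molecular orbitals that are
#' orthonormal in the intra-fragment overlap metric. Orbitals are either
#' supplied explicitly or generated from a one-parameter Wolfsberg-Helmholz
#' model Hamiltonian over the basis (`H_pq = alpha_p` on the diagonal,
#' `K (alpha_p + alpha_q) S_pq / 2` off it). Supplied `orbital_energies`
#' override the model eigenvalues, which lets the synthetic backend target
#' chlorophyll-like frontier gaps while keeping consistent orbitals.
#'
#' The frontier map assigns roles `Hp` (HOMO-1), `H` (HOMO) and `L` (LUMO)
#' from the occupation count: with `n_occ` doubly occupied orbitals,
#' `H = n_occ`, `Hp = n_occ - 1`, `L = n_occ + 1` (1-based).
#'
#' @param label fragment identifier, conventionally `"A"` or `"B"`.
#' @param sites data.frame with columns `tag`, `x`, `y`, `z` (bohr), `charge`
#'   (core charge in e).
#' @param basis data.frame with columns `site` (1-based site index) and `zeta`
#'   (1s Slater exponent in bohr^-1).
#' @param n_occ number of doubly occupied orbitals (>= 1; >= 2 required to use
#'   the `Hp` role).
#' @param orbital_energies optional ascending vector of orbital energies in
#'   hartree, one per basis function.
#' @param mo_coeffs optional basis-by-orbital coefficient matrix; must be
#'   orthonormal in the intra-fragment metric to 1e-10.
#' @param huckel_alpha on-site energies (hartree) for the model Hamiltonian,
#'   recycled over basis functions. Default -0.5.
#' @param huckel_K Wolfsberg-Helmholz constant of the model Hamiltonian.
#' @return object of class `toy_fragment`.
#' @examples
#' frag <- toy_chla_fragment("A")
#' frag$frontier
#' @export
toy_fragment <- function(label, sites, basis, n_occ,
                         orbital_energies = NULL, mo_coeffs = NULL,
                         huckel_alpha = -0.5, huckel_K = 1.75) {
  sites <- as.data.frame(sites)
  basis <- as.data.frame(basis)
  stopifnot(all(c("x", "y", "z") %in% names(sites)),
            all(c("site", "zeta") %in% names(basis)))
  if (is.null(sites$tag)) sites$tag <- paste0("X", seq_len(nrow(sites)))
  if (is.null(sites$charge)) sites$charge <- 0
  if (any(basis$site < 1 | basis$site > nrow(sites)))
    diabex_error("basis site index out of range", "configuration")
  if (any(basis$zeta <= 0))
    diabex_error("Slater exponents must be positive", "invalid_parameter")
  nb <- nrow(basis)
  if (n_occ < 1 || n_occ > nb)
    diabex_error("need 1 <= n_occ <= number of basis functions",
                 "configuration")

  S <- basis_overlap(sites, basis, sites, basis)
  if (is.null(mo_coeffs)) {
    alpha <- rep_len(huckel_alpha, nb)
    H <- 0.5 * huckel_K * outer(alpha, alpha, `+`) * S
    diag(H) <- alpha
    ge <- solve_generalized(H, S)
    mo_coeffs <- ge$vectors
    if (is.null(orbital_energies)) orbital_energies <- ge$values
  }
  mo_coeffs <- fix_phases(as.matrix(mo_coeffs))
  if (is.null(orbital_energies))
    diabex_error("orbital_energies required with explicit mo_coeffs",
                 "configuration")
  if (length(orbital_energies) != ncol(mo_coeffs) || nrow(mo_coeffs) != nb)
    diabex_error("orbital/basis dimension mismatch", "configuration")
  if (is.unsorted(orbital_energies))
    diabex_error("orbital energies must be ascending", "configuration")
  dev <- max(abs(crossprod(mo_coeffs, S %*% mo_coeffs) -
                   diag(ncol(mo_coeffs))))
  if (dev > 1e-10)
    diabex_error(sprintf(
      "orbitals not orthonormal in the fragment metric (max deviation %.2e)",
      dev), "configuration")

  n_occ <- as.integer(n_occ)
  frontier <- list(H = n_occ)
  if (n_occ < nb) frontier$L <- n_occ + 1L
  if (n_occ >= 2) frontier$Hp <- n_occ - 1L

  structure(list(
    label = label, sites = sites, basis = basis,
    mo_coeffs = mo_coeffs, orbital_energies = as.numeric(orbital_energies),
    n_occ = as.integer(n_occ), frontier = frontier, s_intra = S
  ), class = "toy_fragment")
}

# overlap matrix between two (sites, basis) blocks
basis_overlap <- function(sites1, basis1, sites2, basis2) {
  n1 <- nrow(basis1); n2 <- nrow(basis2)
  S <- matrix(0, n1, n2)
  p1 <- as.matrix(sites1[, c("x", "y", "z")])
  p2 <- as.matrix(sites2[, c("x", "y", "z")])
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      R <- sqrt(sum((p1[basis1$site[i], ] - p2[basis2$site[j], ])^2))
      S[i, j] <- sto_overlap(basis1$zeta[i], basis2$zeta[j], R)
    }
  }
  S
}

# deterministic sign convention: largest-|coefficient| entry positive
fix_phases <- function(C) {
  for (k in seq_len(ncol(C))) {
    i <- which.max(abs(C[, k]))
    if (C[i, k] < 0) C[, k] <- -C[, k]
  }
  C
}

#' @export
print.toy_fragment <- function(x, ...) {
  cat(sprintf("<toy_fragment %s: %d sites, %d basis fns, %d occ orbitals>\n",
              x$label, nrow(x$sites), nrow(x$basis), x$n_occ))
  cat("orbital energies (hartree):",
      paste(sprintf("%.4f", x$orbital_energies), collapse = " "), "\n")
  invisible(x)
}

#' Chlorophyll-like default fragment
#'
#' Four 1s Slater functions (`zeta = 1.3` bohr^-1) on a slightly irregular
#' zigzag chain (spacing 2.6 bohr), four electrons (`n_occ = 2`), with
#' orbital energies chosen so that the frontier gaps mimic the
#' chlorophyll-a Q bands: `L - H` = 2.04 eV (Qy) and `L - Hp` = 2.31 eV
#' (Qx). The on-site model energies are deliberately inequivalent so the
#' orbitals are not symmetry-pure: transition dipoles and all
#' inter-fragment overlaps are then generic (nonzero). Core charges make
#' the fragment neutral.
#'
#' @param label fragment identifier.
#' @param zeta Slater exponent in bohr^-1.
#' @param spacing chain spacing in bohr.
#' @param orbital_energies ascending energies in hartree (length 4).
#' @return a [toy_fragment()].
#' @export
toy_chla_fragment <- function(label = "A", zeta = 1.3, spacing = 2.6,
                              orbital_energies = c(-0.201, -0.191,
                                                   -0.116, -0.040)) {
  sites <- data.frame(
    tag = paste0("C", 1:4),
    x = spacing * c(-1.5, -0.5, 0.5, 1.5),
    y = c(0, 0.6, 0, 0.6), z = 0,
    charge = 1)
  basis <- data.frame(site = 1:4, zeta = zeta)
  toy_fragment(label, sites, basis, n_occ = 2,
               orbital_energies = orbital_energies,
               huckel_alpha = c(-0.54, -0.50, -0.47, -0.44))
}

#' Rigidly transform a fragment
#'
#' Applies `positions %*% t(rotation) + shift` to the site coordinates.
#' A 1s basis is rotationally invariant, so orbitals and energies carry over.
#'
#' @param frag a [toy_fragment()].
#' @param shift length-3 translation in bohr.
#' @param rotation 3x3 rotation matrix.
#' @return the transformed fragment.
#' @export
transform_fragment <- function(frag, shift = c(0, 0, 0), rotation = diag(3)) {
  p <- as.matrix(frag$sites[, c("x", "y", "z")])
  p <- p %*% t(rotation)
  p <- sweep(p, 2, -as.numeric(shift))
  frag$sites[, c("x", "y", "z")] <- p
  frag
}

# per-site Mulliken population of a single orbital (one electron)
mulliken_site_populations <- function(frag, orbital) {
  C <- frag$mo_coeffs[, orbital]
  contrib <- C * as.numeric(frag$s_intra %*% C)
  as.numeric(tapply(contrib, factor(frag$basis$site,
                                    levels = seq_len(nrow(frag$sites))), sum,
                    default = 0))
}

#' Mulliken transition charges for a frontier orbital pair
#'
#' Discretizes the transition density of a single-orbital excitation into
#' per-site point charges by a symmetrized Mulliken partition:
#' \deqn{q_t = 1/2 \sum_{b \in t} [C_{occ,b} (S C_{virt})_b +
#'       (S C_{occ})_b C_{virt,b}]}
#' For orthonormal orbital pairs the charges sum to zero, and the derived
#' transition dipole is exactly \eqn{\sum_t q_t r_t}.
#'
#' @param frag a [toy_fragment()].
#' @param role_pair character vector `c(occupied role, virtual role)` using
#'   frontier roles `"Hp"`, `"H"`, `"L"`, or a pair of orbital indices.
#' @return object of class `transition_charges`: data.frame of site positions
#'   and charges with attributes `origin`, `roles` and `dipole` (e bohr).
#' @examples
#' tq <- make_transition_charges(toy_chla_fragment("A"), c("H", "L"))
#' sum(tq$q)   # ~0
#' @export
make_transition_charges <- function(frag, role_pair = c("H", "L")) {
  idx <- vapply(role_pair, function(r) {
    if (is.character(r) || is.factor(r)) {
      r <- as.character(r)
      if (is.null(frag$frontier[[r]]))
        diabex_error(sprintf("role '%s' not present in frontier map", r),
                     "configuration")
      as.integer(frag$frontier[[r]])
    } else as.integer(r)
  }, integer(1))
  o <- idx[1]; v <- idx[2]
  S <- frag$s_intra
  Co <- frag$mo_coeffs[, o]; Cv <- frag$mo_coeffs[, v]
  contrib <- 0.5 * (Co * as.numeric(S %*% Cv) + as.numeric(S %*% Co) * Cv)
  q <- as.numeric(tapply(contrib,
                         factor(frag$basis$site,
                                levels = seq_len(nrow(frag$sites))),
                         sum, default = 0))
  out <- data.frame(site = seq_len(nrow(frag$sites)),
                    x = frag$sites$x, y = frag$sites$y, z = frag$sites$z,
                    q = q)
  structure(out,
            origin = frag$label,
            roles = paste(role_pair, collapse = "->"),
            dipole = colSums(out$q * as.matrix(out[, c("x", "y", "z")])),
            class = c("transition_charges", "data.frame"))
}

#' Transition dipole of a charge set
#'
#' @param tq a `transition_charges` object (or any data.frame with columns
#'   `x`, `y`, `z`, `q` in bohr and e).
#' @return length-3 dipole vector in e bohr.
#' @export
transition_dipole <- function(tq) {
  colSums(tq$q * as.matrix(tq[, c("x", "y", "z")]))
}
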