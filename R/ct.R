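# Charge-transfer energetics: two-state (GS/CT) Marcus analysis with
# non-orthogonal diabats, and the CT state energy decomposed into ionized
# fragment energies plus the charged-pair interaction energy, which carries
# the -1/R long-range limit.

#' Marcus coupling of two non-orthogonal diabatic states
#'
#' \deqn{V_{01} = [H_{01} - S_{01}(H_{00} + H_{11})/2] / (1 - S_{01}^2)}
#'
#' @param H00,H11 diabatic energies (hartree).
#' @param H01 off-diagonal Hamiltonian element.
#' @param S01 diabatic overlap, `|S01| < 1`.
#' @return the effective coupling V01.
#' @examples
#' marcus_coupling(-10, -9, 0.1, 0.1)  # ~1.06061
#' @export
marcus_coupling <- function(H00, H11, H01, S01) {
  if (abs(S01) >= 1)
    diabex_error("|S01| must be < 1", "overlap_domain")
  (H01 - S01 * (H00 + H11) / 2) / (1 - S01^2)
}

#' Adiabatic splitting of a two-state problem
#'
#' \deqn{\Delta E = \sqrt{(H_{11}-H_{00})^2 / (1-S_{01}^2) + 4 V_{01}^2}}
#' In the weak-coupling, small-overlap limit this reduces to the diabatic gap
#' `H11 - H00`; for degenerate diabats it is exactly `2 |V01|`.
#'
#' @inheritParams marcus_coupling
#' @param V01 effective coupling, e.g. from [marcus_coupling()].
#' @return adiabatic energy difference (hartree).
#' @export
adiabatic_gap <- function(H00, H11, S01, V01) {
  if (abs(S01) >= 1)
    diabex_error("|S01| must be < 1", "overlap_domain")
  sqrt((H11 - H00)^2 / (1 - S01^2) + 4 * V01^2)
}

#' Diabatic CT energy with a weak-coupling validity flag
#'
#' Returns the diabatic gap `H11 - H00` as the CT energy, flagging the result
#' invalid when `|V01| / |H11 - H00|` exceeds `threshold` (the weak-coupling
#' approximation then no longer guarantees that diabatic and adiabatic
#' energies coincide).
#'
#' @inheritParams adiabatic_gap
#' @param threshold coupling/gap ratio above which the flag is false.
#' @return list with `value` (= `H11 - H00`) and `weak_coupling` flag.
#' @export
diabatic_ct_energy <- function(H00, H11, V01 = 0, threshold = 0.1) {
  gap <- H11 - H00
  flag <- if (gap == 0) V01 == 0 else abs(V01) / abs(gap) <= threshold
  list(value = gap, weak_coupling = flag)
}

#' Site-centred charge-cloud model of a (possibly ionized) fragment
#'
#' Represents a fragment's charge distribution as nuclear point charges plus
#' one spherical 1s Slater electron cloud per site, populated by Mulliken
#' populations of the doubly occupied orbitals. Ionization removes one
#' electron distributed as the HOMO population (`"cation"`) or adds one as
#' the LUMO population (`"anion"`).
#'
#' @param frag a [toy_fragment()].
#' @param state `"neutral"`, `"cation"` or `"anion"`.
#' @return data.frame with columns `x`, `y`, `z` (bohr), `Z` (core charge),
#'   `p` (electron population) and `zeta` (cloud exponent, from the first
#'   basis function on the site).
#' @export
charge_clouds <- function(frag, state = c("neutral", "cation", "anion")) {
  state <- match.arg(state)
  n_sites <- nrow(frag$sites)
  p <- rep(0, n_sites)
  for (o in seq_len(frag$n_occ))
    p <- p + 2 * mulliken_site_populations(frag, o)
  if (state == "cation")
    p <- p - mulliken_site_populations(frag, frag$frontier$H)
  if (state == "anion")
    p <- p + mulliken_site_populations(frag, frag$frontier$L)
  zeta <- vapply(seq_len(n_sites), function(s) {
    z <- frag$basis$zeta[frag$basis$site == s]
    if (length(z)) z[1] else Inf
  }, numeric(1))
  data.frame(x = frag$sites$x, y = frag$sites$y, z = frag$sites$z,
             Z = frag$sites$charge, p = p, zeta = zeta)
}

#' Classical interaction energy of two charge-cloud sets
#'
#' Sums the electron-electron ([sto_coulomb()]), electron-nucleus
#' ([sto_potential()]) and nucleus-nucleus Coulomb terms between two
#' site-centred charge distributions. Non-additive functional contributions
#' are not part of the model and are recorded as zero in the components.
#' For net charges `qA`, `qB` the large-separation limit is `qA qB / R`;
#' a +1/-1 pair therefore tends to `-1/R`.
#'
#' @param cloudsA,cloudsB data.frames as returned by [charge_clouds()]
#'   (columns `x`, `y`, `z`, `Z`, `p`, `zeta`; `zeta = Inf` marks a point
#'   charge cloud).
#' @return list with `total` (hartree) and `components`
#'   (`nn`, `en`, `ee`, `nonadditive`).
#' @examples
#' plus <- data.frame(x = 0, y = 0, z = 0, Z = 1, p = 0, zeta = Inf)
#' minus <- data.frame(x = 0, y = 0, z = 5, Z = 0, p = 1, zeta = Inf)
#' interaction_energy(plus, minus)$total   # -0.2
#' @export
interaction_energy <- function(cloudsA, cloudsB) {
  nn <- 0; en <- 0; ee <- 0
  for (s in seq_len(nrow(cloudsA))) {
    for (t in seq_len(nrow(cloudsB))) {
      R <- sqrt((cloudsA$x[s] - cloudsB$x[t])^2 +
                (cloudsA$y[s] - cloudsB$y[t])^2 +
                (cloudsA$z[s] - cloudsB$z[t])^2)
      if (R < 1e-8)
        diabex_error("coincident sites across fragments", "singularity")
      nn <- nn + cloudsA$Z[s] * cloudsB$Z[t] / R
      en <- en -
        cloudsA$Z[s] * cloudsB$p[t] * sto_potential(cloudsB$zeta[t], R) -
        cloudsB$Z[t] * cloudsA$p[s] * sto_potential(cloudsA$zeta[s], R)
      if (cloudsA$p[s] != 0 && cloudsB$p[t] != 0) {
        za <- cloudsA$zeta[s]; zb <- cloudsB$zeta[t]
        J <- if (is.infinite(za) && is.infinite(zb)) 1 / R
        else if (is.infinite(za)) sto_potential(zb, R)
        else if (is.infinite(zb)) sto_potential(za, R)
        else sto_coulomb(za, R, zb)
        ee <- ee + cloudsA$p[s] * cloudsB$p[t] * J
      }
    }
  }
  list(total = nn + en + ee,
       components = c(nn = nn, en = en, ee = ee, nonadditive = 0))
}

#' Diabatic CT state energies of a dimer
#'
#' Builds the energies of the two charge-transfer diabats, CT1 (`A+B-`) and
#' CT2 (`A-B+`), as `E_CT = E_ion + E_int`: Koopmans-style ionization
#' energetics of the toy fragments (`E_A+ - E_A = -eps_HA`,
#' `E_B- - E_B = +eps_LB`) plus the classical interaction energy of the two
#' charged clouds referenced to the neutral pair. An optional DRF
#' environment shifts each CT state by the electrostatic plus induction
#' interaction of its state-difference charges with the environment sites.
#'
#' @param dimer a [build_dimer()] result.
#' @param env optional [environment_sites()] table.
#' @param h01,s01 optional GS-CT coupling and overlap used for the
#'   weak-coupling check (defaults 0: flag true).
#' @param unit `"eV"` (default, file convention) or `"hartree"`.
#' @return object of class `ct_energy_result`: list with per-label `E_CT`,
#'   components `E_ion`, `E_int`, `E_env`, and `weak_coupling` flags.
#' @export
ct_state_energies <- function(dimer, env = NULL, h01 = 0, s01 = 0,
                              unit = "eV") {
  A <- dimer$fragA; B <- dimer$fragB
  neutralA <- charge_clouds(A, "neutral")
  neutralB <- charge_clouds(B, "neutral")
  ref <- interaction_energy(neutralA, neutralB)$total

  one_ct <- function(donor, acceptor, neutral_d, neutral_a) {
    e_ion <- -donor$orbital_energies[donor$frontier$H] +
      acceptor$orbital_energies[acceptor$frontier$L]
    cat_cl <- charge_clouds(donor, "cation")
    an_cl <- charge_clouds(acceptor, "anion")
    e_int <- interaction_energy(cat_cl, an_cl)$total - ref
    e_env <- 0
    if (!is.null(env)) {
      dq <- rbind(
        data.frame(x = cat_cl$x, y = cat_cl$y, z = cat_cl$z,
                   q = neutral_d$p - cat_cl$p),
        data.frame(x = an_cl$x, y = an_cl$y, z = an_cl$z,
                   q = neutral_a$p - an_cl$p))
      e_env <- env_interaction_energy(dq, env)
    }
    c(E_ion = e_ion, E_int = e_int, E_env = e_env)
  }
  ct1 <- one_ct(A, B, neutralA, neutralB)
  ct2 <- one_ct(B, A, neutralB, neutralA)
  # clouds for CT2 are donor=B, acceptor=A; interaction order is symmetric

  tab <- rbind(CT1 = ct1, CT2 = ct2)
  e_ct <- rowSums(tab)
  flags <- vapply(e_ct, function(g)
    diabatic_ct_energy(0, g, marcus_coupling(0, g, h01, s01))$weak_coupling,
    logical(1))
  structure(list(
    E_CT = as_unit(e_ct, unit),
    components = as_unit(tab, unit),
    weak_coupling = flags,
    unit = match.arg(unit, c("eV", "hartree")),
    note = "non-additive functional terms omitted (recorded as 0)"
  ), class = "ct_energy_result")
}

#' @export
print.ct_energy_result <- function(x, ...) {
  cat(sprintf("<ct_energy_result (%s)>\n", x$unit))
  print(round(cbind(x$components, E_CT = x$E_CT), 6))
  invisible(x)
}
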