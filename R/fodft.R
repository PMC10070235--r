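# Generalized fragment-orbital (FODFT) LE-CT couplings. The working
# quantities are the fragment/fragment overlap matrix S, the
# supermolecule/fragment overlap matrix S', and the supermolecular orbital
# energies; couplings are bilinear forms in these. The brute-force
# determinant expansion is kept alongside as an independent oracle.

#' Bundle of overlap matrices for coupling evaluation
#'
#' Collects everything the coupling formulas consume: `S`, the overlap matrix
#' between fragment-A and fragment-B orbitals; `Sp` (S'), the overlap between
#' supermolecular and fragment orbitals (rows: supermolecular orbitals p with
#' energies `energies[p]`; columns: fragment orbitals, A block then B block);
#' the number of doubly occupied supermolecular orbitals; and the union-basis
#' column indices of the frontier roles of both fragments.
#'
#' Constructed from a dimer by [compute_overlaps()], or directly (e.g. with
#' randomized entries) for algebraic testing.
#'
#' @param S nA x nB fragment-A/fragment-B orbital overlap matrix.
#' @param Sp nsup x (nA+nB) supermolecule/fragment overlap matrix.
#' @param energies supermolecular orbital energies (hartree), one per row of
#'   `Sp`.
#' @param n_occ number of occupied supermolecular orbitals.
#' @param frontier named list of union-basis column indices with elements
#'   `HA`, `LA`, `HB`, `LB` and optionally `HpA`, `HpB`.
#' @param n_A number of fragment-A orbitals (columns `1:n_A` of `Sp`).
#' @return object of class `overlap_set`.
#' @export
overlap_set <- function(S, Sp, energies, n_occ, frontier, n_A = nrow(S)) {
  S <- as.matrix(S); Sp <- as.matrix(Sp)
  if (length(energies) != nrow(Sp))
    diabex_error("one energy per supermolecular orbital required",
                 "structural")
  if (ncol(Sp) != nrow(S) + ncol(S))
    diabex_error("S' columns must span the union of fragment orbitals",
                 "structural")
  if (max(abs(S)) > 1 + 1e-8 || max(abs(Sp)) > 1 + 1e-8)
    diabex_error("overlap entries must lie in [-1, 1]", "structural")
  for (r in c("HA", "LA", "HB", "LB"))
    if (is.null(frontier[[r]]))
      diabex_error(sprintf("frontier role '%s' missing", r), "configuration")
  structure(list(S = S, Sp = Sp, energies = as.numeric(energies),
                 n_occ = as.integer(n_occ), frontier = frontier,
                 n_A = as.integer(n_A)),
            class = "overlap_set")
}

#' Compute the S and S' overlap matrices of a dimer
#'
#' `S` couples fragment-A to fragment-B orbitals; `S'` couples supermolecular
#' to fragment orbitals, obtained by contracting the supermolecular orbital
#' coefficients with the union metric. When the supermolecular basis spans
#' the union of fragment orbitals, the completeness identity
#' `sum_p S'[p, pi] S'[p, rho] = S_union[pi, rho]` holds.
#'
#' @param dimer a [build_dimer()] result.
#' @return an [overlap_set()].
#' @export
compute_overlaps <- function(dimer) {
  if (!inherits(dimer, "dimer_system"))
    diabex_error("expected a dimer_system", "structural")
  Sp <- crossprod(dimer$coeffs, dimer$s_union)
  frontier <- list(HA = role_index(dimer, "A", "H"),
                   LA = role_index(dimer, "A", "L"),
                   HB = role_index(dimer, "B", "H"),
                   LB = role_index(dimer, "B", "L"))
  if (!is.null(dimer$fragA$frontier$Hp))
    frontier$HpA <- role_index(dimer, "A", "Hp")
  if (!is.null(dimer$fragB$frontier$Hp))
    frontier$HpB <- role_index(dimer, "B", "Hp")
  overlap_set(S = dimer$s_ab, Sp = Sp, energies = dimer$energies,
              n_occ = dimer$n_occ, frontier = frontier,
              n_A = length(dimer$idx_A))
}

# label tables for the 4 LE x 2 CT coupling pairs
le_labels <- c("QyA", "QxA", "QyB", "QxB")
ct_labels <- c("CT1", "CT2")

#' Generalized FODFT coupling between an LE and a CT diabatic state
#'
#' Evaluates the printed coupling formulas for single-orbital-transition LE
#' states and the two frontier CT states, CT1 = `H_A -> L_B` and
#' CT2 = `H_B -> L_A`. With `i` running over occupied and `a` over virtual
#' supermolecular orbitals (energies `eps`), the fragment-A couplings are
#' \deqn{V^{QyA,CT1} = \sum_a eps_a S'_{a,LA} S'_{a,LB}
#'       - \sum_i eps_i S_{LA,LB} S'^2_{i,HA}}
#' \deqn{V^{QxA,CT1} = -\sum_i eps_i S_{LA,LB} S'_{i,HpA} S'_{i,HA}}
#' \deqn{V^{QyA,CT2} = -\sum_i eps_i S'_{i,HA} S'_{i,HB}
#'       + \sum_a eps_a S_{HA,HB} S'^2_{a,LA}}
#' \deqn{V^{QxA,CT2} = -\sum_i eps_i S'_{i,HpA} S'_{i,HB}
#'       + \sum_a eps_a S_{HpA,HB} S'^2_{a,LA}}
#' and the fragment-B couplings follow by exchanging the A and B roles.
#'
#' @param ov an [overlap_set()].
#' @param le LE label: `"QyA"`, `"QxA"`, `"QyB"` or `"QxB"`.
#' @param ct CT label: `"CT1"` or `"CT2"`.
#' @return coupling in hartree.
#' @export
v_le_ct <- function(ov, le, ct) {
  if (!inherits(ov, "overlap_set"))
    diabex_error("expected an overlap_set", "structural")
  if (!(le %in% le_labels) || !(ct %in% ct_labels))
    diabex_error(sprintf("unknown coupling pair (%s, %s)", le, ct),
                 "configuration")
  f <- ov$frontier
  occ <- seq_len(ov$n_occ)
  vir <- setdiff(seq_along(ov$energies), occ)
  eps <- ov$energies
  Sp <- ov$Sp
  # S over the union index pair (columns of Sp); A rows, B columns
  s_u <- function(i, j) {
    ij <- sort(c(i, j))
    ov$S[ij[1], ij[2] - ov$n_A]
  }
  frag <- substr(le, 3, 3)                    # owner of the LE state
  hole_role <- if (substr(le, 2, 2) == "y") "H" else "Hp"
  hole <- f[[paste0(if (hole_role == "H") "H" else "Hp", frag)]]
  if (is.null(hole))
    diabex_error(sprintf("frontier role for %s unavailable", le),
                 "configuration")
  H_this <- f[[paste0("H", frag)]]
  L_this <- f[[paste0("L", frag)]]
  other <- if (frag == "A") "B" else "A"
  H_other <- f[[paste0("H", other)]]
  L_other <- f[[paste0("L", other)]]

  # "same_side" CT: the CT hole sits on the LE fragment (electron transfer
  # channel); otherwise the CT hole is on the other fragment (hole transfer).
  same_side <- (ct == "CT1" && frag == "A") || (ct == "CT2" && frag == "B")
  if (same_side) {
    if (hole_role == "H") {
      sum(eps[vir] * Sp[vir, L_this] * Sp[vir, L_other]) -
        sum(eps[occ] * Sp[occ, hole]^2) * s_u(L_this, L_other)
    } else {
      -sum(eps[occ] * Sp[occ, hole] * Sp[occ, H_this]) *
        s_u(L_this, L_other)
    }
  } else {
    -sum(eps[occ] * Sp[occ, hole] * Sp[occ, H_other]) +
      sum(eps[vir] * Sp[vir, L_this]^2) * s_u(hole, H_other)
  }
}

#' All eight LE-CT couplings of a dimer
#'
#' Evaluates [v_le_ct()] for every (LE, CT) pair. The two pairs whose LE hole
#' is orthogonal to the CT hole on the same fragment (QxA/CT1 and QxB/CT2)
#' carry only the HOMO/HOMO-1 cross term and vanish for orthonormal fragment
#' orbitals.
#'
#' @param x a `dimer_system` or an [overlap_set()].
#' @param unit `"hartree"` (default) or `"eV"`.
#' @return 4 x 2 matrix of couplings, rows `QyA, QxA, QyB, QxB`, columns
#'   `CT1, CT2`, with class `lect_table`.
#' @export
all_le_ct_couplings <- function(x, unit = "hartree") {
  ov <- if (inherits(x, "dimer_system")) compute_overlaps(x) else x
  V <- matrix(NA_real_, 4, 2, dimnames = list(le_labels, ct_labels))
  for (le in le_labels)
    for (ct in ct_labels)
      V[le, ct] <- v_le_ct(ov, le, ct)
  structure(as_unit(V, unit), unit = unit, class = c("lect_table", "matrix"))
}

#' Brute-force determinant matrix element (test oracle)
#'
#' Expands singly excited determinants over fragment orbitals into the
#' supermolecular determinant basis through the S' coefficients (hole part
#' projected on occupied, particle part on virtual supermolecular orbitals)
#' and contracts with the diagonal normal-ordered one-electron Hamiltonian
#' (`eps_a - eps_i` per excitation, zero for the reference). Intended as an
#' independent leading-order check of [v_le_ct()]; limited to small orbital
#' spaces.
#'
#' @param dimer a `dimer_system` with at most `max_orbitals` union orbitals.
#' @param state1,state2 `"reference"` or a list `list(hole=, particle=)` of
#'   frontier role strings (`"HA"`, `"LB"`, ...) or union column indices.
#' @param max_orbitals guard for the combinatorial expansion.
#' @return matrix element in hartree.
#' @export
determinant_oracle <- function(dimer, state1, state2, max_orbitals = 14) {
  if (length(dimer$energies) > max_orbitals)
    diabex_error("orbital space too large for determinant expansion", "size")
  ov <- compute_overlaps(dimer)
  occ <- seq_len(ov$n_occ)
  vir <- setdiff(seq_along(ov$energies), occ)
  coef_matrix <- function(state) {
    if (identical(state, "reference"))
      return(matrix(0, length(occ), length(vir)))
    resolve <- function(s) {
      if (is.character(s)) {
        i <- ov$frontier[[s]]
        if (is.null(i))
          diabex_error(sprintf("unknown orbital label '%s'", s),
                       "configuration")
        i
      } else as.integer(s)
    }
    hole <- resolve(state$hole); part <- resolve(state$particle)
    outer(ov$Sp[occ, hole], ov$Sp[vir, part])
  }
  c1 <- coef_matrix(state1)
  c2 <- coef_matrix(state2)
  de <- outer(ov$energies[occ], ov$energies[vir],
              function(ei, ea) ea - ei)
  sum(c1 * c2 * de)
}
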