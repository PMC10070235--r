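# Assembly of the six-state diabatic model (Qy1, Qx1, Qy2, Qx2, CT1, CT2)
# and its solution as a generalized eigenvalue problem, with Lowdin
# characterization of the adiabatic states.

DIABATIC_LABELS <- c("Qy1", "Qx1", "Qy2", "Qx2", "CT1", "CT2")

# (LE label, CT label) -> H_dia entry, A = fragment 1, B = fragment 2
lect_to_entry <- c(QyA = "Qy1", QxA = "Qx1", QyB = "Qy2", QxB = "Qx2")

#' Assemble the six-state diabatic model
#'
#' Places the LE site energies, LE/LE couplings, CT energies and LE-CT
#' couplings into the blocked 6x6 Hamiltonian over the ordered basis
#' `Qy1, Qx1, Qy2, Qx2, CT1, CT2`. The CT1-CT2 coupling and overlap are zero
#' by construction (opposite-polarity charge transfer is a two-electron
#' process), LE-LE overlaps are unit-matrix elements, and LE-CT overlap
#' entries default to single-determinant orbital-overlap products (hole
#' orthogonality times electron overlap) when an [overlap_set()] is given,
#' or to zero otherwise.
#'
#' @param site a [site_energies()] object (eV).
#' @param le_coupling named list/vector of LE/LE couplings in eV: `VQy`
#'   (Qy1-Qy2), `VQx` (Qx1-Qx2) and optionally `VQy1Qx2`, `VQx1Qy2`
#'   (default 0).
#' @param ct either a [ct_state_energies()] result or a named vector
#'   `c(CT1 =, CT2 =)` in eV.
#' @param lect a [all_le_ct_couplings()] table or a 4x2 matrix (rows
#'   `QyA, QxA, QyB, QxB`, columns `CT1, CT2`) in eV.
#' @param overlaps optional [overlap_set()] used to fill the LE-CT entries
#'   of the overlap matrix.
#' @return object of class `diabatic_model`: list with `labels`, `H` (eV),
#'   `S`, and `provenance` metadata per block.
#' @export
assemble_diabatic <- function(site, le_coupling, ct, lect, overlaps = NULL) {
  H <- matrix(0, 6, 6, dimnames = list(DIABATIC_LABELS, DIABATIC_LABELS))
  S <- diag(6); dimnames(S) <- dimnames(H)

  need <- function(ok, what) {
    if (!ok) diabex_error(paste("missing entry for block:", what), "assembly")
  }
  need(all(DIABATIC_LABELS[1:4] %in% names(site)), "LE site energies")
  for (l in DIABATIC_LABELS[1:4]) H[l, l] <- site[[l]]

  lc <- as.list(le_coupling)
  need(!is.null(lc$VQy) && !is.null(lc$VQx), "LE-LE couplings (VQy, VQx)")
  H["Qy1", "Qy2"] <- H["Qy2", "Qy1"] <- lc$VQy
  H["Qx1", "Qx2"] <- H["Qx2", "Qx1"] <- lc$VQx
  H["Qy1", "Qx2"] <- H["Qx2", "Qy1"] <- if (is.null(lc$VQy1Qx2)) 0 else lc$VQy1Qx2
  H["Qx1", "Qy2"] <- H["Qy2", "Qx1"] <- if (is.null(lc$VQx1Qy2)) 0 else lc$VQx1Qy2

  ctv <- if (inherits(ct, "ct_energy_result")) ct$E_CT else ct
  need(all(c("CT1", "CT2") %in% names(ctv)), "CT energies")
  H["CT1", "CT1"] <- ctv[["CT1"]]
  H["CT2", "CT2"] <- ctv[["CT2"]]
  # opposite-polarity CT states: two-electron process, zero by construction
  H["CT1", "CT2"] <- H["CT2", "CT1"] <- 0

  lect <- as.matrix(lect)
  need(all(rownames(lect) %in% names(lect_to_entry)) &&
         all(c("CT1", "CT2") %in% colnames(lect)), "LE-CT couplings")
  for (le in rownames(lect)) {
    for (ctl in c("CT1", "CT2")) {
      lab <- lect_to_entry[[le]]
      H[lab, ctl] <- H[ctl, lab] <- lect[le, ctl]
    }
  }

  if (!is.null(overlaps)) {
    f <- overlaps$frontier
    s_u <- function(i, j) {
      ij <- sort(c(i, j))
      overlaps$S[ij[1], ij[2] - overlaps$n_A]
    }
    # single-determinant products: hole-orthogonality delta x electron overlap
    S["Qy1", "CT1"] <- S["CT1", "Qy1"] <- s_u(f$LA, f$LB)
    S["Qy2", "CT2"] <- S["CT2", "Qy2"] <- s_u(f$LA, f$LB)
    S["Qy1", "CT2"] <- S["CT2", "Qy1"] <- s_u(f$HA, f$HB)
    S["Qy2", "CT1"] <- S["CT1", "Qy2"] <- s_u(f$HA, f$HB)
    if (!is.null(f$HpA)) S["Qx1", "CT2"] <- S["CT2", "Qx1"] <- s_u(f$HpA, f$HB)
    if (!is.null(f$HpB)) S["Qx2", "CT1"] <- S["CT1", "Qx2"] <- s_u(f$HpB, f$HA)
    # Qx1/CT1 and Qx2/CT2 vanish: orthogonal holes on the same fragment
  }

  structure(list(
    labels = DIABATIC_LABELS, H = (H + t(H)) / 2, S = (S + t(S)) / 2,
    provenance = list(
      site = attr(site, "provenance"),
      ct = if (inherits(ct, "ct_energy_result")) ct$note else "table",
      lect = if (inherits(lect, "lect_table")) "fodft" else "table",
      s_le_ct = if (is.null(overlaps)) "zeroed" else "determinant-overlap")
  ), class = "diabatic_model")
}

#' @export
print.diabatic_model <- function(x, ...) {
  cat("<diabatic_model (eV)>\nH:\n")
  print(round(x$H, 4))
  if (max(abs(x$S - diag(6))) > 0) {
    cat("S (non-identity):\n"); print(round(x$S, 6))
  }
  invisible(x)
}

#' Solve a diabatic model
#'
#' Solves `H C = E S C` over the six diabatic states by Cholesky reduction
#' (canonical orthogonalization fallback for near-singular metrics, see
#' [solve_generalized()]), then computes Lowdin character weights
#' `w = (S^{1/2} C)^2` per adiabatic state. Energies ascend; degeneracies
#' are tie-broken by descending LE fraction, then label order, for
#' deterministic output.
#'
#' @param model a [assemble_diabatic()] result.
#' @param scheme character partition scheme: `"lowdin"` (default) or
#'   `"mulliken"` (diagonal of `C * (S C)`).
#' @return object of class `adiabatic_solution`: list with `energies` (eV,
#'   ascending), `coeffs` (S-normalized columns), `weights` (6 x 6, rows =
#'   diabatic labels), `le_fraction` and `ct_fraction` per state.
#' @export
solve_diabatic <- function(model, scheme = c("lowdin", "mulliken")) {
  scheme <- match.arg(scheme)
  S <- model$S
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    diabex_error(sprintf(
      "diabatic overlap matrix not positive definite (min eigenvalue %.2e)",
      min(ev)), "metric")
  ge <- solve_generalized(model$H, S)
  C <- ge$vectors
  w <- if (scheme == "lowdin") {
    se <- eigen(S, symmetric = TRUE)
    Shalf <- se$vectors %*% (sqrt(se$values) * t(se$vectors))
    (Shalf %*% C)^2
  } else {
    C * (S %*% C)
  }
  rownames(w) <- model$labels
  le_frac <- colSums(w[1:4, , drop = FALSE])
  # deterministic ordering within degenerate clusters
  ord <- order(round(ge$values, 10), -le_frac)
  structure(list(
    energies = ge$values[ord],
    coeffs = C[, ord, drop = FALSE],
    weights = w[, ord, drop = FALSE],
    le_fraction = le_frac[ord],
    ct_fraction = 1 - le_frac[ord],
    scheme = scheme, labels = model$labels
  ), class = "adiabatic_solution")
}

#' @export
print.adiabatic_solution <- function(x, ...) {
  cat("<adiabatic_solution (eV)>\n")
  df <- data.frame(E = round(x$energies, 4),
                   LE = round(x$le_fraction, 3),
                   CT = round(x$ct_fraction, 3))
  dominant <- x$labels[apply(x$weights, 2, which.max)]
  df$dominant <- dominant
  print(df)
  invisible(x)
}

#' Mean shift of the lowest adiabatic state between two ensembles
#'
#' `mean(E1 over B) - mean(E1 over A)`; negative values mean ensemble B is
#' red-shifted relative to ensemble A.
#'
#' @param ensembleA,ensembleB lists of [solve_diabatic()] solutions, or
#'   numeric vectors of lowest-state energies (eV).
#' @return mean energy difference in eV.
#' @export
lowest_state_shift <- function(ensembleA, ensembleB) {
  lowest <- function(ens) {
    if (is.numeric(ens)) return(ens)
    if (length(ens) == 0)
      diabex_error("empty ensemble", "input")
    vapply(ens, function(s) s$energies[1], numeric(1))
  }
  a <- lowest(ensembleA); b <- lowest(ensembleB)
  if (!length(a) || !length(b))
    diabex_error("empty ensemble", "input")
  mean(b) - mean(a)
}
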