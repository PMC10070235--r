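# Supermolecular model: two fragments combined over the union of their
# molecular orbitals, with a Wolfsberg-Helmholz one-electron Hamiltonian that
# is proportional to the inter-fragment overlap. Stands in for the fixed
# supermolecular Kohn-Sham calculation behind the fragment-orbital couplings.

#' Solve the symmetric generalized eigenproblem H C = S C E
#'
#' Reduction by Cholesky factorization of the metric: with `S = R'R`, the
#' problem becomes an ordinary symmetric eigenproblem for `R^-T H R^-1`.
#' Eigenvalues ascend and eigenvectors are S-orthonormal (`C' S C = I`).
#' If the metric is numerically non-positive-definite, canonical
#' orthogonalization is used instead: metric eigenvectors with eigenvalues
#' below `canonical_tol` are discarded with a warning.
#'
#' @param H symmetric matrix.
#' @param S symmetric positive-definite metric of the same dimension.
#' @param canonical_tol metric eigenvalue cutoff for the fallback path.
#' @return list with `values` (ascending) and `vectors` (S-normalized columns).
#' @export
solve_generalized <- function(H, S, canonical_tol = 1e-8) {
  H <- (H + t(H)) / 2
  S <- (S + t(S)) / 2
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ch)) {
    Hi <- backsolve(ch, t(backsolve(ch, t(H), transpose = TRUE)),
                    transpose = TRUE)
    e <- eigen((Hi + t(Hi)) / 2, symmetric = TRUE)
    C <- backsolve(ch, e$vectors)
  } else {
    se <- eigen(S, symmetric = TRUE)
    keep <- se$values > canonical_tol
    if (!any(keep))
      diabex_error("metric is not positive definite", "metric")
    if (!all(keep))
      warning(sprintf(
        "metric near-singular: discarding %d basis combination(s) below %g",
        sum(!keep), canonical_tol))
    X <- se$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(se$values[keep]), sum(keep))
    e <- eigen(crossprod(X, H %*% X), symmetric = TRUE)
    C <- X %*% e$vectors
  }
  ord <- order(e$values)
  list(values = e$values[ord],
       vectors = fix_phases(C[, ord, drop = FALSE]))
}

#' Build a toy supermolecular dimer
#'
#' Places fragment B at `displacement` (bohr) relative to fragment A and
#' solves a model supermolecular problem in the union of the two fragments'
#' orbital sets. The model Hamiltonian is diagonal within a fragment
#' (`H_pp = eps_p`) and Wolfsberg-Helmholz between fragments
#' (`H_pq = K (eps_p + eps_q) S_pq / 2`, default `K = 1.75`), so the
#' non-interacting union is recovered exactly when all inter-fragment
#' overlaps vanish. The returned system carries the supermolecular orbitals
#' and energies plus all fragment/fragment (`S`) and supermolecule/fragment
#' (`S'`) overlap matrices needed by the coupling formulas.
#'
#' @param fragA,fragB [toy_fragment()] objects.
#' @param displacement length-3 shift applied to fragment B, in bohr.
#' @param K Wolfsberg-Helmholz constant.
#' @param overlap_scale factor multiplying all inter-fragment overlaps;
#'   useful for studying the weak-overlap limit (`0` = non-interacting).
#' @param condition_limit maximum allowed condition number of the union
#'   metric before a near-linear-dependence error is raised; the same error
#'   fires when the smallest metric eigenvalue drops below `metric_tol`.
#' @param metric_tol smallest acceptable eigenvalue of the union metric.
#' @return object of class `dimer_system` with elements `fragA`, `fragB`
#'   (B already displaced), `s_union` (union-orbital metric), `energies`
#'   (supermolecular, ascending, hartree), `coeffs` (supermolecular orbitals
#'   over the union fragment-orbital basis), `n_occ` (doubly occupied count)
#'   and index bookkeeping for the two fragments.
#' @examples
#' d <- build_dimer(toy_chla_fragment("A"), toy_chla_fragment("B"),
#'                  displacement = c(0, 0, 7))
#' d$energies
#' @export
build_dimer <- function(fragA, fragB, displacement = c(0, 0, 8),
                        K = 1.75, overlap_scale = 1,
                        condition_limit = 1e10, metric_tol = 1e-6) {
  stopifnot(inherits(fragA, "toy_fragment"), inherits(fragB, "toy_fragment"))
  fragB <- transform_fragment(fragB, shift = displacement)

  pA <- as.matrix(fragA$sites[, c("x", "y", "z")])
  pB <- as.matrix(fragB$sites[, c("x", "y", "z")])
  d2 <- outer(rowSums(pA^2), rowSums(pB^2), `+`) - 2 * pA %*% t(pB)
  if (min(d2) < 1e-12)
    diabex_error("fragment site sets overlap after displacement",
                 "configuration")

  nA <- ncol(fragA$mo_coeffs); nB <- ncol(fragB$mo_coeffs)
  Sb <- basis_overlap(fragA$sites, fragA$basis, fragB$sites, fragB$basis)
  SAB <- crossprod(fragA$mo_coeffs, Sb %*% fragB$mo_coeffs) * overlap_scale

  S <- diag(nA + nB)
  S[seq_len(nA), nA + seq_len(nB)] <- SAB
  S[nA + seq_len(nB), seq_len(nA)] <- t(SAB)

  eps <- c(fragA$orbital_energies, fragB$orbital_energies)
  H <- 0.5 * K * outer(eps, eps, `+`) * S
  diag(H) <- eps

  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < metric_tol || max(ev) / min(ev) > condition_limit) {
    worst <- which(abs(SAB) == max(abs(SAB)), arr.ind = TRUE)[1, ]
    diabex_error(sprintf(
      paste0("union orbital basis is near linearly dependent ",
             "(condition %.2e); largest inter-fragment overlap %.4f between ",
             "A orbital %d and B orbital %d"),
      max(ev) / max(min(ev), .Machine$double.eps),
      max(abs(SAB)), worst[1], worst[2]), "linear_dependence")
  }

  ge <- solve_generalized(H, S)
  structure(list(
    fragA = fragA, fragB = fragB, displacement = as.numeric(displacement),
    K = K, overlap_scale = overlap_scale,
    s_union = S, s_ab = SAB,
    energies = ge$values, coeffs = ge$vectors,
    n_occ = fragA$n_occ + fragB$n_occ,
    idx_A = seq_len(nA), idx_B = nA + seq_len(nB)
  ), class = "dimer_system")
}

#' @export
print.dimer_system <- function(x, ...) {
  cat(sprintf(
    "<dimer_system %s+%s: %d union orbitals, %d occupied, max |S_AB| = %.3e>\n",
    x$fragA$label, x$fragB$label, length(x$energies), x$n_occ,
    max(abs(x$s_ab))))
  invisible(x)
}

# union-basis column index of a fragment frontier role, e.g. role_index(d,"A","H")
role_index <- function(dimer, fragment, role) {
  frag <- if (fragment == "A") dimer$fragA else dimer$fragB
  off <- if (fragment == "A") 0L else length(dimer$idx_A)
  i <- frag$frontier[[role]]
  if (is.null(i))
    diabex_error(sprintf("role '%s' undefined on fragment %s", role, fragment),
                 "configuration")
  off + i
}
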