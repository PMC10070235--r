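# Discrete Reaction Field environment: permanent point charges plus
# isotropic polarizable sites whose induced dipoles are solved
# self-consistently (direct linear solve). Interactions are expressed with
# Cartesian interaction tensors T^(0..2), optionally Thole-damped at short
# range to avoid the polarization catastrophe.

#' Environment site table
#'
#' @param x,y,z positions in bohr.
#' @param q permanent charges in e.
#' @param alpha isotropic polarizabilities in bohr^3 (>= 0).
#' @return data.frame of class `environment_sites`.
#' @export
environment_sites <- function(x, y, z, q = 0, alpha = 0) {
  env <- data.frame(x = x, y = y, z = z, q = q, alpha = alpha)
  if (any(env$alpha < 0))
    diabex_error("polarizabilities must be non-negative", "configuration")
  structure(env, class = c("environment_sites", "data.frame"))
}

#' Cartesian interaction tensor of order 0, 1 or 2
#'
#' Derivatives of `1/R` with `R = p - q`:
#' `T0 = 1/R`, `T1_a = R_a / R^3`, `T2_ab = (3 R_a R_b - R^2 d_ab) / R^5`
#' (traceless).
#'
#' @param p,q length-3 points in bohr (must differ).
#' @param order 0, 1 or 2.
#' @return scalar, length-3 vector or 3x3 matrix.
#' @export
interaction_tensor <- function(p, q, order) {
  R <- as.numeric(p) - as.numeric(q)
  r <- sqrt(sum(R^2))
  if (r == 0)
    diabex_error("interaction tensor at coincident points", "singularity")
  switch(as.character(order),
         "0" = 1 / r,
         "1" = R / r^3,
         "2" = (3 * outer(R, R) - r^2 * diag(3)) / r^5,
         diabex_error("tensor order must be 0, 1 or 2", "configuration"))
}

# Thole exponential damping factors for T1 (f3) and T2 (f3, f5).
# v = a * R / (alpha_i alpha_j)^(1/6); a defaults to 2.1304.
thole_factors <- function(r, alpha_i, alpha_j, a) {
  if (alpha_i <= 0 || alpha_j <= 0) return(c(f3 = 1, f5 = 1))
  v <- a * r / (alpha_i * alpha_j)^(1 / 6)
  ev <- exp(-v)
  f3 <- 1 - (1 + v + v^2 / 2) * ev
  f5 <- f3 - (v^3 / 6) * ev
  c(f3 = f3, f5 = f5)
}

# damped dipole-field tensor between two polarizable sites
damped_T2 <- function(ri, rj, alpha_i, alpha_j, damping, a) {
  R <- ri - rj
  r <- sqrt(sum(R^2))
  if (r == 0)
    diabex_error("coincident polarizable sites", "singularity")
  if (damping == "none") return(interaction_tensor(ri, rj, 2))
  f <- thole_factors(r, alpha_i, alpha_j, a)
  (3 * f[["f5"]] * outer(R, R) / r^5) - f[["f3"]] * diag(3) / r^3
}

#' Solve the induced dipoles of a DRF environment
#'
#' Solves the coupled linear equations
#' \deqn{\mu_s = \alpha_s [E^{perm}(s) + \sum_{t \ne s} T^{(2)}_{st} \mu_t]}
#' by a direct solve of the 3N x 3N response system. The permanent field at
#' each polarizable site collects contributions from the environment's own
#' permanent charges, from optional QM source charges, and from an optional
#' uniform external field. Dipole-dipole (and optionally charge-dipole)
#' interactions are Thole-damped by default (exponential form,
#' `a = 2.1304`); pass `damping = "none"` to disable.
#'
#' @param env an [environment_sites()] table.
#' @param qm_sources optional data.frame of QM point charges (columns `x`,
#'   `y`, `z`, `q`) polarizing the environment.
#' @param external_field optional length-3 uniform field (hartree/(e bohr)).
#' @param damping `"thole"` or `"none"`.
#' @param a Thole damping parameter.
#' @return object of class `induced_dipoles`: list with `dipoles` (N x 3,
#'   e bohr), `field` (the permanent field used), `residual` (linear-system
#'   residual norm) and `energy` (induction energy
#'   `-1/2 sum_s mu_s . E_perm(s)`, hartree).
#' @export
solve_induced_dipoles <- function(env, qm_sources = NULL,
                                  external_field = c(0, 0, 0),
                                  damping = c("thole", "none"), a = 2.1304) {
  damping <- match.arg(damping)
  n <- nrow(env)
  pos <- as.matrix(env[, c("x", "y", "z")])
  pol <- which(env$alpha > 0)
  E <- matrix(rep(as.numeric(external_field), each = n), n, 3)
  # field from permanent env charges at every site (no self term)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (t == s || env$q[t] == 0) next
      E[s, ] <- E[s, ] + env$q[t] * interaction_tensor(pos[s, ], pos[t, ], 1)
    }
  }
  if (!is.null(qm_sources) && nrow(qm_sources) > 0) {
    qpos <- as.matrix(qm_sources[, c("x", "y", "z")])
    for (s in seq_len(n)) {
      for (t in seq_len(nrow(qm_sources))) {
        if (qm_sources$q[t] == 0) next
        E[s, ] <- E[s, ] +
          qm_sources$q[t] * interaction_tensor(pos[s, ], qpos[t, ], 1)
      }
    }
  }
  mu <- matrix(0, n, 3)
  if (length(pol)) {
    m <- length(pol)
    A <- matrix(0, 3 * m, 3 * m)
    for (ii in seq_len(m)) {
      si <- pol[ii]
      rows <- (3 * ii - 3) + 1:3
      A[rows, rows] <- diag(3) / env$alpha[si]
      for (jj in seq_len(m)) {
        if (jj == ii) next
        sj <- pol[jj]
        cols <- (3 * jj - 3) + 1:3
        A[rows, cols] <- -damped_T2(pos[si, ], pos[sj, ],
                                    env$alpha[si], env$alpha[sj], damping, a)
      }
    }
    b <- as.numeric(t(E[pol, , drop = FALSE]))
    if (min(eigen((A + t(A)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values) <= 1e-12)
      diabex_error(paste("polarization catastrophe: response matrix not",
                         "positive definite; consider Thole damping"),
                   "polarization")
    sol <- solve(A, b)
    mu[pol, ] <- matrix(sol, ncol = 3, byrow = TRUE)
    resid <- sqrt(sum((A %*% sol - b)^2))
  } else resid <- 0
  if (any(!is.finite(mu)))
    diabex_error("non-finite induced dipoles", "polarization")
  structure(list(dipoles = mu, field = E, residual = resid,
                 energy = -0.5 * sum(mu * E)),
            class = "induced_dipoles")
}

#' Electrostatic and polarization potentials of an environment
#'
#' `v_el(r) = sum_s q_s T0(s, r)` and `v_pol(r) = sum_s mu_s . T1(s -> r)`,
#' with `T1(s -> r) = (r - r_s)/|r - r_s|^3`. The total DRF potential is
#' their sum.
#'
#' @param env an [environment_sites()] table.
#' @param solution an [solve_induced_dipoles()] result (required for
#'   `v_pol`; may be `NULL` for a charge-only environment).
#' @param points matrix or data.frame of query points (bohr), one per row.
#' @return data.frame with columns `v_el`, `v_pol`, `v_drf` (hartree/e).
#' @export
env_potentials <- function(env, solution = NULL, points) {
  pts <- as.matrix(as.data.frame(points)[, 1:3])
  pos <- as.matrix(env[, c("x", "y", "z")])
  n <- nrow(env)
  out <- data.frame(v_el = numeric(nrow(pts)), v_pol = 0)
  for (k in seq_len(nrow(pts))) {
    for (s in seq_len(n)) {
      R <- pts[k, ] - pos[s, ]
      r <- sqrt(sum(R^2))
      if (r < 1e-10)
        diabex_error("potential queried at an environment site",
                     "singularity")
      out$v_el[k] <- out$v_el[k] + env$q[s] / r
      if (!is.null(solution))
        out$v_pol[k] <- out$v_pol[k] + sum(solution$dipoles[s, ] * R / r^3)
    }
  }
  out$v_drf <- out$v_el + out$v_pol
  out
}

# electrostatic + induction interaction energy of a QM charge set with the
# environment, referenced to the charge-free QM state
env_interaction_energy <- function(charges, env, ...) {
  sol_q <- solve_induced_dipoles(env, qm_sources = charges, ...)
  sol_0 <- solve_induced_dipoles(env, ...)
  pot <- env_potentials(env, NULL, charges[, c("x", "y", "z")])
  sum(charges$q * pot$v_el) + (sol_q$energy - sol_0$energy)
}

#' First-order environment shift of a fragment state energy
#'
#' Contracts state-difference charges (excited-minus-ground, per site) with
#' the full DRF potential, the induced dipoles being re-solved in the
#' presence of those charges:
#' \deqn{\Delta E = \sum_i \Delta q_i \, v^{DRF}(r_i)}
#'
#' @param dq data.frame of state-difference charges (`x`, `y`, `z` bohr,
#'   `q` e).
#' @param env an [environment_sites()] table.
#' @param unit `"eV"` (default) or `"hartree"`.
#' @param ... damping options passed to [solve_induced_dipoles()].
#' @return energy shift in the requested unit.
#' @export
site_energy_shift <- function(dq, env, unit = "eV", ...) {
  if (nrow(dq) == 0 || all(dq$q == 0)) return(0)
  sol <- solve_induced_dipoles(env, qm_sources = dq, ...)
  pot <- env_potentials(env, sol, dq[, c("x", "y", "z")])
  as_unit(sum(dq$q * pot$v_drf),
          match.arg(unit, c("hartree", "eV")))
}

#' Environment response correction to an LE/LE coupling
#'
#' Induced dipoles are solved for the transition charges of fragment A alone
#' (transition densities carry no permanent monopole, so permanent
#' environment charges do not enter), then contracted with the transition
#' charges of fragment B:
#' \deqn{\Delta V = -\sum_s \mu_s^{ind}[\rho_A] \cdot
#'       \sum_t q_t^B T^{(1)}(s \to t)}
#' Linear response makes the result symmetric under exchange of A and B.
#'
#' @param tqA,tqB transition-charge sets ([make_transition_charges()]).
#' @param env an [environment_sites()] table with polarizable sites.
#' @param unit `"eV"` (default) or `"hartree"`.
#' @param ... damping options passed to [solve_induced_dipoles()].
#' @return coupling correction in the requested unit.
#' @export
response_coupling_correction <- function(tqA, tqB, env, unit = "eV", ...) {
  env0 <- env
  env0$q <- 0   # only the transition density induces the response
  sol <- solve_induced_dipoles(env0, qm_sources = tqA, ...)
  pos <- as.matrix(env[, c("x", "y", "z")])
  dV <- 0
  for (t in seq_len(nrow(tqB))) {
    rt <- as.numeric(tqB[t, c("x", "y", "z")])
    for (s in seq_len(nrow(env))) {
      R <- rt - pos[s, ]
      r <- sqrt(sum(R^2))
      dV <- dV - tqB$q[t] * sum(sol$dipoles[s, ] * R / r^3)
    }
  }
  as_unit(dV, match.arg(unit, c("hartree", "eV")))
}
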