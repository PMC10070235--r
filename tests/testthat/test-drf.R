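# Discrete reaction field: interaction tensors against finite differences,
# induced dipoles against a fixed-point oracle, potentials, shifts and the
# response correction to couplings.

test_that("interaction tensors match their formulas and finite differences of 1/R", {
  expect_equal(interaction_tensor(c(0, 0, 2), c(0, 0, 0), 0), 0.5)
  expect_equal(interaction_tensor(c(0, 0, 2), c(0, 0, 0), 1),
               c(0, 0, 0.25))
  p <- c(0.4, -1.2, 2.1); q <- c(-0.3, 0.8, 0.2)
  T2 <- interaction_tensor(p, q, 2)
  expect_equal(sum(diag(T2)), 0, tolerance = 1e-12)   # traceless
  # numeric Hessian of 1/R
  h <- 1e-4
  f <- function(pp) 1 / sqrt(sum((pp - q)^2))
  H <- matrix(0, 3, 3)
  for (a in 1:3) {
    for (b in 1:3) {
      ea <- eb <- numeric(3); ea[a] <- h; eb[b] <- h
      H[a, b] <- (f(p + ea + eb) - f(p + ea - eb) -
                    f(p - ea + eb) + f(p - ea - eb)) / (4 * h^2)
    }
  }
  expect_lt(max(abs(T2 - H)), 1e-8)
  expect_error(interaction_tensor(p, p, 1), class = "diabex_singularity")
})

test_that("a single polarizable site responds as mu = alpha E", {
  env <- environment_sites(0, 0, 0, q = 0, alpha = 1)
  sol <- solve_induced_dipoles(env, external_field = c(0, 0, 0.01))
  expect_equal(sol$dipoles[1, ], c(0, 0, 0.01))
  expect_lt(sol$residual, 1e-12)
  # two neutral sites without a field stay unpolarized
  env2 <- environment_sites(c(0, 4), c(0, 0), c(0, 0), q = 0, alpha = 1)
  expect_equal(max(abs(solve_induced_dipoles(env2)$dipoles)), 0)
})

test_that("direct linear solve agrees with fixed-point iteration on random sites", {
  set.seed(7)
  env <- environment_sites(stats::runif(5, 0, 12), stats::runif(5, 0, 12),
                           stats::runif(5, 0, 12),
                           q = c(0.4, -0.3, 0.2, 0, -0.3),
                           alpha = stats::runif(5, 0.5, 1.5))
  # well-separated sites: compare the undamped equations to the oracle
  sol <- solve_induced_dipoles(env, damping = "none",
                               external_field = c(0.002, -0.001, 0.003))
  mu_fp <- fixed_point_dipoles(env, sol$field)
  expect_lt(max(abs(sol$dipoles - mu_fp)), 1e-10)
  # induction energy is non-positive
  expect_lte(sol$energy, 0)
})

test_that("polarization catastrophe is detected and reported", {
  env <- environment_sites(c(0, 1), c(0, 0), c(0, 0), q = 0, alpha = 10)
  expect_error(solve_induced_dipoles(env, damping = "none",
                                     external_field = c(0, 0, 0.01)),
               class = "diabex_polarization")
  # Thole damping regularizes the same configuration
  expect_s3_class(solve_induced_dipoles(env, damping = "thole",
                                        external_field = c(0, 0, 0.01)),
                  "induced_dipoles")
})

test_that("environment potentials follow the tensor formulas and superpose", {
  env <- environment_sites(0, 0, 0, q = 1, alpha = 0)
  pot <- env_potentials(env, NULL, rbind(c(0, 0, 2)))
  expect_equal(pot$v_el, 0.5)
  # a unit dipole at distance 2 on axis: v_pol = 0.25
  envp <- environment_sites(0, 0, 0, q = 0, alpha = 1)
  sol <- solve_induced_dipoles(envp, external_field = c(0, 0, 1))
  pot2 <- env_potentials(envp, sol, rbind(c(0, 0, 2)))
  expect_equal(pot2$v_pol, 0.25)
  expect_equal(pot2$v_drf, pot2$v_el + pot2$v_pol)
  # superposition of two charge-only sites
  env2 <- environment_sites(c(0, 3), c(0, 0), c(0, 0), q = c(0.7, -0.4),
                            alpha = 0)
  p <- rbind(c(1, 1, 1))
  both <- env_potentials(env2, NULL, p)$v_el
  one <- env_potentials(environment_sites(0, 0, 0, q = 0.7, alpha = 0),
                        NULL, p)$v_el +
    env_potentials(environment_sites(3, 0, 0, q = -0.4, alpha = 0),
                   NULL, p)$v_el
  expect_equal(both, one, tolerance = 1e-12)
  expect_error(env_potentials(env, NULL, rbind(c(0, 0, 0))),
               class = "diabex_singularity")
})

test_that("site-energy shifts vanish for zero difference charges, stabilize favourable dipoles and scale linearly", {
  env <- environment_sites(0, 0, 10, q = 0.5, alpha = 0)
  dq0 <- data.frame(x = c(0, 0), y = c(0, 0), z = c(-0.5, 0.5), q = c(0, 0))
  expect_equal(site_energy_shift(dq0, env), 0)
  # negative end of the difference dipole towards the positive charge:
  # stabilization (negative shift)
  dq <- data.frame(x = c(0, 0), y = c(0, 0), z = c(-0.5, 0.5),
                   q = c(0.1, -0.1))
  expect_lt(site_energy_shift(dq, env), 0)
  # linear in the environment charge when nothing is polarizable
  s1 <- site_energy_shift(dq, env)
  env2 <- env; env2$q <- 2 * env2$q
  expect_equal(site_energy_shift(dq, env2), 2 * s1, tolerance = 1e-12)
})

test_that("response correction matches hand-contracted tensors and is reciprocal", {
  tqA <- data.frame(x = c(-0.5, 0.5), y = 0, z = 0, q = c(0.4, -0.4))
  tqB <- data.frame(x = c(-0.5, 0.5), y = 0, z = 12, q = c(0.4, -0.4))
  env <- environment_sites(0, 0, 6, q = 0.2, alpha = 1.2)
  dv <- response_coupling_correction(tqA, tqB, env, unit = "hartree")
  # independent tensor arithmetic: mu = alpha * sum_t q_t T1(site - t),
  # dV = -sum_t' q_t' mu . T1(site -> t')
  s <- c(0, 0, 6)
  mu <- 1.2 * colSums(tqA$q * t(apply(tqA, 1, function(r) {
    R <- s - as.numeric(r[c("x", "y", "z")])
    R / sqrt(sum(R^2))^3
  })))
  hand <- -sum(vapply(seq_len(2), function(t) {
    R <- as.numeric(tqB[t, c("x", "y", "z")]) - s
    tqB$q[t] * sum(mu * R / sqrt(sum(R^2))^3)
  }, numeric(1)))
  expect_equal(dv, hand, tolerance = 1e-12)
  # zero polarizability: no correction
  env0 <- env; env0$alpha <- 0
  expect_equal(response_coupling_correction(tqA, tqB, env0), 0)
  # reciprocity
  expect_equal(response_coupling_correction(tqB, tqA, env, unit = "hartree"),
               dv, tolerance = 1e-10)
})

test_that("environment quantities are invariant under rigid motion of env plus sources", {
  th <- 0.9
  Rm <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  shift <- c(-1, 4, 2)
  env <- environment_sites(c(0, 5), c(1, -2), c(8, 3), q = c(0.3, -0.1),
                           alpha = c(1, 0.7))
  dq <- data.frame(x = c(0, 1), y = c(0, 0.5), z = c(-1, 0),
                   q = c(0.2, -0.2))
  s1 <- site_energy_shift(dq, env, unit = "hartree")
  rot <- function(df) {
    p <- sweep(as.matrix(df[, c("x", "y", "z")]) %*% t(Rm), 2, -shift)
    df$x <- p[, 1]; df$y <- p[, 2]; df$z <- p[, 3]; df
  }
  env2 <- rot(env)
  class(env2) <- class(env)
  expect_equal(site_energy_shift(rot(dq), env2, unit = "hartree"), s1,
               tolerance = 1e-10)
})
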