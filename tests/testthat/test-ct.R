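# CT energetics: two-state Marcus relations, the weak-coupling criterion,
# the charged-pair interaction energy and its long-range limit, and the
# assembled CT state energies.

test_that("Marcus coupling and adiabatic gap reproduce hand-evaluated cases", {
  expect_equal(marcus_coupling(3, -7, 0, 0), 0)
  expect_equal(marcus_coupling(-10, -9, 0.1, 0.1), (0.1 + 0.95) / 0.99,
               tolerance = 1e-12)
  expect_equal(marcus_coupling(1, 2, 0.3, 0), 0.3)   # orthogonal limit
  expect_equal(adiabatic_gap(0, 1, 0, 0), 1)
  expect_equal(adiabatic_gap(0, 0, 0, 0.05), 0.1)    # symmetric: 2|V|
  expect_equal(adiabatic_gap(0, 1, 0.1, 0.05), sqrt(1 / 0.99 + 0.01),
               tolerance = 1e-12)
  expect_error(marcus_coupling(0, 1, 0, 1), class = "diabex_overlap_domain")
  expect_error(adiabatic_gap(0, 1, 1.2, 0), class = "diabex_overlap_domain")
})

test_that("the diabatic gap approximation converges quadratically in V/gap", {
  for (v_over_gap in 10^seq(-4, -1, by = 0.5)) {
    gap <- 1; V <- v_over_gap; S <- v_over_gap   # overlap of coupling order
    exact <- adiabatic_gap(0, gap, S, V)
    rel <- abs(exact - diabatic_ct_energy(0, gap, V)$value) / gap
    expect_lt(rel, v_over_gap^2 * 10)
  }
  expect_true(diabatic_ct_energy(0, 1, 0.001)$weak_coupling)
  expect_false(diabatic_ct_energy(0, 0.01, 0.05)$weak_coupling)
  expect_false(diabatic_ct_energy(0, 0, 0.01)$weak_coupling)
})

test_that("interaction energy recovers Coulomb's law and the -1/R limit", {
  plus <- data.frame(x = 0, y = 0, z = 0, Z = 1, p = 0, zeta = Inf)
  minus <- data.frame(x = 0, y = 0, z = 5, Z = 0, p = 1, zeta = Inf)
  expect_equal(interaction_energy(plus, minus)$total, -0.2)
  # toy ion pair at long range: R * E_int -> -1
  d <- build_dimer(compact_fragment("A"), compact_fragment("B"),
                   c(0, 0, 50))
  e <- interaction_energy(charge_clouds(d$fragA, "cation"),
                          charge_clouds(d$fragB, "anion"))$total
  expect_lt(abs(50 * e + 1), 1e-4)
  # neutral pair: no monopole term survives
  en <- interaction_energy(charge_clouds(d$fragA), charge_clouds(d$fragB))
  expect_lt(abs(en$total), 1e-6)
  expect_identical(en$components[["nonadditive"]], 0)
  expect_error(interaction_energy(plus, plus), class = "diabex_singularity")
})

test_that("E_int * R tends to the product of net charges for any charge state", {
  fa <- toy_chla_fragment("A"); fb <- toy_chla_fragment("B")
  d <- build_dimer(fa, fb, c(0, 0, 200))
  for (pair in list(c("cation", "anion"), c("cation", "cation"),
                    c("anion", "anion"))) {
    q <- prod(ifelse(pair == "cation", 1, -1))
    e <- interaction_energy(charge_clouds(d$fragA, pair[1]),
                            charge_clouds(d$fragB, pair[2]))$total
    expect_equal(200 * e, q, tolerance = 1e-3)
  }
})

test_that("CT state energies are degenerate for a symmetric dimer and split by an asymmetric environment", {
  d <- build_dimer(toy_chla_fragment("A"), toy_chla_fragment("B"),
                   displacement = c(0, 0, 7))   # mirror-symmetric stacking
  ct <- ct_state_energies(d)
  expect_equal(ct$E_CT[["CT1"]], ct$E_CT[["CT2"]], tolerance = 1e-10)
  expect_equal(ct$E_CT,
               rowSums(ct$components)[names(ct$E_CT)], tolerance = 1e-12)
  # a charge near fragment A only breaks the degeneracy
  env <- environment_sites(x = 3, y = 0, z = -4, q = 0.5, alpha = 0.8)
  ct_env <- ct_state_energies(d, env = env)
  expect_gt(abs(ct_env$E_CT[["CT1"]] - ct_env$E_CT[["CT2"]]), 1e-4)
})

test_that("CT energies decrease monotonically as the fragments approach", {
  Rs <- c(14, 11, 9, 7.5, 6.5)
  e1 <- vapply(Rs, function(R)
    ct_state_energies(toy_dimer(R = R))$E_CT[["CT1"]], numeric(1))
  expect_true(all(diff(e1) < 0))
})

test_that("CT energetics are invariant under rigid motion of the whole system", {
  th <- 0.5
  Rm <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  shift <- c(3, -2, 5)
  fa <- toy_chla_fragment("A"); fb <- toy_chla_fragment("B")
  disp <- c(1, 0.7, 6.5)
  env <- environment_sites(x = c(4, -3), y = c(1, 2), z = c(-3, 9),
                           q = c(0.3, -0.2), alpha = c(1, 0.5))
  d1 <- build_dimer(fa, fb, disp)
  fa2 <- transform_fragment(fa, shift = shift, rotation = Rm)
  p_env <- cbind(env$x, env$y, env$z) %*% t(Rm)
  env2 <- environment_sites(p_env[, 1] + shift[1], p_env[, 2] + shift[2],
                            p_env[, 3] + shift[3], q = env$q,
                            alpha = env$alpha)
  ct1 <- ct_state_energies(d1, env = env)
  # build the transformed dimer directly from transformed fragments
  fb_rot <- transform_fragment(fb, rotation = Rm)
  d2 <- build_dimer(fa2, fb_rot,
                    displacement = as.numeric(Rm %*% disp) + shift)
  ct2 <- ct_state_energies(d2, env = env2)
  expect_equal(ct1$E_CT, ct2$E_CT, tolerance = 1e-8)
})
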