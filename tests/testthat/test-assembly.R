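# Diabatic model assembly and the generalized eigensolver: block placement,
# metric handling, Lowdin characters, level repulsion, ensemble shift.

mean_values <- function(set = "first") {
  ref <- chla_dimer_reference()
  stats::setNames(ref[[paste0("mean_", set)]], ref$label)
}

test_that("assembly places blocks correctly and zeroes the CT1-CT2 coupling", {
  model <- snapshot_model(mean_values("first"))
  expect_equal(model$labels, c("Qy1", "Qx1", "Qy2", "Qx2", "CT1", "CT2"))
  expect_lt(max(abs(model$H - t(model$H))), 1e-12)
  expect_identical(model$H["CT1", "CT2"], 0)
  expect_identical(model$S["CT1", "CT2"], 0)
  expect_equal(diag(model$S), rep(1, 6), ignore_attr = TRUE)
  expect_equal(model$H["Qy1", "Qy2"], 0.021)
  expect_equal(model$H["Qy1", "CT2"], 0.019)
  expect_equal(model$H["Qx1", "CT1"], 0)   # orthogonal holes
  expect_error(
    assemble_diabatic(site_energies(2, 2.2, 2, 2.2),
                      le_coupling = list(VQy = 0.02),
                      ct = c(CT1 = 2.7, CT2 = 3.2),
                      lect = matrix(0, 4, 2)),
    class = "diabex_assembly")
})

test_that("LE-CT overlap entries follow the determinant-overlap products", {
  d <- toy_dimer(R = 6.5)
  ov <- compute_overlaps(d)
  model <- assemble_diabatic(
    toy_site_energies(d),
    le_coupling = list(VQy = 0.01, VQx = 0.005),
    ct = ct_state_energies(d),
    lect = all_le_ct_couplings(d, unit = "eV"),
    overlaps = ov)
  f <- ov$frontier
  expect_equal(model$S["Qy1", "CT1"], ov$S[f$LA, f$LB - 4])
  expect_equal(model$S["Qy1", "CT2"], ov$S[f$HA, f$HB - 4])
  expect_equal(model$S["Qx1", "CT1"], 0)
  expect_true(all(eigen(model$S, only.values = TRUE)$values > 0))
})

test_that("diagonal model returns the sorted diagonal and pure characters", {
  vals <- mean_values("first")
  vals[grep("^V_", names(vals))] <- 0
  sol <- solve_snapshot(vals)
  expect_equal(sol$energies, sort(c(2.02, 2.27, 2.01, 2.26, 2.77, 3.28)))
  # each adiabatic state sits fully on one diabatic label
  expect_equal(apply(sol$weights, 2, max), rep(1, 6), tolerance = 1e-12)
  expect_equal(colSums(sol$weights), rep(1, 6), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("two-state resonance splits to +-V with half/half weights", {
  H <- matrix(c(0, 0.05, 0.05, 0), 2, 2)
  ge <- solve_generalized(H, diag(2))
  expect_equal(ge$values, c(-0.05, 0.05))
  w <- (ge$vectors)^2
  expect_equal(as.numeric(w), rep(0.5, 4), tolerance = 1e-12)
})

test_that("Cholesky path matches the independent S^(-1/2) oracle on random SPD metrics", {
  set.seed(21)
  for (rep in 1:5) {
    H <- matrix(stats::rnorm(36), 6, 6); H <- (H + t(H)) / 2
    S <- random_spd(6)
    ge <- solve_generalized(H, S)
    or <- geigen_sqrt(H, S)
    expect_equal(ge$values, or$values, tolerance = 1e-10)
    # eigenvectors are S-orthonormal
    expect_lt(max(abs(crossprod(ge$vectors, S %*% ge$vectors) - diag(6))),
              1e-10)
  }
})

test_that("Lowdin weights sum to one and reduce to squared coefficients for S = I", {
  sol <- solve_snapshot(mean_values("last"))
  expect_equal(colSums(sol$weights), rep(1, 6), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sol$weights, sol$coeffs^2, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sol$le_fraction + sol$ct_fraction, rep(1, 6),
               tolerance = 1e-12)
  # Mulliken scheme coincides for an identity metric
  model <- snapshot_model(mean_values("last"))
  solm <- solve_diabatic(model, scheme = "mulliken")
  expect_equal(solm$weights, sol$weights, tolerance = 1e-12)
})

test_that("eigenvalues are invariant under a simultaneous label permutation", {
  model <- snapshot_model(mean_values("last"))
  p <- c(3, 1, 6, 2, 5, 4)
  perm <- model
  perm$H <- model$H[p, p]; perm$S <- model$S[p, p]
  perm$labels <- model$labels[p]
  expect_equal(solve_diabatic(perm)$energies, solve_diabatic(model)$energies,
               tolerance = 1e-12)
})

test_that("increasing the lowest LE-CT coupling never raises the lowest state", {
  vals <- mean_values("last")
  lows <- vapply(seq(0, 0.3, by = 0.03), function(v) {
    vals["V_QyB_CT1"] <- v   # couples Qy2 (lowest LE) to CT1
    solve_snapshot(vals)$energies[1]
  }, numeric(1))
  expect_true(all(diff(lows) <= 1e-12))
})

test_that("with remote CT states the low spectrum approaches the LE-only block", {
  vals <- mean_values("first")
  vals[c("CT1", "CT2")] <- 10            # far above the LE band
  v_over_gap <- max(vals[grep("_CT", names(vals))]) / (10 - 2.3)
  sol <- solve_snapshot(vals)
  le_only <- vals; le_only[grep("_CT", names(le_only))] <- 0
  sol0 <- solve_snapshot(le_only)
  rel <- abs(sol$energies[1:4] - sol0$energies[1:4]) / sol0$energies[1:4]
  expect_true(all(rel < v_over_gap^2 * 10))
})

test_that("metric errors and near-singular fallback are reported", {
  model <- snapshot_model(mean_values("first"))
  model$S["Qy1", "CT1"] <- model$S["CT1", "Qy1"] <- 1.2
  expect_error(solve_diabatic(model), class = "diabex_metric")
  # exactly dependent diabats trigger the canonical-orthogonalization warning
  S <- diag(6); S[1, 5] <- S[5, 1] <- 1
  expect_warning(solve_generalized(diag(6), S), "near-singular")
})

test_that("lowest-state shift compares ensembles with the red-shift sign convention", {
  expect_equal(lowest_state_shift(c(2.0, 2.1), c(2.0, 2.1)), 0)
  vals <- mean_values("first")
  vals[grep("^V_", names(vals))] <- 0
  shifted <- vals
  shifted[c("Qy1", "Qy2", "Qx1", "Qx2", "CT1", "CT2")] <-
    shifted[c("Qy1", "Qy2", "Qx1", "Qx2", "CT1", "CT2")] - 0.05
  a <- list(solve_snapshot(vals)); b <- list(solve_snapshot(shifted))
  expect_equal(lowest_state_shift(a, b), -0.05, tolerance = 1e-12)
  expect_error(lowest_state_shift(list(), a), class = "diabex_input")
})
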