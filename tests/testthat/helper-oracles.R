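# Independent oracles and fixture builders used across the suite. Everything
# here is deliberately written as plain brute-force code, separate from the
# package's implementation paths.

# midpoint-rule 3-D grid integral of f(x, y, z) over a box
grid_integral <- function(f, lo, hi, h = 0.2) {
  xs <- seq(lo[1] + h / 2, hi[1], by = h)
  ys <- seq(lo[2] + h / 2, hi[2], by = h)
  zs <- seq(lo[3] + h / 2, hi[3], by = h)
  g <- expand.grid(x = xs, y = ys, z = zs)
  sum(f(g$x, g$y, g$z)) * h^3
}

sto_1s <- function(zeta, x, y, z, cx = 0, cy = 0, cz = 0) {
  r <- sqrt((x - cx)^2 + (y - cy)^2 + (z - cz)^2)
  sqrt(zeta^3 / pi) * exp(-zeta * r)
}

# Monte-Carlo two-cloud Coulomb integral; radial distance of a 1s^2 density
# is Gamma(shape = 3, rate = 2 zeta)
mc_coulomb <- function(zeta1, zeta2, R, n = 1e7, seed = 42) {
  set.seed(seed)
  total <- 0
  chunk <- 1e6
  done <- 0
  sample_cloud <- function(m, zeta, zoff) {
    r <- stats::rgamma(m, shape = 3, rate = 2 * zeta)
    u <- stats::runif(m, -1, 1)
    phi <- stats::runif(m, 0, 2 * pi)
    s <- sqrt(1 - u^2)
    cbind(r * s * cos(phi), r * s * sin(phi), r * u + zoff)
  }
  while (done < n) {
    m <- min(chunk, n - done)
    p1 <- sample_cloud(m, zeta1, 0)
    p2 <- sample_cloud(m, zeta2, R)
    total <- total + sum(1 / sqrt(rowSums((p1 - p2)^2)))
    done <- done + m
  }
  total / n
}

# term-by-term re-implementation of the eight LE-CT coupling formulas,
# using explicit loops and direct matrix indexing
naive_v_le_ct <- function(ov, le, ct) {
  occ <- seq_len(ov$n_occ)
  vir <- setdiff(seq_along(ov$energies), occ)
  eps <- ov$energies; Sp <- ov$Sp; f <- ov$frontier
  Sfun <- function(i, j) {      # union-index overlap, i on A, j on B
    if (i <= ov$n_A) ov$S[i, j - ov$n_A] else ov$S[j, i - ov$n_A]
  }
  acc <- function(idx, expr) { s <- 0; for (k in idx) s <- s + expr(k); s }
  key <- paste(le, ct)
  switch(key,
    "QyA CT1" = acc(vir, function(a) eps[a] * Sp[a, f$LA] * Sp[a, f$LB]) -
      acc(occ, function(i) eps[i] * Sp[i, f$HA]^2) * Sfun(f$LA, f$LB),
    "QxA CT1" = -acc(occ, function(i)
      eps[i] * Sp[i, f$HpA] * Sp[i, f$HA]) * Sfun(f$LA, f$LB),
    "QyA CT2" = -acc(occ, function(i) eps[i] * Sp[i, f$HA] * Sp[i, f$HB]) +
      acc(vir, function(a) eps[a] * Sp[a, f$LA]^2) * Sfun(f$HA, f$HB),
    "QxA CT2" = -acc(occ, function(i) eps[i] * Sp[i, f$HpA] * Sp[i, f$HB]) +
      acc(vir, function(a) eps[a] * Sp[a, f$LA]^2) * Sfun(f$HpA, f$HB),
    "QyB CT2" = acc(vir, function(a) eps[a] * Sp[a, f$LB] * Sp[a, f$LA]) -
      acc(occ, function(i) eps[i] * Sp[i, f$HB]^2) * Sfun(f$LA, f$LB),
    "QxB CT2" = -acc(occ, function(i)
      eps[i] * Sp[i, f$HpB] * Sp[i, f$HB]) * Sfun(f$LA, f$LB),
    "QyB CT1" = -acc(occ, function(i) eps[i] * Sp[i, f$HB] * Sp[i, f$HA]) +
      acc(vir, function(a) eps[a] * Sp[a, f$LB]^2) * Sfun(f$HA, f$HB),
    "QxB CT1" = -acc(occ, function(i) eps[i] * Sp[i, f$HpB] * Sp[i, f$HA]) +
      acc(vir, function(a) eps[a] * Sp[a, f$LB]^2) * Sfun(f$HpB, f$HA),
    stop("unknown pair"))
}

# random OverlapSet over 3 + 3 orbitals (2 occupied + 1 virtual per fragment)
random_overlap_set <- function() {
  nsup <- 6
  Sp <- matrix(stats::runif(nsup * 6, -0.3, 0.3), nsup, 6)
  S <- matrix(stats::runif(9, -0.1, 0.1), 3, 3)
  eps <- sort(stats::rnorm(nsup, -0.2, 0.2))
  overlap_set(S = S, Sp = Sp, energies = eps, n_occ = 4,
              frontier = list(HpA = 1, HA = 2, LA = 3,
                              HpB = 4, HB = 5, LB = 6),
              n_A = 3)
}

# generalized eigensolve through the symmetric S^(-1/2) transformation
geigen_sqrt <- function(H, S) {
  se <- eigen(S, symmetric = TRUE)
  Sih <- se$vectors %*% ((1 / sqrt(se$values)) * t(se$vectors))
  e <- eigen(Sih %*% H %*% Sih, symmetric = TRUE)
  list(values = sort(e$values), vectors = Sih %*% e$vectors)
}

random_spd <- function(n) {
  A <- matrix(stats::rnorm(n * n, sd = 0.1), n, n)
  diag(n) + crossprod(A)
}

# Jacobi-style fixed-point iteration for the induced dipoles (no damping)
fixed_point_dipoles <- function(env, field, n_iter = 50) {
  n <- nrow(env)
  pos <- as.matrix(env[, c("x", "y", "z")])
  mu <- matrix(0, n, 3)
  for (it in seq_len(n_iter)) {
    new <- matrix(0, n, 3)
    for (s in seq_len(n)) {
      if (env$alpha[s] == 0) next
      Es <- field[s, ]
      for (t in seq_len(n)) {
        if (t == s || env$alpha[t] == 0) next
        Es <- Es + as.numeric(interaction_tensor(pos[s, ], pos[t, ], 2) %*%
                                mu[t, ])
      }
      new[s, ] <- env$alpha[s] * Es
    }
    mu <- new
  }
  mu
}

# default toy dimer used in several files; lateral offset keeps the
# geometry generic (no accidental symmetry)
toy_dimer <- function(R = 6.5, overlap_scale = 1, lateral = c(1.0, 0.7)) {
  build_dimer(toy_chla_fragment("A"), toy_chla_fragment("B"),
              displacement = c(lateral, R), overlap_scale = overlap_scale)
}

# compact single-site fragment (two s functions on one centre, 2 electrons):
# its ions are pure monopoles, ideal for long-range interaction checks
compact_fragment <- function(label) {
  toy_fragment(label,
               sites = data.frame(tag = "X", x = 0, y = 0, z = 0, charge = 2),
               basis = data.frame(site = c(1, 1), zeta = c(1, 2)),
               n_occ = 1)
}

# reference means as a one-record snapshot table per frame set
reference_table <- function(set = "first") {
  ref <- chla_dimer_reference()
  snapshot_table(
    data.frame(snapshot = "mean", label = ref$label,
               value_eV = ref[[paste0("mean_", set)]],
               provenance = "environment"),
    set_label = if (set == "first") "First50" else "Last50")
}
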