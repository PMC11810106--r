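test_that("superposition removes rigid motion and is idempotent", {
  st <- make_pam_structure()
  nf <- 8L
  coords <- array(NA_real_, c(nf, nrow(st$atoms), 3L))
  set.seed(12)
  for (f in seq_len(nf)) {
    R <- rotation_matrix(rnorm(3), runif(1, 0, pi))
    shift <- rnorm(3)
    coords[f, , ] <- sweep(st$xyz %*% t(R), 2L, shift, `+`)
  }
  traj <- trajectory_new(st, coords)
  grp <- atom_group(st$atoms$index, "all")
  fitted <- superpose_series(traj, grp)
  for (f in seq_len(nf)) {
    expect_lt(max(abs(fitted$coords[f, , ] - fitted$coords[1, , ])), 1e-9)
  }
  again <- superpose_series(fitted, grp)
  expect_equal(again$coords, fitted$coords, tolerance = 1e-9)
})

test_that("fitted frames agree with an independent quaternion superposition", {
  st <- make_pam_structure()
  traj <- make_wiggle_trajectory(st, n_frames = 6L, sd = 0.05)
  grp <- atom_group(st$atoms$index, "all")
  fitted <- superpose_series(traj, grp)
  m <- st$atoms$mass
  ref <- traj$coords[1, , ]
  for (f in 2:6) {
    rmsd_pkg <- sqrt(sum((m / sum(m)) *
                           rowSums((fitted$coords[f, , ] - ref)^2)))
    rmsd_q <- quaternion_rmsd(ref, traj$coords[f, , ], m)
    expect_equal(rmsd_pkg, rmsd_q, tolerance = 1e-9)
  }
})

test_that("RMSF matches the isotropic Gaussian closed form", {
  spec <- harmonic_ensemble_spec(masses = 12, covariance = diag(0.01, 3),
                                 n_frames = 20000L, seed = 31L)
  traj <- gen_harmonic_ensemble(spec)
  prof <- rmsf(traj, atom_group(0, "atom"))
  expect_equal(prof$rmsf_A[1], sqrt(3) * 0.1 * 10, tolerance = 0.02)

  ## static structure
  st <- make_pam_structure()
  static <- trajectory_new(st, array(rep(st$xyz, each = 5),
                                     c(5, nrow(st$atoms), 3)))
  p0 <- rmsf(static, atom_group(st$atoms$index, "all"))
  expect_true(all(p0$rmsf_A < 1e-12))

  ## invariance under a global rotation of every frame
  R <- rotation_matrix(c(0, 0, 1), 0.8)
  rot <- traj
  for (f in seq_len(n_frames(traj))) {
    rot$coords[f, , ] <- matrix(traj$coords[f, , ], ncol = 3) %*% t(R)
  }
  p1 <- rmsf(rot, atom_group(0, "atom"))
  expect_equal(p1$rmsf_A, prof$rmsf_A, tolerance = 1e-9)
})

test_that("fluctuation covariance recovers the prescribed matrix", {
  Sigma <- matrix(c(0.02, 0.005, 0, 0.005, 0.01, 0, 0, 0, 0.005), 3, 3)
  spec <- harmonic_ensemble_spec(masses = 10, covariance = Sigma,
                                 n_frames = 40000L, seed = 41L)
  traj <- gen_harmonic_ensemble(spec)
  C <- fluctuation_covariance(traj, atom_group(0, "atom"),
                              mass_weighted = FALSE)
  expect_lt(max(abs(C - Sigma)), 0.05 * max(Sigma))
  expect_equal(C, t(C), tolerance = 1e-14, ignore_attr = TRUE)
  Cm <- fluctuation_covariance(traj, atom_group(0, "atom"))
  expect_equal(Cm, 10 * C, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("superposition empties the rigid-body modes of the covariance", {
  ## small fluctuations around a 4-atom frame: after fitting on the group
  ## itself, the 6 rigid-body modes collapse to (near) zero eigenvalues
  atoms <- data.frame(name = paste0("C", 1:4), resid = 1L, resname = "RES",
                      chain = "A", element = "C", mass = 12)
  base <- matrix(c(0, 0, 0, 0.3, 0, 0, 0, 0.3, 0, 0, 0, 0.3), 4, 3,
                 byrow = TRUE)
  st <- structure_new(atoms, base)
  traj <- make_wiggle_trajectory(st, n_frames = 3000L, sd = 0.003, seed = 6L)
  grp <- atom_group(st$atoms$index, "all")
  fitted <- superpose_series(traj, grp)
  C <- fluctuation_covariance(fitted, grp)
  ev <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(ev[6], 1e-3 * ev[12])   # rank <= 3A - 6 up to linearization
  expect_lt(ev[3], 1e-10 * ev[12])  # translations removed exactly
})

test_that("quasi-harmonic entropy matches the closed form and its limits", {
  hbar <- 1.054571817e-34; kB <- 1.380649e-23; Rgas <- 8.31446261815324
  Temp <- 300
  ## eigenvalue chosen so hbar*omega/kBT = 1, in amu nm^2
  lam1 <- hbar^2 / (kB * Temp) / (1.66053906660e-27 * 1e-18)
  res <- quasiharmonic_entropy(matrix(lam1, 1, 1), Temp)
  expect_equal(res$S, Rgas * (1 / (exp(1) - 1) - log(1 - exp(-1))),
               tolerance = 1e-10)
  expect_equal(res$n_modes_used, 1L)

  ## stiff (frozen) mode contributes nothing
  stiff <- quasiharmonic_entropy(matrix(lam1 * 1e-6, 1, 1), Temp)
  expect_lt(stiff$S, 1e-3)

  ## monotone non-decreasing in each eigenvalue
  s_lo <- quasiharmonic_entropy(diag(c(lam1, 2 * lam1)), Temp)$S
  s_hi <- quasiharmonic_entropy(diag(c(3 * lam1, 2 * lam1)), Temp)$S
  expect_gt(s_hi, s_lo)

  ## invariant under orthogonal transformation of the coordinates
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  Cdiag <- diag(c(lam1, 2 * lam1, 5 * lam1))
  s1 <- quasiharmonic_entropy(Cdiag, Temp)$S
  s2 <- quasiharmonic_entropy(Q %*% Cdiag %*% t(Q), Temp)$S
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("ensemble entropy converges to the prescribed-spectrum value", {
  hbar <- 1.054571817e-34; kB <- 1.380649e-23
  Temp <- 300
  lam1 <- hbar^2 / (kB * Temp) / (1.66053906660e-27 * 1e-18)
  mass <- 12
  Sigma <- diag(c(1, 4, 9)) * lam1 / mass   # positional, nm^2
  spec <- harmonic_ensemble_spec(masses = mass, covariance = Sigma,
                                 n_frames = 30000L, temperature = Temp,
                                 seed = 51L)
  traj <- gen_harmonic_ensemble(spec)
  C <- fluctuation_covariance(traj, atom_group(0, "atom"))
  s_est <- quasiharmonic_entropy(C, Temp)$S
  s_true <- quasiharmonic_entropy(Sigma * mass, Temp)$S
  expect_lt(abs(s_est - s_true) / s_true, 0.03)
})

test_that("entropy differences are plain bookkeeping on S values", {
  expect_equal(entropy_difference(320.01, 103.18), 216.83, tolerance = 1e-9)
  a <- quasiharmonic_entropy(diag(1e-3, 3), 310)
  b <- quasiharmonic_entropy(diag(2e-3, 3), 310)
  expect_equal(entropy_difference(b, a), b$S - a$S)
})
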