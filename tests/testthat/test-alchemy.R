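test_that("reduced-potential matrices validate their shape", {
  u <- matrix(rnorm(20), 2, 10)
  expect_error(reduced_potentials(u, c(4, 4)), "samples")
  rpm <- reduced_potentials(u, c(4, 6))
  expect_identical(rpm$source, rep(1:2, c(4L, 6L)))
  expect_error(reduced_potentials(matrix(c(1, Inf), 1, 2), 2), "finite")
})

test_that("MBAR returns zeros for identical states and obeys antisymmetry", {
  set.seed(1)
  x <- rnorm(300)
  u <- rbind(0.5 * x^2, 0.5 * x^2, 0.5 * x^2)
  res <- mbar_free_energies(reduced_potentials(u, c(100, 100, 100)))
  expect_lt(max(abs(res$dg_kT)), 1e-10)

  g <- gen_alchemical_harmonics(c(1, 4), n_per_state = 2000, seed = 2L)
  fwd <- mbar_free_energies(g$u)
  rev_rpm <- reduced_potentials(g$u$u[2:1, ], g$u$N_k[2:1],
                                c(2L, 1L)[g$u$source])
  rev <- mbar_free_energies(rev_rpm)
  expect_equal(fwd$dg_kT[2], -rev$dg_kT[2], tolerance = 1e-9)
})

test_that("MBAR recovers harmonic closed forms within its own error bars", {
  g <- gen_alchemical_harmonics(c(1, 4), n_per_state = 2000, seed = 8L)
  res <- mbar_free_energies(g$u, temperature = 300)
  expect_lt(abs(res$dg_kT[2] - 0.5 * log(4)), 3 * res$se_kT[2])
  expect_gt(res$se_kT[2], 0)
  expect_equal(res$dg_kcal[2], res$dg_kT[2] * 0.0019872041 * 300)

  ## three-state path additivity is exact for one joint solve
  g3 <- gen_alchemical_harmonics(c(1, 4, 16), n_per_state = 500, seed = 9L)
  r3 <- mbar_free_energies(g3$u)
  expect_equal(r3$dg_kT[3],
               (r3$dg_kT[2] - r3$dg_kT[1]) + (r3$dg_kT[3] - r3$dg_kT[2]),
               tolerance = 1e-12)
})

test_that("MBAR reduces to BAR for two states", {
  g <- gen_alchemical_harmonics(c(1, 9), n_per_state = 800, seed = 14L)
  res <- mbar_free_energies(g$u, tolerance = 1e-12)
  bar <- bar_uniroot(g$u$u, g$u$N_k)
  expect_equal(res$dg_kT[2], bar, tolerance = 1e-8)
})

test_that("exchange acceptance matches Metropolis limits and Monte Carlo", {
  set.seed(6)
  x <- rnorm(400)
  same <- reduced_potentials(rbind(0.5 * x^2, 0.5 * x^2), c(200, 200))
  expect_equal(exchange_acceptance(same)$acceptance, 1)

  far <- gen_alchemical_harmonics(c(1, 1e6), n_per_state = 200, seed = 3L)
  expect_lt(exchange_acceptance(far$u)$acceptance, 0.02)

  ## brute-force Metropolis simulation agrees with the analytic mean
  g <- gen_alchemical_harmonics(c(1, 5), n_per_state = 400, seed = 4L)
  acc <- exchange_acceptance(g$u)$acceptance
  si <- which(g$u$source == 1)[1:400]
  sj <- which(g$u$source == 2)[1:400]
  delta <- (g$u$u[2, si] - g$u$u[1, si]) + (g$u$u[1, sj] - g$u$u[2, sj])
  set.seed(99)
  reps <- 200
  sim_acc <- mean(vapply(seq_len(reps), function(r)
    mean(runif(length(delta)) < exp(-delta)), numeric(1)))
  se <- sqrt(acc * (1 - acc) / (reps * length(delta)))
  expect_lt(abs(sim_acc - acc), 4 * se + 1e-3)
})

test_that("schedule optimizer finds the symmetric midpoint", {
  k_of <- function(l) exp(4 * l)
  u_fun <- function(l, x) 0.5 * k_of(l) * x^2
  pl <- seq(0, 1, length.out = 41)
  set.seed(10)
  ps <- lapply(pl, function(l) rnorm(3000, 0, sqrt(1 / k_of(l))))
  pilot <- alchemical_pilot(u_fun, pl, ps)
  sched <- optimize_lambda_schedule(pilot, 3, target_acceptance = 0.10)
  expect_equal(sched$values[2], 0.5, tolerance = 0.03)
  expect_equal(sched$values[c(1, 3)], c(0, 1))
})

test_that("optimizer improves a steep-then-flat system over uniform spacing", {
  ## all the lambda-dependence is compressed into [0, 0.2]
  k_of <- function(l) exp(46 * pmin(l, 0.2))
  u_fun <- function(l, x) 0.5 * k_of(l) * x^2
  pl <- seq(0, 1, length.out = 81)
  set.seed(20)
  ps <- lapply(pl, function(l) rnorm(2000, 0, sqrt(1 / k_of(l))))
  pilot <- alchemical_pilot(u_fun, pl, ps)
  n_win <- 8L
  sched <- optimize_lambda_schedule(pilot, n_win, target_acceptance = 0.10)
  unif_acc <- vapply(seq_len(n_win - 1L), function(i)
    pamscope:::.pilot_acceptance(pilot, (i - 1) / (n_win - 1),
                                 i / (n_win - 1)), numeric(1))
  expect_gte(sched$min_acceptance, min(unif_acc))
  expect_gte(sched$min_acceptance, 0.10)
  expect_true(all(diff(sched$values) > 0))
})

test_that("unreachable acceptance targets advise more windows", {
  k_of <- function(l) exp(40 * l)
  u_fun <- function(l, x) 0.5 * k_of(l) * x^2
  pl <- seq(0, 1, length.out = 21)
  set.seed(30)
  ps <- lapply(pl, function(l) rnorm(500, 0, sqrt(1 / k_of(l))))
  pilot <- alchemical_pilot(u_fun, pl, ps)
  expect_error(optimize_lambda_schedule(pilot, 2, target_acceptance = 0.5),
               "n_windows")
})

test_that("thermodynamic cycle combines legs with quadrature errors", {
  r <- thermodynamic_cycle(2, -3)
  expect_equal(r$ddg, -5)
  expect_equal(r$err, 0)
  expect_equal(thermodynamic_cycle(1.7, 1.7)$ddg, 0)
  expect_equal(thermodynamic_cycle(0, 0, 0.3, 0.4)$err, 0.5, tolerance = 1e-12)
})

test_that("enthalpic decomposition is exact on constants and partitions totals", {
  g0 <- list(r1 = rep(-50, 100), r2 = rep(-20, 100))
  g1 <- list(r1 = rep(-65, 100), r2 = rep(-20, 100))
  dec <- interaction_energy_decomposition(g0, g1)
  expect_equal(dec$delta_e, c(-15, 0))
  expect_equal(dec$se, c(0, 0))

  set.seed(44)
  t0 <- g0$r1 + g0$r2 + rnorm(100, -30)
  t1 <- g1$r1 + g1$r2 + rnorm(100, -10)
  dec2 <- interaction_energy_decomposition(g0, g1, t0, t1)
  expect_equal(sum(dec2$delta_e), unname(attr(dec2, "total")["delta_e"]),
               tolerance = 1e-6)
  expect_error(interaction_energy_decomposition(
    list(a = 1:3), list(a = 1:3), n_blocks = 5L), "blocks")
})

test_that("block-average errors agree with the i.i.d. closed form on average", {
  ## E[se] over repetitions ~ c4(5) * sigma/sqrt(n) per end state
  sigma <- 2; n <- 2000
  set.seed(55)
  ses <- vapply(1:150, function(r) {
    dec <- interaction_energy_decomposition(
      list(g = rnorm(n, 0, sigma)), list(g = rep(0, n)),
      discard_fraction = 0)
    dec$se[1]
  }, numeric(1))
  analytic <- sigma / sqrt(n)   # sd(block means)/sqrt(5) = sigma/sqrt(n)
  expect_lt(abs(mean(ses) - analytic) / analytic, 0.2)
})

test_that("u-matrix TSV round-trips", {
  g <- gen_alchemical_harmonics(c(1, 2, 4), n_per_state = 20, seed = 61L)
  f <- tempfile(fileext = ".tsv")
  write_reduced_potentials(g$u, f)
  back <- read_reduced_potentials(f)
  expect_equal(back$u, g$u$u, tolerance = 1e-10, ignore_attr = TRUE)
  expect_identical(back$N_k, g$u$N_k)
  expect_identical(back$source, g$u$source)
})
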