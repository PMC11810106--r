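test_that("bias potential sums recorded Gaussians exactly", {
  params <- metad_params()  # omega 1 kJ/mol/ps, t_G 10 ps -> nominal 10 kJ/mol
  empty <- hill_records(numeric(0), matrix(numeric(0), 0, 1), 0.05,
                        numeric(0), 4)
  expect_equal(bias_potential(empty, c(0.5, 0.9)), c(0, 0))

  one <- hill_records(10, matrix(0.6), 0.05, params$omega * params$t_G, 4)
  expect_equal(bias_potential(one, 0.6), 10)
  expect_equal(bias_potential(one, 0.65), 10 * exp(-0.5), tolerance = 1e-12)

  ## 2D hill factorizes over CVs
  h2 <- hill_records(10, matrix(c(0.5, 0.7), 1, 2), c(0.05, 0.1), 6, 4)
  expect_equal(bias_potential(h2, matrix(c(0.55, 0.8), 1, 2)),
               6 * exp(-0.5) * exp(-0.5), tolerance = 1e-12)
})

test_that("free-energy estimator applies -gamma/(gamma-1) and min-shifts", {
  params <- metad_params(bias_factor = 4)
  grid <- list(cv1 = seq(0.3, 1.2, length.out = 91))
  flat <- hill_records(numeric(0), matrix(numeric(0), 0, 1), 0.05,
                       numeric(0), 4)
  fes0 <- free_energy_surface(flat, grid, params)
  expect_true(all(fes0$F == 0))

  one <- hill_records(10, matrix(0.6), 0.05, 9, 4)
  fes <- free_energy_surface(one, grid, params)
  v <- bias_potential(one, grid$cv1)
  expect_equal(min(fes$F), 0)
  ## prefactor 4/3: total relief equals 4/3 of the bias range
  expect_equal(max(fes$F) - min(fes$F), 4 / 3 * (max(v) - min(v)),
               tolerance = 1e-12)
  ## argmax of V is argmin of F
  expect_equal(which.min(fes$F), which.max(v))
})

test_that("wall restraints are one-sided, quadratic and C1 at the bounds", {
  params <- metad_params()
  expect_equal(wall_force(0.7, params)$energy, 0)
  expect_equal(wall_force(0.3, params)$energy, 0)
  w <- wall_force(1.3, params)
  expect_equal(w$energy, 0.5 * 3500 * 0.1^2, tolerance = 1e-12)
  expect_equal(w$grad, 3500 * 0.1, tolerance = 1e-12)
  lo <- wall_force(0.25, params)
  expect_equal(lo$grad, 3500 * -0.05, tolerance = 1e-12)
  ## continuity just at the bound
  eps <- 1e-8
  expect_lt(abs(wall_force(1.2 + eps, params)$grad), 3500 * 2 * eps)
})

test_that("HILLS files round-trip through the text dialect", {
  set.seed(4)
  hills <- hill_records(time = seq(10, 100, by = 10),
                        centers = cbind(runif(10, 0.3, 1.2)),
                        sigma = 0.05, height = runif(10, 1, 10),
                        bias_factor = 4)
  f <- tempfile(fileext = ".hills")
  write_hills(hills, f)
  back <- read_hills(f)
  expect_equal(back$time, hills$time)
  expect_equal(back$cv1, hills$cv1)
  expect_equal(back$height, hills$height)
  expect_equal(back$biasf[1], 4)
})

test_that("deposited heights follow the well-tempered scaling", {
  pot <- potential_spec("double_well", a = 4000, half_sep = 0.2, tilt = 10,
                        center = 0.75)
  params <- metad_params(omega = 1, t_G = 1, bias_factor = 4,
                         temperature = 300, sigma = 0.05)
  run <- run_wt_metad(pot, params, n_walkers = 1L, n_steps = 60000L,
                      seed = 21L, dt = 2e-3, friction = 20)
  h <- run$hills
  nominal <- params$omega * params$t_G
  expect_true(all(h$height > 0 & h$height <= nominal + 1e-12))
  ## each height equals nominal * exp(-V_prior(center)/(kB dT)) with the
  ## bias of all earlier hills (engine grid vs exact hill sum: ~1%)
  kBdT <- 0.008314462618 * (params$bias_factor - 1) * params$temperature
  idx <- seq(5, nrow(h), by = 7)
  for (i in idx) {
    v_prior <- bias_potential(h[seq_len(i - 1L), , drop = FALSE], h$cv1[i])
    expect_equal(h$height[i], nominal * exp(-v_prior / kBdT),
                 tolerance = 0.03)
  }
})

test_that("a symmetric double well reconstructs a vanishing basin difference", {
  pot <- potential_spec("double_well", a = 4000, half_sep = 0.2, tilt = 0,
                        center = 0.75)
  params <- metad_params(omega = 1, t_G = 1, bias_factor = 4,
                         temperature = 300, sigma = 0.05)
  run <- run_wt_metad(pot, params, n_walkers = 2L, n_steps = 250000L,
                      seed = 5L, dt = 2e-3, friction = 20)
  grid <- list(cv1 = seq(0.25, 1.25, length.out = 201))
  fes <- free_energy_surface(run$hills, grid, params)
  df <- basin_delta_f(fes, c(0.3, 0.75), c(0.75, 1.2), 300)
  kT <- 0.008314462618 * 300
  expect_lt(abs(df) / kT, 0.3)
})

test_that("walkers sharing one bias agree with a single walker", {
  pot <- potential_spec("double_well", a = 4000, half_sep = 0.2, tilt = 10,
                        center = 0.75)
  params <- metad_params(omega = 1, t_G = 1, bias_factor = 4,
                         temperature = 300, sigma = 0.05)
  grid <- list(cv1 = seq(0.25, 1.25, length.out = 201))
  kT <- 0.008314462618 * 300
  df <- vapply(list(c(1L, 400000L), c(4L, 100000L)), function(cfg) {
    run <- run_wt_metad(pot, params, n_walkers = cfg[1], n_steps = cfg[2],
                        seed = 31L, dt = 2e-3, friction = 20)
    basin_delta_f(free_energy_surface(run$hills, grid, params),
                  c(0.3, 0.75), c(0.75, 1.2), 300)
  }, numeric(1))
  expect_lt(abs(df[1] - df[2]) / kT, 0.6)
})

test_that("convergence profiles end at the full-surface value and flatten", {
  pot <- potential_spec("double_well", a = 4000, half_sep = 0.2, tilt = 10,
                        center = 0.75)
  params <- metad_params(omega = 1, t_G = 1, bias_factor = 4,
                         temperature = 300, sigma = 0.05)
  run <- run_wt_metad(pot, params, n_walkers = 2L, n_steps = 250000L,
                      seed = 7L, dt = 2e-3, friction = 20)
  grid <- list(cv1 = seq(0.25, 1.25, length.out = 201))
  t_end <- max(run$hills$time)
  cp <- seq(t_end / 5, t_end, length.out = 5)
  prof <- convergence_profile(run$hills, cp, grid, params,
                              c(0.3, 0.75), c(0.75, 1.2))
  full <- basin_delta_f(free_energy_surface(run$hills, grid, params),
                        c(0.3, 0.75), c(0.75, 1.2), 300)
  expect_equal(prof$delta_f[5], full, tolerance = 1e-12)
  kT <- 0.008314462618 * 300
  expect_lt(max(abs(prof$delta_f[4:5] - full)) / kT, 0.3)
  expect_error(convergence_profile(run$hills, numeric(0), grid, params,
                                   c(0.3, 0.75), c(0.75, 1.2)),
               "checkpoint")
})

test_that("engine rejects non-tempered bias factors", {
  pot <- potential_spec("double_well")
  expect_error(metad_params(bias_factor = 1), "bias factor")
  params <- metad_params()
  expect_error(run_wt_metad(pot, params, n_steps = 10L, n_walkers = 0L),
               "walker")
})
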