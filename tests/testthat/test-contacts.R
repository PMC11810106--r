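test_that("COM distances reduce to geometry and match brute force", {
  atoms <- data.frame(name = c("A1", "B1"), resid = 1:2,
                      resname = "RES", chain = "A",
                      element = "C", mass = c(12, 12))
  coords <- array(0, c(1, 2, 3))
  coords[1, 2, ] <- c(0.3, 0.4, 0)
  traj <- trajectory_new(structure_new(atoms, matrix(0, 2, 3)), coords)
  ga <- atom_group(0, "a"); gb <- atom_group(1, "b")
  expect_equal(com_distance_series(traj, ga, gb), 0.5, tolerance = 1e-12)
  expect_equal(com_distance_series(traj, ga, ga), 0, tolerance = 1e-12)

  ## brute-force oracle on a many-atom wiggling trajectory
  st <- make_pam_structure()
  traj2 <- make_wiggle_trajectory(st, n_frames = 10L)
  g1 <- select_atoms(st, "resid 1335 and name NE CZ NH1 NH2")
  g2 <- select_atoms(st, "resid 3 and name O6 N7")
  d <- com_distance_series(traj2, g1, g2)
  m <- st$atoms$mass
  brute <- vapply(1:10, function(f) {
    com <- function(g) {
      r <- g$indices + 1L
      colSums(traj2$coords[f, r, , drop = FALSE][1, , ] * m[r]) / sum(m[r])
    }
    sqrt(sum((com(g1) - com(g2))^2))
  }, numeric(1))
  expect_equal(d, brute, tolerance = 1e-12)
})

test_that("candidate pairs obey the pooled 5% proximity filter", {
  crit <- contact_criteria()
  series <- list(
    steady_base = rep(0.4, 1000),                       # always below 0.6
    marginal = c(rep(0.5, 40), rep(0.9, 960)),          # 4% below: rejected
    at_threshold = c(rep(0.5, 50), rep(0.9, 950)))      # exactly 5%: kept
  res <- find_candidate_pairs(series, crit, "base")
  expect_true(res$candidate[res$pair == "steady_base"])
  expect_false(res$candidate[res$pair == "marginal"])
  expect_true(res$candidate[res$pair == "at_threshold"])

  ## phosphate kind uses the 0.5 nm cutoff
  ph <- find_candidate_pairs(list(p = rep(0.55, 100)), crit, "phosphate")
  expect_false(ph$candidate)
  expect_true(find_candidate_pairs(list(p = rep(0.55, 100)), crit,
                                   "base")$candidate)

  ## pooling across replicates: below-cutoff only in one replicate
  pooled <- find_candidate_pairs(
    list(pair = list(rep(0.4, 60), rep(0.9, 940))), crit, "base")
  expect_true(pooled$candidate)
  expect_equal(pooled$fraction_below, 0.06)
})

test_that("contact classification applies both criteria with attractive sign", {
  crit <- contact_criteria()
  occ <- classify_contacts(c(0.4, 0.4, 0.4, 0.7), c(-120, -80, 120, -500),
                           crit, "base")
  expect_identical(occ$values, c(1L, 0L, 0L, 0L))
  ## phosphate threshold is 350 kJ/mol
  occp <- classify_contacts(c(0.45, 0.45), c(-200, -400), crit, "phosphate")
  expect_identical(occp$values, c(0L, 1L))
  expect_error(classify_contacts(c(0.4, 0.4), -120, crit, "base"),
               "frame-aligned")
})

test_that("classification recovers the hidden Markov state path exactly", {
  sim <- gen_markov_contact(markov_contact_spec(n_frames = 5000L, seed = 17L))
  d <- com_distance_series(sim$trajectory, atom_group(0, "arg"),
                           atom_group(1, "base"))
  occ <- classify_contacts(d, sim$energy$values, contact_criteria(), "base")
  expect_identical(occ$values, sim$truth$states)
})

test_that("classification is monotone in the energy threshold", {
  sim <- gen_markov_contact(markov_contact_spec(n_frames = 2000L, seed = 23L))
  d <- com_distance_series(sim$trajectory, atom_group(0, "a"), atom_group(1, "b"))
  occ_prev <- NULL
  for (th in c(20, 60, 100, 140)) {
    crit <- contact_criteria(base_energy_threshold = th)
    occ <- classify_contacts(d, sim$energy$values, crit, "base")
    if (!is.null(occ_prev)) expect_true(all(occ$values <= occ_prev))
    occ_prev <- occ$values
  }
})

test_that("integrated autocorrelation time matches white-noise and AR(1) forms", {
  set.seed(31)
  tau_wn <- integrated_autocorrelation_time(rnorm(100000), dt = 1)
  expect_lt(abs(tau_wn - 1), 0.1)

  phi <- 0.9
  x <- as.numeric(stats::arima.sim(list(ar = phi), 100000))
  tau_ar <- integrated_autocorrelation_time(x, dt = 1)
  tau_true <- (1 + phi) / (1 - phi)
  expect_lt(abs(tau_ar - tau_true) / tau_true, 0.1)

  tau_c <- integrated_autocorrelation_time(rep(5, 200), dt = 2)
  expect_equal(as.numeric(tau_c), 2)
  expect_true(attr(tau_c, "constant"))
  expect_error(integrated_autocorrelation_time(rnorm(50)), "short")
})

test_that("frequency estimates carry Bernoulli errors on effective samples", {
  ones <- structure(list(values = rep(1L, 500), dt = 1, pair = "p",
                         category = "PAM_NB"), class = "OccupancySeries")
  set.seed(3)
  est1 <- frequency_with_error(ones, rnorm(500))
  expect_equal(est1$mean, 1)
  expect_equal(est1$stderr, 0)

  ## the largest replicate autocorrelation time is the one reported
  set.seed(5)
  e_fast <- rnorm(2000)
  e_slow <- as.numeric(stats::arima.sim(list(ar = 0.8), 2000))
  occ <- classify_contacts(rep(0.4, 2000), rnorm(2000, -150, 5),
                           contact_criteria(), "base")
  est2 <- frequency_with_error(list(occ, occ), list(e_fast, e_slow))
  t1 <- as.numeric(integrated_autocorrelation_time(e_fast, 1))
  t2 <- as.numeric(integrated_autocorrelation_time(e_slow, 1))
  expect_equal(est2$tau, max(t1, t2))
  expect_equal(est2$n_replicates, 2L)

  ## stderr shrinks as 1/sqrt(n_eff) when independent segments replicate
  sim <- gen_markov_contact(markov_contact_spec(n_frames = 4000L, seed = 2L))
  d <- com_distance_series(sim$trajectory, atom_group(0, "a"), atom_group(1, "b"))
  occ1 <- classify_contacts(d, sim$energy$values, contact_criteria(), "base")
  est_a <- frequency_with_error(occ1, sim$energy$values)
  est_b <- frequency_with_error(rep(list(occ1), 4),
                                rep(list(sim$energy$values), 4))
  expect_equal(est_b$stderr / est_a$stderr, 0.5, tolerance = 0.05)

  expect_error(frequency_with_error(list(), list()), "replicate")
})

test_that("category aggregation uses any-pair semantics", {
  mk <- function(v, cat) structure(list(values = v, dt = 1, pair = "p",
                                        category = cat),
                                   class = "OccupancySeries")
  occs <- list(mk(c(1L, 0L, 0L), "PAM_NB"), mk(c(0L, 1L, 0L), "PAM_NB"),
               mk(c(0L, 0L, 1L), "NONPAM"))
  agg <- category_occupancy(occs, "PAM_NB")
  expect_identical(agg$values, c(1L, 1L, 0L))
  expect_equal(category_occupancy(occs, "PAM_NB", mode = "mean"),
               c(0.5, 0.5, 0))
  expect_error(category_occupancy(occs, "PAM_BB"), "no occupancy")
})
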