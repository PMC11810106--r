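## synthetic: generators with known ground truth for every input class the
## pipeline consumes. Each generator uses its own explicitly seeded RNG
## stream and restores the caller's RNG state afterwards.

.with_seed <- function(seed, code) {
  .assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
          "seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Specification of a two-state Markov contact process
#'
#' Defines a bound/unbound (on/off) contact with stationary occupancy
#' `p_on` and relaxation time `tau`. The defaults give well-separated
#' state energy distributions (attractive-negative convention) so a
#' threshold classifier can recover the hidden state path exactly.
#'
#' @param p_on Stationary occupancy, in (0,1).
#' @param tau Correlation (relaxation) time, ps; must be >= `dt`.
#' @param dt Frame spacing, ps.
#' @param n_frames Number of frames.
#' @param e_on_mean,e_on_sd Interaction energy in the bound state, kJ/mol.
#' @param e_off_mean,e_off_sd Interaction energy in the unbound state.
#' @param d_on,d_off Probe-target COM distance per state, nm (`d_on < d_off`).
#' @param seed RNG seed for [gen_markov_contact()].
#' @return A `MarkovContactSpec` list.
#' @export
markov_contact_spec <- function(p_on = 0.3, tau = 10, dt = 1,
                                n_frames = 20000L,
                                e_on_mean = -150, e_on_sd = 10,
                                e_off_mean = -10, e_off_sd = 10,
                                d_on = 0.35, d_off = 0.8, seed = 1L) {
  .assert(p_on > 0 && p_on < 1, "p_on must be in (0,1)")
  .assert(tau >= dt, "tau (%g ps) must be >= dt (%g ps)", tau, dt)
  .assert(d_on < d_off, "d_on must be smaller than d_off")
  .assert(n_frames >= 1, "n_frames must be >= 1")
  structure(list(p_on = p_on, tau = tau, dt = dt,
                 n_frames = as.integer(n_frames),
                 e_on_mean = e_on_mean, e_on_sd = e_on_sd,
                 e_off_mean = e_off_mean, e_off_sd = e_off_sd,
                 d_on = d_on, d_off = d_off, seed = seed),
            class = "MarkovContactSpec")
}

## Exact discretization of the two-state rate model at step dt:
## with k_on = p_on/tau, k_off = (1-p_on)/tau the propagator gives
## P(on|on) = p_on + (1-p_on) q and P(on|off) = p_on (1-q), q = exp(-dt/tau),
## so the stationary occupancy is exactly p_on and the autocorrelation of
## the indicator decays as q^k.
.markov_transition <- function(p_on, tau, dt) {
  q <- exp(-dt / tau)
  list(p_on_on = p_on + (1 - p_on) * q, p_on_off = p_on * (1 - q), q = q)
}

#' Generate a synthetic Markov contact trajectory
#'
#' Emulates one arginine-nucleotide contact: a single-atom probe sits at
#' distance `d_on` (bound) or `d_off` (unbound) from a fixed single-atom
#' target, and the pair interaction energy is drawn from the state's
#' Gaussian. The exact hidden state path is returned as ground truth.
#'
#' @param spec A [markov_contact_spec()].
#' @return List with `trajectory` (a `Trajectory`), `energy` (list of
#'   `times`, `values` in kJ/mol), and `truth` (hidden states, the spec,
#'   and the analytic integrated autocorrelation time `tau_int` in ps).
#' @export
gen_markov_contact <- function(spec) {
  .assert(inherits(spec, "MarkovContactSpec"), "spec must be a MarkovContactSpec")
  tr <- .markov_transition(spec$p_on, spec$tau, spec$dt)
  .with_seed(spec$seed, {
    init <- as.integer(runif(1) < spec$p_on)
    states <- cpp_markov_chain(spec$n_frames, tr$p_on_on, tr$p_on_off, init)
    energies <- ifelse(states == 1L,
                       rnorm(spec$n_frames, spec$e_on_mean, spec$e_on_sd),
                       rnorm(spec$n_frames, spec$e_off_mean, spec$e_off_sd))
    atoms <- data.frame(
      name = c("CZ", "N9"), resid = c(1L, 2L),
      resname = c("ARG", "DG"), chain = c("A", "B"),
      element = c("C", "N"), mass = c(12.011, 14.007))
    coords <- array(0, c(spec$n_frames, 2L, 3L))
    coords[, 2L, 1L] <- ifelse(states == 1L, spec$d_on, spec$d_off)
    traj <- trajectory_new(structure_new(atoms, matrix(0, 2, 3)),
                           coords, times = (seq_len(spec$n_frames) - 1) * spec$dt)
    tau_int <- spec$dt * (1 + tr$q) / (1 - tr$q)
    list(trajectory = traj,
         energy = list(times = traj$times, values = energies),
         truth = list(states = as.integer(states), spec = spec,
                      tau_int = tau_int))
  })
}

#' Specification of a harmonic positional ensemble
#'
#' @param masses Atom masses, amu.
#' @param covariance Symmetric positive-definite `3A x 3A` positional
#'   covariance, nm^2 (coordinate order x1,y1,z1,x2,...).
#' @param n_frames Number of independent frames to draw.
#' @param temperature Temperature label, K (metadata only; the prescribed
#'   covariance fully determines the ensemble).
#' @param mean Mean positions (length `3A`), defaults to zero.
#' @param seed RNG seed.
#' @return A `HarmonicEnsembleSpec` list.
#' @export
harmonic_ensemble_spec <- function(masses, covariance, n_frames = 1000L,
                                   temperature = 300, mean = NULL,
                                   seed = 1L) {
  covariance <- as.matrix(covariance)
  a <- length(masses)
  .assert(all(masses > 0), "masses must be positive")
  .assert(nrow(covariance) == 3 * a && ncol(covariance) == 3 * a,
          "covariance must be 3A x 3A with A = length(masses)")
  .assert(max(abs(covariance - t(covariance))) < 1e-10,
          "covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  .assert(min(ev) > -1e-12 * max(abs(ev)),
          "covariance must be positive semi-definite")
  if (is.null(mean)) mean <- rep(0, 3 * a)
  structure(list(masses = masses, covariance = covariance,
                 n_frames = as.integer(n_frames), temperature = temperature,
                 mean = mean, seed = seed),
            class = "HarmonicEnsembleSpec")
}

#' Generate a harmonic (Gaussian) positional ensemble
#'
#' Frames are independent multivariate-normal draws about a fixed mean
#' with the prescribed covariance - the idealised input of the
#' quasi-harmonic entropy machinery.
#'
#' @param spec A [harmonic_ensemble_spec()].
#' @return A `Trajectory` (dt = 1 ps labels; frames are independent).
#' @export
gen_harmonic_ensemble <- function(spec) {
  .assert(inherits(spec, "HarmonicEnsembleSpec"),
          "spec must be a HarmonicEnsembleSpec")
  a <- length(spec$masses)
  .with_seed(spec$seed, {
    draws <- MASS::mvrnorm(spec$n_frames, mu = spec$mean,
                           Sigma = spec$covariance)
    if (spec$n_frames == 1L) draws <- matrix(draws, nrow = 1L)
    atoms <- data.frame(
      name = paste0("C", seq_len(a)), resid = 1L, resname = "RES",
      chain = "A", element = "C", mass = spec$masses)
    coords <- array(NA_real_, c(spec$n_frames, a, 3L))
    for (i in seq_len(a)) {
      coords[, i, ] <- draws[, (3 * i - 2):(3 * i), drop = FALSE]
    }
    trajectory_new(structure_new(atoms, matrix(spec$mean, a, 3, byrow = TRUE)),
                   coords, times = seq_len(spec$n_frames) - 1)
  })
}

#' Generate a donor-hydrogen-acceptor geometry fixture
#'
#' Places an arginine-like donor nitrogen at the origin, the acceptor at
#' `d_da` along +x, and the hydrogen at 0.1 nm from the donor rotated so
#' the hydrogen-donor-acceptor angle (vertex at the donor) equals
#' `theta_hda` exactly.
#'
#' @param d_da Donor-acceptor distance, nm.
#' @param theta_hda Hydrogen-donor-acceptor angle, degrees.
#' @return A 3-atom `Structure` (donor `NE`/ARG, hydrogen `HE`/ARG,
#'   acceptor `O6`/DG).
#' @export
gen_hbond_frame <- function(d_da, theta_hda) {
  .assert(d_da > 0, "d_da must be positive")
  th <- theta_hda * pi / 180
  atoms <- data.frame(
    name = c("NE", "HE", "O6"), resid = c(1L, 1L, 2L),
    resname = c("ARG", "ARG", "DG"), chain = c("A", "A", "B"),
    element = c("N", "H", "O"), mass = c(14.007, 1.008, 15.999))
  xyz <- rbind(c(0, 0, 0),
               0.1 * c(cos(th), sin(th), 0),
               c(d_da, 0, 0))
  structure_new(atoms, xyz)
}

#' Generate harmonic-oscillator alchemical states with closed-form dG
#'
#' State k is a 1D harmonic oscillator `u_k(x) = 0.5 k_k x^2` in kT units,
#' so the exact free energy of state k relative to state 1 is
#' `0.5 log(k_k / k_1)` kT. Either pass one spring constant per state, or
#' endpoints plus a lambda schedule with geometric interpolation
#' `k(lambda) = k_0 (k_1/k_0)^lambda`.
#'
#' @param spring_constants Per-state spring constants, kT/nm^2 (length
#'   `>= 2`), or length-2 endpoints when `lambdas` is given.
#' @param lambdas Optional lambda schedule in [0,1] (first 0, last 1).
#' @param n_per_state Samples drawn from each state.
#' @param temperature Temperature, K (for kcal/mol reporting downstream).
#' @param seed RNG seed.
#' @return List: `u` (`ReducedPotentialMatrix`: `u` K x N matrix in kT,
#'   `N_k`, `source`), `samples` (list of per-state draws, nm),
#'   `dg_true` (kT, relative to state 1), `spring_constants`,
#'   `temperature`.
#' @export
gen_alchemical_harmonics <- function(spring_constants, lambdas = NULL,
                                     n_per_state = 1000L, temperature = 300,
                                     seed = 1L) {
  if (!is.null(lambdas)) {
    .assert(length(spring_constants) == 2L,
            "with a lambda schedule, give the two endpoint spring constants")
    .assert(abs(lambdas[1]) < 1e-12 && abs(lambdas[length(lambdas)] - 1) < 1e-12,
            "lambda schedule must start at 0 and end at 1")
    .assert(all(diff(lambdas) > 0), "lambda schedule must be increasing")
    k <- spring_constants[1] * (spring_constants[2] / spring_constants[1])^lambdas
  } else {
    k <- spring_constants
  }
  K <- length(k)
  .assert(K >= 2L, "need at least two states")
  .assert(all(k > 0), "spring constants must be positive")
  .with_seed(seed, {
    samples <- lapply(seq_len(K), function(i)
      rnorm(n_per_state, 0, sqrt(1 / k[i])))
    x <- unlist(samples)
    u <- matrix(NA_real_, K, K * n_per_state)
    for (i in seq_len(K)) u[i, ] <- 0.5 * k[i] * x^2
    rpm <- reduced_potentials(u, N_k = rep(as.integer(n_per_state), K))
    list(u = rpm, samples = samples,
         dg_true = 0.5 * log(k / k[1]),
         spring_constants = k, temperature = temperature)
  })
}

## ---------------------------------------------------------------------------
## Analytic potentials and the plain Langevin sampler

#' Define an analytic CV-space potential
#'
#' Two families are provided for engine validation:
#' \describe{
#'   \item{harmonic}{`U = sum_d 0.5 k_d (x_d - c_d)^2`; arguments `k`, `center`
#'     (vectors, one entry per CV dimension).}
#'   \item{double_well}{`U = a ((x - c)^2 - w^2)^2 + b (x - c)` along CV 1
#'     (wells near `c +- w`, tilt `b` makes it asymmetric); arguments `a`
#'     (kJ/mol/nm^4), `half_sep` = w (nm), `tilt` = b (kJ/mol/nm), `center`
#'     = c (nm); optional `k2`, `center2` add a harmonic second CV.}
#' }
#'
#' @param type `"harmonic"` or `"double_well"`.
#' @param ... Family parameters as above.
#' @return A `PotentialSpec` list with fields `type`, `dim`, `code`, `par`.
#' @export
potential_spec <- function(type = c("harmonic", "double_well"), ...) {
  type <- match.arg(type)
  args <- list(...)
  if (type == "harmonic") {
    k <- args$k %||% 1
    center <- args$center %||% rep(0, length(k))
    .assert(length(k) == length(center), "k and center lengths differ")
    .assert(length(k) %in% 1:2, "1 or 2 CV dimensions supported")
    par <- as.numeric(rbind(k, center))
    out <- list(type = type, dim = length(k), code = 1L, par = par)
  } else {
    a <- args$a %||% 4000
    w <- args$half_sep %||% 0.2
    b <- args$tilt %||% 0
    cc <- args$center %||% 0.75
    par <- c(a, w^2, b, cc)
    dim <- 1L
    if (!is.null(args$k2)) {
      par <- c(par, args$k2, args$center2 %||% 0)
      dim <- 2L
    }
    out <- list(type = type, dim = dim, code = 2L, par = par)
  }
  class(out) <- "PotentialSpec"
  out
}

#' Evaluate an analytic potential
#'
#' @param pot A [potential_spec()].
#' @param x Numeric vector (one CV point) or matrix (points in rows).
#' @return Potential energy, kJ/mol.
#' @export
potential_energy <- function(pot, x) {
  .assert(inherits(pot, "PotentialSpec"), "pot must be a PotentialSpec")
  x <- if (is.matrix(x)) x else matrix(x, ncol = pot$dim)
  .assert(ncol(x) == pot$dim, "x has %d columns, potential has %d CVs",
          ncol(x), pot$dim)
  if (pot$code == 1L) {
    u <- 0
    for (d in seq_len(pot$dim)) {
      u <- u + 0.5 * pot$par[2 * d - 1] * (x[, d] - pot$par[2 * d])^2
    }
  } else {
    a <- pot$par[1]; w2 <- pot$par[2]; b <- pot$par[3]; cc <- pot$par[4]
    dx <- x[, 1] - cc
    u <- a * (dx^2 - w2)^2 + b * dx
    if (pot$dim == 2L) u <- u + 0.5 * pot$par[5] * (x[, 2] - pot$par[6])^2
  }
  as.numeric(u)
}

#' Sample an analytic potential with overdamped Langevin dynamics
#'
#' Euler-Maruyama update `x <- x - grad(U + V_bias) dt / friction +
#' sqrt(2 kT dt / friction) xi`. With `bias = NULL` the loop runs in
#' compiled code; an R-callable `bias(x)` returning `list(value, grad)`
#' switches to an R loop.
#'
#' @param pot A [potential_spec()] (1D or 2D).
#' @param kT Thermal energy, kJ/mol.
#' @param friction Friction coefficient, amu/ps.
#' @param dt Time step, ps.
#' @param n_steps Number of steps.
#' @param seed RNG seed.
#' @param x0 Start point (defaults to the potential's centre parameters).
#' @param bias Optional bias callable.
#' @param stride Keep every `stride`-th position.
#' @return Matrix of sampled CV positions (rows), nm.
#' @export
gen_langevin <- function(pot, kT, friction = 1, dt = 1e-3, n_steps = 10000L,
                         seed = 1L, x0 = NULL, bias = NULL, stride = 1L) {
  .assert(inherits(pot, "PotentialSpec"), "pot must be a PotentialSpec")
  .assert(kT >= 0 && friction > 0 && dt > 0, "kT>=0, friction>0, dt>0 required")
  if (is.null(x0)) {
    x0 <- if (pot$code == 1L) pot$par[seq(2, 2 * pot$dim, by = 2)]
          else c(pot$par[4] - sqrt(pot$par[2]), if (pot$dim == 2L) pot$par[6])
  }
  .with_seed(seed, {
    if (is.null(bias)) {
      cpp_langevin(pot$code, pot$par, pot$dim, as.numeric(x0), kT, friction,
                   dt, as.integer(n_steps), as.integer(stride))
    } else {
      x <- as.numeric(x0)
      out <- matrix(NA_real_, n_steps %/% stride, pot$dim)
      noise <- sqrt(2 * kT * dt / friction)
      eps <- 1e-6
      row <- 0L
      for (i in seq_len(n_steps)) {
        g <- .num_grad(function(z) potential_energy(pot, z), x, eps)
        bb <- bias(x)
        x <- x - (g + bb$grad) * dt / friction + noise * rnorm(pot$dim)
        if (i %% stride == 0L && row < nrow(out)) {
          row <- row + 1L
          out[row, ] <- x
        }
      }
      out
    }
  })
}

.num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(d) {
    xp <- x; xm <- x
    xp[d] <- xp[d] + eps; xm[d] <- xm[d] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}
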