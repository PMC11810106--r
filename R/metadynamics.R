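## metadynamics: history-dependent bias bookkeeping, free-energy
## reconstruction, wall restraints, and the toy well-tempered engine.

#' Well-tempered metadynamics parameters
#'
#' @param omega Bias deposition rate, kJ/mol/ps.
#' @param t_G Deposition stride of the Gaussian hills, ps.
#' @param bias_factor `gamma = (T + dT)/T` (> 1).
#' @param temperature Simulation temperature T, K.
#' @param sigma Hill width per CV, nm.
#' @param wall_lo,wall_hi One-sided harmonic wall positions per CV, nm.
#' @param wall_k Wall force constant, kJ/(mol nm^2).
#' @return A `MetadParams` list.
#' @export
metad_params <- function(omega = 1.0, t_G = 10, bias_factor = 4,
                         temperature = 300, sigma = 0.05,
                         wall_lo = 0.3, wall_hi = 1.2, wall_k = 3500) {
  .assert(omega > 0 && t_G > 0, "omega and t_G must be positive")
  .assert(bias_factor > 1, "bias factor must exceed 1")
  .assert(temperature > 0, "temperature must be positive")
  .assert(all(sigma > 0), "hill widths must be positive")
  .assert(all(wall_lo < wall_hi), "wall_lo must be below wall_hi")
  .assert(wall_k >= 0, "wall force constant must be non-negative")
  structure(list(omega = omega, t_G = t_G, bias_factor = bias_factor,
                 temperature = temperature, sigma = sigma,
                 wall_lo = wall_lo, wall_hi = wall_hi, wall_k = wall_k),
            class = "MetadParams")
}

.hills_dim <- function(hills) sum(grepl("^cv[0-9]+$", names(hills)))

#' Assemble a hill-record table
#'
#' @param time Deposition times, ps.
#' @param centers CV centres: vector (1D) or matrix with one column per CV.
#' @param sigma Hill width per CV, nm.
#' @param height Deposited (already tempering-scaled) heights, kJ/mol.
#' @param bias_factor The well-tempered bias factor the heights were
#'   scaled with.
#' @return A `HillRecords` data frame: `time`, `cv1[,cv2]`,
#'   `sigma_cv1[,sigma_cv2]`, `height`, `biasf`.
#' @export
hill_records <- function(time, centers, sigma, height, bias_factor) {
  centers <- as.matrix(centers)
  dim <- ncol(centers)
  .assert(dim %in% 1:2, "1 or 2 CVs supported")
  .assert(length(sigma) %in% c(1L, dim), "sigma must have one entry per CV")
  if (length(sigma) == 1L) sigma <- rep(sigma, dim)
  .assert(all(sigma > 0), "hill widths must be positive")
  .assert(length(time) == nrow(centers) && length(height) == nrow(centers),
          "time/centers/height lengths differ")
  .assert(all(height > 0), "deposited heights must be positive")
  .assert(!is.unsorted(time), "hills must be time-ordered")
  n <- nrow(centers)
  df <- data.frame(time = as.numeric(time))
  for (d in seq_len(dim)) df[[paste0("cv", d)]] <- centers[, d]
  for (d in seq_len(dim)) df[[paste0("sigma_cv", d)]] <- rep(sigma[d], n)
  df$height <- as.numeric(height)
  df$biasf <- rep(bias_factor, n)
  class(df) <- c("HillRecords", "data.frame")
  df
}

#' Evaluate the deposited bias potential
#'
#' `V(s) = sum_hills h exp(-sum_d (s_d - c_d)^2 / (2 sigma_d^2))`, using
#' the tempering-scaled height recorded at each hill's deposition time.
#'
#' @param hills A `HillRecords` table.
#' @param s Evaluation points: vector (1D CV values) or matrix with one
#'   column per CV.
#' @return Bias potential at each point, kJ/mol.
#' @export
bias_potential <- function(hills, s) {
  dim <- .hills_dim(hills)
  s <- if (is.matrix(s)) s else matrix(s, ncol = dim)
  .assert(ncol(s) == dim, "points have %d columns but hills have %d CVs",
          ncol(s), dim)
  v <- numeric(nrow(s))
  if (nrow(hills) == 0L) return(v)
  for (i in seq_len(nrow(hills))) {
    ex <- 0
    for (d in seq_len(dim)) {
      ex <- ex + (s[, d] - hills[[paste0("cv", d)]][i])^2 /
        (2 * hills[[paste0("sigma_cv", d)]][i]^2)
    }
    v <- v + hills$height[i] * exp(-ex)
  }
  v
}

#' Reconstruct the free-energy surface from hills
#'
#' Applies the well-tempered estimator `F(s) = -gamma/(gamma-1) V(s)`
#' (the prefactor is `(T + dT)/dT`) on a regular grid and fixes the
#' undetermined constant by shifting the minimum to zero.
#'
#' @param hills A `HillRecords` table.
#' @param grid List of grid axes: `cv1` (and `cv2` for 2D), nm.
#' @param params A [metad_params()] providing the bias factor.
#' @param t_max Use only hills deposited at `time <= t_max` (default all).
#' @return A `FreeEnergySurface`: `grid`, `F` (vector or matrix,
#'   kJ/mol, min 0), `bias_factor`, `t_max`.
#' @export
free_energy_surface <- function(hills, grid, params, t_max = Inf) {
  .assert(inherits(params, "MetadParams"), "params must be MetadParams")
  dim <- .hills_dim(hills)
  .assert(!is.null(grid$cv1), "grid must provide cv1 axis")
  .assert((dim == 2L) == !is.null(grid$cv2),
          "grid dimensionality must match the hills")
  hills_t <- hills[hills$time <= t_max, , drop = FALSE]
  if (dim == 1L) {
    pts <- matrix(grid$cv1, ncol = 1L)
  } else {
    pts <- as.matrix(expand.grid(cv1 = grid$cv1, cv2 = grid$cv2))
  }
  v <- bias_potential(hills_t, pts)
  g <- params$bias_factor
  f <- -g / (g - 1) * v
  f <- f - min(f)
  if (dim == 2L) f <- matrix(f, nrow = length(grid$cv1))
  structure(list(grid = grid, F = f, bias_factor = g,
                 t_max = if (nrow(hills_t)) max(hills_t$time) else 0),
            class = "FreeEnergySurface")
}

#' One-sided harmonic wall restraint
#'
#' `0.5 k (s - bound)^2` outside `[wall_lo, wall_hi]` per CV, zero inside;
#' the gradient is continuous at the bounds.
#'
#' @param s CV point (vector, one entry per CV).
#' @param params A [metad_params()].
#' @return List `energy` (kJ/mol) and `grad` (kJ/mol/nm per CV).
#' @export
wall_force <- function(s, params) {
  .assert(inherits(params, "MetadParams"), "params must be MetadParams")
  dim <- length(s)
  lo <- rep(params$wall_lo, length.out = dim)
  hi <- rep(params$wall_hi, length.out = dim)
  e <- 0
  g <- numeric(dim)
  for (d in seq_len(dim)) {
    if (s[d] < lo[d]) {
      e <- e + 0.5 * params$wall_k * (s[d] - lo[d])^2
      g[d] <- params$wall_k * (s[d] - lo[d])
    } else if (s[d] > hi[d]) {
      e <- e + 0.5 * params$wall_k * (s[d] - hi[d])^2
      g[d] <- params$wall_k * (s[d] - hi[d])
    }
  }
  list(energy = e, grad = g)
}

#' Run the toy Langevin + well-tempered metadynamics engine
#'
#' Overdamped Langevin walkers on an analytic potential under the shared
#' history-dependent bias plus wall restraints. Every `t_G` ps one walker
#' (round-robin) deposits a Gaussian hill with instantaneous height
#' `omega t_G exp(-V(s)/(k_B dT))`.
#'
#' @param pot A [potential_spec()] (1D or 2D).
#' @param params A [metad_params()].
#' @param n_walkers Number of walkers sharing the bias.
#' @param n_steps Langevin steps (per walker).
#' @param seed RNG seed.
#' @param dt Langevin time step, ps.
#' @param friction Friction coefficient, amu/ps.
#' @param x0 Start points, matrix `n_walkers x dim` (default: spread
#'   across the wall range).
#' @param grid_n Bias-grid nodes per CV for the engine's internal grid.
#' @param out_stride Keep every `out_stride`-th CV sample.
#' @return List `hills` (`HillRecords`), `cv` (samples matrix), `cv_time`,
#'   `params`, `kT` (kJ/mol).
#' @export
run_wt_metad <- function(pot, params, n_walkers = 1L, n_steps = 100000L,
                         seed = 1L, dt = 2e-3, friction = 20, x0 = NULL,
                         grid_n = 601L, out_stride = 100L) {
  .assert(inherits(pot, "PotentialSpec"), "pot must be a PotentialSpec")
  .assert(inherits(params, "MetadParams"), "params must be MetadParams")
  .assert(n_walkers >= 1L, "need at least one walker")
  dim <- pot$dim
  kT <- .kB * params$temperature
  lo <- rep(params$wall_lo, length.out = dim)
  hi <- rep(params$wall_hi, length.out = dim)
  sigma <- rep(params$sigma, length.out = dim)
  if (is.null(x0)) {
    x0 <- sapply(seq_len(dim), function(d)
      lo[d] + (hi[d] - lo[d]) * (seq_len(n_walkers) / (n_walkers + 1)))
    x0 <- matrix(x0, nrow = n_walkers)
  }
  x0 <- as.matrix(x0)
  .assert(nrow(x0) == n_walkers && ncol(x0) == dim,
          "x0 must be n_walkers x dim")
  margin <- 4 * max(sigma)
  res <- .with_seed(seed, cpp_wt_metad(
    pot$code, pot$par, dim, x0, kT, friction, dt, as.integer(n_steps),
    params$omega, params$t_G, params$bias_factor, params$temperature,
    sigma, lo, hi, params$wall_k,
    lo - margin, hi + margin, rep(as.integer(grid_n), dim),
    as.integer(out_stride)))
  hills <- hill_records(res$hill_time, res$hill_center, sigma,
                        res$hill_height, params$bias_factor)
  list(hills = hills, cv = res$cv, cv_time = res$cv_time,
       params = params, kT = kT)
}

#' Basin free-energy difference from a reconstructed surface
#'
#' Boltzmann-integrates `exp(-F/kT)` over each basin of CV1 rather than
#' comparing minima, which is less grid-sensitive:
#' `dF = F(basin_b) - F(basin_a)`.
#'
#' @param fes A [free_energy_surface()] result (1D).
#' @param basin_a,basin_b CV1 intervals `c(lo, hi)`, nm.
#' @param temperature Temperature for the Boltzmann weights, K.
#' @return Free-energy difference, kJ/mol.
#' @export
basin_delta_f <- function(fes, basin_a, basin_b, temperature) {
  .assert(inherits(fes, "FreeEnergySurface"), "fes must be a FreeEnergySurface")
  .assert(is.null(fes$grid$cv2), "basin integration implemented for 1D surfaces")
  kT <- .kB * temperature
  x <- fes$grid$cv1
  f <- fes$F
  gint <- function(b) {
    sel <- x >= b[1] & x <= b[2]
    .assert(any(sel), "basin [%g, %g] contains no grid nodes", b[1], b[2])
    -kT * (logsumexp(-f[sel] / kT) + log(mean(diff(x))))
  }
  gint(basin_b) - gint(basin_a)
}

#' Convergence profile of a basin free-energy difference
#'
#' Reconstructs the surface from hills truncated at each checkpoint time
#' and reports the basin difference as a function of simulation time;
#' at the final checkpoint the value equals the full-surface difference
#' by construction.
#'
#' @param hills A `HillRecords` table.
#' @param checkpoints Increasing times, ps (non-empty).
#' @param grid Grid axes as in [free_energy_surface()].
#' @param params A [metad_params()].
#' @param basin_a,basin_b CV1 basin intervals, nm.
#' @return Data frame `time`, `delta_f` (kJ/mol).
#' @export
convergence_profile <- function(hills, checkpoints, grid, params,
                                basin_a, basin_b) {
  .assert(length(checkpoints) > 0L, "checkpoint list must not be empty")
  .assert(all(diff(checkpoints) > 0), "checkpoints must be increasing")
  df <- vapply(checkpoints, function(tc) {
    fes <- free_energy_surface(hills, grid, params, t_max = tc)
    basin_delta_f(fes, basin_a, basin_b, params$temperature)
  }, numeric(1))
  data.frame(time = checkpoints, delta_f = df)
}

## ---------------------------------------------------------------------------
## HILLS text format (PLUMED dialect)

#' Write hills in the HILLS text dialect
#'
#' Columns: time, CV centres, sigmas, height, biasf, under a
#' `#! FIELDS` header.
#'
#' @param hills A `HillRecords` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hills <- function(hills, path) {
  dim <- .hills_dim(hills)
  cvn <- paste0("cv", seq_len(dim))
  cols <- c("time", cvn, paste0("sigma_", cvn), "height", "biasf")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(cols, collapse = " ")), con)
  m <- cbind(hills$time,
             as.matrix(hills[cvn]),
             as.matrix(hills[paste0("sigma_cv", seq_len(dim))]),
             hills$height, hills$biasf)
  writeLines(apply(m, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  invisible(path)
}

#' Read hills from the HILLS text dialect
#'
#' @param path HILLS file (1 or 2 CVs; `#`/`@` comment lines ignored).
#' @return A `HillRecords` table.
#' @export
read_hills <- function(path) {
  ts <- read_timeseries(path)
  m <- cbind(ts$times, ts$values)
  dim <- (ncol(m) - 3L) / 2L
  .assert(dim %in% 1:2, "HILLS file must have 1 or 2 CVs (got %d columns)",
          ncol(m))
  hill_records(time = m[, 1],
               centers = m[, 1 + seq_len(dim), drop = FALSE],
               sigma = m[1, 1 + dim + seq_len(dim)],
               height = m[, 2 + 2 * dim],
               bias_factor = m[1, 3 + 2 * dim])
}
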