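## alchemy: MBAR free energies over lambda windows, exchange-acceptance
## estimation and schedule optimization, thermodynamic-cycle bookkeeping,
## and enthalpic decomposition with block-average errors.

.KB_KCAL <- 0.0019872041  # kcal/(mol K)

#' Reduced-potential sample matrix
#'
#' `u[k, n]` is the reduced potential (kT units) of sample `n` evaluated
#' in state `k`; `N_k` counts the samples drawn from each state.
#'
#' @param u K x N numeric matrix, kT.
#' @param N_k Integer vector of per-state sample counts (sums to N).
#' @param source Optional source-state index per sample (default: the
#'   first `N_1` samples from state 1, the next `N_2` from state 2, ...).
#' @return A `ReducedPotentialMatrix` list (`u`, `N_k`, `source`).
#' @export
reduced_potentials <- function(u, N_k, source = NULL) {
  u <- as.matrix(u)
  .assert(all(is.finite(u)), "reduced potentials must be finite")
  N_k <- as.integer(N_k)
  .assert(length(N_k) == nrow(u), "N_k must have one entry per state (row)")
  .assert(sum(N_k) == ncol(u),
          "sum(N_k) = %d but u has %d samples", sum(N_k), ncol(u))
  .assert(all(N_k >= 0), "N_k must be non-negative")
  if (is.null(source)) source <- rep(seq_along(N_k), N_k)
  .assert(length(source) == ncol(u), "source must tag every sample")
  structure(list(u = u, N_k = N_k, source = as.integer(source)),
            class = "ReducedPotentialMatrix")
}

## MBAR weights at a given f: W[n, k] = exp(f_k - u_kn) / sum_j N_j exp(f_j - u_jn)
.mbar_log_denom <- function(u, f, log_N) {
  ## log sum_j exp(log N_j + f_j - u_jn), per sample n
  M <- t(-u + f)               # N x K with entries f_k - u_kn
  logsumexp_rows(M, log_N)
}

#' MBAR free energies
#'
#' Solves the multistate Bennett acceptance ratio self-consistency
#' equations for the dimensionless free energies of all sampled states
#' (self-consistent iteration warm start, then Newton polish on the MBAR
#' objective), and estimates uncertainties from the asymptotic covariance
#' of the weight matrix.
#'
#' @param rpm A [reduced_potentials()] object (every state sampled).
#' @param tolerance Convergence tolerance on free-energy increments, kT.
#' @param max_iter Iteration cap (self-consistent + Newton combined).
#' @param temperature Optional temperature (K) to also report kcal/mol.
#' @return A `FreeEnergyResult`: `dg_kT` (per state, relative to state 1,
#'   so `dg_kT[1] = 0`), `se_kT`, `theta` (covariance of the f's),
#'   `n_iter`, and when `temperature` is given `dg_kcal`, `se_kcal`.
#' @export
mbar_free_energies <- function(rpm, tolerance = 1e-8, max_iter = 2000L,
                               temperature = NULL) {
  .assert(inherits(rpm, "ReducedPotentialMatrix"),
          "rpm must be a ReducedPotentialMatrix")
  u <- rpm$u
  N_k <- rpm$N_k
  .assert(all(N_k > 0), "every state must be sampled (N_k > 0)")
  K <- nrow(u); N <- ncol(u)
  log_N <- log(N_k)
  f <- rep(0, K)

  iter <- 0L
  repeat {
    iter <- iter + 1L
    ld <- .mbar_log_denom(u, f, log_N)
    f_new <- vapply(seq_len(K), function(k) -logsumexp(-u[k, ] - ld),
                    numeric(1))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < 1e-4 || iter >= max_iter %/% 2L) break
  }

  ## Newton polish on the convex MBAR objective
  repeat {
    iter <- iter + 1L
    ld <- .mbar_log_denom(u, f, log_N)
    W <- exp(t(-u) - ld + rep(f, each = N))     # N x K
    colW <- colSums(W)
    grad <- N_k * (colW - 1)
    ## H_kl = delta_kl N_k sum_n W_nk - N_k N_l sum_n W_nk W_nl
    H <- diag(N_k * colW, K) - crossprod(W) * outer(N_k, N_k)
    step <- tryCatch(
      solve(H[-1, -1, drop = FALSE], grad[-1]),
      error = function(e) grad[-1] * 0)
    if (all(step == 0) && max(abs(grad[-1])) > sqrt(tolerance)) {
      ## singular Hessian: damped gradient step
      step <- grad[-1] / max(N_k)
    }
    f_new <- f
    f_new[-1] <- f[-1] - step
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    ## guard: fall back to self-consistent update if Newton overshoots
    if (!all(is.finite(f_new)) || delta > 5) {
      ld <- .mbar_log_denom(u, f, log_N)
      f_new <- vapply(seq_len(K), function(k) -logsumexp(-u[k, ] - ld),
                      numeric(1))
      f_new <- f_new - f_new[1]
      delta <- max(abs(f_new - f))
    }
    f <- f_new
    if (delta < tolerance) break
    if (iter >= max_iter) {
      stop(sprintf(
        "MBAR did not converge in %d iterations (residual %.3g kT)",
        iter, delta), call. = FALSE)
    }
  }

  ## asymptotic covariance (SVD form of the weight-matrix estimator)
  ld <- .mbar_log_denom(u, f, log_N)
  W <- exp(t(-u) - ld + rep(f, each = N))
  sv <- svd(W, nu = 0)
  V <- sv$v; S <- sv$d
  A <- diag(K) - diag(S) %*% t(V) %*% (V * N_k) %*% diag(S)
  Ainv <- tryCatch(solve(A), error = function(e) MASS::ginv(A))
  Theta <- V %*% diag(S) %*% Ainv %*% diag(S) %*% t(V)
  se <- vapply(seq_len(K), function(k) {
    v <- Theta[k, k] + Theta[1, 1] - 2 * Theta[k, 1]
    sqrt(max(v, 0))
  }, numeric(1))

  out <- list(dg_kT = f, se_kT = se, theta = Theta, n_iter = iter,
              N_k = N_k)
  if (!is.null(temperature)) {
    out$temperature <- temperature
    out$dg_kcal <- f * .KB_KCAL * temperature
    out$se_kcal <- se * .KB_KCAL * temperature
  }
  class(out) <- "FreeEnergyResult"
  out
}

#' @export
print.FreeEnergyResult <- function(x, ...) {
  cat("FreeEnergyResult (relative to state 1):\n")
  for (k in seq_along(x$dg_kT)) {
    cat(sprintf("  state %2d: %8.4f +/- %.4f kT\n", k, x$dg_kT[k], x$se_kT[k]))
  }
  invisible(x)
}

#' Mean Metropolis exchange acceptance between neighbouring states
#'
#' For each neighbour pair (i, i+1), pairs the samples drawn from the two
#' states and averages the Metropolis factor `min(1, exp(-Delta))` with
#' the replica-exchange energy difference
#' `Delta = [u_j(x_i) - u_i(x_i)] + [u_i(x_j) - u_j(x_j)]`.
#'
#' @param rpm A [reduced_potentials()] object.
#' @return Data frame `i`, `j`, `acceptance`.
#' @export
exchange_acceptance <- function(rpm) {
  .assert(inherits(rpm, "ReducedPotentialMatrix"),
          "rpm must be a ReducedPotentialMatrix")
  K <- nrow(rpm$u)
  .assert(K >= 2L, "need at least two states")
  out <- data.frame(i = seq_len(K - 1L), j = 2:K, acceptance = NA_real_)
  for (i in seq_len(K - 1L)) {
    j <- i + 1L
    si <- which(rpm$source == i)
    sj <- which(rpm$source == j)
    .assert(length(si) > 0L && length(sj) > 0L,
            "states %d/%d have no samples", i, j)
    m <- min(length(si), length(sj))
    si <- si[seq_len(m)]; sj <- sj[seq_len(m)]
    delta <- (rpm$u[j, si] - rpm$u[i, si]) + (rpm$u[i, sj] - rpm$u[j, sj])
    out$acceptance[i] <- mean(pmin(1, exp(-delta)))
  }
  out
}

#' Pilot model of a lambda-dependent alchemical system
#'
#' Packages what the schedule optimizer needs: a reduced-potential
#' function `u_fun(lambda, x)` (kT, vectorized over samples `x`) and
#' pilot samples drawn at a grid of lambda values; acceptance between
#' arbitrary lambdas is estimated with the samples of the nearest pilot
#' windows.
#'
#' @param u_fun Function `(lambda, x) -> u` in kT.
#' @param lambdas Pilot lambda grid in [0, 1].
#' @param samples List of sample vectors, one per pilot lambda.
#' @return An `AlchemicalPilot` list.
#' @export
alchemical_pilot <- function(u_fun, lambdas, samples) {
  .assert(is.function(u_fun), "u_fun must be a function")
  .assert(length(lambdas) == length(samples), "one sample set per lambda")
  .assert(all(diff(lambdas) > 0), "pilot lambdas must be increasing")
  structure(list(u_fun = u_fun, lambdas = lambdas, samples = samples),
            class = "AlchemicalPilot")
}

.pilot_acceptance <- function(pilot, la, lb) {
  ia <- which.min(abs(pilot$lambdas - la))
  ib <- which.min(abs(pilot$lambdas - lb))
  xa <- pilot$samples[[ia]]
  xb <- pilot$samples[[ib]]
  m <- min(length(xa), length(xb))
  xa <- xa[seq_len(m)]; xb <- xb[seq_len(m)]
  delta <- (pilot$u_fun(lb, xa) - pilot$u_fun(la, xa)) +
           (pilot$u_fun(la, xb) - pilot$u_fun(lb, xb))
  mean(pmin(1, exp(-delta)))
}

.schedule_acceptances <- function(pilot, lambdas) {
  vapply(seq_len(length(lambdas) - 1L), function(i)
    .pilot_acceptance(pilot, lambdas[i], lambdas[i + 1L]), numeric(1))
}

#' Optimize a lambda schedule for replica exchange
#'
#' Adjusts the interior lambda values by gradient descent on an
#' acceptance-equalization loss (variance of the neighbour acceptances,
#' plus a penalty whenever the minimum acceptance falls below the
#' target), keeping the endpoints pinned at 0 and 1 and the schedule
#' strictly monotone. Iterates until the minimum acceptance reaches the
#' target and the loss stalls, or the iteration cap; errors if the
#' target is unreachable with the given window count.
#'
#' @param pilot An [alchemical_pilot()].
#' @param n_windows Number of lambda windows (>= 2, endpoints included).
#' @param target_acceptance Minimum neighbour acceptance to reach
#'   (default 0.10).
#' @param max_iter Gradient-descent iteration cap.
#' @param step0 Initial step size in lambda units.
#' @return A `LambdaSchedule`: `values`, `acceptance` (per pair),
#'   `min_acceptance`, `n_iter`, `loss` metadata (the declared objective).
#' @export
optimize_lambda_schedule <- function(pilot, n_windows,
                                     target_acceptance = 0.10,
                                     max_iter = 200L, step0 = 0.05) {
  .assert(inherits(pilot, "AlchemicalPilot"), "pilot must be an AlchemicalPilot")
  .assert(n_windows >= 2L, "need at least two windows")
  lam <- seq(0, 1, length.out = n_windows)

  loss_fn <- function(interior) {
    l <- c(0, interior, 1)
    if (any(diff(l) <= 1e-6)) return(Inf)
    acc <- .schedule_acceptances(pilot, l)
    stats::var(acc) + 1000 * max(0, target_acceptance - min(acc))^2
  }

  ## initial placement: equalize the accumulated -log acceptance measured
  ## between adjacent pilot grid points (a thermodynamic-length proxy),
  ## then let gradient descent refine
  pg <- pilot$lambdas
  if (length(pg) > 2L && n_windows > 2L) {
    cost <- vapply(seq_len(length(pg) - 1L), function(i)
      -log(max(.pilot_acceptance(pilot, pg[i], pg[i + 1L]), 1e-12)),
      numeric(1))
    cum <- c(0, cumsum(cost))
    if (cum[length(cum)] > 0) {
      targets <- seq(0, cum[length(cum)], length.out = n_windows)
      lam_init <- stats::approx(cum, pg, xout = targets, ties = "ordered")$y
      lam_init[1] <- 0; lam_init[n_windows] <- 1
      if (all(diff(lam_init) > 1e-6) &&
          loss_fn(lam_init[-c(1L, n_windows)]) <=
            loss_fn(lam[-c(1L, n_windows)])) {
        lam <- lam_init
      }
    }
  }

  interior <- lam[-c(1L, n_windows)]
  n_int <- length(interior)
  step <- step0
  loss <- loss_fn(interior)
  iter <- 0L
  if (n_int > 0L) {
    eps <- 1e-4
    while (iter < max_iter) {
      iter <- iter + 1L
      g <- vapply(seq_len(n_int), function(d) {
        up <- interior; dn <- interior
        up[d] <- up[d] + eps; dn[d] <- dn[d] - eps
        (loss_fn(up) - loss_fn(dn)) / (2 * eps)
      }, numeric(1))
      gn <- sqrt(sum(g^2))
      if (!is.finite(gn) || gn == 0) break
      cand <- interior - step * g / gn
      cand <- pmin(pmax(sort(cand), 1e-4), 1 - 1e-4)
      l_cand <- loss_fn(cand)
      if (l_cand < loss) {
        interior <- cand
        loss <- l_cand
        step <- min(step * 1.2, 0.1)
      } else {
        step <- step / 2
        if (step < 1e-5) break
      }
    }
  }
  values <- c(0, interior, 1)
  acc <- .schedule_acceptances(pilot, values)
  ## never hand back a schedule whose weakest link is worse than uniform
  ## spacing on the same pilot model
  unif <- seq(0, 1, length.out = n_windows)
  acc_unif <- .schedule_acceptances(pilot, unif)
  if (min(acc) < min(acc_unif)) {
    values <- unif
    acc <- acc_unif
  }
  if (min(acc) < target_acceptance) {
    stop(sprintf(
      paste("schedule optimization reached min acceptance %.3f < target %.3f",
            "with %d windows; increase n_windows"),
      min(acc), target_acceptance, n_windows), call. = FALSE)
  }
  structure(list(values = values, acceptance = acc,
                 min_acceptance = min(acc), n_iter = iter,
                 loss = "variance of neighbour acceptances + penalty below target",
                 target_acceptance = target_acceptance),
            class = "LambdaSchedule")
}

#' @export
print.LambdaSchedule <- function(x, ...) {
  cat(sprintf("LambdaSchedule: %d windows, min acceptance %.3f\n",
              length(x$values), x$min_acceptance))
  cat("  lambda:", paste(sprintf("%.3f", x$values), collapse = " "), "\n")
  invisible(x)
}

#' Thermodynamic-cycle double free-energy difference
#'
#' Combines the alchemical transformation free energies without
#' (`dg_m1`) and with (`dg_m2`) bound DNA into the binding free-energy
#' change `ddG = dG_m2 - dG_m1` with errors propagated in quadrature.
#'
#' @param dg_m1,dg_m2 Leg free energies, kcal/mol.
#' @param err_m1,err_m2 Their uncertainties, kcal/mol.
#' @return A `ThermoCycleResult`: `dg_m1`, `dg_m2`, `ddg`, `err` fields.
#' @export
thermodynamic_cycle <- function(dg_m1, dg_m2, err_m1 = 0, err_m2 = 0) {
  .assert(err_m1 >= 0 && err_m2 >= 0, "errors must be non-negative")
  structure(list(dg_m1 = dg_m1, err_m1 = err_m1,
                 dg_m2 = dg_m2, err_m2 = err_m2,
                 ddg = dg_m2 - dg_m1,
                 err = sqrt(err_m1^2 + err_m2^2)),
            class = "ThermoCycleResult")
}

#' @export
print.ThermoCycleResult <- function(x, ...) {
  cat(sprintf("ddG = %.3f +/- %.3f kcal/mol (dG_m2 %.3f +/- %.3f, dG_m1 %.3f +/- %.3f)\n",
              x$ddg, x$err, x$dg_m2, x$err_m2, x$dg_m1, x$err_m1))
  invisible(x)
}

.block_stats <- function(x, n_blocks) {
  n <- length(x)
  .assert(n >= n_blocks, "series has fewer frames (%d) than blocks (%d)",
          n, n_blocks)
  size <- n %/% n_blocks
  means <- vapply(seq_len(n_blocks), function(b)
    mean(x[((b - 1) * size + 1):(b * size)]), numeric(1))
  list(mean = mean(x), se = stats::sd(means) / sqrt(n_blocks))
}

#' Per-group enthalpic decomposition with block-average errors
#'
#' For each residue group, `dE = <E>_lambda1 - <E>_lambda0` from the
#' physical end-state trajectories after discarding the initial
#' equilibration fraction; the error of each end-state mean comes from
#' the standard error of `n_blocks` contiguous block means, combined
#' across end states in quadrature. When total protein-DNA series are
#' supplied, the residual `prot-rest` term (total minus the selected
#' groups) is appended so the terms partition the total exactly.
#'
#' @param groups0,groups1 Named lists of frame-aligned energy series
#'   (kJ/mol) at lambda = 0 and lambda = 1 (same names, same lengths
#'   within each end state).
#' @param total0,total1 Optional total protein-DNA energy series.
#' @param discard_fraction Initial fraction dropped as equilibration
#'   (default 0.10).
#' @param n_blocks Number of blocks (default 5).
#' @return A `DecompositionResult` data frame: `group`, `delta_e`, `se`
#'   (kJ/mol); attribute `total` holds the total-series row when given.
#' @export
interaction_energy_decomposition <- function(groups0, groups1,
                                             total0 = NULL, total1 = NULL,
                                             discard_fraction = 0.10,
                                             n_blocks = 5L) {
  .assert(length(groups0) == length(groups1) &&
            setequal(names(groups0), names(groups1)),
          "end states must carry the same residue groups")
  .assert(discard_fraction >= 0 && discard_fraction < 1,
          "discard_fraction must be in [0, 1)")
  trim <- function(x) x[(floor(length(x) * discard_fraction) + 1L):length(x)]
  one <- function(e0, e1) {
    s0 <- .block_stats(trim(e0), n_blocks)
    s1 <- .block_stats(trim(e1), n_blocks)
    c(delta_e = s1$mean - s0$mean, se = sqrt(s0$se^2 + s1$se^2))
  }
  nm <- names(groups0)
  rows <- t(vapply(nm, function(g) one(groups0[[g]], groups1[[g]]),
                   numeric(2)))
  out <- data.frame(group = nm, delta_e = rows[, 1], se = rows[, 2],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(total0) && !is.null(total1)) {
    rest0 <- trim(total0) - Reduce(`+`, lapply(groups0, trim))
    rest1 <- trim(total1) - Reduce(`+`, lapply(groups1, trim))
    s0 <- .block_stats(rest0, n_blocks)
    s1 <- .block_stats(rest1, n_blocks)
    out <- rbind(out, data.frame(
      group = "prot-rest", delta_e = s1$mean - s0$mean,
      se = sqrt(s0$se^2 + s1$se^2), stringsAsFactors = FALSE))
    tt <- one(total0, total1)
    attr(out, "total") <- c(delta_e = unname(tt[1]), se = unname(tt[2]))
  }
  class(out) <- c("DecompositionResult", "data.frame")
  out
}

## ---------------------------------------------------------------------------
## u-matrix TSV io: rows = samples (source-state column + one column per
## evaluation state)

#' Write a reduced-potential matrix as TSV
#'
#' @param rpm A [reduced_potentials()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reduced_potentials <- function(rpm, path) {
  df <- data.frame(source = rpm$source, t(rpm$u))
  names(df) <- c("source", paste0("u", seq_len(nrow(rpm$u))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reduced-potential matrix from TSV
#'
#' @param path TSV written by [write_reduced_potentials()].
#' @return A `ReducedPotentialMatrix`.
#' @export
read_reduced_potentials <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  .assert("source" %in% names(df), "u-matrix TSV needs a 'source' column")
  u <- t(as.matrix(df[, setdiff(names(df), "source"), drop = FALSE]))
  src <- as.integer(df$source)
  N_k <- vapply(seq_len(nrow(u)), function(k) sum(src == k), integer(1))
  reduced_potentials(u, N_k, src)
}
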