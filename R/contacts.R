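## contacts: dual distance/energy contact classification and the
## Bernoulli + autocorrelation error model for interaction frequencies.

#' Contact classification criteria
#'
#' Dual criteria for arginine-DNA contacts: a pair is a *candidate* if its
#' COM distance is below the kind's cutoff (0.6 nm for arginine-base,
#' 0.5 nm for arginine-phosphate) in at least `candidate_fraction` of the
#' pooled trajectory, and a candidate frame is an *effective contact* only
#' if, in addition, the attractive interaction energy magnitude reaches
#' the kind's threshold (100 kJ/mol base, 350 kJ/mol phosphate).
#'
#' @param base_distance_cutoff nm, arginine-nucleobase COM cutoff.
#' @param phosphate_distance_cutoff nm, arginine-phosphate COM cutoff.
#' @param candidate_fraction Minimum fraction of pooled frames below the
#'   cutoff for a pair to be considered at all.
#' @param base_energy_threshold kJ/mol magnitude, arginine-base.
#' @param phosphate_energy_threshold kJ/mol magnitude, arginine-phosphate.
#' @return A `ContactCriteria` list.
#' @export
contact_criteria <- function(base_distance_cutoff = 0.6,
                             phosphate_distance_cutoff = 0.5,
                             candidate_fraction = 0.05,
                             base_energy_threshold = 100,
                             phosphate_energy_threshold = 350) {
  .assert(base_distance_cutoff > 0 && phosphate_distance_cutoff > 0,
          "distance cutoffs must be positive")
  .assert(candidate_fraction > 0 && candidate_fraction < 1,
          "candidate_fraction must be in (0,1)")
  .assert(base_energy_threshold >= 0 && phosphate_energy_threshold >= 0,
          "energy thresholds must be non-negative")
  structure(list(base_distance_cutoff = base_distance_cutoff,
                 phosphate_distance_cutoff = phosphate_distance_cutoff,
                 candidate_fraction = candidate_fraction,
                 base_energy_threshold = base_energy_threshold,
                 phosphate_energy_threshold = phosphate_energy_threshold),
            class = "ContactCriteria")
}

.criteria_for_kind <- function(criteria, kind = c("base", "phosphate")) {
  kind <- match.arg(kind)
  if (kind == "base") {
    list(d = criteria$base_distance_cutoff, e = criteria$base_energy_threshold)
  } else {
    list(d = criteria$phosphate_distance_cutoff,
         e = criteria$phosphate_energy_threshold)
  }
}

## COM of a group in one coordinate matrix (atoms x 3), optionally
## mass-weighted. indices are 0-based.
.group_com <- function(coords, indices, masses, mass_weighted = TRUE) {
  rows <- indices + 1L
  w <- if (mass_weighted) masses[rows] else rep(1, length(rows))
  colSums(coords[rows, , drop = FALSE] * w) / sum(w)
}

#' Per-frame COM-COM distance between two atom groups
#'
#' @param traj A `Trajectory`.
#' @param a,b `AtomGroup`s on the trajectory's topology.
#' @param mass_weighted Use mass-weighted centres of mass (default) or
#'   plain geometric centres.
#' @return Numeric vector, one distance (nm) per frame.
#' @export
com_distance_series <- function(traj, a, b, mass_weighted = TRUE) {
  .assert(inherits(traj, "Trajectory"), "traj must be a Trajectory")
  .assert(inherits(a, "AtomGroup") && inherits(b, "AtomGroup"),
          "a and b must be AtomGroups")
  na <- nrow(traj$structure$atoms)
  .assert(all(a$indices < na) && all(b$indices < na),
          "group indices exceed the trajectory's atom count")
  m <- traj$structure$atoms$mass
  com_series <- function(idx) {
    rows <- idx + 1L
    w <- if (mass_weighted) m[rows] else rep(1, length(rows))
    w <- w / sum(w)
    out <- matrix(NA_real_, n_frames(traj), 3L)
    for (d in 1:3) {
      out[, d] <- matrix(traj$coords[, rows, d], nrow = nrow(out)) %*% w
    }
    out
  }
  dxyz <- com_series(a$indices) - com_series(b$indices)
  sqrt(rowSums(dxyz^2))
}

#' Filter candidate contact pairs by pooled proximity
#'
#' A pair is retained iff its COM distance falls below the kind's cutoff
#' in at least `candidate_fraction` of the *pooled* frames (all replicate
#' series concatenated, matching the cumulative-trajectory convention).
#'
#' @param distance_series Named list; each element is one pair's distance
#'   series (nm) - either a numeric vector or a list of per-replicate
#'   vectors, which are pooled.
#' @param criteria A [contact_criteria()].
#' @param kind `"base"` or `"phosphate"`.
#' @return Data frame with `pair`, `fraction_below`, `candidate`.
#' @export
find_candidate_pairs <- function(distance_series, criteria,
                                 kind = c("base", "phosphate")) {
  kind <- match.arg(kind)
  .assert(inherits(criteria, "ContactCriteria"), "criteria must be ContactCriteria")
  .assert(length(distance_series) > 0L, "no distance series given")
  cut <- .criteria_for_kind(criteria, kind)$d
  if (is.null(names(distance_series)))
    names(distance_series) <- paste0("pair", seq_along(distance_series))
  frac <- vapply(distance_series, function(s) {
    s <- unlist(s, use.names = FALSE)
    .assert(length(s) > 0L, "empty distance series")
    mean(s < cut)
  }, numeric(1))
  data.frame(pair = names(distance_series), fraction_below = unname(frac),
             candidate = unname(frac >= criteria$candidate_fraction),
             stringsAsFactors = FALSE)
}

#' Classify effective contacts frame by frame
#'
#' A frame counts as a contact iff the COM distance is below the kind's
#' cutoff AND the interaction energy is attractive (negative) with
#' magnitude at least the kind's threshold. Repulsive frames never count,
#' whatever their magnitude.
#'
#' @param distances Per-frame COM distances, nm.
#' @param energies Frame-aligned interaction energies, kJ/mol
#'   (attractive-negative convention).
#' @param criteria A [contact_criteria()].
#' @param kind `"base"` or `"phosphate"`.
#' @param dt Frame spacing, ps.
#' @param pair Pair label.
#' @param category Interaction category tag (`PAM_NB`, `PAM_BB`, `NONPAM`).
#' @return An `OccupancySeries`: list with binary `values`, `dt`, `pair`,
#'   `category`.
#' @export
classify_contacts <- function(distances, energies, criteria,
                              kind = c("base", "phosphate"), dt = 1,
                              pair = "pair", category = "PAM_NB") {
  kind <- match.arg(kind)
  .assert(length(distances) == length(energies),
          "distance (%d) and energy (%d) series are not frame-aligned",
          length(distances), length(energies))
  th <- .criteria_for_kind(criteria, kind)
  vals <- as.integer(distances < th$d & energies <= -th$e)
  structure(list(values = vals, dt = dt, pair = pair, category = category),
            class = "OccupancySeries")
}

#' Integrated autocorrelation time of a series
#'
#' `tau = dt (1 + 2 sum_k rho(k))`, with the sum truncated at the first
#' lag where the empirical autocorrelation drops below zero
#' (initial-positive-sequence window). A constant series carries no
#' correlation information and returns `tau = dt` with a flag.
#'
#' @param series Numeric series (length >= 100).
#' @param dt Sample spacing, ps.
#' @param lag_max Longest lag examined (default `min(n - 1, 2000)`; the
#'   initial-positive-sequence window almost always closes much earlier).
#' @return `tau` in ps, with attributes `n_lags_used` and `constant`.
#' @export
integrated_autocorrelation_time <- function(series, dt = 1, lag_max = NULL) {
  .assert(length(series) >= 100L,
          "series too short (%d < 100) for autocorrelation analysis",
          length(series))
  .assert(dt > 0, "dt must be positive")
  if (stats::var(series) == 0) {
    return(structure(dt, n_lags_used = 0L, constant = TRUE))
  }
  n <- length(series)
  if (is.null(lag_max)) lag_max <- min(n - 1L, 2000L)
  rho <- as.numeric(stats::acf(series, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)[-1]
  first_neg <- which(rho < 0)[1]
  if (!is.na(first_neg)) rho <- rho[seq_len(first_neg - 1L)]
  tau <- dt * (1 + 2 * sum(rho))
  structure(max(tau, dt), n_lags_used = length(rho), constant = FALSE)
}

#' Interaction frequency with autocorrelation-corrected error
#'
#' Pools per-replicate binary occupancy series into a mean frequency and
#' treats the indicator as Bernoulli: `var = mean (1 - mean)`. The number
#' of effectively independent samples is `n_eff = T_total / tau`, with
#' `tau` the *largest* integrated autocorrelation time of the replicate
#' interaction-energy series, so
#' `stderr = sqrt(mean (1 - mean) / n_eff)`. The replicate scatter
#' (standard deviation of the mean over replicates) is reported alongside
#' as `stderr_replicate`.
#'
#' @param occupancies One `OccupancySeries` or a list of them (replicates).
#' @param energy_series Matching energy series (vector or list), used for
#'   the autocorrelation time.
#' @param dt Frame spacing, ps (taken from the occupancy series if absent).
#' @return A `FrequencyEstimate`: `mean`, `stderr`, `stderr_replicate`,
#'   `tau` (ps), `n_eff`, `n_replicates`, `n_frames`.
#' @export
frequency_with_error <- function(occupancies, energy_series, dt = NULL) {
  if (inherits(occupancies, "OccupancySeries")) occupancies <- list(occupancies)
  if (is.numeric(energy_series)) energy_series <- list(energy_series)
  .assert(length(occupancies) >= 1L, "need at least one replicate")
  .assert(length(occupancies) == length(energy_series),
          "occupancy and energy replicate counts differ")
  for (o in occupancies) {
    .assert(inherits(o, "OccupancySeries"), "occupancies must be OccupancySeries")
    .assert(length(o$values) > 0L, "zero-length occupancy series")
    .assert(all(o$values %in% c(0L, 1L)), "occupancy values must be binary")
  }
  if (is.null(dt)) dt <- occupancies[[1]]$dt
  rep_means <- vapply(occupancies, function(o) mean(o$values), numeric(1))
  n_per <- vapply(occupancies, function(o) length(o$values), numeric(1))
  pooled <- sum(rep_means * n_per) / sum(n_per)
  taus <- vapply(energy_series, function(e)
    as.numeric(integrated_autocorrelation_time(e, dt)), numeric(1))
  tau <- max(taus)
  t_total <- sum(n_per) * dt
  n_eff <- min(t_total / tau, sum(n_per))
  stderr <- sqrt(pooled * (1 - pooled) / n_eff)
  stderr_rep <- if (length(rep_means) > 1L)
    stats::sd(rep_means) / sqrt(length(rep_means)) else NA_real_
  structure(list(mean = pooled, stderr = stderr,
                 stderr_replicate = stderr_rep, tau = tau, n_eff = n_eff,
                 n_replicates = length(occupancies),
                 n_frames = sum(n_per)),
            class = "FrequencyEstimate")
}

#' @export
print.FrequencyEstimate <- function(x, ...) {
  cat(sprintf(
    "FrequencyEstimate: mean %.4f +/- %.4f (tau %.2f ps, n_eff %.0f, %d replicate%s)\n",
    x$mean, x$stderr, x$tau, x$n_eff, x$n_replicates,
    if (x$n_replicates == 1L) "" else "s"))
  invisible(x)
}

#' Aggregate per-pair occupancies into category occupancy
#'
#' A frame counts for a category (PAM_NB / PAM_BB / NONPAM) if *any* pair
#' of that category is in contact in that frame; `mode = "mean"` instead
#' averages the pair indicators.
#'
#' @param occupancies List of `OccupancySeries` with equal lengths.
#' @param category Category to aggregate.
#' @param mode `"any"` (default) or `"mean"`.
#' @return An `OccupancySeries` for `mode = "any"`; numeric series for
#'   `"mean"`.
#' @export
category_occupancy <- function(occupancies, category, mode = c("any", "mean")) {
  mode <- match.arg(mode)
  sel <- Filter(function(o) identical(o$category, category), occupancies)
  .assert(length(sel) > 0L, "no occupancy series in category '%s'", category)
  lens <- vapply(sel, function(o) length(o$values), integer(1))
  .assert(length(unique(lens)) == 1L, "category series lengths differ")
  m <- do.call(rbind, lapply(sel, function(o) o$values))
  if (mode == "any") {
    structure(list(values = as.integer(colSums(m) > 0), dt = sel[[1]]$dt,
                   pair = paste0("category:", category), category = category),
              class = "OccupancySeries")
  } else {
    colMeans(m)
  }
}
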