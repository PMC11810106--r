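## flex_entropy: superposition, RMSF, fluctuation covariance, and
## quasi-harmonic conformational entropy.

## Weighted Kabsch superposition. Returns the proper rotation R and the
## centroids such that (Y - cy) %*% R + cx least-squares matches X.
.kabsch_fit <- function(X, Y, w = NULL) {
  .assert(nrow(X) == nrow(Y), "coordinate sets differ in atom count")
  if (is.null(w)) w <- rep(1, nrow(X))
  w <- w / sum(w)
  cx <- colSums(X * w)
  cy <- colSums(Y * w)
  A <- sweep(Y, 2L, cy)
  B <- sweep(X, 2L, cx)
  H <- t(A * w) %*% B
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(rotation = R, center_ref = cx, center_mobile = cy)
}

#' Superpose every frame onto a reference
#'
#' Removes rotational and translational motion by mass-weighted
#' least-squares superposition of each frame onto the reference frame
#' over the alignment group; the fitted rigid motion is applied to all
#' atoms.
#'
#' @param traj A `Trajectory`.
#' @param align_group `AtomGroup` defining the fit atoms.
#' @param ref_frame Reference frame index (default 1).
#' @param mass_weighted Mass-weight the fit (default TRUE).
#' @return The superposed `Trajectory`.
#' @export
superpose_series <- function(traj, align_group, ref_frame = 1L,
                             mass_weighted = TRUE) {
  .assert(inherits(traj, "Trajectory"), "traj must be a Trajectory")
  rows <- align_group$indices + 1L
  m <- traj$structure$atoms$mass
  w <- if (mass_weighted) m[rows] else rep(1, length(rows))
  ref <- traj$coords[ref_frame, rows, , drop = TRUE]
  if (is.null(dim(ref))) ref <- matrix(ref, ncol = 3L)
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    fr <- traj$coords[f, , , drop = TRUE]
    if (is.null(dim(fr))) fr <- matrix(fr, ncol = 3L)
    fit <- .kabsch_fit(ref, fr[rows, , drop = FALSE], w)
    moved <- sweep(fr, 2L, fit$center_mobile) %*% fit$rotation
    out[f, , ] <- sweep(moved, 2L, fit$center_ref, `+`)
  }
  trajectory_new(traj$structure, out, traj$times)
}

#' Root-mean-square fluctuations
#'
#' Per-atom RMSF about the time-mean position of an (already superposed)
#' trajectory, reported in Angstroms; the per-residue value is the mean
#' over the residue's atoms in the group.
#'
#' @param traj A superposed `Trajectory`.
#' @param group `AtomGroup` to profile.
#' @param per_residue Also aggregate per residue.
#' @return An `RMSFProfile`: data frame (`index`, `name`, `resid`,
#'   `rmsf_A`), with a `residue` attribute when `per_residue` is TRUE.
#' @export
rmsf <- function(traj, group, per_residue = TRUE) {
  .assert(inherits(traj, "Trajectory"), "traj must be a Trajectory")
  rows <- group$indices + 1L
  xyz <- traj$coords[, rows, , drop = FALSE]
  mean_pos <- apply(xyz, c(2L, 3L), mean)
  dev2 <- sweep(xyz, c(2L, 3L), mean_pos)^2
  per_atom_nm <- sqrt(apply(dev2, 2L, mean) * 3)  # mean over frames & axes
  ## mean over axes of squared dev summed: RMSF^2 = <|dx|^2> = sum_axes <dx_a^2>
  prof <- data.frame(index = group$indices,
                     name = traj$structure$atoms$name[rows],
                     resid = traj$structure$atoms$resid[rows],
                     rmsf_A = per_atom_nm * 10,
                     stringsAsFactors = FALSE)
  class(prof) <- c("RMSFProfile", "data.frame")
  if (per_residue) {
    agg <- stats::aggregate(rmsf_A ~ resid, data = prof, FUN = mean)
    attr(prof, "residue") <- agg
  }
  prof
}

#' Mass-weighted covariance of atomic fluctuations
#'
#' `C_ij = <dx_i dx_j>` over frames (deviations from the time mean,
#' coordinate order x1,y1,z1,x2,...), optionally mass-weighted by
#' `sqrt(m_i m_j)` so its eigenvalues are in amu nm^2 as required by
#' [quasiharmonic_entropy()].
#'
#' @param traj A superposed `Trajectory`.
#' @param group `AtomGroup`.
#' @param mass_weighted Apply `sqrt(m_i m_j)` weighting (default TRUE).
#' @return `3A x 3A` symmetric matrix (attribute `mass_weighted`).
#' @export
fluctuation_covariance <- function(traj, group, mass_weighted = TRUE) {
  .assert(inherits(traj, "Trajectory"), "traj must be a Trajectory")
  rows <- group$indices + 1L
  nf <- n_frames(traj)
  a <- length(rows)
  X <- matrix(NA_real_, nf, 3L * a)
  for (i in seq_len(a)) {
    X[, (3 * i - 2):(3 * i)] <- traj$coords[, rows[i], ]
  }
  Xc <- sweep(X, 2L, colMeans(X))
  C <- crossprod(Xc) / nf
  if (mass_weighted) {
    sm <- sqrt(rep(traj$structure$atoms$mass[rows], each = 3L))
    C <- C * tcrossprod(sm)
  }
  C <- (C + t(C)) / 2
  attr(C, "mass_weighted") <- mass_weighted
  C
}

#' Quasi-harmonic conformational entropy
#'
#' Treats the eigenmodes of the mass-weighted fluctuation covariance as
#' independent harmonic oscillators with frequencies
#' `omega_i = sqrt(k_B T / lambda_i)` and sums the quantum
#' harmonic-oscillator entropy
#' `S = R sum_i [ a_i/(exp(a_i)-1) - log(1-exp(-a_i)) ]`,
#' `a_i = hbar omega_i / (k_B T)`. The quantum form is the default
#' because the classical expression diverges for stiff modes; set
#' `formula = "classical"` for `S = R sum_i [1 - log(a_i)]` (only modes
#' with `a_i < 1` contribute positively there; reported as-is).
#'
#' @param covariance Mass-weighted covariance (amu nm^2 eigenvalues), as
#'   from [fluctuation_covariance()].
#' @param temperature Temperature, K.
#' @param eigen_floor Modes with eigenvalue below this (amu nm^2) are
#'   excluded (numerical zeros from constraint removal).
#' @param formula `"quantum"` (default) or `"classical"`.
#' @return An `EntropyResult`: `S` (J/(mol K)), `eigenvalues` (amu nm^2),
#'   `n_modes_used`, `temperature`, `formula`, `per_mode` (J/(mol K)).
#' @export
quasiharmonic_entropy <- function(covariance, temperature,
                                  eigen_floor = 1e-12,
                                  formula = c("quantum", "classical")) {
  formula <- match.arg(formula)
  covariance <- as.matrix(covariance)
  .assert(temperature > 0, "temperature must be positive")
  .assert(max(abs(covariance - t(covariance))) <
            1e-8 * max(1, max(abs(covariance))),
          "covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  .assert(min(ev) > -1e-8 * max(abs(ev), 1e-30),
          "covariance has significantly negative eigenvalues")
  used <- ev[ev > eigen_floor]
  if (length(used) == 0L) {
    res <- list(S = 0, eigenvalues = ev, n_modes_used = 0L,
                temperature = temperature, formula = formula,
                per_mode = numeric(0))
    class(res) <- "EntropyResult"
    return(res)
  }
  lambda_si <- used * .AMU * 1e-18          # kg m^2 per molecule
  kT_si <- .KB_SI * temperature             # J
  alpha <- .HBAR / sqrt(kT_si * lambda_si)  # hbar*omega / kB T
  per_mode <- if (formula == "quantum") {
    .R_GAS * (alpha / expm1(alpha) - log1p(-exp(-alpha)))
  } else {
    .R_GAS * (1 - log(alpha))
  }
  res <- list(S = sum(per_mode), eigenvalues = ev,
              n_modes_used = length(used), temperature = temperature,
              formula = formula, per_mode = per_mode)
  class(res) <- "EntropyResult"
  res
}

#' @export
print.EntropyResult <- function(x, ...) {
  cat(sprintf("EntropyResult: S = %.2f J/(mol K) at %g K (%s, %d mode%s)\n",
              x$S, x$temperature, x$formula, x$n_modes_used,
              if (x$n_modes_used == 1L) "" else "s"))
  invisible(x)
}

#' Entropy difference between two states
#'
#' Bookkeeping helper for comparing conformational entropies of a residue
#' in two systems (e.g. an engineered variant vs. the wild type):
#' `dS = S_a - S_b` in J/(mol K).
#'
#' @param s_a,s_b `EntropyResult`s or plain numbers in J/(mol K).
#' @return Numeric difference, J/(mol K).
#' @export
entropy_difference <- function(s_a, s_b) {
  val <- function(s) if (inherits(s, "EntropyResult")) s$S else as.numeric(s)
  val(s_a) - val(s_b)
}
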