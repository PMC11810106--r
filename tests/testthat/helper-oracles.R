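## Shared fixtures and independent oracles used across the suite.

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  C <- 1 - c_
  matrix(c(
    c_ + a[1]^2 * C,        a[1] * a[2] * C - a[3] * s_, a[1] * a[3] * C + a[2] * s_,
    a[2] * a[1] * C + a[3] * s_, c_ + a[2]^2 * C,        a[2] * a[3] * C - a[1] * s_,
    a[3] * a[1] * C - a[2] * s_, a[3] * a[2] * C + a[1] * s_, c_ + a[3]^2 * C),
    3, 3, byrow = TRUE)
}

## Horn's quaternion-based optimal superposition: an algorithm independent
## of the SVD route used by the package. Returns the weighted RMSD (nm).
quaternion_rmsd <- function(X, Y, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(X))
  w <- w / sum(w)
  cx <- colSums(X * w); cy <- colSums(Y * w)
  A <- sweep(Y, 2L, cy); B <- sweep(X, 2L, cx)
  S <- t(A * w) %*% B
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  qw <- q[1]; qx <- q[2]; qy <- q[3]; qz <- q[4]
  R <- matrix(c(
    1-2*(qy^2+qz^2), 2*(qx*qy-qw*qz), 2*(qx*qz+qw*qy),
    2*(qx*qy+qw*qz), 1-2*(qx^2+qz^2), 2*(qy*qz-qw*qx),
    2*(qx*qz-qw*qy), 2*(qy*qz+qw*qx), 1-2*(qx^2+qy^2)),
    3, 3, byrow = TRUE)
  moved <- t(R %*% t(A))
  sqrt(sum(w * rowSums((moved - B)^2)))
}

## Two-state BAR solved as a one-parameter root of the MBAR stationarity
## condition via uniroot - an algorithmic path independent of the
## package's self-consistent + Newton solver.
bar_uniroot <- function(u, N_k) {
  stopifnot(nrow(u) == 2L)
  n <- ncol(u)
  g <- function(f2) {
    lw1 <- log(N_k[1]) - u[1, ]
    lw2 <- log(N_k[2]) + f2 - u[2, ]
    m <- pmax(lw1, lw2)
    denom <- m + log(exp(lw1 - m) + exp(lw2 - m))
    sum(exp(lw2 - denom)) - N_k[2]
  }
  stats::uniroot(g, c(-80, 80), tol = 1e-12)$root
}

## Boltzmann-quadrature basin free-energy difference on an analytic 1D
## potential (the metadynamics oracle).
quadrature_delta_f <- function(pot, kT, split, lo, hi, n = 20001L) {
  xs <- seq(lo, hi, length.out = n)
  U <- potential_energy(pot, xs)
  fa <- -kT * log(sum(exp(-U[xs < split] / kT)))
  fb <- -kT * log(sum(exp(-U[xs >= split] / kT)))
  fb - fa
}

## Small protein/DNA-like structure: one arginine side chain (with polar
## hydrogens), one guanine-like nucleotide (base + phosphate atoms) and
## one non-PAM nucleotide.
make_pam_structure <- function() {
  atoms <- data.frame(
    name = c("CD", "NE", "HE", "CZ", "NH1", "HH11", "HH12", "NH2", "HH21", "HH22",
             "P", "OP1", "OP2", "C1'", "N9", "C8", "N7", "C6", "O6", "N1",
             "P", "OP1", "OP2", "N3", "O2"),
    resid = c(rep(1335L, 10), rep(3L, 10), rep(8L, 5)),
    resname = c(rep("ARG", 10), rep("DG", 10), rep("DT", 5)),
    chain = c(rep("B", 10), rep("C", 10), rep("C", 5)),
    stringsAsFactors = FALSE)
  set.seed(1234)
  xyz <- matrix(runif(nrow(atoms) * 3, 0, 2), ncol = 3)
  structure_new(atoms, xyz)
}

## Deterministic multi-frame trajectory around a base structure.
make_wiggle_trajectory <- function(st, n_frames = 25L, sd = 0.02, seed = 99L) {
  set.seed(seed)
  a <- nrow(st$atoms)
  coords <- array(NA_real_, c(n_frames, a, 3L))
  for (f in seq_len(n_frames)) {
    coords[f, , ] <- st$xyz + matrix(rnorm(a * 3, 0, sd), ncol = 3)
  }
  trajectory_new(st, coords, times = seq_len(n_frames) - 1)
}
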