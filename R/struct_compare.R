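## struct_compare: domain COM distances, Kabsch RMSD, Z-score comparison
## of distance distributions, kernel densities.

#' Define a structural domain by residue ranges
#'
#' The shipped defaults follow the standard SpCas9 domain annotation:
#' REC3 = residues 498-718, HNH = residues 775-908 (author numbering).
#' They are configuration, not constants - every distance report carries
#' the ranges it used.
#'
#' @param name Domain name.
#' @param ranges List of inclusive residue intervals `c(lo, hi)`.
#' @param scope Atom scope: `"heavy"`, `"backbone"` (N, CA, C, O) or
#'   `"CA"`.
#' @param chain Optional chain restriction.
#' @return A `DomainDefinition` list.
#' @export
domain_definition <- function(name, ranges, scope = c("heavy", "backbone", "CA"),
                              chain = NULL) {
  scope <- match.arg(scope)
  if (is.numeric(ranges)) ranges <- list(ranges)
  for (r in ranges) .assert(length(r) == 2L && r[1] <= r[2],
                            "ranges must be c(lo, hi) with lo <= hi")
  if (length(ranges) > 1L) {
    m <- do.call(rbind, ranges)
    m <- m[order(m[, 1]), , drop = FALSE]
    .assert(all(m[-1, 1] > m[-nrow(m), 2]),
            "residue ranges overlap within domain '%s'", name)
  }
  structure(list(name = name, ranges = ranges, scope = scope, chain = chain),
            class = "DomainDefinition")
}

#' Standard Cas9 domain boundaries
#'
#' @return Named list of [domain_definition()]s for `REC3` and `HNH`.
#' @export
cas9_domains <- function() {
  list(REC3 = domain_definition("REC3", c(498, 718)),
       HNH = domain_definition("HNH", c(775, 908)))
}

.domain_indices <- function(struct, dom) {
  at <- struct$atoms
  in_range <- Reduce(`|`, lapply(dom$ranges, function(r)
    at$resid >= r[1] & at$resid <= r[2]))
  if (!is.null(dom$chain)) in_range <- in_range & at$chain %in% dom$chain
  keep <- switch(dom$scope,
    heavy = toupper(at$element) != "H",
    backbone = toupper(at$name) %in% c("N", "CA", "C", "O"),
    CA = toupper(at$name) == "CA")
  idx <- at$index[in_range & keep]
  .assert(length(idx) > 0L, "domain '%s' selects no atoms", dom$name)
  idx
}

#' COM distance between two domains
#'
#' Mass-weighted centre-of-mass distance, reported in Angstroms (the
#' reporting unit of crystal-structure comparisons).
#'
#' @param x A `Structure` or `Trajectory`.
#' @param dom_a,dom_b [domain_definition()]s.
#' @return Scalar (structure) or per-frame vector (trajectory) of
#'   distances in Angstroms; attribute `domains` records the definitions.
#' @export
com_domain_distance <- function(x, dom_a, dom_b) {
  if (inherits(x, "Structure")) {
    st <- x
    traj <- trajectory_new(st, st$xyz)
    scalar <- TRUE
  } else {
    .assert(inherits(x, "Trajectory"), "x must be a Structure or Trajectory")
    traj <- x
    st <- x$structure
    scalar <- FALSE
  }
  ga <- atom_group(.domain_indices(st, dom_a), dom_a$name, "DOMAIN", st)
  gb <- atom_group(.domain_indices(st, dom_b), dom_b$name, "DOMAIN", st)
  d_nm <- com_distance_series(traj, ga, gb, mass_weighted = TRUE)
  out <- d_nm * 10
  if (scalar) out <- out[1]
  attr(out, "domains") <- list(a = dom_a, b = dom_b)
  out
}

.match_atoms <- function(ref, mobile, selection = NULL) {
  key <- function(st) paste(st$atoms$chain, st$atoms$resid, st$atoms$insert %||% "",
                            toupper(st$atoms$name))
  ka <- key(ref); kb <- key(mobile)
  if (!is.null(selection)) {
    ka_keep <- ref$atoms$index %in% selection$indices
  } else ka_keep <- rep(TRUE, nrow(ref$atoms))
  common <- intersect(ka[ka_keep], kb)
  if (length(common) == 0L) {
    miss <- head(setdiff(ka[ka_keep], kb), 10)
    stop("no matching atoms between structures; first unmatched: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ia <- match(common, ka)
  ib <- match(common, kb)
  list(ref = ia, mobile = ib, n = length(common),
       unmatched = setdiff(ka[ka_keep], kb))
}

#' Kabsch superposition and RMSD
#'
#' Least-squares optimal proper rotation (det = +1) of `mobile` onto
#' `ref` over atoms matched by chain/residue/atom name (optionally
#' restricted to a selection), with the RMSD reported in Angstroms.
#'
#' @param ref,mobile `Structure`s (or bare `n x 3` coordinate matrices in
#'   nm, taken as already matched).
#' @param selection Optional `AtomGroup` on `ref` restricting the match.
#' @param mass_weighted Mass-weight the fit.
#' @return List `rotation` (3x3), `translation` (nm), `rmsd_A`,
#'   `n_atoms`.
#' @export
kabsch_rmsd <- function(ref, mobile, selection = NULL, mass_weighted = FALSE) {
  if (is.matrix(ref) && is.matrix(mobile)) {
    X <- ref; Y <- mobile
    w <- rep(1, nrow(X))
  } else {
    .assert(inherits(ref, "Structure") && inherits(mobile, "Structure"),
            "ref and mobile must be Structures or coordinate matrices")
    mm <- .match_atoms(ref, mobile, selection)
    if (length(mm$unmatched) > 0L) {
      stop("unmatched atoms in superposition: ",
           paste(head(mm$unmatched, 10), collapse = ", "), call. = FALSE)
    }
    X <- ref$xyz[mm$ref, , drop = FALSE]
    Y <- mobile$xyz[mm$mobile, , drop = FALSE]
    w <- if (mass_weighted) ref$atoms$mass[mm$ref] else rep(1, nrow(X))
  }
  .assert(nrow(X) == nrow(Y), "coordinate sets differ in atom count")
  fit <- .kabsch_fit(X, Y, w)
  moved <- sweep(sweep(Y, 2L, fit$center_mobile) %*% fit$rotation,
                 2L, fit$center_ref, `+`)
  wn <- w / sum(w)
  rmsd_nm <- sqrt(sum(wn * rowSums((moved - X)^2)))
  list(rotation = fit$rotation,
       translation = fit$center_ref -
         as.numeric(fit$center_mobile %*% fit$rotation),
       rmsd_A = rmsd_nm * 10, n_atoms = nrow(X))
}

#' Backbone RMSD between two structures
#'
#' Convenience wrapper: matches N, CA, C, O atoms (or CA only) and
#' reports the superposed RMSD in Angstroms.
#'
#' @param ref,mobile `Structure`s.
#' @param atoms `"backbone"` or `"CA"`.
#' @param resid_range Optional residue interval `c(lo, hi)` to restrict
#'   the RMSD computation (e.g. one domain after a global fit).
#' @return As [kabsch_rmsd()].
#' @export
backbone_rmsd <- function(ref, mobile, atoms = c("backbone", "CA"),
                          resid_range = NULL) {
  atoms <- match.arg(atoms)
  expr <- if (atoms == "backbone") "name N CA C O" else "name CA"
  if (!is.null(resid_range)) {
    expr <- sprintf("%s and resid %d to %d", expr, resid_range[1],
                    resid_range[2])
  }
  sel <- select_atoms(ref, expr)
  kabsch_rmsd(ref, mobile, selection = sel)
}

#' Two-tailed Z test on effective sample sizes
#'
#' `Z = (mean1 - mean2) / sqrt(s1^2/n_eff1 + s2^2/n_eff2)`,
#' `p = 2 (1 - Phi(|Z|))`. Effective sample sizes (e.g. from
#' [integrated_autocorrelation_time()]) replace raw frame counts so
#' correlated frames do not inflate significance.
#'
#' @param samples1,samples2 Sample vectors.
#' @param n_eff1,n_eff2 Effective sample sizes (default: raw lengths).
#' @return List `z`, `p`, `mean1`, `mean2`.
#' @export
z_test_two_tailed <- function(samples1, samples2,
                              n_eff1 = length(samples1),
                              n_eff2 = length(samples2)) {
  .assert(n_eff1 >= 2 && n_eff2 >= 2, "n_eff must be at least 2")
  m1 <- mean(samples1); m2 <- mean(samples2)
  s1 <- stats::sd(samples1); s2 <- stats::sd(samples2)
  se <- sqrt(s1^2 / n_eff1 + s2^2 / n_eff2)
  z <- if (se == 0) 0 else (m1 - m2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), mean1 = m1, mean2 = m2)
}

#' Gaussian kernel density of a distance sample on a fixed grid
#'
#' @param samples Distance samples, Angstroms.
#' @param grid Evaluation grid, Angstroms (uniform).
#' @param bandwidth Kernel standard deviation, Angstroms (default:
#'   Silverman's rule).
#' @return A `DistanceDistribution`: `samples`, `grid`, `density`
#'   (normalized to integrate to 1 on the grid), `bandwidth`.
#' @export
distance_density <- function(samples, grid, bandwidth = NULL) {
  .assert(length(samples) >= 1L, "need at least one sample")
  .assert(length(grid) >= 2L && all(diff(grid) > 0), "grid must be increasing")
  if (is.null(bandwidth)) {
    bandwidth <- stats::bw.nrd0(samples)
    if (bandwidth <= 0) bandwidth <- max(diff(grid)[1], 1e-6)
  }
  dens <- vapply(grid, function(g)
    mean(stats::dnorm(g, mean = samples, sd = bandwidth)), numeric(1))
  h <- mean(diff(grid))
  total <- sum(dens) * h
  .assert(total > 0, "density vanishes on the supplied grid")
  structure(list(samples = samples, grid = grid, density = dens / total,
                 bandwidth = bandwidth),
            class = "DistanceDistribution")
}
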