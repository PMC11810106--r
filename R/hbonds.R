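## hbonds: geometric hydrogen-bond detection, frequency normalisation,
## and the PAM specificity index.

#' Hydrogen-bond geometric criteria
#'
#' An event requires donor-acceptor distance <= `da_cutoff` and
#' hydrogen-donor-acceptor angle (vertex at the donor) <= `hda_angle_cutoff`.
#'
#' @param da_cutoff Donor-acceptor distance cutoff, nm (default 0.35,
#'   i.e. 3.5 Angstroms).
#' @param hda_angle_cutoff H-D-A angle cutoff, degrees (default 30).
#' @return An `HBondCriteria` list.
#' @export
hbond_criteria <- function(da_cutoff = 0.35, hda_angle_cutoff = 30) {
  .assert(da_cutoff > 0, "da_cutoff must be positive")
  .assert(hda_angle_cutoff > 0 && hda_angle_cutoff < 90,
          "hda_angle_cutoff must be in (0, 90) degrees")
  structure(list(da_cutoff = da_cutoff, hda_angle_cutoff = hda_angle_cutoff),
            class = "HBondCriteria")
}

## Residue templates: donor atom -> attached polar hydrogens. Arginine
## guanidinium/backbone donors plus the generic fixture donor names.
.DONOR_HYDROGENS <- list(
  ARG = list(NE = c("HE"), NH1 = c("HH11", "HH12"), NH2 = c("HH21", "HH22"),
             N = c("H", "HN"))
)

## Nucleotide atom-name sets splitting acceptors into nucleobase (NB) and
## backbone/sugar (BB) classes.
.NB_ATOM_NAMES <- c("N1", "C2", "O2", "N2", "N3", "C4", "N4", "O4", "C5",
                    "C6", "N6", "O6", "N7", "C8", "N9")
.BB_ATOM_NAMES <- c("P", "OP1", "OP2", "O1P", "O2P", "O5'", "C5'", "C4'",
                    "O4'", "C3'", "O3'", "C2'", "O2'", "C1'")

.acceptor_category <- function(atoms, idx, pam_resids) {
  a <- atoms[idx + 1L, ]
  if (!(a$resid %in% pam_resids)) return("NONPAM")
  nm <- toupper(a$name)
  if (nm %in% .BB_ATOM_NAMES) "PAM_BB" else "PAM_NB"
}

.find_donor_hydrogens <- function(atoms, donor_row, override = NULL) {
  if (!is.null(override)) {
    hn <- override[[toupper(donor_row$name)]]
  } else {
    tmpl <- .DONOR_HYDROGENS[[toupper(donor_row$resname)]]
    hn <- if (is.null(tmpl)) NULL else tmpl[[toupper(donor_row$name)]]
  }
  if (is.null(hn)) {
    ## fall back: hydrogens of the same residue whose name extends the
    ## donor's heavy-atom name with an H prefix (NE -> HE, N9 -> H9 ...)
    stem <- sub("^[A-Z]", "H", toupper(donor_row$name))
    hn <- stem
  }
  hit <- which(atoms$resid == donor_row$resid &
               atoms$chain == donor_row$chain &
               toupper(atoms$name) %in% toupper(hn))
  atoms$index[hit]
}

.angle_deg <- function(v1, v2) {
  c1 <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, c1))) * 180 / pi
}

#' Detect hydrogen bonds along a trajectory
#'
#' Enumerates (donor, hydrogen, acceptor) triples from the donor group
#' (heavy atoms; attached hydrogens resolved through arginine-style
#' residue templates) and the acceptor group, and marks an event in each
#' frame where both geometric criteria hold.
#'
#' @param traj A `Trajectory` (or single-frame `Structure`).
#' @param donors `AtomGroup` of donor heavy atoms (hydrogens resolved
#'   automatically).
#' @param acceptors `AtomGroup` of acceptor O/N atoms.
#' @param criteria An [hbond_criteria()].
#' @param pam_resids Residue numbers forming the PAM; acceptors in these
#'   residues are tagged `PAM_NB`/`PAM_BB` by atom class, all others
#'   `NONPAM`.
#' @param donor_hydrogens Optional named list overriding the residue
#'   template (donor atom name -> hydrogen names).
#' @return An `HBondEventTable`: `triples` data frame (indices, names,
#'   `category`) and binary `events` matrix (frames x triples), plus `dt`.
#' @export
detect_hbonds <- function(traj, donors, acceptors, criteria = hbond_criteria(),
                          pam_resids = integer(0), donor_hydrogens = NULL) {
  if (inherits(traj, "Structure")) traj <- trajectory_new(traj, traj$xyz)
  .assert(inherits(traj, "Trajectory"), "traj must be a Trajectory")
  .assert(inherits(criteria, "HBondCriteria"), "criteria must be HBondCriteria")
  atoms <- traj$structure$atoms

  triples <- list()
  for (d in donors$indices) {
    drow <- atoms[d + 1L, ]
    hyd <- .find_donor_hydrogens(atoms, drow, donor_hydrogens)
    .assert(length(hyd) > 0L,
            "donor %s/%s%d has no attached hydrogen in the topology",
            drow$name, drow$resname, drow$resid)
    for (h in hyd) for (a in acceptors$indices) {
      if (a == d) next
      triples[[length(triples) + 1L]] <- data.frame(
        donor = d, hydrogen = h, acceptor = a,
        donor_name = drow$name, acceptor_name = atoms$name[a + 1L],
        acceptor_resid = atoms$resid[a + 1L],
        category = .acceptor_category(atoms, a, pam_resids),
        stringsAsFactors = FALSE)
    }
  }
  .assert(length(triples) > 0L, "no donor-acceptor triples to test")
  triples <- do.call(rbind, triples)

  nf <- n_frames(traj)
  events <- matrix(0L, nf, nrow(triples))
  for (f in seq_len(nf)) {
    fr <- traj$coords[f, , , drop = TRUE]
    if (is.null(dim(fr))) fr <- matrix(fr, ncol = 3L)
    for (t in seq_len(nrow(triples))) {
      D <- fr[triples$donor[t] + 1L, ]
      H <- fr[triples$hydrogen[t] + 1L, ]
      A <- fr[triples$acceptor[t] + 1L, ]
      dda <- sqrt(sum((D - A)^2))
      if (dda > criteria$da_cutoff) next
      if (.angle_deg(H - D, A - D) <= criteria$hda_angle_cutoff)
        events[f, t] <- 1L
    }
  }
  structure(list(triples = triples, events = events,
                 dt = attr(traj, "dt")),
            class = "HBondEventTable")
}

#' Per-category hydrogen-bond frequencies
#'
#' Frequency = event frames / total frames with any-triple semantics per
#' category (a frame counts once per category however many triples bond),
#' consistent with the contact-category aggregation.
#'
#' @param table An `HBondEventTable`.
#' @param categories Categories to report (default the canonical three).
#' @return Named numeric vector of raw frequencies in [0,1].
#' @export
hbond_frequencies <- function(table,
                              categories = c("PAM_NB", "PAM_BB", "NONPAM")) {
  .assert(inherits(table, "HBondEventTable"), "table must be an HBondEventTable")
  vapply(categories, function(cat) {
    cols <- which(table$triples$category == cat)
    if (length(cols) == 0L) return(0)
    mean(rowSums(table$events[, cols, drop = FALSE]) > 0)
  }, numeric(1))
}

#' Normalise frequencies to fractions summing to one
#'
#' @param freqs Non-negative frequencies (named vector).
#' @return `freqs / sum(freqs)`; error if all entries are zero.
#' @export
normalize_frequencies <- function(freqs) {
  .assert(all(freqs >= 0), "frequencies must be non-negative")
  s <- sum(freqs)
  .assert(s > 0, "cannot normalise: all frequencies are zero")
  freqs / s
}

#' Specificity index
#'
#' Ratio of an arginine's hydrogen-bond frequency with the PAM
#' nucleotides to its frequency with non-PAM residues:
#' `(f_pam + eps) / (f_nonpam + eps)`. With the default `eps = 0` a zero
#' denominator against a positive numerator is reported as `Inf`.
#'
#' @param f_pam,f_nonpam Frequencies (>= 0).
#' @param epsilon Pseudocount added to both terms.
#' @return The ratio (possibly `Inf`).
#' @export
specificity_index <- function(f_pam, f_nonpam, epsilon = 0) {
  .assert(f_pam >= 0 && f_nonpam >= 0, "frequencies must be non-negative")
  .assert(epsilon >= 0, "epsilon must be non-negative")
  num <- f_pam + epsilon
  den <- f_nonpam + epsilon
  if (den == 0) {
    if (num == 0) return(NaN)
    return(Inf)
  }
  num / den
}
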