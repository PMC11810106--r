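## io_selection: structures, trajectories, time series, atom selections.
##
## Internal units everywhere: nm, ps, kJ/mol, K. Angstroms appear only at
## the PDB boundary (on read they are converted to nm; on write back to A)
## and in reporting helpers that say so in their names.

.ELEMENT_MASS <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
  S = 32.06, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  `NA` = 22.990, K = 39.098, MG = 24.305, CA = 40.078, MN = 54.938,
  FE = 55.845, ZN = 65.38, CU = 63.546, SE = 78.971
)

## Infer the element from PDB metadata; fall back to the atom name with
## the usual heuristic (leading digits stripped, greek remoteness letters
## after the first character ignored).
.infer_element <- function(name, elesy = NULL) {
  el <- toupper(trimws(elesy %||% ""))
  name <- toupper(gsub("^[0-9']+", "", trimws(name)))
  out <- character(length(name))
  for (i in seq_along(name)) {
    e <- if (length(el) >= i) el[i] else ""
    if (nzchar(e) && e %in% names(.ELEMENT_MASS)) {
      out[i] <- e
    } else {
      two <- substr(name[i], 1L, 2L)
      one <- substr(name[i], 1L, 1L)
      # two-letter symbols only when the name cannot be a remoteness code
      if (two %in% c("CL", "BR", "MG", "ZN", "FE", "MN", "SE", "CU") ||
          (two %in% c("NA", "CA", "K ") && nchar(name[i]) == 2L &&
           !grepl("[A-Z]", substr(name[i], 3L, 3L)))) {
        out[i] <- trimws(two)
      } else {
        out[i] <- one
      }
    }
  }
  out
}

.element_mass <- function(element) {
  m <- .ELEMENT_MASS[element]
  unname(ifelse(is.na(m), 12.011, m))  # unknown atoms get a carbon-like mass
}

#' Construct a molecular structure
#'
#' A `Structure` couples an atom-metadata table with one set of 3D
#' coordinates in nanometres. It is the topology object every trajectory
#' and selection operates on.
#'
#' @param atoms Data frame with columns `name`, `resid` (author residue
#'   number), `resname`, `chain`, and optionally `element`, `mass`
#'   (amu) and `charge` (e). Missing elements/masses are inferred from
#'   atom names.
#' @param xyz Numeric matrix, one row per atom, columns x/y/z in nm.
#' @return An object of class `Structure` with 0-based `atoms$index`.
#' @export
structure_new <- function(atoms, xyz) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  xyz <- as.matrix(xyz)
  .assert(nrow(atoms) >= 1L, "structure must contain at least one atom")
  .assert(nrow(xyz) == nrow(atoms) && ncol(xyz) == 3L,
          "coords must be an n_atoms x 3 matrix (got %d x %d for %d atoms)",
          nrow(xyz), ncol(xyz), nrow(atoms))
  .assert(all(is.finite(xyz)), "coordinates must be finite")
  for (col in c("name", "resid", "resname", "chain")) {
    .assert(col %in% names(atoms), "atoms table lacks column '%s'", col)
  }
  if (is.null(atoms$element)) atoms$element <- .infer_element(atoms$name)
  if (is.null(atoms$mass)) atoms$mass <- .element_mass(atoms$element)
  .assert(all(atoms$mass > 0), "atom masses must be positive")
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  atoms$index <- seq_len(nrow(atoms)) - 1L
  atoms$resid <- as.integer(atoms$resid)
  rownames(atoms) <- NULL
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              paste(unique(x$atoms$chain), collapse = " ")))
  invisible(x)
}

#' Construct a trajectory
#'
#' Ordered frames of coordinates over one topology, with strictly
#' increasing times on a uniform grid.
#'
#' @param struct A [structure_new()] topology.
#' @param coords Array `frames x atoms x 3`, nm.
#' @param times Frame times, ps; strictly increasing, uniform step.
#' @return Object of class `Trajectory` (fields `structure`, `coords`,
#'   `times`, attribute `dt` in ps).
#' @export
trajectory_new <- function(struct, coords, times = NULL) {
  .assert(inherits(struct, "Structure"), "struct must be a Structure")
  if (length(dim(coords)) == 2L) coords <- array(coords, c(1L, dim(coords)))
  .assert(length(dim(coords)) == 3L && dim(coords)[3] == 3L,
          "coords must be frames x atoms x 3")
  .assert(dim(coords)[2] == nrow(struct$atoms),
          "coords atom dimension (%d) does not match topology (%d)",
          dim(coords)[2], nrow(struct$atoms))
  nf <- dim(coords)[1]
  if (is.null(times)) times <- seq_len(nf) - 1
  .assert(length(times) == nf, "times length must equal frame count")
  if (nf > 1L) {
    dts <- diff(times)
    .assert(all(dts > 0), "times must be strictly increasing")
    .assert(max(abs(dts - dts[1])) <= 1e-9 + 1e-6 * dts[1],
            "time step must be uniform")
    dt <- dts[1]
  } else dt <- NA_real_
  structure(list(structure = struct, coords = coords, times = as.numeric(times)),
            class = "Trajectory", dt = dt)
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, dt = %s ps\n",
              dim(x$coords)[1], dim(x$coords)[2],
              format(attr(x, "dt"))))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `Trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

## ---------------------------------------------------------------------------
## PDB reading/writing (bio3d behind the module surface)

.validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in idx) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (anyNA(xyz)) {
      stop(sprintf("malformed PDB coordinate record at line %d: %s",
                   i, trimws(lines[i])), call. = FALSE)
    }
  }
  length(idx)
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records, resolves alternate locations to the
#' highest-occupancy conformer, and converts coordinates from Angstroms
#' to nanometres. Residue numbers are kept exactly as authored.
#'
#' @param path Path to a PDB file.
#' @param model Model number to extract from a multi-model file (1-based).
#' @return A [structure_new()] object.
#' @export
read_structure <- function(path, model = 1L) {
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  n_atom_rec <- .validate_pdb_lines(lines)
  .assert(n_atom_rec > 0L, "no ATOM/HETATM records in %s", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  nmodels <- nrow(pdb$xyz)
  .assert(model >= 1L && model <= nmodels,
          "model %d requested but file has %d model(s)", model, nmodels)
  at <- pdb$atom
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  ## resolve altlocs: keep the highest-occupancy record per atom site
  alt <- at$alt
  if (any(!is.na(alt) & alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[duplicated(key)])) {
      rows <- which(key == k)
      if (length(rows) > 1L) {
        best <- rows[which.max(occ[rows])]
        keep[setdiff(rows, best)] <- FALSE
      }
    }
    at <- at[keep, , drop = FALSE]
    xyz <- xyz[keep, , drop = FALSE]
  }
  atoms <- data.frame(
    name = trimws(at$elety), resid = at$resno,
    resname = trimws(at$resid), chain = ifelse(is.na(at$chain), "", at$chain),
    insert = ifelse(is.na(at$insert), "", at$insert),
    stringsAsFactors = FALSE
  )
  atoms$element <- .infer_element(atoms$name, at$elesy)
  atoms$mass <- .element_mass(atoms$element)
  structure_new(atoms, xyz * 0.1)  # A -> nm
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL becomes one frame; coordinates are converted to nm. This is
#' the toolkit's native text trajectory format, so the analysis stack runs
#' with no binary-format dependencies; binary readers can be plugged in via
#' [trajectory_new()].
#'
#' @param path Multi-model PDB file.
#' @param dt Frame spacing in ps (PDB stores no times).
#' @return A `Trajectory`.
#' @export
read_trajectory <- function(path, dt = 1) {
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  .validate_pdb_lines(lines)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  nf <- nrow(pdb$xyz)
  ref <- read_structure(path, model = 1L)
  coords <- array(NA_real_, c(nf, nrow(ref$atoms), 3L))
  for (f in seq_len(nf)) {
    coords[f, , ] <- matrix(pdb$xyz[f, ], ncol = 3L, byrow = TRUE) * 0.1
  }
  trajectory_new(ref, coords, times = (seq_len(nf) - 1) * dt)
}

.format_pdb_atom <- function(i, a, xyz_A) {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i %% 100000L,
          ifelse(nchar(a$name) < 4L, paste0(" ", a$name), a$name),
          substr(a$resname, 1, 3), substr(paste0(a$chain, "A"), 1, 1),
          a$resid %% 10000L, xyz_A[1], xyz_A[2], xyz_A[3], 1, 0,
          substr(a$element, 1, 2))
}

#' Write a trajectory (or structure) as a multi-model PDB file
#'
#' @param x A `Trajectory` or `Structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_frames <- function(x, path) {
  if (inherits(x, "Structure")) x <- trajectory_new(x, x$xyz)
  .assert(inherits(x, "Trajectory"), "x must be a Trajectory or Structure")
  at <- x$structure$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(x))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    for (i in seq_len(nrow(at))) {
      writeLines(.format_pdb_atom(i, at[i, ], x$coords[f, i, ] * 10), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Whitespace time series (XVG dialect)

#' Read a whitespace-delimited time series (XVG dialect)
#'
#' Lines starting with `#` or `@` are ignored. Column 1 is time (ps),
#' remaining columns are values (kJ/mol or nm depending on content).
#'
#' @param path Input file.
#' @return List with `times` and `values` (vector, or matrix if the file
#'   has more than two columns).
#' @export
read_timeseries <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))]
  .assert(length(lines) > 0L, "no data rows in %s", path)
  fields <- strsplit(trimws(lines), "\\s+")
  ncols <- lengths(fields)
  .assert(all(ncols == ncols[1]),
          "ragged rows in %s (first at data row %d)",
          path, which(ncols != ncols[1])[1])
  .assert(ncols[1] >= 2L, "need at least a time and one value column")
  m <- matrix(as.numeric(unlist(fields)), ncol = ncols[1], byrow = TRUE)
  .assert(!anyNA(m), "non-numeric field in %s", path)
  times <- m[, 1]
  .assert(all(diff(times) > 0), "times must be strictly increasing in %s", path)
  values <- if (ncol(m) == 2L) m[, 2] else m[, -1, drop = FALSE]
  list(times = times, values = values)
}

#' Write a time series in the XVG text dialect
#'
#' @param times Time values, ps.
#' @param values Vector or matrix of values.
#' @param path Output path.
#' @param comment Optional header comment (written with a leading `#`).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(times, values, path, comment = NULL) {
  values <- as.matrix(values)
  .assert(length(times) == nrow(values), "times/values length mismatch")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  m <- cbind(times, values)
  writeLines(apply(m, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Atom selections

#' Construct an atom group
#'
#' @param indices 0-based atom indices into a structure.
#' @param label Human-readable label.
#' @param role Semantic role tag: one of `ARG_GUANIDINIUM`, `PAM_NB`,
#'   `PAM_BB`, `NONPAM`, `DOMAIN`, `OTHER`.
#' @param struct Optional structure for validation.
#' @return Object of class `AtomGroup`.
#' @export
atom_group <- function(indices, label = "group", role = "OTHER", struct = NULL) {
  roles <- c("ARG_GUANIDINIUM", "PAM_NB", "PAM_BB", "NONPAM", "DOMAIN", "OTHER")
  .assert(role %in% roles, "unknown role '%s'", role)
  indices <- sort(unique(as.integer(indices)))
  .assert(length(indices) > 0L, "atom group '%s' is empty", label)
  if (!is.null(struct)) {
    .assert(all(indices >= 0L & indices < nrow(struct$atoms)),
            "group '%s' has indices outside the structure", label)
  }
  structure(list(label = label, indices = indices, role = role),
            class = "AtomGroup")
}

#' @export
print.AtomGroup <- function(x, ...) {
  cat(sprintf("AtomGroup '%s' (%s): %d atoms\n", x$label, x$role,
              length(x$indices)))
  invisible(x)
}

## Selection grammar:
##   expr    := term ('or' term)*
##   term    := factor ('and' factor)*
##   factor  := 'not' factor | '(' expr ')' | primitive
##   primitive := ('resid'|'resname'|'name'|'chain') value+ | 'all'
##   value for resid may be 'a to b' ranges; other keys take literal lists.
.sel_tokenize <- function(expr) {
  expr <- gsub("\\(", " ( ", expr)
  expr <- gsub("\\)", " ) ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  .assert(length(toks) > 0L, "empty selection expression")
  toks
}

.sel_parse <- function(toks, struct) {
  pos <- 1L
  n <- length(toks)
  peek <- function() if (pos <= n) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  keywords <- c("resid", "resname", "name", "chain", "and", "or", "not",
                "(", ")", "all", "to")

  parse_primitive <- function() {
    kw <- advance()
    at <- struct$atoms
    if (identical(kw, "all")) return(rep(TRUE, nrow(at)))
    .assert(kw %in% c("resid", "resname", "name", "chain"),
            "selection: unexpected token '%s'", kw)
    vals <- character(0)
    while (!is.na(peek()) && !(peek() %in% keywords)) vals <- c(vals, advance())
    ## 'a to b' residue ranges
    if (kw == "resid" && identical(peek(), "to")) {
      advance()
      .assert(!is.na(peek()), "selection: 'to' needs an upper bound")
      hi <- advance()
      lo <- vals[length(vals)]
      vals <- vals[-length(vals)]
      lo <- suppressWarnings(as.integer(lo)); hi <- suppressWarnings(as.integer(hi))
      .assert(!is.na(lo) && !is.na(hi), "selection: non-integer residue range")
      rng <- if (lo <= hi) lo:hi else integer(0)
      vals <- c(vals, as.character(rng))
      while (!is.na(peek()) && !(peek() %in% keywords)) vals <- c(vals, advance())
    }
    .assert(length(vals) > 0L, "selection: '%s' needs at least one value", kw)
    switch(kw,
      resid   = at$resid %in% suppressWarnings(as.integer(vals)),
      resname = toupper(at$resname) %in% toupper(vals),
      name    = toupper(at$name) %in% toupper(vals),
      chain   = toupper(at$chain) %in% toupper(vals))
  }

  parse_factor <- function() {
    t <- peek()
    if (identical(t, "not")) { advance(); return(!parse_factor()) }
    if (identical(t, "(")) {
      advance()
      m <- parse_expr()
      .assert(identical(peek(), ")"), "selection: missing ')'")
      advance()
      return(m)
    }
    parse_primitive()
  }

  parse_term <- function() {
    m <- parse_factor()
    while (identical(peek(), "and")) { advance(); m <- m & parse_factor() }
    m
  }

  parse_expr <- function() {
    m <- parse_term()
    while (identical(peek(), "or")) { advance(); m <- m | parse_term() }
    m
  }

  m <- parse_expr()
  .assert(pos > n, "selection: trailing tokens from '%s'", peek())
  m
}

#' Select atoms by expression
#'
#' Grammar: `resid`/`resname`/`name`/`chain` filters with value lists,
#' `resid a to b` ranges, `and`/`or`/`not`, parentheses, `all`. Examples:
#' `"resid 3 and name O6 N7"` (guanine major-groove acceptors),
#' `"name OP1 OP2 P"` (backbone phosphate groups).
#'
#' @param struct A `Structure`.
#' @param expr Selection expression (character).
#' @param label Label for the resulting group (defaults to `expr`).
#' @param role Role tag, see [atom_group()].
#' @return An `AtomGroup`; error if the selection is empty.
#' @export
select_atoms <- function(struct, expr, label = expr, role = "OTHER") {
  .assert(inherits(struct, "Structure"), "struct must be a Structure")
  mask <- .sel_parse(.sel_tokenize(tolower(expr)), struct)
  idx <- struct$atoms$index[mask]
  .assert(length(idx) > 0L, "selection '%s' matched no atoms", expr)
  atom_group(idx, label = label, role = role, struct = struct)
}
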