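# Multi-model PDB input/output and chymotrypsin-numbering-aware atom
# selection. Parsing and formatting delegate to bio3d; this layer adds the
# ensemble container, roster validation and the selection mini-language.

.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, CA = 40.078, MG = 24.305, ZN = 65.38,
  FE = 55.845, MN = 54.938, CU = 63.546, `NA` = 22.990, K = 39.098,
  CL = 35.45, BR = 79.904, I = 126.904, F = 18.998
)

#' Atomic mass lookup
#'
#' Resolves element symbols to atomic masses (unified atomic mass units)
#' using a fixed internal table. Unknown elements fall back to the mass of
#' carbon (12.011 u) with a warning, so that mass-weighted analyses never
#' fail on nonstandard records.
#'
#' @param element Character vector of element symbols (e.g. `"C"`, `"CA"`).
#' @return Numeric vector of masses in u.
#' @export
element_mass <- function(element) {
  key <- toupper(trimws(element))
  m <- .element_masses[key]
  unknown <- is.na(m) | key == ""
  if (any(unknown)) {
    warning("unknown element(s) ",
            paste(unique(key[unknown]), collapse = ", "),
            "; defaulting to 12.011 u")
    m[unknown] <- 12.011
  }
  unname(m)
}

# Guess the element symbol from a PDB atom name when the element column is
# blank (first alphabetic character that is not a digit; two-letter symbols
# like CA-the-ion must come from the element column, so plain names map to
# one-letter elements).
.element_from_name <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  toupper(substr(nm, 1, 1))
}

.residue_key <- function(resno, insert) paste0(resno, ifelse(insert == "", "", insert))

.atom_key <- function(atoms) {
  paste(atoms$chain_id, atoms$residue_number, atoms$insertion_code,
        atoms$atom_name, sep = "|")
}

#' @noRd
new_structure <- function(atoms, xyz, label = "") {
  stopifnot(is.data.frame(atoms), is.matrix(xyz), ncol(xyz) == 3,
            nrow(xyz) == nrow(atoms))
  if (!all(is.finite(xyz))) stop("non-finite coordinates in structure")
  obj <- list(atoms = atoms, xyz = xyz, label = label, meta = list())
  class(obj) <- "zymo_structure"
  obj
}

#' @noRd
new_ensemble <- function(reference, coords, times = NULL, label = "") {
  stopifnot(inherits(reference, "zymo_structure"),
            length(dim(coords)) == 3,
            dim(coords)[1] == nrow(reference$atoms),
            dim(coords)[2] == 3)
  t_frames <- dim(coords)[3]
  if (t_frames < 1) stop("an ensemble needs at least one frame")
  if (is.null(times)) times <- seq_len(t_frames)
  obj <- list(reference = reference, coords = coords,
              frame_times = times, label = label, meta = list())
  class(obj) <- "zymo_ensemble"
  obj
}

#' Number of frames in an ensemble
#' @param ensemble A `zymo_ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(ensemble) {
  stopifnot(inherits(ensemble, "zymo_ensemble"))
  dim(ensemble$coords)[3]
}

#' Extract one frame of an ensemble as a coordinate matrix
#' @param ensemble A `zymo_ensemble`.
#' @param i Frame index.
#' @return N x 3 coordinate matrix (Angstrom).
#' @export
get_frame <- function(ensemble, i) {
  stopifnot(inherits(ensemble, "zymo_ensemble"))
  ensemble$coords[, , i, drop = TRUE]
}

#' @export
print.zymo_structure <- function(x, ...) {
  cat("Structure", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      "\n  atoms:   ", nrow(x$atoms),
      "\n  residues:", length(unique(.residue_key(x$atoms$residue_number,
                                                  x$atoms$insertion_code))),
      "\n  chains:  ", paste(unique(x$atoms$chain_id), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.zymo_ensemble <- function(x, ...) {
  cat("Ensemble", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      "\n  frames:", n_frames(x), "\n  atoms: ", nrow(x$reference$atoms), "\n")
  invisible(x)
}

# Pre-parse validation pass: malformed coordinate fields are reported with
# their line number; atom counts per MODEL must agree.
.validate_pdb_lines <- function(lines, path) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in '", path, "'")
  at <- which(is_atom)
  for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
    val <- suppressWarnings(as.numeric(substr(lines[at], fld[1], fld[2])))
    bad <- which(is.na(val))
    if (length(bad) > 0) {
      stop("malformed coordinate field at line ", at[bad[1]], " of '",
           path, "': '", lines[at[bad[1]]], "'")
    }
  }
  model_starts <- grepl("^MODEL", lines)
  if (any(model_starts)) {
    model_id <- cumsum(model_starts)
    counts <- table(model_id[is_atom & model_id > 0])
    if (length(unique(as.integer(counts))) > 1) {
      stop("inconsistent atom roster across models in '", path,
           "': counts ", paste(as.integer(counts), collapse = ", "))
    }
  }
  sum(model_starts)
}

#' Read a structure or multi-model ensemble from a PDB file
#'
#' Parses ATOM/HETATM records (fixed-width wwPDB v3.3) preserving insertion
#' codes, with MODEL/ENDMDL boundaries defining frames. Alternate locations
#' other than blank or "A" are discarded (bio3d policy), hydrogens are
#' dropped by default, and an optional chain filter is applied. Numbering is
#' taken verbatim from the file; no renumbering is performed.
#'
#' @param path Path to a PDB file.
#' @param model_policy `"first"` returns a single [zymo_structure][read_structure]
#'   from the first model; `"all"` returns a `zymo_ensemble` with one frame
#'   per model (all models must share the atom roster).
#' @param chain Optional chain identifier(s) to keep.
#' @param drop_hydrogens Drop H/D atoms on read (default `TRUE`).
#' @param label Label attached to the returned object (defaults to the file
#'   base name).
#' @return A `zymo_structure` or, for `model_policy = "all"` on a
#'   multi-model file, a `zymo_ensemble`.
#' @export
read_structure <- function(path, model_policy = c("first", "all"),
                           chain = NULL, drop_hydrogens = TRUE,
                           label = NULL) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  n_models <- .validate_pdb_lines(lines, path)
  multi <- n_models > 1
  pdb <- bio3d::read.pdb(path, multi = multi, rm.alt = TRUE, verbose = FALSE)

  a <- pdb$atom
  insert <- ifelse(is.na(a$insert), "", a$insert)
  elesy <- ifelse(is.na(a$elesy) | trimws(a$elesy) == "",
                  .element_from_name(a$elety), trimws(a$elesy))
  keep <- rep(TRUE, nrow(a))
  if (drop_hydrogens) keep <- keep & !(toupper(elesy) %in% c("H", "D"))
  if (!is.null(chain)) keep <- keep & (a$chain %in% chain)
  if (!any(keep)) stop("no atoms left after chain/hydrogen filtering")

  atoms <- data.frame(
    atom_name = a$elety[keep],
    residue_name = a$resid[keep],
    chain_id = ifelse(is.na(a$chain[keep]), "", a$chain[keep]),
    residue_number = a$resno[keep],
    insertion_code = insert[keep],
    element = elesy[keep],
    b_factor = ifelse(is.na(a$b[keep]), 0, a$b[keep]),
    stringsAsFactors = FALSE
  )
  atoms$mass <- suppressWarnings(element_mass(atoms$element))
  if (anyDuplicated(.atom_key(atoms)) > 0) {
    stop("duplicate (chain, residue, insertion code, atom name) records ",
         "within a model")
  }
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))

  xyz_cols <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1,
                              3 * which(keep)))
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  xyz <- xyz[, xyz_cols, drop = FALSE]
  n_at <- nrow(atoms)
  t_frames <- nrow(xyz)

  frame_mat <- function(row) matrix(xyz[row, ], ncol = 3, byrow = TRUE)
  if (model_policy == "first" || t_frames == 1) {
    return(new_structure(atoms, frame_mat(1), label))
  }
  coords <- array(NA_real_, dim = c(n_at, 3, t_frames))
  for (t in seq_len(t_frames)) coords[, , t] <- frame_mat(t)
  new_ensemble(new_structure(atoms, frame_mat(1), label), coords,
               label = label)
}

.check_pdb_range <- function(xyz) {
  if (any(xyz >= 10000 | xyz <= -1000)) {
    stop("coordinate exceeds the PDB fixed-width field (must lie in ",
         "(-1000, 10000) Angstrom)")
  }
}

.write_models <- function(atoms, xyz_rows, path) {
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz_rows,
    resno = atoms$residue_number, resid = atoms$residue_name,
    eleno = seq_len(nrow(atoms)), elety = atoms$atom_name,
    chain = atoms$chain_id, insert = atoms$insertion_code,
    b = atoms$b_factor, elesy = atoms$element
  )
  invisible(path)
}

#' Write a structure to a single-model PDB file
#' @param structure A `zymo_structure`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "zymo_structure"))
  .check_pdb_range(structure$xyz)
  .write_models(structure$atoms, matrix(t(structure$xyz), nrow = 1), path)
}

#' Write an ensemble to a multi-model PDB file
#'
#' Emits one MODEL/ENDMDL block per frame; coordinates are stored at PDB
#' precision (0.001 Angstrom), so a read/write round trip reproduces them to
#' three decimals.
#'
#' @param ensemble A `zymo_ensemble`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "zymo_ensemble"))
  .check_pdb_range(ensemble$coords)
  t_frames <- n_frames(ensemble)
  n_at <- nrow(ensemble$reference$atoms)
  rows <- matrix(NA_real_, nrow = t_frames, ncol = 3 * n_at)
  for (t in seq_len(t_frames)) rows[t, ] <- as.vector(t(ensemble$coords[, , t]))
  .write_models(ensemble$reference$atoms, rows, path)
}

#' Default region map for trypsin-like protease domains
#'
#' Named residue ranges in chymotrypsin numbering: activation loops
#' AL1 (144-152), AL2 (184-193), AL3 (221A-226), the 215-217 segment, the
#' N-terminal tail (16-18), the S1 rim (190-195) and a configurable
#' 170-loop window.
#'
#' @param loop_170 Range string for the 170-loop (default `"165-175"`,
#'   spanning any 170A-170C insertion-coded residues present).
#' @return Named character vector of `"start-end"` residue ranges; range
#'   endpoints may carry insertion codes (e.g. `"221A-226"`).
#' @export
region_map <- function(loop_170 = "165-175") {
  c(AL1 = "144-152", AL2 = "184-193", AL3 = "221A-226",
    segment_215_217 = "215-217", n_tail = "16-18", s1_rim = "190-195",
    loop_170 = loop_170)
}

.parse_resid_token <- function(token) {
  m <- regmatches(token, regexec("^(-?[0-9]+)([A-Za-z]?)$", token))[[1]]
  if (length(m) == 0) stop("malformed residue identifier '", token, "'")
  list(resno = as.integer(m[2]), insert = toupper(m[3]))
}

# Residues in file order, as keys "resno|insert"
.residue_order <- function(atoms) {
  unique(paste(atoms$residue_number, atoms$insertion_code, sep = "|"))
}

.select_resid_range <- function(atoms, range_str) {
  parts <- strsplit(range_str, "-(?=[0-9])", perl = TRUE)[[1]]
  if (length(parts) == 1) parts <- c(parts, parts)
  lo <- .parse_resid_token(parts[1])
  hi <- .parse_resid_token(parts[2])
  if (lo$insert == "" && hi$insert == "") {
    return(atoms$residue_number >= lo$resno & atoms$residue_number <= hi$resno)
  }
  # Insertion-coded endpoint: span in file order between the endpoints.
  ord <- .residue_order(atoms)
  key_lo <- paste(lo$resno, lo$insert, sep = "|")
  key_hi <- paste(hi$resno, hi$insert, sep = "|")
  i_lo <- match(key_lo, ord)
  i_hi <- match(key_hi, ord)
  if (is.na(i_lo) || is.na(i_hi)) {
    stop("residue range endpoint not present in structure: '", range_str, "'")
  }
  span <- ord[seq(min(i_lo, i_hi), max(i_lo, i_hi))]
  paste(atoms$residue_number, atoms$insertion_code, sep = "|") %in% span
}

.select_term <- function(atoms, term, regions) {
  term <- trimws(term)
  if (term == "all") return(rep(TRUE, nrow(atoms)))
  if (term == "heavy") return(!(toupper(atoms$element) %in% c("H", "D")))
  if (term == "calpha") {
    return(atoms$atom_name == "CA" & toupper(atoms$element) == "C")
  }
  kv <- strsplit(term, "\\s+")[[1]]
  if (length(kv) != 2) stop("cannot parse selection term '", term, "'")
  value <- kv[2]
  switch(kv[1],
    name = atoms$atom_name %in% strsplit(value, ",")[[1]],
    elem = toupper(atoms$element) %in% toupper(strsplit(value, ",")[[1]]),
    chain = atoms$chain_id %in% strsplit(value, ",")[[1]],
    resid = .select_resid_range(atoms, value),
    region = {
      if (!value %in% names(regions)) {
        stop("unknown region '", value, "'; known: ",
             paste(names(regions), collapse = ", "))
      }
      .select_resid_range(atoms, regions[[value]])
    },
    stop("unknown selection keyword '", kv[1], "'")
  )
}

#' Select atoms with a small conjunctive mini-language
#'
#' Terms joined by `" and "` are intersected. Supported terms:
#' `"all"`, `"heavy"` (non-hydrogen), `"calpha"` (carbon CA atoms, excludes
#' calcium ions), `"name CA,CB"`, `"elem C,N"`, `"chain A"`,
#' `"resid 144-152"` (endpoints may carry insertion codes, e.g.
#' `"resid 221A-226"`, resolved by file order), and `"region AL1"` against a
#' [region_map()].
#'
#' @param x A `zymo_structure` or `zymo_ensemble`.
#' @param selection Selection string; `NULL` selects everything.
#' @param regions Named ranges used by `"region"` terms
#'   (default [region_map()]).
#' @return Ordered integer indices into the atom roster. Selecting zero
#'   atoms is an error, never silent.
#' @export
select_atoms <- function(x, selection = NULL, regions = region_map()) {
  atoms <- if (inherits(x, "zymo_ensemble")) x$reference$atoms
           else if (inherits(x, "zymo_structure")) x$atoms
           else stop("x must be a zymo_structure or zymo_ensemble")
  if (is.null(selection)) return(seq_len(nrow(atoms)))
  terms <- strsplit(selection, "\\s+and\\s+")[[1]]
  keep <- rep(TRUE, nrow(atoms))
  for (tm in terms) keep <- keep & .select_term(atoms, tm, regions)
  idx <- which(keep)
  if (length(idx) == 0) {
    stop("selection '", selection, "' matched zero atoms")
  }
  idx
}

#' Pair atoms of two structures by identity
#'
#' Matches atoms on (chain, residue number, insertion code, atom name);
#' used to compare numbering-consistent constructs without sequence
#' alignment.
#'
#' @param atoms_a,atoms_b Atom tables (`$atoms` of a `zymo_structure`).
#' @param require_all Error if any atom of `atoms_a` is unmatched.
#' @return List with integer vectors `idx_a`, `idx_b` of equal length, in
#'   `atoms_a` order.
#' @export
pair_atoms <- function(atoms_a, atoms_b, require_all = TRUE) {
  key <- function(at) paste(at$residue_number, at$insertion_code,
                            at$atom_name, sep = "|")
  ka <- key(atoms_a)
  kb <- key(atoms_b)
  if (anyDuplicated(ka) || anyDuplicated(kb)) {
    ka <- paste(atoms_a$chain_id, ka, sep = "|")
    kb <- paste(atoms_b$chain_id, kb, sep = "|")
  }
  m <- match(ka, kb)
  if (require_all && anyNA(m)) {
    stop("atom pairing failed for ", sum(is.na(m)), " atom(s), e.g. ",
         ka[which(is.na(m))[1]])
  }
  keep <- which(!is.na(m))
  list(idx_a = keep, idx_b = m[keep])
}

#' Subset a structure to an atom index set
#' @param structure A `zymo_structure`.
#' @param idx Atom indices to keep (order preserved).
#' @return A `zymo_structure`.
#' @export
subset_structure <- function(structure, idx) {
  stopifnot(inherits(structure, "zymo_structure"))
  out <- new_structure(structure$atoms[idx, , drop = FALSE],
                       structure$xyz[idx, , drop = FALSE],
                       structure$label)
  out$meta <- structure$meta
  out
}

#' Subset an ensemble to an atom index set
#' @param ensemble A `zymo_ensemble`.
#' @param idx Atom indices to keep (order preserved).
#' @return A `zymo_ensemble`.
#' @export
subset_ensemble <- function(ensemble, idx) {
  stopifnot(inherits(ensemble, "zymo_ensemble"))
  out <- new_ensemble(subset_structure(ensemble$reference, idx),
                      ensemble$coords[idx, , , drop = FALSE],
                      ensemble$frame_times, ensemble$label)
  out$meta <- ensemble$meta
  out
}
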