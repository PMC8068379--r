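# In-silico zymogenization: removal of the inserted N-terminal tail
# (residues 16-18, "IVG" in FVIIa/trypsin) to produce a desIVG construct.
# The new N-terminus G19 is flagged as neutral-capped (amidation is recorded
# as metadata; no atoms are built, since the package analyses ensembles and
# does not prepare forcefield input).

.tail_mask <- function(atoms) {
  atoms$residue_number %in% 16:18 & atoms$insertion_code == ""
}

#' Truncate the inserted N-terminal tail (zymogenize in silico)
#'
#' Removes all atoms of residues 16, 17 and 18 (no insertion codes) and
#' flags residue 19 as the new, neutral-capped N-terminus. All remaining
#' coordinates are bitwise unchanged and numbering is preserved, so
#' downstream analyses need no renumbering. Applying the operation to a
#' construct that already starts at residue 19 raises an error rather than
#' silently re-truncating.
#'
#' @param structure A `zymo_structure` containing residues 16-18 and 19.
#' @return A list with elements `structure` (the truncated
#'   `zymo_structure`) and `report` (class `zymogenization_report`:
#'   `removed_residues` data frame, `removed_atom_count`,
#'   `new_n_terminus`, `cap_applied`).
#' @export
truncate_n_terminus <- function(structure) {
  stopifnot(inherits(structure, "zymo_structure"))
  atoms <- structure$atoms
  tail_idx <- which(.tail_mask(atoms))
  if (length(tail_idx) == 0) {
    stop("residues 16-18 not present: construct is already zymogenized ",
         "or uses non-standard numbering (not activatable)")
  }
  have <- sort(unique(atoms$residue_number[tail_idx]))
  if (!all(16:18 %in% have)) {
    stop("incomplete N-terminal tail: found residue(s) ",
         paste(have, collapse = ", "), ", need 16, 17 and 18")
  }
  res19 <- which(atoms$residue_number == 19 & atoms$insertion_code == "")
  if (length(res19) == 0) {
    stop("residue 19 not present; cannot define the new N-terminus")
  }
  if (!any(atoms$residue_name[res19] %in% c("GLY", "G"))) {
    warning("residue 19 is ", atoms$residue_name[res19][1],
            ", not glycine; proceeding (variant numbering assumed correct)")
  }

  rem <- atoms[tail_idx, , drop = FALSE]
  removed_residues <- unique(rem[, c("residue_number", "insertion_code",
                                     "residue_name")])
  rownames(removed_residues) <- NULL

  keep <- setdiff(seq_len(nrow(atoms)), tail_idx)
  out <- subset_structure(structure, keep)
  out$label <- if (nzchar(structure$label)) {
    paste0(structure$label, "-desIVG")
  } else "desIVG"
  out$meta$zymogenized <- TRUE
  out$meta$n_cap <- list(residue = "19", treatment = "amidated", charge = 0)

  report <- list(removed_residues = removed_residues,
                 removed_atom_count = length(tail_idx),
                 new_n_terminus = "19",
                 cap_applied = TRUE)
  class(report) <- "zymogenization_report"
  list(structure = out, report = report)
}

#' @export
print.zymogenization_report <- function(x, ...) {
  cat("Zymogenization (desIVG) report\n",
      " removed residues: ",
      paste(paste0(x$removed_residues$residue_name,
                   x$removed_residues$residue_number), collapse = ", "),
      "\n  removed atoms:    ", x$removed_atom_count,
      "\n  new N-terminus:   residue ", x$new_n_terminus,
      if (x$cap_applied) " (neutral amide cap)" else "", "\n", sep = "")
  invisible(x)
}

#' Zymogenize every frame of an ensemble
#'
#' Applies [truncate_n_terminus()] to the reference roster and drops the
#' corresponding atoms from all frames.
#'
#' @param ensemble A `zymo_ensemble`.
#' @return A list with elements `ensemble` and `report`.
#' @export
zymogenize_ensemble <- function(ensemble) {
  stopifnot(inherits(ensemble, "zymo_ensemble"))
  res <- truncate_n_terminus(ensemble$reference)
  keep <- which(!.tail_mask(ensemble$reference$atoms))
  out <- subset_ensemble(ensemble, keep)
  out$reference <- res$structure
  out$label <- res$structure$label
  out$meta$zymogenized <- TRUE
  list(ensemble = out, report = res$report)
}
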