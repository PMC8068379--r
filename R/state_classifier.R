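# Two-state geometric classifier of the 215-217 segment.  A frame is
# substrate-accessible (E, or Z in a zymogenized construct) when the
# W215/CG-H57/CG distance strictly exceeds 6.5 A AND the W215/CG-S195/OG
# distance strictly exceeds 6.0 A; otherwise the active site is occluded
# (E*/Z*).  Distances are rigid-invariant, so no superposition is applied.

#' Distance cut-off criterion for the E/Z vs E*/Z* states
#'
#' @param cutoff_his Cut-off (Angstrom) for the probe-to-His57 distance
#'   (default 6.5).
#' @param cutoff_ser Cut-off (Angstrom) for the probe-to-Ser195 distance
#'   (default 6.0).
#' @param probe Probe atom, `list(resno, insert, name)` (default W215/CG).
#' @param anchor_his,anchor_ser Anchor atoms (default H57/CG and S195/OG).
#'   Remappable for variants carrying a non-tryptophan residue 215.
#' @return Object of class `state_criterion`. The accessible state requires
#'   both distances to be strictly greater than their cut-offs; ties go to
#'   the occluded state.
#' @export
state_criterion <- function(cutoff_his = 6.5, cutoff_ser = 6.0,
                            probe = list(resno = 215, insert = "",
                                         name = "CG"),
                            anchor_his = list(resno = 57, insert = "",
                                              name = "CG"),
                            anchor_ser = list(resno = 195, insert = "",
                                              name = "OG")) {
  if (cutoff_his <= 0 || cutoff_ser <= 0) stop("cut-offs must be positive")
  out <- list(cutoff_his = cutoff_his, cutoff_ser = cutoff_ser,
              probe = probe, anchor_his = anchor_his,
              anchor_ser = anchor_ser)
  class(out) <- "state_criterion"
  out
}

.find_atom <- function(atoms, spec) {
  i <- which(atoms$residue_number == spec$resno &
             atoms$insertion_code == spec$insert &
             atoms$atom_name == spec$name)
  if (length(i) == 0) {
    stop("atom not found: residue ", spec$resno, spec$insert, " atom ",
         spec$name)
  }
  i[1]
}

#' Classify ensemble frames into accessible vs occluded states
#'
#' @param ensemble A `zymo_ensemble` containing the probe and anchor atoms.
#' @param criterion A [state_criterion()].
#' @param zymogen Logical; selects the Z/Z* nomenclature instead of E/E*
#'   (the geometric test is identical). Defaults to the ensemble's
#'   zymogenization metadata, if any.
#' @return A `state_series` data frame with columns `frame`, `time`,
#'   `d_57`, `d_195` (Angstrom), `accessible` (logical) and `label`
#'   (`"E"`/`"E*"` or `"Z"`/`"Z*"`).
#' @export
classify_frames <- function(ensemble, criterion = state_criterion(),
                            zymogen = NULL) {
  stopifnot(inherits(ensemble, "zymo_ensemble"),
            inherits(criterion, "state_criterion"))
  if (is.null(zymogen)) {
    zymogen <- isTRUE(ensemble$meta$zymogenized) ||
      isTRUE(ensemble$reference$meta$zymogenized)
  }
  atoms <- ensemble$reference$atoms
  ip <- .find_atom(atoms, criterion$probe)
  ih <- .find_atom(atoms, criterion$anchor_his)
  is <- .find_atom(atoms, criterion$anchor_ser)
  dist_t <- function(a, b) {
    sqrt(colSums((ensemble$coords[a, , ] - ensemble$coords[b, , ])^2))
  }
  d_57 <- dist_t(ip, ih)
  d_195 <- dist_t(ip, is)
  accessible <- d_57 > criterion$cutoff_his & d_195 > criterion$cutoff_ser
  open_lab <- if (zymogen) "Z" else "E"
  occl_lab <- paste0(open_lab, "*")
  out <- data.frame(frame = seq_len(n_frames(ensemble)),
                    time = ensemble$frame_times,
                    d_57 = d_57, d_195 = d_195,
                    accessible = accessible,
                    label = ifelse(accessible, open_lab, occl_lab),
                    stringsAsFactors = FALSE)
  attr(out, "criterion") <- criterion
  attr(out, "construct") <- if (zymogen) "zymogenized" else "enzyme"
  class(out) <- c("state_series", "data.frame")
  out
}

.as_accessible <- function(series) {
  if (inherits(series, "state_series") ||
      (is.data.frame(series) && "accessible" %in% names(series))) {
    return(as.logical(series$accessible))
  }
  if (is.logical(series)) return(series)
  if (is.numeric(series) && all(series %in% c(0, 1))) return(series == 1)
  stop("series must be a state_series or a logical/0-1 vector")
}

#' State population with bootstrap standard error
#'
#' The accessible-state population is the exact fraction of accessible
#' frames; the bootstrap affects only its standard error, computed as the
#' standard deviation of the fraction over `n_boot` resamples of the frames
#' (iid with replacement, same size). A moving-block bootstrap is available
#' for autocorrelated trajectories via `block_length`; the iid default
#' mirrors the plain 1000-sample bootstrap convention.
#'
#' @param series A `state_series` (or a logical accessible-state vector).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional RNG seed for reproducibility.
#' @param block_length Optional block length for a moving-block bootstrap;
#'   `NULL` (default) resamples frames independently.
#' @return Object of class `population_estimate` with fields
#'   `p_accessible`, `p_occluded`, `bootstrap_se`, `n_frames`, `n_boot`,
#'   `n_transitions`.
#' @export
population <- function(series, n_boot = 1000, seed = NULL,
                       block_length = NULL) {
  acc <- .as_accessible(series)
  n <- length(acc)
  if (n < 1) stop("empty series")
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  x <- as.numeric(acc)
  if (is.null(block_length)) {
    boot_p <- vapply(seq_len(n_boot), function(b) {
      mean(x[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
  } else {
    block_length <- max(1L, as.integer(block_length))
    n_blocks <- ceiling(n / block_length)
    starts_max <- max(1L, n - block_length + 1L)
    boot_p <- vapply(seq_len(n_boot), function(b) {
      starts <- sample.int(starts_max, n_blocks, replace = TRUE)
      idx <- as.vector(outer(0:(block_length - 1L), starts, `+`))[seq_len(n)]
      mean(x[idx])
    }, numeric(1))
  }
  n_trans <- if (n >= 2) sum(acc[-1] != acc[-n]) else 0L
  out <- list(p_accessible = mean(x),
              p_occluded = 1 - mean(x),
              bootstrap_se = stats::sd(boot_p),
              n_frames = n, n_boot = n_boot,
              n_transitions = as.integer(n_trans))
  class(out) <- "population_estimate"
  out
}

#' @export
print.population_estimate <- function(x, ...) {
  cat(sprintf(
    "Accessible-state population: %.4f +/- %.4f (bootstrap SE, %d resamples)\n",
    x$p_accessible, x$bootstrap_se, x$n_boot))
  cat(sprintf("  frames: %d   transitions: %d\n", x$n_frames,
              x$n_transitions))
  invisible(x)
}

#' Transition count and dwell-length decomposition
#'
#' @param series A `state_series` (or logical accessible vector) with at
#'   least 2 frames.
#' @return List with `n_transitions` (label changes between consecutive
#'   frames) and `dwells`, a data frame of maximal constant-state segments
#'   (`state`, `length`) partitioning the series.
#' @export
transitions <- function(series) {
  acc <- .as_accessible(series)
  if (length(acc) < 2) stop("need at least 2 frames to count transitions")
  r <- rle(acc)
  list(n_transitions = length(r$lengths) - 1L,
       dwells = data.frame(state = ifelse(r$values, "accessible",
                                          "occluded"),
                           length = r$lengths,
                           stringsAsFactors = FALSE))
}

#' Export the state scatter table
#'
#' Plain per-frame export of the two defining distances and the state
#' label, suitable for time-coloured scatter plotting of the probe position
#' relative to the catalytic residues.
#'
#' @param series A `state_series`.
#' @param path Optional TSV output path.
#' @return Data frame with columns `frame_time`, `d_57`, `d_195`, `label`
#'   (invisibly when `path` is given).
#' @export
scatter_export <- function(series, path = NULL) {
  stopifnot(inherits(series, "state_series"))
  out <- data.frame(frame_time = series$time, d_57 = series$d_57,
                    d_195 = series$d_195, label = series$label,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
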