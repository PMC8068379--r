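# Rigid-body superposition and derived descriptors: Kabsch least-squares
# fits, RMSD series/matrices, iterated average structures, running
# averages, per-residue RMSF and the Debye-Waller conversion
# B = (8 pi^2 / 3) * MSF.

#' Kabsch least-squares rigid superposition
#'
#' Computes the proper rotation and translation minimising the (optionally
#' weighted) least-squares deviation of `mobile` onto `target` in a single
#' pass, with no outlier-rejection cycles. The reflection branch of the SVD
#' solution is corrected so the rotation determinant is +1.
#'
#' @param mobile,target N x 3 coordinate matrices with matched atom order,
#'   N >= 3.
#' @param weights Optional non-negative per-atom weights.
#' @return Object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length-3, Angstrom), `rmsd` (Angstrom, weighted),
#'   `n_atoms_used`. The fitted coordinates are
#'   `mobile %*% rotation + translation` (rows).
#' @export
kabsch_superpose <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile)
  target <- as.matrix(target)
  stopifnot(ncol(mobile) == 3, ncol(target) == 3)
  n <- nrow(mobile)
  if (nrow(target) != n) stop("coordinate sets differ in size")
  if (n < 3) stop("underdetermined: need at least 3 atoms to superpose")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum")
  }
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  p <- sweep(mobile, 2, cm)
  q <- sweep(target, 2, ct)
  if (qr(p)$rank < 2 || qr(q)$rank < 2) {
    warning("(near-)collinear coordinates: rotation is rank deficient ",
            "but a minimising transform is still returned")
  }
  h <- crossprod(p * w, q)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rot <- t(rot)  # row-vector convention: fitted = p %*% rot
  fitted <- p %*% rot
  rmsd <- sqrt(sum(w * rowSums((fitted - q)^2)))
  out <- list(rotation = rot,
              translation = as.numeric(ct - cm %*% rot),
              rmsd = rmsd, n_atoms_used = n)
  class(out) <- "superposition"
  out
}

#' Apply a superposition transform to coordinates
#' @param xyz N x 3 coordinate matrix.
#' @param fit A `superposition` from [kabsch_superpose()].
#' @return Transformed N x 3 matrix.
#' @export
apply_transform <- function(xyz, fit) {
  stopifnot(inherits(fit, "superposition"))
  sweep(as.matrix(xyz) %*% fit$rotation, 2, -fit$translation)
}

#' RMSD between two coordinate sets after optimal superposition
#' @inheritParams kabsch_superpose
#' @return RMSD in Angstrom.
#' @export
rmsd_pair <- function(mobile, target, weights = NULL) {
  kabsch_superpose(mobile, target, weights)$rmsd
}

.resolve_pairing <- function(ensemble, reference, selection, regions) {
  idx_e <- select_atoms(ensemble, selection, regions)
  ref_atoms <- reference$atoms
  pairing <- pair_atoms(ensemble$reference$atoms[idx_e, , drop = FALSE],
                        ref_atoms)
  list(ens = idx_e[pairing$idx_a], ref = pairing$idx_b)
}

#' Per-frame RMSD of an ensemble against one or two references
#'
#' Each frame is independently superposed onto the reference over the
#' selected atoms (paired by residue number, insertion code and atom name)
#' and the fitted RMSD recorded. A second reference (e.g. the simulated
#' average structures of an enzyme and its zymogen) yields a second aligned
#' column for direct comparison of which basin a trajectory occupies.
#'
#' @param ensemble A `zymo_ensemble`.
#' @param reference A `zymo_structure`.
#' @param selection Selection string (default `"calpha"`).
#' @param reference2 Optional second `zymo_structure`.
#' @param regions Region map for `"region"` selection terms.
#' @return Data frame with columns `frame`, `time`, `rmsd_ref1` and, when
#'   `reference2` is given, `rmsd_ref2` (Angstrom).
#' @export
rmsd_series <- function(ensemble, reference, selection = "calpha",
                        reference2 = NULL, regions = region_map()) {
  stopifnot(inherits(ensemble, "zymo_ensemble"),
            inherits(reference, "zymo_structure"))
  one_ref <- function(ref) {
    pr <- .resolve_pairing(ensemble, ref, selection, regions)
    tgt <- ref$xyz[pr$ref, , drop = FALSE]
    vapply(seq_len(n_frames(ensemble)), function(t) {
      kabsch_superpose(ensemble$coords[pr$ens, , t], tgt)$rmsd
    }, numeric(1))
  }
  out <- data.frame(frame = seq_len(n_frames(ensemble)),
                    time = ensemble$frame_times,
                    rmsd_ref1 = one_ref(reference))
  if (!is.null(reference2)) out$rmsd_ref2 <- one_ref(reference2)
  out
}

#' Trailing running average
#'
#' Smooths a series with a trailing moving mean: element k is the mean of
#' the last `min(k, window)` points, so the output has the input's length
#' and the leading edge uses the available prefix.
#'
#' @param x Numeric series.
#' @param window Window length in points (>= 1).
#' @return Smoothed numeric series, same length as `x`.
#' @export
running_average <- function(x, window) {
  stopifnot(is.numeric(x))
  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1")
  n <- length(x)
  if (window > n) stop("window (", window, ") exceeds series length (", n, ")")
  cs <- cumsum(x)
  k <- seq_len(n)
  lag <- pmax(k - window, 0)
  (cs - c(0, cs)[lag + 1]) / pmin(k, window)
}

#' Iteratively superposed average structure
#'
#' Superposes every frame onto the running mean over the selected atoms and
#' recomputes the mean until it moves less than `tol` (mean per-atom
#' displacement), then returns the per-atom mean coordinates of all atoms.
#' The result is a positional average, not a structural realisation: bond
#' lengths and angles are not preserved, and the output is flagged
#' accordingly in its metadata.
#'
#' @param ensemble A `zymo_ensemble` with at least 2 frames.
#' @param selection Atoms used for fitting (default `"calpha"`); all atoms
#'   are averaged.
#' @param tol Convergence tolerance on the mean displacement (Angstrom).
#' @param max_iter Maximum fit/average iterations.
#' @param regions Region map for selection terms.
#' @return A `zymo_structure` with `meta$positional_average = TRUE` and
#'   `meta$iterations`.
#' @export
average_structure <- function(ensemble, selection = "calpha", tol = 1e-6,
                              max_iter = 100, regions = region_map()) {
  stopifnot(inherits(ensemble, "zymo_ensemble"))
  t_frames <- n_frames(ensemble)
  if (t_frames < 2) stop("need at least 2 frames to average")
  fit_idx <- select_atoms(ensemble, selection, regions)
  coords <- ensemble$coords
  mean_fit <- coords[fit_idx, , 1]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    full_sum <- matrix(0, nrow = dim(coords)[1], ncol = 3)
    for (t in seq_len(t_frames)) {
      fit <- kabsch_superpose(coords[fit_idx, , t], mean_fit)
      full_sum <- full_sum + apply_transform(coords[, , t], fit)
    }
    new_mean_full <- full_sum / t_frames
    new_mean_fit <- new_mean_full[fit_idx, , drop = FALSE]
    shift <- mean(sqrt(rowSums((new_mean_fit - mean_fit)^2)))
    mean_fit <- new_mean_fit
    if (shift < tol) {
      converged <- TRUE
      mean_full <- new_mean_full
      break
    }
  }
  if (!converged) {
    stop("average_structure did not converge in ", max_iter,
         " iterations (last mean displacement ", signif(shift, 3), " A)")
  }
  out <- new_structure(ensemble$reference$atoms, mean_full,
                       paste0("<", ensemble$label, ">"))
  out$meta$positional_average <- TRUE
  out$meta$iterations <- it
  out
}

# Superpose all frames of an ensemble onto the iterated mean over the
# selected atoms; returns the transformed ensemble (internal workhorse for
# RMSF, PCA and DCC).
.superpose_to_mean <- function(ensemble, selection, regions = region_map(),
                               tol = 1e-6, max_iter = 100) {
  avg <- average_structure(ensemble, selection, tol, max_iter, regions)
  fit_idx <- select_atoms(ensemble, selection, regions)
  tgt <- avg$xyz[fit_idx, , drop = FALSE]
  coords <- ensemble$coords
  for (t in seq_len(dim(coords)[3])) {
    fit <- kabsch_superpose(coords[fit_idx, , t], tgt)
    coords[, , t] <- apply_transform(coords[, , t], fit)
  }
  out <- ensemble
  out$coords <- coords
  out$meta$superposed_on <- selection
  out
}

#' Pairwise RMSD matrix
#'
#' Every pair is fitted independently ([kabsch_superpose()]); the matrix is
#' symmetric with a zero diagonal.
#'
#' @param structures List of `zymo_structure` objects, or a
#'   `zymo_ensemble` (frames become the items).
#' @param selection Selection string (default `"calpha"`).
#' @param regions Region map for selection terms.
#' @return Symmetric numeric matrix of superposed RMSDs (Angstrom).
#' @export
rmsd_matrix <- function(structures, selection = "calpha",
                        regions = region_map()) {
  if (inherits(structures, "zymo_ensemble")) {
    ens <- structures
    idx <- select_atoms(ens, selection, regions)
    n <- n_frames(ens)
    sets <- lapply(seq_len(n), function(t) ens$coords[idx, , t])
    labels <- as.character(seq_len(n))
  } else {
    stopifnot(is.list(structures), length(structures) >= 2)
    n <- length(structures)
    base_idx <- select_atoms(structures[[1]], selection, regions)
    base_atoms <- structures[[1]]$atoms[base_idx, , drop = FALSE]
    sets <- vector("list", n)
    sets[[1]] <- structures[[1]]$xyz[base_idx, , drop = FALSE]
    for (i in seq_len(n)[-1]) {
      pr <- tryCatch(pair_atoms(base_atoms, structures[[i]]$atoms),
                     error = function(e) {
                       stop("pairing failed between structure 1 and ",
                            "structure ", i, ": ", conditionMessage(e))
                     })
      if (length(pr$idx_a) < length(base_idx)) {
        stop("structure ", i, " lacks ",
             length(base_idx) - length(pr$idx_a),
             " selected atom(s) of structure 1")
      }
      sets[[i]] <- structures[[i]]$xyz[pr$idx_b, , drop = FALSE]
    }
    labels <- vapply(structures, function(s) s$label, character(1))
  }
  if (n < 2) stop("need at least 2 structures/frames")
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- kabsch_superpose(sets[[i]], sets[[j]])$rmsd
      m[i, j] <- r
      m[j, i] <- r
    }
  }
  m
}

#' Per-residue flexibility profile (MSF, RMSF, simulated B-factor)
#'
#' Frames are first superposed onto the iterated average structure over the
#' selection; the mean squared fluctuation of each atom about its
#' time-mean position is then averaged over the atoms of each residue
#' (every atom in the residue selection contributes), and converted to a
#' Debye-Waller factor via B = (8 pi^2 / 3) * MSF.
#'
#' @param ensemble A `zymo_ensemble` with at least 2 frames.
#' @param selection Atom selection (default `"calpha"`).
#' @param fit Superpose frames onto the iterated mean first (default
#'   `TRUE`). With `fit = FALSE` a net-drift warning is emitted and the
#'   profile is computed on the raw coordinates.
#' @param regions Region map for selection terms.
#' @return A `flexibility_profile` data frame with columns `residue_number`,
#'   `insertion_code`, `residue_name`, `n_atoms`, `msf` (A^2), `rmsf` (A)
#'   and `b_factor` (A^2), plus `crystal_b` copied from the input B-factor
#'   column when present.
#' @export
rmsf_profile <- function(ensemble, selection = "calpha", fit = TRUE,
                         regions = region_map()) {
  stopifnot(inherits(ensemble, "zymo_ensemble"))
  if (n_frames(ensemble) < 2) stop("need at least 2 frames for RMSF")
  if (fit) {
    ensemble <- .superpose_to_mean(ensemble, selection, regions)
  } else {
    first <- colMeans(ensemble$coords[, , 1, drop = TRUE])
    last <- colMeans(ensemble$coords[, , n_frames(ensemble), drop = TRUE])
    if (sqrt(sum((first - last)^2)) > 1) {
      warning("ensemble appears to drift and fit = FALSE: ",
              "net motion will inflate the MSF")
    }
  }
  idx <- select_atoms(ensemble, selection, regions)
  sub <- ensemble$coords[idx, , , drop = FALSE]
  mean_xyz <- apply(sub, c(1, 2), mean)
  disp2 <- sweep(sub, c(1, 2), mean_xyz)^2
  msf_atom <- apply(disp2, 1, sum) / dim(sub)[3]

  atoms <- ensemble$reference$atoms[idx, , drop = FALSE]
  res_key <- factor(paste(atoms$residue_number, atoms$insertion_code,
                          sep = "|"),
                    levels = unique(paste(atoms$residue_number,
                                          atoms$insertion_code, sep = "|")))
  msf_res <- tapply(msf_atom, res_key, mean)
  first_of <- match(levels(res_key), res_key)
  out <- data.frame(
    residue_number = atoms$residue_number[first_of],
    insertion_code = atoms$insertion_code[first_of],
    residue_name = atoms$residue_name[first_of],
    n_atoms = as.integer(table(res_key)),
    msf = as.numeric(msf_res),
    stringsAsFactors = FALSE
  )
  out$rmsf <- sqrt(out$msf)
  out$b_factor <- msf_to_bfactor(out$msf)
  crystal_b <- tapply(atoms$b_factor, res_key, mean)
  if (any(crystal_b != 0)) out$crystal_b <- as.numeric(crystal_b)
  class(out) <- c("flexibility_profile", "data.frame")
  out
}

#' Debye-Waller conversion between MSF and B-factor
#'
#' `B = (8 pi^2 / 3) * MSF`, with MSF in A^2 and B in A^2.
#'
#' @param msf Mean squared fluctuation(s), A^2.
#' @return Simulated B-factor(s), A^2.
#' @export
msf_to_bfactor <- function(msf) (8 * pi^2 / 3) * msf

#' @rdname msf_to_bfactor
#' @param b B-factor(s), A^2.
#' @export
bfactor_to_msf <- function(b) b * 3 / (8 * pi^2)

#' Write a per-residue profile into a structure's B-factor column
#'
#' Exports simulated B-factors into the PDB B column so external viewers
#' can render flexibility (e.g. putty/sausage representations).
#'
#' @param structure A `zymo_structure`.
#' @param profile A `flexibility_profile` from [rmsf_profile()].
#' @return The structure with `b_factor` replaced per residue (atoms of
#'   residues absent from the profile get 0).
#' @export
profile_to_bfactor <- function(structure, profile) {
  stopifnot(inherits(structure, "zymo_structure"),
            inherits(profile, "flexibility_profile"))
  key_s <- paste(structure$atoms$residue_number,
                 structure$atoms$insertion_code, sep = "|")
  key_p <- paste(profile$residue_number, profile$insertion_code, sep = "|")
  b <- profile$b_factor[match(key_s, key_p)]
  structure$atoms$b_factor <- ifelse(is.na(b), 0, b)
  structure
}
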