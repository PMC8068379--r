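# Essential-dynamics PCA on the mass-weighted covariance of positional
# fluctuations, UPGMA clustering of frames on pairwise C-alpha RMSD, and
# dynamic cross-correlation maps.

#' Mass-weighted essential-dynamics PCA
#'
#' Frames are superposed onto the iterated average structure over the
#' selection, centred, and mass-weighted (each atomic displacement scaled
#' by sqrt(m)); the covariance matrix C = (1/T) sum_t w x_t x_t' w over the
#' 3N selected coordinates is eigendecomposed. Eigenvector signs are fixed
#' so the largest-magnitude component of each vector is positive, making
#' projections reproducible across runs and libraries. The covariance is
#' normalised by T (population convention).
#'
#' @param ensemble A `zymo_ensemble` with more frames than components.
#' @param selection Atom selection (default `"heavy"`, i.e. all
#'   non-hydrogen atoms).
#' @param n_components Number of components to retain (default
#'   `min(T - 1, 3N)`).
#' @param regions Region map for selection terms.
#' @return Object of class `pca_model`: `mean_coordinates` (N x 3),
#'   `eigenvalues` (descending, mass-weighted A^2 u), `eigenvectors`
#'   (3N x k, orthonormal columns), `projections` (T x k score matrix),
#'   `mass_weights` (per atom), `total_variance` (trace of the weighted
#'   covariance), `atom_indices`.
#' @export
pca_ensemble <- function(ensemble, selection = "heavy", n_components = NULL,
                         regions = region_map()) {
  stopifnot(inherits(ensemble, "zymo_ensemble"))
  t_frames <- n_frames(ensemble)
  if (t_frames <= 1) stop("insufficient frames for PCA (need T > 1)")
  ens <- .superpose_to_mean(ensemble, selection, regions)
  idx <- select_atoms(ens, selection, regions)
  n_sel <- length(idx)
  if (is.null(n_components)) n_components <- min(t_frames - 1, 3 * n_sel)
  if (t_frames <= n_components) {
    stop("insufficient frames for ", n_components, " components")
  }
  masses <- ens$reference$atoms$mass[idx]

  # T x 3N coordinate matrix, atom-major column order (x1,y1,z1,x2,...)
  x <- matrix(NA_real_, nrow = t_frames, ncol = 3 * n_sel)
  for (k in 1:3) {
    x[, seq(k, 3 * n_sel, by = 3)] <- t(ens$coords[idx, k, , drop = TRUE])
  }
  mean_x <- colMeans(x)
  xc <- sweep(x, 2, mean_x)
  w <- rep(sqrt(masses), each = 3)
  xw <- sweep(xc, 2, w, `*`)
  cov_w <- crossprod(xw) / t_frames
  eig <- eigen(cov_w, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-|component| entry positive
  for (j in seq_len(ncol(vecs))) {
    i_max <- which.max(abs(vecs[, j]))
    if (vecs[i_max, j] < 0) vecs[, j] <- -vecs[, j]
  }
  proj <- xw %*% vecs
  colnames(proj) <- paste0("PC", seq_len(ncol(proj)))
  out <- list(
    mean_coordinates = matrix(mean_x, ncol = 3, byrow = TRUE),
    eigenvalues = vals[seq_len(n_components)],
    all_eigenvalues = vals,
    eigenvectors = vecs,
    projections = proj,
    mass_weights = masses,
    total_variance = sum(diag(cov_w)),
    atom_indices = idx
  )
  class(out) <- "pca_model"
  out
}

#' @export
print.pca_model <- function(x, ...) {
  k <- min(5, length(x$eigenvalues))
  frac <- x$eigenvalues[seq_len(k)] / x$total_variance
  cat("Essential-dynamics PCA model\n  components retained:",
      length(x$eigenvalues), "\n  leading variance fractions:",
      paste(sprintf("%.3f", frac), collapse = " "), "\n")
  invisible(x)
}

#' Subspace compactness of the PC1-PC2 projection
#'
#' Summarises the spread of an ensemble in its essential subspace: small
#' values indicate conformational rigidity (a compact PC1-PC2 scatter),
#' large values plasticity. The primary scalar is the total population
#' variance of the PC1 and PC2 scores; the convex-hull area of the scatter
#' is reported as a secondary, outlier-sensitive summary.
#'
#' @param model A `pca_model` with at least 2 components.
#' @return List with `pc_variance` (A^2 u), `hull_area` and `n_frames`.
#' @export
subspace_compactness <- function(model) {
  stopifnot(inherits(model, "pca_model"))
  if (ncol(model$projections) < 2) stop("need at least 2 components")
  s <- model$projections[, 1:2, drop = FALSE]
  t_frames <- nrow(s)
  v <- sum(apply(s, 2, function(col) mean((col - mean(col))^2)))
  hull <- 0
  if (t_frames >= 3 && v > 0) {
    h <- grDevices::chull(s)
    hx <- s[h, 1]; hy <- s[h, 2]
    hull <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  }
  list(pc_variance = v, hull_area = hull, n_frames = t_frames)
}

#' UPGMA clustering of frames on pairwise RMSD
#'
#' Computes the pairwise superposed RMSD matrix over the selected atoms
#' (each pair fitted independently) and agglomerates with average linkage
#' (UPGMA). Frames may be strided to bound the quadratic matrix.
#'
#' @param ensemble A `zymo_ensemble`.
#' @param selection Atom selection (default `"calpha"`).
#' @param stride Keep every `stride`-th frame (default 1).
#' @param max_frames Guard on the strided frame count (default 2000); an
#'   error advises a larger stride beyond it.
#' @param regions Region map for selection terms.
#' @return Object of class `upgma_dendrogram`: `merge`, `height`
#'   (non-decreasing), `order`, `frames` (original frame indices of the
#'   leaves), and the underlying `hclust` object.
#' @export
upgma_cluster <- function(ensemble, selection = "calpha", stride = 1,
                          max_frames = 2000, regions = region_map()) {
  stopifnot(inherits(ensemble, "zymo_ensemble"))
  keep <- seq(1, n_frames(ensemble), by = max(1L, as.integer(stride)))
  if (length(keep) < 2) stop("strided frame count < 2")
  if (length(keep) > max_frames) {
    stop(length(keep), " strided frames exceed the cap of ", max_frames,
         "; increase `stride` (or raise `max_frames`)")
  }
  sub <- ensemble
  sub$coords <- ensemble$coords[, , keep, drop = FALSE]
  sub$frame_times <- ensemble$frame_times[keep]
  d <- rmsd_matrix(sub, selection, regions)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  out <- list(merge = hc$merge, height = hc$height, order = hc$order,
              frames = keep, hclust = hc, n_leaves = length(keep))
  class(out) <- "upgma_dendrogram"
  out
}

#' Cut a UPGMA dendrogram into flat clusters
#'
#' @param dendrogram An `upgma_dendrogram`.
#' @param k Desired number of clusters, or
#' @param h Height cut-off (Angstrom): merges above `h` are split.
#' @return Integer cluster labels, one per leaf (named by frame index).
#' @export
cut_dendrogram <- function(dendrogram, k = NULL, h = NULL) {
  stopifnot(inherits(dendrogram, "upgma_dendrogram"))
  if (is.null(k) == is.null(h)) stop("supply exactly one of `k` or `h`")
  if (!is.null(k) && k > dendrogram$n_leaves) {
    stop("k (", k, ") exceeds the number of leaves (",
         dendrogram$n_leaves, ")")
  }
  labels <- stats::cutree(dendrogram$hclust, k = k, h = h)
  names(labels) <- dendrogram$frames
  labels
}

#' Export a dendrogram as a linkage table (and Newick string)
#' @param dendrogram An `upgma_dendrogram`.
#' @return List with `linkage` (data frame: `node_a`, `node_b`, `height`,
#'   `size`; negative ids are leaves, positive ids earlier merges, as in
#'   [stats::hclust()]) and `newick`.
#' @export
dendrogram_export <- function(dendrogram) {
  stopifnot(inherits(dendrogram, "upgma_dendrogram"))
  m <- dendrogram$merge
  sizes <- integer(nrow(m))
  count <- function(id) if (id < 0) 1L else sizes[id]
  nwk <- character(nrow(m))
  leaf <- function(id) paste0("f", dendrogram$frames[-id])
  for (i in seq_len(nrow(m))) {
    sizes[i] <- count(m[i, 1]) + count(m[i, 2])
    part <- function(id) if (id < 0) leaf(id) else nwk[id]
    nwk[i] <- paste0("(", part(m[i, 1]), ",", part(m[i, 2]), "):",
                     format(dendrogram$height[i], digits = 10))
  }
  list(linkage = data.frame(node_a = m[, 1], node_b = m[, 2],
                            height = dendrogram$height, size = sizes),
       newick = paste0(sub(":[^:]*$", "", nwk[nrow(m)]), ";"))
}

#' Dynamic cross-correlation matrix
#'
#' After superposition onto the iterated mean, computes the normalised
#' covariance of displacement vectors,
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`, over the selected
#' atoms (C-alpha by default). Values of 1 (-1) indicate complete
#' (anti)correlation and 0 no correlation. Atoms with zero fluctuation get
#' a zeroed row/column with a unit diagonal and a warning.
#'
#' @param ensemble A `zymo_ensemble` with at least 2 frames.
#' @param selection Atom selection (default `"calpha"`).
#' @param fit Superpose onto the iterated mean first (default `TRUE`).
#' @param regions Region map for selection terms.
#' @return Symmetric N x N matrix in `[-1, 1]` with unit diagonal,
#'   residue-id dimnames.
#' @export
dynamic_cross_correlation <- function(ensemble, selection = "calpha",
                                      fit = TRUE, regions = region_map()) {
  stopifnot(inherits(ensemble, "zymo_ensemble"))
  if (n_frames(ensemble) < 2) stop("need at least 2 frames for DCC")
  if (fit) ensemble <- .superpose_to_mean(ensemble, selection, regions)
  idx <- select_atoms(ensemble, selection, regions)
  t_frames <- n_frames(ensemble)
  num <- matrix(0, length(idx), length(idx))
  for (k in 1:3) {
    a <- t(ensemble$coords[idx, k, , drop = TRUE])  # T x N
    a <- sweep(a, 2, colMeans(a))
    num <- num + crossprod(a) / t_frames
  }
  amp <- diag(num)
  static <- amp <= .Machine$double.eps
  if (any(static)) {
    warning(sum(static), " atom(s) with zero fluctuation: their ",
            "correlations are set to 0")
    amp[static] <- 1
  }
  cc <- num / sqrt(outer(amp, amp))
  cc[static, ] <- 0
  cc[, static] <- 0
  cc <- pmin(pmax(cc, -1), 1)
  diag(cc) <- 1
  atoms <- ensemble$reference$atoms[idx, , drop = FALSE]
  ids <- paste0(atoms$residue_number, atoms$insertion_code)
  dimnames(cc) <- list(ids, ids)
  cc
}
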