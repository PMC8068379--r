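test_that("a rank-1 ensemble loads >= 99.9% of variance on PC1", {
  set.seed(20)
  n <- 12
  ref <- random_coords(n)
  direction <- matrix(stats::rnorm(3 * n), ncol = 3)
  direction <- direction / sqrt(sum(direction^2))
  # remove net translation so superposition cannot absorb the motion
  direction <- sweep(direction, 2, colMeans(direction))
  amp <- stats::rnorm(40, sd = 2)
  ens <- make_ensemble(make_structure(atom_table(n), ref),
                       lapply(amp, function(a) ref + a * direction))
  m <- pca_ensemble(ens, selection = "name CA", n_components = 5)
  expect_gt(m$eigenvalues[1] / m$total_variance, 0.999)
})

test_that("pca eigen-structure satisfies its invariants", {
  set.seed(22)
  ens <- make_gaussian_ensemble(10, 80, 0.5)
  m <- pca_ensemble(ens, selection = "name CA", n_components = 10)
  expect_true(all(diff(m$all_eigenvalues) <= 1e-9))
  expect_true(all(m$all_eigenvalues >= -1e-9))
  expect_equal(crossprod(m$eigenvectors), diag(10), tolerance = 1e-8)
  expect_equal(sum(m$all_eigenvalues), m$total_variance,
               tolerance = 1e-6 * m$total_variance)
  # sign convention: the largest-|component| entry is positive
  for (j in seq_len(ncol(m$eigenvectors))) {
    expect_gt(m$eigenvectors[which.max(abs(m$eigenvectors[, j])), j], 0)
  }
  expect_error(pca_ensemble(make_gaussian_ensemble(5, 3, 0.1),
                            selection = "name CA", n_components = 10),
               "insufficient frames")
})

test_that("full-rank projection reconstructs the weighted displacements", {
  set.seed(23)
  n <- 5
  t_frames <- 60
  ens <- make_gaussian_ensemble(n, t_frames, 0.4)
  m <- pca_ensemble(ens, selection = "name CA", n_components = 3 * n)
  recon <- m$projections %*% t(m$eigenvectors)
  # rebuild the weighted displacement matrix independently
  idx <- select_atoms(ens, "name CA")
  ens_fit <- zymodyn:::.superpose_to_mean(ens, "name CA")
  x <- matrix(NA_real_, t_frames, 3 * n)
  for (k in 1:3) x[, seq(k, 3 * n, 3)] <- t(ens_fit$coords[idx, k, ])
  xw <- sweep(sweep(x, 2, colMeans(x)), 2,
              rep(sqrt(ens$reference$atoms$mass[idx]), each = 3), `*`)
  expect_equal(recon, xw, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("equal-mass isotropic noise gives a flat spectrum", {
  set.seed(24)
  ens <- make_gaussian_ensemble(30, 5000, 0.5)
  m <- pca_ensemble(ens, selection = "name CA", n_components = 30)
  # superposition removes ~6 rigid degrees of freedom; compare within the
  # leading bulk of the spectrum
  lambda <- m$all_eigenvalues[1:80]
  expect_lt(lambda[1] / stats::median(lambda), 1.3)
})

test_that("two-state switching shows up as a bimodal PC1", {
  g <- generate_ensemble(generator_spec(n_frames = 600, seed = 25,
                                        markov_a = 0.05, markov_b = 0.05,
                                        loop_flex_enabled = FALSE))
  m <- pca_ensemble(g$ensemble, selection = "heavy", n_components = 3)
  pc1 <- m$projections[, 1]
  lab <- g$truth$accessible
  r_pb <- abs(stats::cor(pc1, as.numeric(lab)))
  expect_gt(r_pb, 0.8)
  ser <- classify_frames(g$ensemble)
  expect_equal(ser$accessible, lab)
})

test_that("subspace compactness is zero for a static ensemble and grows with spread", {
  n <- 8
  x <- random_coords(n)
  static <- make_ensemble(make_structure(atom_table(n), x),
                          list(x, x, x, x))
  m0 <- pca_ensemble(static, selection = "name CA", n_components = 2)
  expect_equal(subspace_compactness(m0)$pc_variance, 0, tolerance = 1e-12)

  set.seed(26)
  v_small <- subspace_compactness(pca_ensemble(
    make_gaussian_ensemble(20, 300, 0.3), "name CA", 2))$pc_variance
  v_large <- subspace_compactness(pca_ensemble(
    make_gaussian_ensemble(20, 300, 1.2), "name CA", 2))$pc_variance
  expect_gt(v_large, v_small)
})

test_that("upgma merges match the textbook quadratic oracle", {
  # deterministic small cases
  set.seed(27)
  n <- 6
  x <- random_coords(n)
  ens2 <- make_ensemble(make_structure(atom_table(n), x), list(x, x))
  d2 <- upgma_cluster(ens2, "name CA")
  expect_equal(d2$height, 0, tolerance = 1e-9)

  # two tight pairs of conformers, well separated: intra-pair merges first
  base <- random_coords(n)
  far <- random_coords(n)
  jitter <- function(x, s) x + matrix(stats::rnorm(3 * n, sd = s), ncol = 3)
  frames <- list(base, jitter(base, 0.01), far, jitter(far, 0.012))
  ens4 <- make_ensemble(make_structure(atom_table(n), base), frames)
  d4 <- upgma_cluster(ens4, "name CA")
  first_two <- list(sort(abs(d4$merge[1, ])), sort(abs(d4$merge[2, ])))
  expect_true(all(c(1, 2) %in% unlist(first_two[1])) ||
                all(c(1, 2) %in% unlist(first_two[2])))
  expect_setequal(unlist(first_two), 1:4)  # both first merges intra-pair
  expect_gt(d4$height[3], d4$height[2])
  expect_equal(d4$height, upgma_reference(rmsd_matrix(ens4, "name CA")),
               tolerance = 1e-9)

  # random instances against the oracle
  for (case in 1:15) {
    t_frames <- sample(4:10, 1)
    frames <- lapply(seq_len(t_frames), function(i) random_coords(n))
    ens <- make_ensemble(make_structure(atom_table(n), frames[[1]]),
                         frames)
    dend <- upgma_cluster(ens, "name CA")
    expect_equal(dend$height,
                 upgma_reference(rmsd_matrix(ens, "name CA")),
                 tolerance = 1e-9)
    expect_true(all(diff(dend$height) >= -1e-12))  # UPGMA monotonicity
  }
})

test_that("dendrogram cutting yields the requested cluster counts", {
  set.seed(28)
  n <- 6
  frames <- lapply(1:8, function(i) random_coords(n))
  ens <- make_ensemble(make_structure(atom_table(n), frames[[1]]), frames)
  dend <- upgma_cluster(ens, "name CA")
  expect_equal(length(unique(cut_dendrogram(dend, k = 1))), 1)
  expect_equal(length(unique(cut_dendrogram(dend, k = 8))), 8)
  expect_equal(length(unique(cut_dendrogram(dend, k = 3))), 3)
  expect_error(cut_dendrogram(dend, k = 9), "exceeds")
  expect_error(cut_dendrogram(dend), "exactly one")
  # height cut at 0 gives singletons for distinct frames
  expect_equal(length(unique(cut_dendrogram(dend, h = 0))), 8)
})

test_that("two-state frames cluster into the state partition", {
  # keep residue noise well below the ~3.3 A state jump of the probe so
  # the two conformational basins dominate the pairwise-RMSD structure
  g <- generate_ensemble(generator_spec(n_frames = 120, seed = 29,
                                        markov_a = 0.1, markov_b = 0.1,
                                        sigma_core = 0.1, sigma_site = 0.1,
                                        loop_flex_enabled = FALSE))
  dend <- upgma_cluster(g$ensemble, "heavy")
  labels <- cut_dendrogram(dend, k = 2)
  expect_gt(adjusted_rand(labels, g$truth$accessible), 0.8)
})

test_that("stride and frame-cap guards work", {
  g <- generate_ensemble(generator_spec(n_frames = 60, seed = 30))
  expect_error(upgma_cluster(g$ensemble, stride = 1, max_frames = 10),
               "stride")
  dend <- upgma_cluster(g$ensemble, stride = 10)
  expect_equal(dend$n_leaves, 6)
  expect_equal(dend$frames, seq(1, 60, by = 10))
})

test_that("dendrogram export emits a linkage table and newick string", {
  set.seed(31)
  n <- 5
  frames <- lapply(1:5, function(i) random_coords(n))
  ens <- make_ensemble(make_structure(atom_table(n), frames[[1]]), frames)
  dend <- upgma_cluster(ens, "name CA")
  exp <- dendrogram_export(dend)
  expect_equal(nrow(exp$linkage), 4)
  expect_equal(exp$linkage$size[4], 5)
  expect_equal(exp$linkage$height, dend$height)
  expect_match(exp$newick, "^\\(.*f1.*\\);$")
})

test_that("dcc satisfies definition, bounds and symmetry", {
  # identical and opposite displacement series -> +1 / -1 (no fitting)
  set.seed(32)
  n <- 4
  ref <- random_coords(n)
  disp <- stats::rnorm(30, sd = 0.5)
  frames <- lapply(disp, function(d) {
    f <- ref
    f[1, 1] <- f[1, 1] + d
    f[2, 1] <- f[2, 1] + d
    f[3, 1] <- f[3, 1] - d
    f
  })
  ens <- make_ensemble(make_structure(atom_table(n), ref), frames)
  expect_warning(cc <- dynamic_cross_correlation(ens, "name CA",
                                                 fit = FALSE),
                 "zero fluctuation")
  expect_equal(cc[1, 2], 1, tolerance = 1e-9)
  expect_equal(cc[1, 3], -1, tolerance = 1e-9)
  expect_equal(cc[4, 4], 1)   # static atom keeps unit diagonal
  expect_equal(cc[4, 1], 0)   # but zero off-diagonal
  expect_equal(cc, t(cc))
  expect_true(all(cc >= -1 & cc <= 1))

  # independent atoms decorrelate at the 1/sqrt(T) scale (the shared
  # 6-dof fit contributes ~1/N spurious correlation, so use a
  # protein-sized atom count)
  ens_iid <- make_gaussian_ensemble(100, 2000, 0.5)
  cc2 <- dynamic_cross_correlation(ens_iid, "name CA")
  off <- abs(cc2[upper.tri(cc2)])
  expect_gt(mean(off < 0.1), 0.99)
  expect_equal(diag(cc2), rep(1, 100), ignore_attr = TRUE)
})

test_that("dcc is invariant to global rigid motion after superposition", {
  g <- generate_ensemble(generator_spec(n_frames = 100, seed = 33))
  g_mov <- generate_ensemble(generator_spec(n_frames = 100, seed = 33,
                                            rigid_motion = TRUE))
  cc_fix <- dynamic_cross_correlation(g$ensemble, "calpha")
  cc_mov <- dynamic_cross_correlation(g_mov$ensemble, "calpha")
  expect_equal(cc_fix, cc_mov, tolerance = 1e-4)
})
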