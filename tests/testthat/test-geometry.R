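test_that("kabsch_superpose recovers trivial transforms", {
  set.seed(1)
  x <- random_coords(6)
  fit <- kabsch_superpose(x, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  # pure translation: the recovered shift is the negative offset
  fit2 <- kabsch_superpose(x + rep(c(5, 0, 0), each = 6), x)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit2$translation, c(-5, 0, 0), tolerance = 1e-8)
  # rigid invariance: rotated copy superposes exactly
  r <- euler_rotation(c(0.3, -1.1, 2.0))
  fit3 <- kabsch_superpose(x %*% t(r) + 3, x)
  expect_equal(fit3$rmsd, 0, tolerance = 1e-9)
  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), "underdetermined")
  expect_warning(kabsch_superpose(cbind(1:4, 0, 0), cbind(1:4, 0, 0)),
                 "collinear")
})

test_that("kabsch rmsd matches the brute-force rotational minimiser", {
  set.seed(21)
  for (case in 1:20) {
    n <- sample(4:8, 1)
    x <- random_coords(n)
    y <- x %*% t(euler_rotation(stats::runif(3, -pi, pi))) +
      matrix(stats::rnorm(3 * n, sd = 0.6), ncol = 3)
    expect_equal(kabsch_superpose(x, y)$rmsd, brute_force_rmsd(x, y),
                 tolerance = 1e-6)
  }
})

test_that("weighted superposition privileges the heavy atoms", {
  set.seed(3)
  x <- random_coords(5)
  y <- x
  y[5, ] <- y[5, ] + c(4, 0, 0)  # one outlier atom
  w_focus <- c(1, 1, 1, 1, 1e-9)
  fit <- kabsch_superpose(y, x, weights = w_focus)
  expect_lt(fit$rmsd, 1e-4)
  expect_gt(kabsch_superpose(y, x)$rmsd, 0.5)
  expect_error(kabsch_superpose(y, x, weights = rep(-1, 5)),
               "non-negative")
})

test_that("running_average is a trailing mean with prefix handling", {
  expect_equal(running_average(c(0, 2), 2), c(0, 1))
  expect_equal(running_average(rep(3.5, 100), 50), rep(3.5, 100))
  expect_equal(running_average(1:5, 1), as.numeric(1:5))
  expect_equal(running_average(c(1, 2, 3, 4), 3),
               c(1, 1.5, 2, 3))
  expect_error(running_average(1:5, 10), "exceeds")
  expect_error(running_average(1:5, 0), ">= 1")
  # variance reduction of white noise ~ 1/window
  set.seed(4)
  x <- stats::rnorm(1e4)
  sm <- running_average(x, 50)
  ratio <- stats::var(sm[51:1e4]) / stats::var(x)
  expect_gt(ratio, 0.8 / 50)
  expect_lt(ratio, 1.2 / 50)
})

test_that("rmsd_series is zero on the reference and tracks linear drift", {
  set.seed(5)
  n <- 15
  ref_xyz <- random_coords(n)
  ref <- make_structure(atom_table(n), ref_xyz)
  ens0 <- make_ensemble(ref, replicate(4, ref_xyz, simplify = FALSE))
  ser0 <- rmsd_series(ens0, ref, selection = "name CA")
  expect_equal(ser0$rmsd_ref1, rep(0, 4), tolerance = 1e-9)

  # drift from A toward B: series vs A rises, vs B falls, one crossing
  b_xyz <- ref_xyz + matrix(stats::rnorm(3 * n, sd = 2), ncol = 3)
  b <- make_structure(atom_table(n), b_xyz, "B")
  w <- seq(0, 1, length.out = 21)
  ens <- make_ensemble(ref, lapply(w, function(wi) {
    (1 - wi) * ref_xyz + wi * b_xyz
  }))
  ser <- rmsd_series(ens, ref, selection = "name CA", reference2 = b)
  expect_true(all(diff(ser$rmsd_ref1) > -1e-9))
  expect_true(all(diff(ser$rmsd_ref2) < 1e-9))
  sgn <- sign(ser$rmsd_ref1 - ser$rmsd_ref2)
  expect_equal(sum(diff(sgn[sgn != 0]) != 0), 1)
})

test_that("rmsd_series pairs atoms by identity and errors on mismatch", {
  set.seed(6)
  n <- 10
  ref <- make_structure(atom_table(n), random_coords(n))
  ens <- make_ensemble(ref, list(ref$xyz, ref$xyz + 1))
  other <- make_structure(atom_table(n, resno = seq_len(n) + 100),
                          random_coords(n))
  expect_error(rmsd_series(ens, other), "pairing failed")
})

test_that("average_structure converges to the positional mean", {
  set.seed(8)
  n <- 12
  x <- random_coords(n)
  ens_same <- make_ensemble(make_structure(atom_table(n), x),
                            list(x, x, x))
  avg <- average_structure(ens_same, "name CA")
  expect_equal(avg$xyz, x, tolerance = 1e-8)
  expect_true(avg$meta$positional_average)

  # two translation-symmetric frames average to the midpoint
  shift <- rep(c(1.5, -0.5, 2), each = n)
  ens_sym <- make_ensemble(make_structure(atom_table(n), x),
                           list(x + shift, x - shift))
  avg2 <- average_structure(ens_sym, "name CA")
  expect_equal(rmsd_pair(avg2$xyz, x), 0, tolerance = 1e-8)

  # CLT: the mean of a Gaussian ensemble approaches the reference
  sigma <- 0.3
  t_frames <- 300
  ens_g <- make_gaussian_ensemble(20, t_frames, sigma)
  avg3 <- average_structure(ens_g, "name CA")
  expect_lt(rmsd_pair(avg3$xyz, ens_g$reference$xyz),
            2 * sigma * sqrt(3) / sqrt(t_frames))
})

test_that("rmsd_matrix is a symmetric zero-diagonal premetric", {
  set.seed(9)
  n <- 8
  a <- make_structure(atom_table(n), random_coords(n), "a")
  rot <- euler_rotation(c(1, 0.2, -0.7))
  a_rot <- make_structure(atom_table(n), a$xyz %*% t(rot) + 2, "a_rot")
  c3 <- make_structure(atom_table(n), random_coords(n), "c")
  m <- rmsd_matrix(list(a, a_rot, c3), selection = "name CA")
  expect_equal(diag(m), c(a = 0, a_rot = 0, c = 0), tolerance = 1e-9)
  expect_equal(m, t(m), tolerance = 1e-9)
  expect_equal(m[1, 2], 0, tolerance = 1e-9)  # rigid invariance
  # consistency with element-wise superposition
  expect_equal(m[1, 3], rmsd_pair(a$xyz, c3$xyz), tolerance = 1e-9)
  expect_gt(m[1, 3], 0)
})

test_that("rmsf recovers known fluctuations and obeys the B conversion", {
  # static ensemble: zero everywhere
  n <- 10
  x <- random_coords(n)
  ens0 <- make_ensemble(make_structure(atom_table(n), x), list(x, x, x))
  prof0 <- rmsf_profile(ens0, "name CA")
  expect_equal(prof0$rmsf, rep(0, n), tolerance = 1e-9)
  expect_equal(prof0$b_factor, rep(0, n), tolerance = 1e-9)

  # isotropic sigma: RMSF -> sigma * sqrt(3)
  set.seed(10)
  sigma <- 0.5
  ens <- make_gaussian_ensemble(25, 2000, sigma)
  prof <- rmsf_profile(ens, "name CA")
  expect_equal(mean(prof$rmsf), sigma * sqrt(3), tolerance = 0.05)
  # field invariant B = (8 pi^2 / 3) MSF, and MSF = RMSF^2
  expect_equal(prof$b_factor, 8 * pi^2 / 3 * prof$msf, tolerance = 1e-12)
  expect_equal(prof$rmsf^2, prof$msf, tolerance = 1e-12)
  expect_equal(msf_to_bfactor(1), 8 * pi^2 / 3)
  expect_equal(bfactor_to_msf(msf_to_bfactor(2.3)), 2.3)
})

test_that("rmsf is invariant under a global rigid transform of all frames", {
  set.seed(11)
  ens <- make_gaussian_ensemble(15, 80, 0.4)
  rot <- euler_rotation(c(0.5, 1.2, -0.3))
  ens2 <- ens
  for (t in seq_len(n_frames(ens2))) {
    ens2$coords[, , t] <- ens2$coords[, , t] %*% t(rot) +
      rep(c(10, -4, 2), each = 15)
  }
  p1 <- rmsf_profile(ens, "name CA")
  p2 <- rmsf_profile(ens2, "name CA")
  expect_equal(p1$rmsf, p2$rmsf, tolerance = 1e-8)
})

test_that("flexible loops exceed the core in the generated RMSF pattern", {
  g <- generate_ensemble(generator_spec(n_frames = 400, seed = 12,
                                        sigma_core = 0.4, sigma_loop = 1.5))
  prof <- rmsf_profile(g$ensemble, "calpha")
  in_loops <- prof$residue_number %in% c(144:152, 184:193, 222:226) |
    (prof$residue_number == 221 & prof$insertion_code == "A")
  core <- prof$residue_number < 140 & prof$residue_number > 19
  expect_gt(min(prof$rmsf[in_loops]), max(prof$rmsf[core]))
})

test_that("profile_to_bfactor paints per-residue B onto the structure", {
  g <- generate_ensemble(generator_spec(n_frames = 50, seed = 13))
  prof <- rmsf_profile(g$ensemble, "calpha")
  s <- profile_to_bfactor(g$ensemble$reference, prof)
  ca_idx <- select_atoms(s, "calpha")
  key_s <- paste(s$atoms$residue_number[ca_idx],
                 s$atoms$insertion_code[ca_idx])
  key_p <- paste(prof$residue_number, prof$insertion_code)
  expect_equal(s$atoms$b_factor[ca_idx],
               prof$b_factor[match(key_s, key_p)])
})
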