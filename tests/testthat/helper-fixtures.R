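# Fixtures and independent oracles, all built in code at test time.

# --- tiny PDB fixture writer (fixed-width, wwPDB v3.3 columns) ------------

pdb_atom_line <- function(serial, name, resname, chain, resno, icode,
                          x, y, z, b = 0, element = "C") {
  sprintf("ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), resname, chain, resno, icode,
          x, y, z, 1.0, b, element)
}

write_fixture_pdb <- function(path, models) {
  # models: list of data frames with columns name, resname, chain, resno,
  # icode, x, y, z, b, element
  lines <- character()
  multi <- length(models) > 1
  for (m in seq_along(models)) {
    df <- models[[m]]
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_len(nrow(df))) {
      lines <- c(lines, pdb_atom_line(i, df$name[i], df$resname[i],
                                      df$chain[i], df$resno[i], df$icode[i],
                                      df$x[i], df$y[i], df$z[i],
                                      df$b[i], df$element[i]))
    }
    if (multi) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  path
}

# Minimal protease-domain-like fixture: CA trace for residues 16..30 plus
# side-chain probes, ILE16/VAL17/GLY18 tail, and a 221A insertion block.
fixture_atoms <- function() {
  resno <- c(16:30, 221, 221, 222)
  icode <- c(rep("", 15), "", "A", "")
  resname <- c("ILE", "VAL", "GLY", "GLY", rep("ALA", 11),
               "ALA", "ALA", "ALA")
  data.frame(name = "CA", resname = resname, chain = "A", resno = resno,
             icode = icode,
             x = seq_along(resno) * 3.8, y = 0, z = 0, b = 10,
             element = "C", stringsAsFactors = FALSE)
}

# --- direct ensemble construction ----------------------------------------

make_structure <- function(atoms, xyz, label = "fixture") {
  zymodyn:::new_structure(atoms, xyz, label)
}

make_ensemble <- function(reference, frames, label = "fixture") {
  coords <- array(NA_real_, dim = c(nrow(reference$atoms), 3,
                                    length(frames)))
  for (t in seq_along(frames)) coords[, , t] <- frames[[t]]
  zymodyn:::new_ensemble(reference, coords, label = label)
}

atom_table <- function(n, resno = seq_len(n) + 15, name = "CA",
                       resname = "ALA", element = "C") {
  df <- data.frame(atom_name = rep(name, n)[seq_len(n)],
                   residue_name = rep(resname, n)[seq_len(n)],
                   chain_id = "A",
                   residue_number = resno,
                   insertion_code = "",
                   element = rep(element, n)[seq_len(n)],
                   b_factor = 0,
                   stringsAsFactors = FALSE)
  df$mass <- suppressWarnings(zymodyn::element_mass(df$element))
  df
}

random_coords <- function(n, scale = 10) {
  matrix(stats::runif(3 * n, -scale, scale), ncol = 3)
}

# Gaussian ensemble about a fixed reference (iid per frame, per atom).
make_gaussian_ensemble <- function(n_atoms, t_frames, sigma,
                                   reference = NULL, label = "gauss") {
  if (is.null(reference)) reference <- random_coords(n_atoms)
  frames <- lapply(seq_len(t_frames), function(t) {
    reference + matrix(stats::rnorm(3 * n_atoms, sd = sigma), ncol = 3)
  })
  make_ensemble(make_structure(atom_table(n_atoms), reference, label),
                frames, label)
}

# Site-only ensemble whose (d_57, d_195) distances are prescribed exactly:
# 57/CG at the origin, 195/OG at (0, 0, c); the 215/CG probe solves the
# two-sphere constraint per frame.
make_site_ensemble <- function(d_57, d_195, c_sep = 5) {
  stopifnot(length(d_57) == length(d_195))
  atoms <- data.frame(
    atom_name = c("CA", "CG", "CA", "OG", "CA", "CG"),
    residue_name = c("HIS", "HIS", "SER", "SER", "TRP", "TRP"),
    chain_id = "A",
    residue_number = c(57, 57, 195, 195, 215, 215),
    insertion_code = "",
    element = c("C", "C", "C", "O", "C", "C"),
    b_factor = 0, stringsAsFactors = FALSE)
  atoms$mass <- zymodyn::element_mass(atoms$element)
  place <- function(r1, r2) {
    z <- (r1^2 - r2^2 + c_sep^2) / (2 * c_sep)
    x <- sqrt(max(r1^2 - z^2, 0))
    c(x, 0, z)
  }
  ref <- rbind(c(-2, 0, 0), c(0, 0, 0), c(-2, 0, c_sep), c(0, 0, c_sep),
               c(10, 0, 0), place(d_57[1], d_195[1]))
  frames <- lapply(seq_along(d_57), function(t) {
    f <- ref
    f[6, ] <- place(d_57[t], d_195[t])
    f
  })
  make_ensemble(make_structure(atoms, ref, "site"), frames, "site")
}

# --- independent oracles --------------------------------------------------

# Brute-force rotational minimiser: optimises Euler angles numerically
# after centroid removal, with multiple restarts.  Independent of the SVD
# path it checks.
euler_rotation <- function(a) {
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  rz %*% ry %*% rx
}

brute_force_rmsd <- function(mobile, target, n_starts = 12) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(target, 2, colMeans(target))
  obj <- function(a) {
    sqrt(mean(rowSums((p %*% t(euler_rotation(a)) - q)^2)))
  }
  best <- Inf
  starts <- rbind(c(0, 0, 0),
                  matrix(stats::runif(3 * (n_starts - 1), -pi, pi),
                         ncol = 3))
  for (s in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[s, ], obj, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    best <- min(best, fit$value)
  }
  best
}

# Quadratic-time textbook UPGMA: scan for the global minimum, merge,
# average the distances weighted by cluster sizes.
upgma_reference <- function(d) {
  n <- nrow(d)
  active <- seq_len(n)
  sizes <- rep(1, n)
  dm <- d
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    best_val <- Inf
    for (i in seq_along(active)[-length(active)]) {
      for (j in (i + 1):length(active)) {
        if (dm[i, j] < best_val) {
          best_val <- dm[i, j]
          best <- c(i, j)
        }
      }
    }
    heights[step] <- best_val
    i <- best[1]; j <- best[2]
    ni <- sizes[i]; nj <- sizes[j]
    new_row <- (ni * dm[i, ] + nj * dm[j, ]) / (ni + nj)
    keep <- setdiff(seq_along(active), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], new_row[keep]),
                c(new_row[keep], 0))
    sizes <- c(sizes[keep], ni + nj)
    active <- c(active[keep], n + step)
  }
  heights
}

# Adjusted Rand index between two label vectors.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_index <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  (sum_ij - exp_index) / (max_index - exp_index)
}

# Asymptotic standard error of the occupation fraction of a two-state
# Markov chain with switching probabilities a (open->closed) and
# b (closed->open): var = p(1-p)(2-a-b) / ((a+b) T).
markov_se <- function(a, b, t_frames) {
  p <- b / (a + b)
  sqrt(p * (1 - p) * (2 - a - b) / ((a + b) * t_frames))
}
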