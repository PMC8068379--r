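# Seeded synthetic-ensemble generator.  Emits multi-model ensembles with
# the statistical structure the analyses assume: a numbering-faithful
# C-alpha scaffold in chymotrypsin numbering (16-245 plus the 221A
# insertion), per-residue Gaussian fluctuations with region-dependent
# amplitude (rigid core vs flexible activation loops and S1 rim), two-state
# Markov switching of the 215/CG probe between a substrate-accessible and
# an occluded placement, and optional per-frame rigid-body motion.  The
# scaffold is NOT a physical protein model; it is a ground-truth-known
# stand-in with the right statistics.

#' Specification for the synthetic-ensemble generator
#'
#' @param n_frames Number of frames to generate.
#' @param seed RNG seed; identical specs and seeds give bit-identical
#'   ensembles.
#' @param sigma_core Per-axis Gaussian fluctuation of core residues,
#'   Angstrom (default 0.4).
#' @param sigma_loop Fluctuation of flexible-region residues (activation
#'   loops AL1-3 plus the S1 rim 190-195), Angstrom (default 1.5); applied
#'   only when `loop_flex_enabled`.
#' @param sigma_site Jitter of the three classifier site atoms (57/CG,
#'   195/OG, 215/CG), Angstrom (default 0.15). Kept small and
#'   region-independent so the two-state placement, not residue-level
#'   noise, carries the probe's motion.
#' @param loop_flex_enabled Apply `sigma_loop` to the flexible regions
#'   (plastic/zymogen-like presets); otherwise all residues use
#'   `sigma_core`.
#' @param markov_a Per-frame switching probability accessible -> occluded.
#' @param markov_b Per-frame switching probability occluded -> accessible.
#'   The stationary accessible fraction is `markov_b / (markov_a +
#'   markov_b)`.
#' @param include_n_tail Include residues 16-18 (intact construct); `FALSE`
#'   emulates a desIVG/zymogen construct.
#' @param rigid_motion Apply a random per-frame rigid rotation and
#'   translation (analyses must be invariant to it).
#' @param state_geometry List with numeric vectors `accessible` and
#'   `occluded`, each `c(d_57, d_195)` in Angstrom, defining the probe
#'   placement in the two states. Defaults (8.0, 7.5) and (5.0, 4.5) sit
#'   at least 1.5 A away from the 6.5/6.0 A classification cut-offs.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(n_frames = 1000, seed = 1,
                           sigma_core = 0.4, sigma_loop = 1.5,
                           sigma_site = 0.15, loop_flex_enabled = TRUE,
                           markov_a = 0.05, markov_b = 0.05,
                           include_n_tail = TRUE, rigid_motion = FALSE,
                           state_geometry = list(
                             accessible = c(d_57 = 8.0, d_195 = 7.5),
                             occluded = c(d_57 = 5.0, d_195 = 4.5))) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (sigma_core <= 0 || sigma_loop <= 0 || sigma_site <= 0) {
    stop("fluctuation sigmas must be positive")
  }
  for (p in c(markov_a, markov_b)) {
    if (p <= 0 || p > 1) stop("Markov switching probabilities must lie in (0, 1]")
  }
  g <- state_geometry
  if (!all(c("accessible", "occluded") %in% names(g)) ||
      any(vapply(g, length, 0L) != 2) || any(unlist(g) <= 0)) {
    stop("state_geometry needs positive `accessible` and `occluded` ",
         "distance pairs")
  }
  out <- list(n_frames = as.integer(n_frames), seed = as.integer(seed),
              sigma_core = sigma_core, sigma_loop = sigma_loop,
              sigma_site = sigma_site,
              loop_flex_enabled = loop_flex_enabled,
              markov_a = markov_a, markov_b = markov_b,
              include_n_tail = include_n_tail,
              rigid_motion = rigid_motion, state_geometry = g)
  class(out) <- "generator_spec"
  out
}

#' Stationary accessible fraction of a generator spec
#' @param spec A `generator_spec`.
#' @return `markov_b / (markov_a + markov_b)`.
#' @export
stationary_accessible <- function(spec) {
  spec$markov_b / (spec$markov_a + spec$markov_b)
}

# Residue roster: chymotrypsin numbers 16-245 with the 221A insertion.
.scaffold_residues <- function(include_n_tail) {
  resno <- 16:245
  icode <- rep("", length(resno))
  at <- which(resno == 221)
  resno <- append(resno, 221L, after = at)
  icode <- append(icode, "A", after = at)
  if (!include_n_tail) {
    keep <- !(resno %in% 16:18)
    resno <- resno[keep]
    icode <- icode[keep]
  }
  data.frame(resno = resno, icode = icode, stringsAsFactors = FALSE)
}

# Alpha-helix-like smooth curve: 2.3 A radius, 100 deg turn and 1.5 A rise
# per residue gives a constant C-alpha spacing of ~3.83 A (>= 3.8 A).
.helix_ca <- function(n) {
  i <- seq_len(n) - 1
  theta <- i * 100 * pi / 180
  cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
}

# Point at given distances (r_a, r_b) from anchors a and b, offset along a
# unit vector `w` perpendicular to b - a.
.bilaterate <- function(a, b, r_a, r_b, w) {
  ab <- b - a
  d2 <- sum(ab^2)
  t <- (d2 + r_a^2 - r_b^2) / (2 * d2)
  x0 <- a + t * ab
  rc2 <- r_a^2 - t^2 * d2
  if (rc2 <= 0) stop("state geometry infeasible for the scaffold site")
  x0 + sqrt(rc2) * w
}

.flexible_residue_mask <- function(res) {
  (res$resno >= 144 & res$resno <= 152) |               # AL1
    (res$resno >= 184 & res$resno <= 193) |             # AL2
    (res$resno >= 222 & res$resno <= 226) |             # AL3 tail
    (res$resno == 221 & res$icode == "A") |             # AL3 start (221A)
    (res$resno >= 190 & res$resno <= 195)               # S1 rim
}

.random_rotation <- function() {
  # uniform rotation from a normalised random quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Generate a synthetic ensemble with known ground truth
#'
#' Builds the reference scaffold (one C-alpha per residue plus
#' pseudo-side-chain atoms 57/CG, 195/OG and 215/CG), simulates the
#' two-state Markov chain of the 215-217 segment, and adds per-residue
#' Gaussian fluctuations (and, optionally, per-frame rigid motion).
#'
#' @param spec A [generator_spec()].
#' @param label Label for the emitted ensemble.
#' @return List with `ensemble` (a `zymo_ensemble`; zymogenized metadata is
#'   set when the N-tail is absent) and `truth` (class `ground_truth`:
#'   per-frame `states`/`accessible`, `stationary_p`, `n_transitions`,
#'   per-residue `sigma`, and the `spec`).
#' @export
generate_ensemble <- function(spec, label = "synthetic") {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  res <- .scaffold_residues(spec$include_n_tail)
  n_res <- nrow(res)
  ca <- .helix_ca(n_res)

  resname <- rep("ALA", n_res)
  resname[res$resno == 19 & res$icode == ""] <- "GLY"
  resname[res$resno == 57 & res$icode == ""] <- "HIS"
  resname[res$resno == 195 & res$icode == ""] <- "SER"
  resname[res$resno == 215 & res$icode == ""] <- "TRP"

  rows <- data.frame(
    atom_name = rep("CA", n_res), residue_name = resname,
    chain_id = "A", residue_number = res$resno,
    insertion_code = res$icode, element = "C", b_factor = 0,
    stringsAsFactors = FALSE
  )
  xyz <- ca
  add_atom <- function(resno, name, elem, pos) {
    at <- max(which(rows$residue_number == resno & rows$insertion_code == ""))
    rows <<- rbind(rows[1:at, ],
                   data.frame(atom_name = name,
                              residue_name = rows$residue_name[at],
                              chain_id = "A", residue_number = resno,
                              insertion_code = "", element = elem,
                              b_factor = 0, stringsAsFactors = FALSE),
                   rows[-(1:at), ])
    xyz <<- rbind(xyz[1:at, , drop = FALSE], pos, xyz[-(1:at), , drop = FALSE])
  }

  # Active-site construction: 57/CG radially out from the helix axis,
  # 195/OG 5 A above it along the axis; the probe placements solve the
  # two-sphere (d_57, d_195) constraints of each state.  Sequence-distant
  # catalytic residues are not spatially adjacent on a smooth curve, so the
  # site is built as its own geometric unit (toy scaffold, not physics).
  i57 <- which(res$resno == 57 & res$icode == "")
  axis_pt <- c(0, 0, ca[i57, 3])
  u <- ca[i57, ] - axis_pt
  u <- u / sqrt(sum(u^2))
  cg57 <- ca[i57, ] + 1.5 * u
  og195 <- cg57 + c(0, 0, 5)
  g <- spec$state_geometry
  p_open <- .bilaterate(cg57, og195, g$accessible[1], g$accessible[2], u)
  p_occl <- .bilaterate(cg57, og195, g$occluded[1], g$occluded[2], u)

  add_atom(57, "CG", "C", cg57)
  add_atom(195, "OG", "O", og195)
  add_atom(215, "CG", "C", p_open)
  rows$mass <- suppressWarnings(element_mass(rows$element))
  reference <- new_structure(rows, xyz, label)

  n_at <- nrow(rows)
  is_site <- (rows$residue_number == 57 & rows$atom_name == "CG") |
    (rows$residue_number == 195 & rows$atom_name == "OG") |
    (rows$residue_number == 215 & rows$atom_name == "CG")
  flex <- .flexible_residue_mask(
    data.frame(resno = rows$residue_number, icode = rows$insertion_code))
  sigma_atom <- ifelse(is_site, spec$sigma_site,
                       ifelse(flex & spec$loop_flex_enabled,
                              spec$sigma_loop, spec$sigma_core))
  i_probe <- which(rows$residue_number == 215 & rows$atom_name == "CG")

  # Markov chain of the 215-217 segment state
  t_frames <- spec$n_frames
  p_stat <- stationary_accessible(spec)
  acc <- logical(t_frames)
  acc[1] <- stats::runif(1) < p_stat
  if (t_frames > 1) {
    u01 <- stats::runif(t_frames - 1)
    for (t in 2:t_frames) {
      acc[t] <- if (acc[t - 1]) u01[t - 1] >= spec$markov_a
                else u01[t - 1] < spec$markov_b
    }
  }

  noise <- array(stats::rnorm(n_at * 3 * t_frames, sd = sigma_atom),
                 dim = c(n_at, 3, t_frames))
  coords <- array(xyz, dim = c(n_at, 3, t_frames)) + noise
  for (t in seq_len(t_frames)) {
    coords[i_probe, , t] <- (if (acc[t]) p_open else p_occl) +
      noise[i_probe, , t]
  }
  if (spec$rigid_motion) {
    for (t in seq_len(t_frames)) {
      rot <- .random_rotation()
      shift <- stats::rnorm(3, sd = 2)
      coords[, , t] <- sweep(coords[, , t] %*% rot, 2, -shift)
    }
  }

  ens <- new_ensemble(reference, coords, label = label)
  if (!spec$include_n_tail) ens$meta$zymogenized <- TRUE
  sigma_res <- sigma_atom[rows$atom_name == "CA"]
  names(sigma_res) <- paste0(rows$residue_number[rows$atom_name == "CA"],
                             rows$insertion_code[rows$atom_name == "CA"])
  truth <- list(states = ifelse(acc, "accessible", "occluded"),
                accessible = acc,
                stationary_p = p_stat,
                n_transitions = if (t_frames >= 2) {
                  sum(acc[-1] != acc[-t_frames])
                } else 0L,
                sigma = sigma_res,
                spec = spec)
  class(truth) <- "ground_truth"
  list(ensemble = ens, truth = truth)
}

#' Generator presets emulating the studied construct classes
#'
#' Each preset fixes the flexibility and state-equilibrium regime of one
#' construct class: `trypsin_like` (rigid, locked accessible),
#' `vyt_like` (a trypsin-mimicking engineered variant: rigid, accessible),
#' `trypsinogen_like` (zymogen: flexible loops, no N-tail, accessible),
#' `fviia_like` (plastic loops, predominantly occluded),
#' `fviia_desIVG_like` (most plastic, no N-tail, predominantly occluded)
#' and `near_boundary` (a stress preset whose state geometries sit only
#' 0.2 A from the classification cut-offs).
#'
#' @param name Preset name.
#' @param n_frames,seed Passed through to [generator_spec()].
#' @return A `generator_spec`.
#' @export
preset_spec <- function(name = c("trypsin_like", "vyt_like",
                                 "trypsinogen_like", "fviia_like",
                                 "fviia_desIVG_like", "near_boundary"),
                        n_frames = 1000, seed = 1) {
  name <- tryCatch(match.arg(name), error = function(e) {
    stop("unknown preset '", name[1], "'; known: trypsin_like, vyt_like, ",
         "trypsinogen_like, fviia_like, fviia_desIVG_like, near_boundary")
  })
  args <- switch(name,
    trypsin_like = list(loop_flex_enabled = FALSE,
                        markov_a = 0.001, markov_b = 0.1),
    vyt_like = list(loop_flex_enabled = FALSE, sigma_core = 0.45,
                    markov_a = 0.002, markov_b = 0.1),
    trypsinogen_like = list(loop_flex_enabled = TRUE, sigma_loop = 1.2,
                            include_n_tail = FALSE,
                            markov_a = 0.001, markov_b = 0.1),
    fviia_like = list(loop_flex_enabled = TRUE, sigma_loop = 1.5,
                      markov_a = 0.08, markov_b = 0.02),
    fviia_desIVG_like = list(loop_flex_enabled = TRUE, sigma_loop = 2.0,
                             include_n_tail = FALSE,
                             markov_a = 0.08, markov_b = 0.02),
    near_boundary = list(state_geometry = list(
      accessible = c(d_57 = 6.7, d_195 = 6.2),
      occluded = c(d_57 = 6.3, d_195 = 5.8)))
  )
  do.call(generator_spec, c(list(n_frames = n_frames, seed = seed), args))
}
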