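---
title: "Methods: conformational-ensemble analysis of trypsin-like protease domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational-ensemble analysis of trypsin-like protease domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zymodyn)
```

## Scope and model

Trypsin-like serine proteases are synthesised as inactive zymogens.
Proteolytic activation inserts the newly formed N-terminus (residue I16 in
chymotrypsin numbering) into the activation pocket, where the I16-D194 salt
bridge stabilises the catalytically competent conformation, matures the S1
specificity pocket and orders the activation loops AL1 (residues 144-152),
AL2 (184-193) and AL3 (221A-226). zymodyn analyses conformational ensembles
of such domains with the converse operation as its anchor: *in-silico
zymogenization*, the removal of the inserted tail ¹⁶IVG¹⁸ to produce a
"desIVG" construct whose ensemble relaxes toward zymogen-like behaviour.

The package operates on multi-model coordinate ensembles (one PDB MODEL per
frame) and provides five analysis layers:

1. **Geometry** — single-pass Kabsch least-squares superposition (no
   outlier-rejection cycles), RMSD series and matrices, iterated average
   structures, per-residue RMSF and the Debye-Waller conversion
   \(B_i = \tfrac{8\pi^2}{3}\,\langle \mathrm{MSF}_i \rangle\).
2. **State classification** — each frame is assigned to the
   substrate-accessible state (E, or Z in a zymogenized construct) when the
   W215/CG-H57/CG distance strictly exceeds 6.5 Å *and* the W215/CG-S195/OG
   distance strictly exceeds 6.0 Å; otherwise it is occluded (E*/Z*).
   Populations carry a 1000-resample bootstrap standard error.
3. **Essential dynamics** — PCA of the mass-weighted covariance of heavy-atom
   positional fluctuations; the PC1-PC2 score variance quantifies
   "subspace compactness" (small = rigid, large = plastic).
4. **Clustering and correlations** — UPGMA (average-linkage) agglomeration
   of frames on pairwise superposed Cα RMSD, and dynamic cross-correlation
   maps \(C_{ij} = \langle \Delta r_i \cdot \Delta r_j\rangle /
   \sqrt{\langle|\Delta r_i|^2\rangle \langle|\Delta r_j|^2\rangle}\).
5. **T-REMD protocol arithmetic** — arithmetic temperature ladders,
   exchange-attempt scheduling and acceptance statistics from swap logs.
   The MD engine itself is out of scope; engine settings are carried as
   opaque metadata only.

## Conventions and numerical choices

**Numbering.** All residue identifiers are chymotrypsin numbering taken
verbatim from the input, insertion codes included (170A-170C, 221A). No
renumbering is performed: the compared constructs are numbering-consistent
variants, so atom pairing is by (residue number, insertion code, atom name)
identity and no sequence alignment is embedded.

**Superposition.** `kabsch_superpose()` is a single weighted least-squares
pass with the SVD reflection branch corrected to a proper rotation
(det = +1). No rejection cycles are run, matching the convention of
aligning without outlier pruning. Fewer than 3 atoms is an error;
collinear sets warn but still return a minimising transform.

**Average structures.** `average_structure()` iterates
superpose-to-running-mean until the mean moves less than 1e-6 Å (at most
100 iterations), because a single-pass mean depends on the arbitrary
initial frame. The output is flagged as a positional average: it is not a
realisable conformation (bond geometry is not preserved).

**Running averages** are trailing means (the last `min(k, window)` points,
window 50 by default in the pipeline). A trailing window preserves the
causality of the time series; the choice is config-exposed.

**RMSF.** Frames are superposed onto the iterated mean before computing
fluctuations; per-residue MSF is the unweighted mean over the member atoms
of the selection ("each atom in the residue selection contributes"), RMSF
its square root, and B the Debye-Waller conversion above, held as an exact
field invariant.

**Classifier boundaries.** The inequalities are strict exactly as stated;
tie frames (a measure-zero event) are occluded. E vs Z nomenclature is
purely a labelling concern keyed to zymogenization metadata — the geometry
test is identical.

**Bootstrap.** The population estimate is the exact label mean; the
bootstrap touches only the standard error. Frames are resampled iid with
replacement (1000 resamples by default). Because MD frames are
autocorrelated, a moving-block bootstrap (`block_length`) is provided; iid
remains the default to mirror the plain bootstrap convention. For
validation against a two-state Markov chain with switching probabilities
\(a, b\), the appropriate sampling error of the occupation fraction is the
chain's asymptotic standard error
\(\sqrt{p(1-p)(2-a-b)/((a+b)T)}\), not the binomial formula — the tests use
it wherever a stationary population is recovered.

**PCA.** The covariance is normalised by \(T\) (population convention;
immaterial for eigenvectors, documented for eigenvalue tests), and
eigenvector signs are fixed by making the largest-magnitude component
positive, so projections are reproducible across runs and linear-algebra
backends. Superposition before PCA uses the same selection as the analysis
itself. Compactness is reported as the PC1-PC2 score variance (primary)
with the convex-hull area of the scatter as a secondary, outlier-sensitive
summary.

**UPGMA.** The distance is the pairwise superposed RMSD (each pair fitted
independently, never one-reference RMSD). Agglomeration is delegated to
`stats::hclust(method = "average")`, which implements textbook UPGMA; the
test suite holds it against an independent quadratic-time agglomerator on
random instances. Frames can be strided, with a guard (default 2000
frames) on the quadratic matrix.

**DCC.** Zero-fluctuation atoms would divide by zero; their rows/columns
are zeroed (unit diagonal retained) with a warning. Note a finite-size
caveat: the shared 6-degree-of-freedom superposition induces spurious
correlations of order \(1/N\), visible for toy systems with few atoms and
negligible at protein-sized \(N\).

## The synthetic-ensemble generator

No trajectories are distributed with the package, so every stage is
validated against a seeded generator (`generator_spec()`,
`generate_ensemble()`) that emits ensembles with known ground truth. It
emulates exactly the statistical structure the analyses assume:

- a numbering-faithful scaffold — one Cα per residue 16-245 plus the 221A
  insertion, laid on a smooth helical curve with ≥ 3.8 Å Cα spacing, plus
  pseudo-side-chain atoms 57/CG, 195/OG and 215/CG;
- iid per-frame Gaussian positional noise with region-dependent amplitude:
  `sigma_core` 0.4 Å, and `sigma_loop` 1.5 Å on AL1-3 and the S1 rim
  (190-195) when loop flexibility is enabled — amplitudes chosen to give
  core RMSF under 1 Å and loop RMSF of a few Å, the contrast seen between
  rigid proteases and their zymogen-like forms;
- two-state Markov switching of the 215/CG probe between an accessible
  placement (d₅₇ = 8.0 Å, d₁₉₅ = 7.5 Å) and an occluded one (5.0, 4.5 Å),
  both at least 1.5 Å from the 6.5/6.0 Å cut-offs so classifier tests probe
  thresholds, not noise (a `near_boundary` stress preset with 0.2 Å margins
  exists for boundary testing);
- optional per-frame rigid-body motion, against which every analysis must
  be invariant.

Two deliberate design points. First, the three site atoms carry their own
small jitter (`sigma_site`, 0.15 Å) independent of the region sigmas:
residue 195 lies in the flexible S1 rim, and letting a 1.5 Å loop sigma act
on the anchor would swamp the constructed state margins — the two-state
placement, not residue-level noise, is meant to carry the probe's motion.
Second, the active site is built as its own geometric unit (195/OG is
placed 5 Å from 57/CG rather than near its own Cα), because
sequence-distant catalytic residues are not spatially adjacent on a smooth
curve. Both points underline what the scaffold is: a ground-truth-known
statistical stand-in, *not* a physical protein model — it has no sterics,
bonds, or Ramachandran structure, and passing tests demonstrate estimator
correctness, not force-field realism. Real ensembles additionally carry
temporal correlation of the noise (here only the state variable is
autocorrelated), anisotropic and collective motions, and solvent effects.

Presets encode the construct classes studied with these tools:
`trypsin_like` (rigid, locked accessible: a = 0.001, b = 0.1, stationary
accessible fraction ≈ 0.99), `vyt_like` (an engineered, trypsin-mimicking
variant: rigid, accessible), `trypsinogen_like` (flexible loops, no N-tail,
accessible), `fviia_like` (plastic, predominantly occluded: a = 0.08,
b = 0.02, accessible fraction 0.2) and `fviia_desIVG_like` (no N-tail and
the largest loop sigma — the most plastic preset). The switching rates and
sigma levels were chosen once to reproduce the qualitative regime of each
class (near-locked vs intermittently switching; compactness increasing
from rigid enzyme to truncated zymogen-like construct) and are part of the
generator's definition, not tuning knobs.

## Problem sizes used in validation

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which the statistical checks are sharp: parameter
recovery uses 5000-frame ensembles (~234 atoms), population grids 4000
frames, PCA monotonicity 800 frames, oracle comparisons 100 random
instances each for superposition (≤ 8 atoms) and UPGMA (≤ 10 leaves), and
the pipeline demonstration 120 frames per construct.

## Known limitations

- Only PDB-format ensembles are read; binary trajectory formats would need
  an external conversion step honouring the same multi-model contract.
- Absolute dwell times cannot be reported in physical units unless the
  user supplies the frame-saving interval; everything is per-frame.
- The iid bootstrap understates the SE on strongly autocorrelated series;
  use `block_length` when that matters.
- `average_structure` output is non-physical by construction (positional
  averaging does not preserve bond geometry).
- Cross-construct DCC similarity has no principled threshold here; any
  such comparison is exploratory.

## A compact worked example

```{r example, eval = FALSE}
set.seed(1)
rigid <- generate_ensemble(preset_spec("trypsin_like",
                                       n_frames = 500, seed = 1),
                           label = "rigid")
plastic <- generate_ensemble(preset_spec("fviia_like",
                                         n_frames = 500, seed = 2),
                             label = "plastic")

population(classify_frames(rigid$ensemble), n_boot = 1000, seed = 3)
population(classify_frames(plastic$ensemble), n_boot = 1000, seed = 3)

subspace_compactness(pca_ensemble(rigid$ensemble, "heavy",
                                  n_components = 2))$pc_variance
subspace_compactness(pca_ensemble(plastic$ensemble, "heavy",
                                  n_components = 2))$pc_variance
```

The rigid preset classifies almost entirely accessible with a small
PC1-PC2 variance; the plastic preset is predominantly occluded with a much
larger one — the rigidity/plasticity contrast the analyses are designed to
resolve.
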