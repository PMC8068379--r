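Package: zymodyn
Title: Conformational Ensemble Analysis for Trypsin-Like Serine Protease Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of conformational ensembles of trypsin-like serine
    protease domains in chymotrypsin numbering. Provides multi-model PDB
    input/output with insertion-code awareness, in-silico zymogenization by
    truncation of the inserted N-terminal tail (desIVG constructs), Kabsch
    superposition with RMSD/RMSF profiling and Debye-Waller B-factor
    conversion, a two-state geometric classifier of the 215-217 segment
    (substrate-accessible E/Z versus occluded E*/Z*) with bootstrap
    population errors, mass-weighted essential-dynamics principal component
    analysis, UPGMA clustering of frames on pairwise C-alpha RMSD, dynamic
    cross-correlation maps, temperature replica-exchange ladder design with
    exchange-log statistics, and a seeded synthetic-ensemble generator with
    region-dependent flexibility and Markov state switching for end-to-end
    validation without molecular dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
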