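Package: cgbsdock
Title: Restrained Conjugate-Gradient Refinement and Rescoring of Docked
    Ligand Poses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-docking refinement and rescoring of protein-ligand binding
    poses. Implements a conjugate-gradient geometry optimizer with Armijo
    backtracking line search (CG-BS), harmonic positional and torsional
    restraints, frozen-region support, and pluggable potential-energy
    backends (analytic test potentials and an adapter for the ANI-2x
    machine-learning potential). Provides the pocket truncation and
    frozen/active region protocol, binding-energy rescoring
    (dEbind = Ecom - Erec - Elig) and pose re-ranking, receptor-anchored
    ligand RMSD, Top-1/3/5/10 docking-power analysis, Pearson/Spearman
    scoring- and ranking-power metrics, Ki-to-energy conversion and
    compound-selection filters, plus deterministic synthetic toy complexes,
    decoy pose sets and screening tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
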