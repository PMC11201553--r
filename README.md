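# cgbsdock

Post-docking refinement and rescoring of protein–ligand binding poses in R.

Docking engines are good at generating near-native ligand poses but much
weaker at *ranking* them: the pose with the best docking score is often not
the most native-like one, and docking scores correlate poorly with measured
binding affinities. `cgbsdock` implements the follow-up step that addresses
this: each docked pose is geometry-optimized in a truncated, restrained
binding pocket under an accurate potential-energy backend, rescored by its
binding energy, and re-ranked — together with the full evaluation machinery
(docking, scoring and ranking power) needed to quantify whether the
refinement helped.

## What is implemented

**CG-BS optimizer.** A nonlinear conjugate-gradient minimizer
(Polak–Ribière+ update, periodic steepest-descent restarts) with an Armijo
backtracking line search; the curvature (second Wolfe) condition is
monitored per step. Convergence uses the four standard quantum-chemistry
criteria in atomic units: max force ≤ 0.00045 Hartree/Bohr, RMS force
≤ 0.0003, max displacement ≤ 0.0018 Bohr, RMS displacement ≤ 0.0012, all
compared with ≤ on per-atom vector norms of the free atoms.

**Pocket protocol.** The receptor is truncated to whole residues within a
radius (default 12 Å) of the ligand's geometric center, with hydrogen caps
on severed backbone bonds. Receptor atoms within 2.5 Å of any ligand atom
form the *active part* (harmonic positional restraint, k = 5 kcal/mol/Å²,
encoded as a B-factor "temperature coefficient" of 5.00); the rest is the
*frozen part* (B-factor −1.00, immobile). Ligand atoms are unrestrained.

**Rescoring.** After minimizing the complex, the binding energy is

&nbsp;&nbsp;&nbsp;&nbsp;ΔE_bind = E_com − E_rec − E_lig

with E_rec and E_lig single-point energies of the components at their
in-complex optimized coordinates; poses are ranked by ascending ΔE_bind.

**Potential backends.** Analytic Lennard-Jones and harmonic-well test
potentials, harmonic positional and torsional restraint terms, arbitrary
composites with frozen-atom masks, and an adapter for the ANI-2x
machine-learning potential (H/C/N/O/S/F/Cl; requires the `torchani` Python
package). Every backend obeys one contract: coordinates (Å) in, energy
(kcal/mol) and forces (kcal/mol/Å) out, with forces equal to the negative
energy gradient.

**Evaluation metrics.** Receptor-anchored ligand RMSD (Kabsch superposition
on receptor atoms only, so ligand movement inside the pocket counts),
Top-1/3/5/10 docking-power categories and success rates, Pearson R (scoring
power), Spearman ρ (ranking power), Ki → ΔG conversion (RT ln Ki) and the
affinity-tier compound-selection filters.

**Synthetic fixtures.** Deterministic LJ toy complexes (native ligand at
the global minimum of the receptor's adsorption landscape), rigid-body
decoy pose sets, and affinity-stratified screening tables — so the entire
pipeline is testable without a docking engine or any download.

## Worked example

```r
library(cgbsdock)

# toy receptor slab + native ligand, and 10 docking-like decoy poses
toy    <- make_toy_complex(n_receptor_atoms = 18, n_ligand_atoms = 1, seed = 7)
decoys <- make_decoys(toy$ligand, n_decoys = 10, max_translation = 2,
                      max_rotation = 0, seed = 107)

# frozen/active assignment and restrained refinement of every pose
asg <- assign_regions(toy$receptor, toy$ligand, boundary = 2.5)
res <- refine_pose_set(toy$receptor, decoys, asg, lj_pair_model(1, 1),
                       control = cgbs_control(max_iterations = 300))
res$scores[order(res$scores$rank)[1:3], ]
#>    pose_id    E_com    E_rec E_lig delta_E_bind converged rank
#> 9  pose_09 -41.1588 -32.8121     0     -8.34669      TRUE    1
#> 8  pose_08 -41.0911 -32.7457     0     -8.34544      TRUE    2
#> 10 pose_10 -41.1931 -32.8477     0     -8.34539      TRUE    3

# receptor-anchored RMSD of each refined pose to the native complex
native <- combine_structures(toy$receptor, toy$ligand)
lig    <- seq.int(n_atoms(toy$receptor) + 1, n_atoms(native))
rmsd   <- sapply(res$structures, receptor_anchored_rmsd,
                 reference_complex = native, ligand_selection = lig)
top_category_minima(rmsd[order(res$scores$rank)], tolerance = 0.05)
#> top-category minima (A): top1=0.10 top3=0.10 top5=0.10 top10=0.10;
#> first category Top 1 (success)
```

The rank-1 pose has the most negative binding energy (−8.35 kcal/mol; the
single-atom ligand has E_lig = 0, and E_rec absorbs the restrained pocket's
internal energy) and lies 0.10 Å from the native site, so the lowest RMSD
among the top 10 already occurs at Top 1 — a docking-power "success".

A thin command-line wrapper over the same functions ships in
`inst/cli/cgbsdock` (`optimize`, `prep`, `score`, `evaluate`, `fixtures`
subcommands).

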