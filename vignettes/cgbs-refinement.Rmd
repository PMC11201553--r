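---
title: "Restrained CG-BS pose refinement: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restrained CG-BS pose refinement: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgbsdock)
```

This vignette is the package's own account of the science it implements:
the optimization algorithm, the pocket restraint protocol, the rescoring
model, the evaluation metrics, and the reasoning behind every numerical
choice that the interfaces expose.

## The problem

A docking engine produces a ranked list of candidate ligand poses. Two
distinct failure modes follow: the pose ranked first is often not the most
native-like one among the candidates (weak *docking power*), and the
scores correlate poorly with measured affinities (weak *scoring* and
*ranking power*). The package implements the corrective step: re-optimize
every candidate pose inside a truncated, restrained binding pocket under a
physically meaningful potential, rescore each by its binding energy, and
re-rank — plus the metrics needed to decide whether that helped.

## The CG-BS optimizer

`cgbs_minimize()` is a nonlinear conjugate-gradient minimizer over atomic
Cartesian coordinates with a backtracking line search:

* **Direction update.** Polak–Ribière+ , `beta = max(0, g1·(g1−g0)/|g0|²)`,
  with a forced steepest-descent restart every 3N free coordinates and
  whenever the proposed direction is not a descent direction. PR+ with
  restarts is the standard robust choice for energy surfaces that are
  smooth only piecewise — which is exactly the regime of machine-learning
  potentials the optimizer is designed to accept.
* **Line search.** Armijo backtracking: the first trial step satisfying
  `E(x+αd) ≤ E0 + c1 α (g·d)` is accepted, with `c1 = 1e-4` and shrink
  factor 0.5. The curvature (second Wolfe) condition with `c2 = 0.9` is
  evaluated at the accepted point and recorded in the trace as a
  diagnostic; pure backtracking cannot *guarantee* it, so it is monitored
  rather than enforced. Accepted steps therefore decrease the energy
  strictly — the energy trace is monotone by construction, and the test
  suite asserts it on every run.
* **Step sizing.** The first trial step of an iteration is scaled so that
  the largest single-atom displacement is `initial_step` = 0.05 Å — a
  trust-radius-like cap typical of geometry optimizers, which keeps the
  optimizer inside the region where the potential is trustworthy.
  Subsequent iterations try twice the last accepted step, capped at the
  same scale. A line-search failure (Armijo unmet within 20 trials)
  triggers one steepest-descent restart at a 10× smaller trial step; two
  consecutive failures terminate with `converged = FALSE`. Hitting
  `max_iterations` (default 5000) likewise returns a flagged result
  rather than raising.
* **Frozen atoms.** Atoms flagged frozen have their forces zeroed after
  composition and never receive updates; their coordinates are
  bit-identical on output (asserted in the tests, not merely approximate).

**Convergence** is declared when all four criteria hold simultaneously on
the free atoms, compared with `≤` in atomic units: maximum and RMS
per-atom force ≤ 0.00045 and 0.0003 Hartree/Bohr, maximum and RMS per-atom
displacement of the last accepted step ≤ 0.0018 and 0.0012 Bohr. These are
the standard quantum-chemistry optimizer thresholds (the Gaussian 16
defaults). Two conventions had to be fixed where common practice varies:
"maximum displacement" is interpreted as the per-atom displacement vector
norm (not a per-coordinate component), and on iteration 0 the displacement
criteria are defined as not-yet-satisfied because there is no prior
geometry. All optimization arithmetic is done in kcal/mol and Å;
quantities are converted to atomic units only at the convergence check, so
the quoted thresholds are applied exactly rather than through rounded
conversion constants.

## Potential backends and restraints

All backends implement one contract (`energy_model()`): coordinates (Å) in,
energy (kcal/mol) and forces (kcal/mol/Å = negative gradient) out. The
analytic backends — the 12-6 Lennard-Jones pair potential and an isotropic
harmonic well — exist because their minima are known in closed form, which
turns optimizer correctness into an exactly checkable statement. Every
backend (including each restraint term) is validated against a central
finite-difference oracle on seeded random structures; the oracle step is
1e-5 Å for analytic potentials and would be 1e-4 Å for the ML backend,
whose surface is less smooth.

Restraints use `E = k·Δ²` with **no ½ factor**: the protocol specifies
weights in kcal/mol/Å² that are written directly into the B-factor column,
and the no-half convention makes a weight of 5 mean literally 5 kcal/mol
per Å² of squared displacement. Torsional restraints harmonically restrain
a four-atom dihedral with the angular difference wrapped to (−180°, 180°];
the analytic dihedral gradient distributes over the four atoms and sums to
zero (translation invariance). The refinement protocol itself applies no
torsional restraints by default — the capability is provided for users who
wish to pin rotatable bonds during refinement.

The ANI-2x adapter drives the published `torchani` implementation through
the `python` interpreter, converting Hartree to kcal/mol. It is optional:
element screening (H/C/N/O/S/F/Cl only — a bromine-containing ligand is
rejected by name before any model call) and the availability error path
are always testable, while the numerical path requires `torchani` to be
installed. Frozen atoms still contribute to the potential energy — they
are a static environment; the −1 weight is a mobility flag, not an energy
term.

## The pocket protocol and ΔE~bind~

`truncate_receptor()` keeps whole residues with any atom inside the
truncation radius of the ligand's geometric center. The radius default is
12 Å — the midpoint of the 8–15 Å range the protocol allows — and values
outside that range warn rather than fail. Severed peptide backbone bonds
(a kept residue whose sequence neighbour was discarded) are capped with a
hydrogen at 1.09 Å along the former C–N bond vector; hydrogen caps rather
than ACE/NME groups keep the perturbation minimal and the element set
ML-potential-compatible. Residues without named C/N backbone atoms
(nucleotides, toy systems) are left uncapped, and nucleic-acid receptors
are truncated by the same whole-residue rule with nucleotides as residues.

`assign_regions()` splits pocket atoms at 2.5 Å from any ligand atom:
inside (inclusive `≤`, atom centers, hydrogens included) is the *active
part*, harmonically restrained to its input position with k = 5
kcal/mol/Å²; outside is the *frozen part*. The boundary comparison is
inclusive so that an atom exactly at 2.5 Å is active — the more permissive
choice at a measure-zero boundary. Ligand atoms belong to neither set and
move freely.

`refine_pose()` builds the complex (pocket atoms first, then pose atoms),
composes the base potential with the active-region restraints and the
frozen mask, minimizes, and computes

$$\Delta E_{bind} = E_{com} - E_{rec} - E_{lig}$$

on the **bare** potential (restraint terms are scaffolding, not physics).
`E_rec` and `E_lig` are single-point energies at the in-complex optimized
coordinates — a rigid decomposition. Whether the components should instead
be relaxed separately before their single points is genuinely ambiguous in
the protocol this implements; rigid decomposition is the default because
it makes ΔE~bind~ exactly the receptor–ligand interaction energy for any
pairwise-additive potential (a property the test suite exploits), and
`relax_parts = TRUE` provides the alternative mode. One consequence worth
knowing: receptor strain cancels between `E_com` and `E_rec`, so poses
that pry restrained pocket atoms apart are scored by their improved
contacts without paying the distortion penalty. Ranking is by ascending
ΔE~bind~ with ties broken by input (docking) order, so re-ranking is a
stable refinement of the docking rank.

## Evaluation metrics

*Receptor-anchored RMSD.* The least-squares (Kabsch) superposition is
computed on receptor atoms only and applied to the whole predicted
complex; the RMSD is then taken over ligand heavy atoms with no further
fitting. Joint rigid motion of the complex therefore cancels exactly,
while translation/rotation of the ligand within the pocket contributes
fully. Hydrogens are excluded by default (their docked positions are
ambiguous); no graph-automorphism symmetry correction is applied, which
can overstate the RMSD of symmetric ligands — a known limitation.

*Docking power.* For the ranked RMSDs of one system, the lowest RMSD
within the Top 1/3/5/10 poses gives four non-increasing minima; the first
category whose minimum equals the Top-10 minimum (equality tolerance 1e-9
on raw values, exact on 2-decimal table readbacks) is where the
native-like pose first appears, and a system counts as a success when
that category is ≤ 3. Success rates are reported both unrounded and
rounded to the nearest integer percent, matching how such tables are
printed.

*Scoring/ranking power.* Pearson R on predicted score vs experimental
ΔG, Spearman ρ as Pearson on fractional (average) ranks. Experimental
affinities enter as raw ΔG = RT ln Ki (R = 1.98720425864e-3 kcal/mol/K,
T = 298.15 K, Ki referenced to 1 M) rather than pKi; since ΔG is a fixed
positive multiple of ln Ki the Spearman value is unaffected and the
Pearson value only reflects the (log-scale) linearity the metric is meant
to probe.

*Compound selection.* Screening sets drop compounds with elements outside
{C, H, O, N, S, F, Cl}, drop very weak binders (ΔG above −4 kcal/mol,
i.e. Ki weaker than ~1.2 mM), stratify into four affinity tiers (<10 nM,
10 nM–1 µM, 1–100 µM, ≥100 µM) and cap each tier at 300 compounds via a
seeded uniform subsample.

## Synthetic fixtures: what they emulate and what they do not

The fixtures module replaces the two external dependencies of a real
study — a commercial docking engine and curated affinity sets — with
deterministic synthetic counterparts:

* `make_toy_complex()` builds a jittered-lattice LJ receptor and places
  the native ligand at the **global minimum** of the frozen-receptor
  adsorption landscape, located by a dense grid scan (0.25 σ resolution)
  of the probe interaction energy followed by local relaxation of the
  best spatially distinct candidate basins. The grid-plus-polish search
  is needed because lattice jitter makes competing adsorption sites
  nearly degenerate; relaxing only the single best grid point can land in
  a basin a few hundredths of ε above the true minimum. With this
  construction "the native pose" is well defined: it is the deepest
  binding site of that specific jittered receptor.
* `make_decoys()` emulates a ranked docking output as rigid-body
  perturbations of the native pose (uniform rotation axis, uniform angle
  up to 30°, uniform translation direction and magnitude up to 2 Å by
  default). Per-atom displacement is bounded by
  `max_translation + 2 R sin(max_rotation/2)` with R the maximal centroid
  distance, and the suite asserts that bound.
* `make_screening_table()` draws Ki log-uniformly within each affinity
  tier (tiers assigned in rotation), converts to ΔG, and adds Gaussian
  noise to form the predicted score. Tier 4 is capped at the −4 kcal/mol
  cutoff Ki so a default-filtered selection keeps every generated
  compound. Under this additive-noise model the expected Pearson
  correlation is the analytic attenuation factor
  `sd(ΔG)/sqrt(sd(ΔG)² + σ²)`, which the tests recover within 0.05 at
  n = 1000.

What the toys deliberately do **not** emulate: chemical realism
(conformational flexibility, torsions, protonation), docking-engine
scoring bias in pose order, receptor conformational change, and solvent.
A passing pipeline suite therefore demonstrates that the machinery —
optimization, restraints, rescoring, ranking, RMSD — is correct and
internally consistent, not that any particular potential predicts real
affinities.

The end-to-end ranking property is tested under a rigid toy pocket
(an assignment boundary below the LJ contact distance, which freezes every
receptor atom). This makes the refinement landscape identical to the
landscape in which the native site was defined, so "the decoy nearest the
native minimum ranks first" is a sharp statement; the pose-rank margin of
0.5 σ distinguishes different adsorption sites (1.5 σ apart) from
sub-basin jitter. With the protocol's restrained-active pocket instead,
the strain-cancellation property of the rigid ΔE~bind~ decomposition can
legitimately reorder near-degenerate sites — behaviour that is inherent to
the rescoring model, not a defect of the optimizer, and is exercised by
the other refinement tests.

## Problem sizes and determinism

The shipped tests and the acceptance script run on deliberately small
systems — toy receptors of 4–18 atoms, 10 decoys per system, screening
tables of up to 1000 compounds, quadratics up to dimension 30 — chosen so
the full suite completes in about a minute while still exercising every
code path at meaningful accuracy. All stochastic fixtures take an explicit
integer seed and restore the RNG state afterwards (`withr::with_seed`);
there is no hidden global random state, and identical seeds reproduce
results bit-for-bit. The published benchmark tables in `inst/extdata/` are
inputs, and every aggregate quoted anywhere in the documentation is
recomputed from them (or from seeded runs) by the test suite and
`scripts/acceptance.R` at run time.

## Known limitations

* ΔE~bind~ is a gas-phase interaction energy: no solvation, no entropy,
  no strain accounting (see above) — adequate for re-ranking poses of one
  ligand, not for absolute affinity prediction.
* The ANI-2x path needs an external Python environment; the package
  deliberately treats it as a pluggable backend rather than a dependency.
* RMSD has no ligand-symmetry correction.
* The PDB writer emits minimal fixed-column records (no CONECT, no
  occupancy semantics beyond a constant 1.00).
* Truncation capping handles peptide C–N backbone breaks only; other
  polymer chemistries are truncated without caps.
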