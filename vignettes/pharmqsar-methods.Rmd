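---
title: "Pharmacophore-aligned atom-based 3D-QSAR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacophore-aligned atom-based 3D-QSAR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmqsar)
```

## The modelling problem

Benzamide-class HDAC1 inhibitors share a 2-aminophenyl amide "zinc-binding"
head group; their inhibitory potencies (IC50) span roughly five orders of
magnitude, from single-digit nanomolar to the 50 micromolar assay ceiling.
`pharmqsar` implements the classical ligand-based pipeline for this setting:

1. **Preparation** — ionization at physiological pH and generation of a
   pruned conformer ensemble per ligand.
2. **Common-feature pharmacophore elucidation** — find the arrangement of
   chemical features (acceptor A, donor D, hydrophobe H, negative N,
   positive P, aromatic ring R) shared by the most potent compounds, score
   the candidates, and select one hypothesis.
3. **Alignment** — rigidly superpose every ligand onto the hypothesis via
   its matched features; this is the alignment rule of the 3D-QSAR step.
4. **Atom-based 3D-QSAR** — encode each aligned ligand as binary occupancy
   of grid cubes by classified atoms and regress pIC50 on those bits by
   partial least squares (PLS).
5. **Validation** — internal cross-validation (Q2), external-set metrics
   (Q2F3, r2), and a decoy-screening layer (EF, GH, %YA, %RA, ROC/AUC).

All responses are pIC50 on the micromolar scale, `pIC50 = -log10(IC50[nM]/1000)`,
so 1 uM maps to 0. Potency classes: *active* IC50 <= 10 nM, *inactive*
5-50 uM (inclusive), *moderate* in between; anything above 50 uM is outside
the modelled domain.

## Molecule preparation

**Ionization** is rule-based rather than pKa-predicted: carboxylic and
sulfonic acids are deprotonated; aliphatic amines, amidines and guanidines
are protonated; anilines, amides and pyridine-type nitrogens stay neutral.
At pH 7.4 these rules are the fixed points of any standard pKa table, and
exactly one state is emitted per ligand. The 2-aminophenyl amide head group
is therefore neutral, which is what the alignment and donor-feature logic
assume.

**Conformers** are generated in torsion space: the input geometry's bond
lengths, angles and rings are kept rigid and only acyclic single bonds
between non-terminal heavy atoms rotate (amide bonds are held planar).
Random torsion vectors are drawn (seeded), each is locally minimized, and
the pooled minima are pruned to an energy window of 21 kJ/mol above the
global minimum with a 0.5 Angstrom heavy-atom RMSD redundancy cutoff. The
minimizer honours a 2000-iteration cap and a 0.001 gradient threshold.

The energy model is deliberately small: a threefold torsional potential
(V3 = 12 kJ/mol) plus truncated Lennard-Jones interactions between atoms
more than three bonds apart (1-4 pairs scaled by 0.5, sigma from Bondi
radii, epsilon = 0.4 kJ/mol). It is not a general force field: it ranks
torsional minima of drug-like molecules sensibly, which is all the
window/cutoff contracts require, and it is exactly reproducible. The test
suite cross-checks the stochastic search against an exhaustive 120-degree
torsion-grid scan under the same energy model and pruning rules.

## Feature perception

Features are detected by an explicit, inspectable rule table
(`feature_rules()`): acceptors on neutral lone-pair oxygens and
pyridine-type nitrogens (direction = lone-pair axis), donors on N-H/O-H
heavy atoms (direction = mean X-H axis), aromatic rings at 5/6-ring
centroids (direction = ring normal, via an approximate planarity +
sp2-membership Hueckel rule), hydrophobes at centroids of connected apolar
carbon/halogen clusters, and N/P on formally charged atoms. Perception is
deterministic, canonical in its output ordering, and invariant under rigid
motion and atom renumbering (both properties are asserted as tests).

## Hypothesis enumeration, scoring and selection

For every conformer of every potent ligand, all k-subsets (k = 5 by
default) of its features are keyed by the feature-kind multiset together
with the ten sorted inter-feature distances discretized into 1.0 Angstrom
bins. This distance-key hashing is a reproducible, order-independent
realization of tree-based distance partitioning: two subsets share a key
exactly when they agree kind-for-kind and bin-for-bin. Keys shared by all
actives (the default `min_matched`) become candidates; each candidate's
geometry is taken from the lowest-energy contributing conformer.

Scoring follows the classical survival recipe. For a candidate aligned
against the active set: `site` = 1 - mean feature RMSD / tolerance
(clamped to [0,1]); `vector` = mean |cosine| between matched direction
vectors (ring normals are sign-ambiguous, hence the absolute value);
`volume` = mean pairwise common-volume ratio of the aligned actives under
a sphere-overlap approximation (pairwise analytic sphere intersections,
union = total volume minus common part, clamped to [0,1]);
`selectivity` = -log10 of the candidate's match rate in a background
library (zero matches are capped at one match to keep the logarithm
finite); `energy` = mean relative conformational energy of the matched
conformers, entering as a penalty scaled by 1/(k x 2.5 kJ/mol) — the
thermal-energy scale — so survival magnitudes are comparable across site
counts; `activity` = pIC50 of the reference ligand. All component weights
default to 1. The same function applied to the inactive set (without the
active-set notions of selectivity and activity) gives the inactive score,
and the adjusted survival is their difference, exactly. Selection is the
argmax of adjusted survival, ties broken by lower reference energy, then
lexicographic label. Absolute survival magnitudes are conventions of the
original commercial implementation and are not reproduced; only the
ranking behaviour is contractual here.

## Alignment

Matching a ligand onto a hypothesis enumerates every kind-respecting
injective assignment of hypothesis features to ligand features (exhaustive
for k <= 6) over every conformer, and scores each by the RMSD of the
least-squares rigid superposition (Kabsch, proper rotations only;
reflections are excluded by flipping the smallest singular direction).
A pose matches when all k features map within the tolerance
(default 2.0 Angstrom — the tolerance is not stated in the source
protocol and is exposed as a parameter), or k-1 in partial mode.
Hypothesis generation and model fitting require full matches; screening
uses partial mode, mirroring the observation that non-binders fail to
satisfy all pharmacophore features yet still receive (very poor)
predictions. Direction vectors never enter the positional least-squares;
they only contribute to the vector score, keeping superposition a standard
point-set problem.

## Occupancy-grid PLS

Aligned heavy atoms are classified into six classes — D donor-H carriers,
H hydrophobic carbons, N negative, P positive, W acceptor/electron-
withdrawing (other N/O, halogens, sulfur), X everything else — and a cubic
grid of 0.5 Angstrom spacing is laid over the training poses with one
van der Waals radius of margin. A (cube, class) bit is set when any atom
of that class contains the cube center inside its Bondi vdW sphere: the
cheapest exactly-testable occupancy rule, and the one the test suite
verifies bit-for-bit against a brute-force triple loop. Columns are
restricted to cubes occupied by at least one training pose.

PLS is single-response NIPALS on mean-centered X and y. With as many
factors as the matrix rank it coincides with ordinary least squares (an
acceptance-tested identity). The factor scan runs 1-7; per factor the
package reports training R2, regression SD, F (dof = (a, n-a-1)) with its
p-value, and a cross-validated Q2. Cross-validation realizes leave-n-out
as seeded, stratified 10-fold: observations are ordered by response and
dealt round-robin, so each fold covers the response range; Q2 =
1 - PRESS/SS_tot over the concatenated held-out predictions with SS_tot
about the full-sample mean. The working model is the smallest factor
count whose SD reaches the experimental error (default 0.3 pIC50 units, a
typical inter-assay median error), falling back to the best Q2.

External predictivity uses the size-normalized metric
`Q2F3 = 1 - [SSE_out/n_out] / [SS_tot,train/n_train]`,
which is 1 for exact predictions, 0 in expectation for the
training-mean predictor, and unbounded below.

Prediction aligns, encodes on the stored active cubes, and applies the
linear model. Molecules that fail to align receive the *floor prediction*
— the minimum training pIC50 — and a `matched = FALSE` flag; this ranks
them last in screening, which is what the ROC layer needs. The
coefficient field can be exported thresholded at |coef| >= 1.5e-2 (the
conventional display cutoff), as CSV or PDB pseudo-atoms with the
coefficient in the B-factor column.

## Screening validation

`screen()` ranks a library by predicted pIC50 (ties broken by id for
reproducibility) and takes the top of the ranking as hits: an explicit
`hit_count` — the published protocols fix cutoffs like "top 30" — or a
library fraction rounded to the nearest integer with a floor of one.
`enrichment_report()` then computes, exactly from the counts:
EF = (Ha/Ht)/(A/D), GH = [Ha(3A+Ht)/(4HtA)][1-(Ht-Ha)/(D-A)],
%YA = 100 Ha/Ht and %RA = 100 Ha/A, plus a ROC curve by threshold sweep.
Tied scores contribute diagonal segments (average-rank convention), which
makes the trapezoid AUC equal to the normalized Mann-Whitney rank-sum
statistic — an identity the tests assert to 1e-12.

## The synthetic-data generator

Real benzamide SAR sets are not redistributable, so the package ships a
seed-controlled generator whose defaults define the study conditions used
throughout the tests: 300 compounds (20 targeted potent, 220 moderate, 60
inactive), 50 decoys per active, and Gaussian pIC50 noise of sd 0.3 — a
typical inter-assay error for enzymatic IC50 data.

Each compound is a substituted N-(2-aminophenyl)arylamide built from an
internal 3D template (idealized ring geometry, planar amide, explicit
hydrogens). Every scaffold carries the planted five-feature motif — the
amide carbonyl acceptor, the amide NH and aniline NH2 donors, and the two
aromatic rings (kinds A, D, D, R, R). Activity is additive in the ring
substituents: beneficial para substituents on the aroyl ring
(+0.55 to +0.6 pIC50) and bulk penalties at meta/ortho (-0.15 to -1.9),
over a base of 1.45, clipped to the 6 nM - 50 uM assay range. Two design
choices matter:

* the four beneficial para substituents span *different* feature kinds
  (NH2 donor, OMe acceptor, OH both, F hydrophobe) at equal potency gain,
  so the potent class is always feature-diverse and the only feature
  arrangement common to all actives is the planted scaffold motif — an
  earlier draft with a pyridyl potency bonus allowed chemically biased
  active subsets in which a more specific six-feature variant honestly
  outranked the planted hypothesis;
* activity is exactly linear in substituent presence, hence in grid
  occupancy, so the PLS stage has a recoverable signal whose
  noise ceiling is known.

Ensembles contain the planted conformer (per-atom placement noise of
0.015 Angstrom plus a random rigid motion) and two alternates with the
aroyl ring rotated 25-75 degrees about the amide-aryl bond, at 2-15
kJ/mol. The placement noise is kept small relative to the 1.0 Angstrom
distance bins so that all copies of the scaffold hash to one key.

Decoys are sampled from a combinatorial pool of donor-free, non-amide
scaffolds (aryl ketones, esters, ethers, alkylbenzenes, biphenyls,
methylsulfones with varied ring substituents), matched per paired active
to molecular weight within +/-25, computed logP within +/-1, identical net
charge, and 2D path-fingerprint Tanimoto < 0.4 against *every* active,
under a Lipinski filter. logP is a fragment-additive estimate (literature
parent-compound values plus Hansch pi constants), applied identically to
actives and decoys so the window compares like with like; the fingerprint
is the package's linear-path hash (`path_fingerprint()`). Lacking the two
donors, no decoy can satisfy even k-1 of the ADDRR features, so decoys
enter the ROC at the floor prediction — the generator's deliberately
clean analogue of "inactives fail to completely satisfy the pharmacophore".

**What passing tests do and do not show.** The generator emulates the
*shape* of a benzamide SAR study: scaffold-dominated alignment, additive
substituent effects, assay noise, property-matched topologically dissimilar
decoys. It does not emulate activity cliffs, tautomerism, stereochemistry,
flexible zinc-binding geometries, or decoys that are near-misses of the
pharmacophore; success here shows the machinery is correct and calibrated,
not that any real HDAC1 dataset would reach the same statistics.

## Numerical choices and degenerate inputs

* Superposition requires >= 3 non-collinear pairs; collinear sets raise an
  error rather than returning an arbitrary rotation.
* Aromatic perception demands near-planarity (0.35 Angstrom) so badly
  embedded rings are not called aromatic.
* Zero-variance responses, constant external predictions, rank-exceeding
  factor requests, and empty screening libraries are all errors with
  specific messages; an empty inactive set downgrades to a warning with
  inactive score 0.
* Score ties in ranking break by id; ROC ties follow the average-rank
  convention; hypothesis-selection ties break by energy then label.
* Seeds: every stochastic step (conformer search, splits, CV folds,
  generator, decoy sampling) takes an explicit seed; derived child seeds
  stay below 2^31.

## Problem sizes used by the checks

Module tests run on a reduced library (12/60/16 compounds, seed fixed)
with the fitted pipeline cached across test files; the hypothesis-recovery
property uses 20 generator seeds at 10/30/10; the end-to-end validation
runs the full default conditions (300 compounds, 50 decoys per active,
sigma 0.3) over 5 seeds, generating a fresh 113-compound external set per
seed. These sizes are the package's chosen study conditions; the same
functions scale to larger libraries unchanged.

## Known limitations

* The conformer energy model is torsional + sterics only; conjugation,
  electrostatics and solvation are out of scope, so relative energies are
  qualitative.
* Seeds control every stochastic step inside the package, but the initial
  3D embedding of SMILES input is delegated to Open Babel, which is not
  deterministic across processes; workflows needing bit-reproducible
  geometries should start from SDF coordinates (or the synthetic
  generator's templates) rather than SMILES.
* Feature definitions are a fixed rule table, not a learned or
  SMARTS-configurable set; exotic warheads would need new rules.
* The assignment search is exhaustive and therefore exponential in
  features-per-kind; it is intended for k <= 6 with drug-like feature
  counts.
* Survival-score magnitudes are package conventions; compare rankings,
  not absolute values, across implementations.
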