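---
title: "Predicting and validating zinc-binding sites with znsite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and validating zinc-binding sites with znsite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Roughly a third of proteins need metal cofactors, and zinc is the most
common transition metal in deposited structures. Its sites fall into three
broad functional classes that track the number of protein ligands:
structural sites are usually four-coordinate (often Cys4 or Cys3His1),
catalytic sites three-coordinate, and regulatory or inhibitory sites
two-coordinate, transient, and frequently left unmodelled by
experimenters. `znsite` predicts where zinc ions sit in a macromolecular
structure and which residues coordinate them, using only local geometry and
physicochemistry — no homologs, no electron density. It also implements a
quantitative validation of metal sites that are already modelled, so
predictions and deposited ions can be judged with the same instrument.

The pipeline is deliberately staged:

1. **Candidate search.** Cysteine SG and histidine ring atoms (ND1, NE2,
   CE1, CD2 — the carbons included because ring conformations are often
   flipped or mislabelled) are collected and residue pairs whose eligible
   atoms fall in a 2.4–4.5 Å window become edges of a compatibility graph.
   Fully compatible sets of 2–4 residues are the candidate sites (groups
   CH2, CH3, CH4 by ligand count). SG pairs below 2.400 Å are disulfide
   bonds, not metal sites: that cutoff is the upper confidence bound
   μ + 2.575 σ of the disulfide SG–SG peak (μ = 2.058 Å, σ = 0.133 Å) at
   two-tailed p = 0.01.
2. **Zinc placement.** Six subgroup-specific geometric strategies deduce
   the most probable zinc position from the ligand atoms alone (details
   below). Placing first means the expensive radial profiles are evaluated
   at one point per site instead of on a grid — the design choice that
   makes the method fast.
3. **Hybrid verification.** Two-residue sites, where geometry alone is
   weakest, are scored by a five-learner ensemble over 61 features;
   three- and four-residue sites are scored by Pearson correlation of
   their hydrophobicity profiles against per-group reference curves.
   Certainty > 0.5 verifies a site.
4. **Redundancy removal and annotation.** Verified zincs closer than
   2.5 Å are merged (highest ligand count, then certainty, wins); pairs at
   3–4 Å survive, which is exactly the separation of genuine dinuclear
   sites. Auxiliary non-Cys/His donors (Glu/Asp carboxylates, backbone
   O/N, waters) are reported within the first (≤ 2.5 Å) and second
   (≤ 4 Å) coordination spheres.

## Bond-valence validation

A modelled or predicted site is scored by three dimensionless quantities,
each in [0, 1]. Let each coordination bond *i* carry the empirical bond
valence \(V_i = \exp((R_0 - d_i)/b)\) with \(b = 0.37\) Å and tabulated
\(R_0\) (Zn–O 1.704, Zn–N 1.77, Zn–S 2.09 Å), directed from metal to donor
as the vector \(\vec v_i\).

* **Valence agreement** \(Q_v = \min(S/V_{ox},\, V_{ox}/S)\) with
  \(S = \sum V_i\) and \(V_{ox} = 2\) for zinc.
* **Completeness** \(Q_c = 1 - |\sum \vec v_i| / N\): a full, symmetric
  sphere cancels vectorially. Two normalisations \(N\) are implemented.
  The literal form divides by \(\sum V_i\); for two-ligand sites the
  package instead divides by \(V_{ox}\), because only that convention
  reproduces the two-ligand optimum of 0.71 (two valence-0.5 bonds at the
  tetrahedral angle give a resultant of 0.58; 1 − 0.58/2 = 0.71) from
  which the published two-ligand threshold 0.355 = 0.71/2 derives. Under
  the literal normalisation the same geometry scores 0.42, which is
  inconsistent with that threshold; both forms are exposed and the
  discrepancy is documented rather than hidden.
* **Environment agreement**
  \(Q_e = \min(2\min(O_m, O_e), 1)\cdot\min\!\big(\tfrac{B_m O_m}{B_e O_e},
  \tfrac{B_e O_e}{B_m O_m}\big)\), where \(O_e\) and \(B_e\) are
  valence-weighted means of donor occupancies and B-factors. The second
  factor is read as a ratio of products; with equal B-factors but reduced
  metal occupancy both factors engage (e.g. \(O_m = 0.4\) gives
  0.8 × 0.4 = 0.32).

Acceptance thresholds depend on the ligand count: three or more donors
must exceed 0.5 on all three scores (half the four-ligand optimum);
exactly two donors use \(Q_v > 0.25\), \(Q_c > 0.355\), \(Q_e > 0.5\);
fewer than two donors always fail. The first coordination sphere is 2.5 Å,
with at most one donor atom per residue (the closest); waters count as O
donors for validation but never as primary search ligands.

## Placement strategies

* **(a) CC.** The zinc is constrained to the circle of radius 1.2 Å
  around the SG–SG midpoint in the plane perpendicular to the SG–SG
  segment, scored by the squared deviation of both Zn–SG–CB angles from
  109°; locus points on the CB side of either SG are rejected as clashes.
  The circle is scanned at 0.1° resolution (3600 points) and the best
  point refined by golden-section search, so the result is grid-free to
  well below coordinate precision. If every point fails the distal-side
  test the constraint relaxes to a continuous penalty instead of failing.
  The 1.2 Å radius is kept as the method's operating constant and is
  configurable; note that it is exact for tetrahedral geometry
  (√(2.1² − 1.715²) = 1.21 Å at the 3.43 Å tetrahedral ligand
  separation) and approximate at the empirical mean separation of 3.6 Å.
* **(b) CH.** As (a), with per-role angular targets: 109° for SG, 100°
  for ND1, 155° for NE2. The ring carbons CE1/CD2 — eligible only because
  of possible ring mislabelling — take 128°, the midpoint of the two
  nitrogen targets, as no empirical value is printed for them.
* **(c) HH.** Each imidazole's centroid→ring-atom rays are the lone-pair
  directions; a candidate zinc is placed 2.1 Å beyond each eligible ring
  atom along its ray, and the closest cross-ring candidate pair is
  averaged. Placing the candidate 2.1 Å from the *ring atom* (not 2.1 Å
  from the centroid, which would leave it ~0.9 Å past the atom) is the
  chemically consistent reading of the construction, matching the 2.1 Å
  coordination bond length used everywhere else.
* **(d) HHH.** Strategy (c) on each of the three His pairs; the three
  results are averaged.
* **(e) Mixed CH3.** The three ligand pairs are placed with (a)–(c) as
  appropriate; the two candidates with the smallest mutual distance form a
  2-of-3 majority and their midpoint wins. Cysteines adopt
  non-coordinating rotamers more often than histidines, so the outlier
  pairwise candidate is discarded.
* **(f) CH4.** The centroid of the four coordinating atoms. Four-residue
  sites are geometrically so constrained that this is accurate to a few
  hundredths of an Ångström on real structural sites.

All placements are equivariant under rigid motion of the input (tested to
1e-6 Å) because every construction uses only internal geometry; the only
frame-dependent object, the scan grid's phase on the locus circle, is
eliminated by the golden-section refinement.

## Hydrophobicity profiles

Buried metal sites show a characteristic radial pattern: a hydrophilic
(N/O/S) inner shell wrapped in a larger carbon shell. Around each placed
zinc the package evaluates, at 21 radii from 2 to 7 Å in 0.25 Å steps, the
hydrophobicity contrast \(C(R)\) — the sum of atomic solvation parameters
over the outer shell \(R/2 < r \le R\) minus the sum over the inner ball —
and the mean solvation parameter within \(R\). The default per-class
solvation parameters (cal mol⁻¹ Å⁻²) are C +16, neutral N/O −6, charged O
−24 (Glu/Asp carboxylates, OXT), charged N −50 (Lys NZ, Arg guanidinium),
S +21; hydrogens contribute 0 and metals are excluded. The two-shell
difference form of \(C\) is isolated behind one function so an alternative
analytic form can be swapped without touching callers; all tests depend
only on its contract properties (empty-ball zero, sign convention,
rotation invariance), not the specific form.

Verification of CH3/CH4 sites computes the Pearson correlation of the
site's two curves against per-group reference curves (pointwise means over
validated sites) and averages the two correlations, clamped to [0, 1];
constant curves contribute correlation 0. Group-mean references (rather
than nearest-site matching) were chosen as the simpler estimator with the
obvious population interpretation. Packaged reference curves for real use
are a data artifact of the training harness; the test suite builds its own
from the synthetic generator.

## The CH2 ensemble

Two-residue sites are verified by five base learners — logistic
regression, a decision tree, a single-hidden-layer perceptron, a
radial-kernel SVM, and a larger feed-forward network (one hidden layer of
16 units; a deliberately compact architecture, since 61 inputs and a few
hundred training rows do not support deeper nets) — each emitting a class
probability. A site is accepted when at least 3 of 5 learners vote
positive (probability > 0.5); its certainty is the mean of the five
probabilities, matching the convention that the reported score is a
probability rather than a vote fraction.

The 61 features are: per ligand (canonically ordered by chain, resseq,
icode, which makes the encoding order-invariant) a Cys/His flag plus a
5-way one-hot of the coordinating atom (12); donor–donor, CA–CA and CB–CB
distances (3); the four angles CA1–donor1–Zn, CA2–donor2–Zn, CB1–donor1–Zn,
CB2–donor2–Zn in degrees (4) — this angle set is one reasonable
reconstruction of "four angles describing the CA/CB orientation" and is
swappable behind the encoder; and the 21 contrast plus 21 mean-solvation
values (42). Training splits the data 70/30 stratified by label and CH2
subgroup, standardises features on the training portion, and tunes each
learner by 10-fold cross-validated AUC over a small grid (tree complexity
0.001/0.01/0.05; perceptron size 4/8 × decay 0.01/0.1; SVM cost 0.5/2/8;
network decay 0.001/0.01). All randomness flows from one recorded seed.
Negative training examples are candidate sites with no modelled metal
within 4 Å of the placed zinc that fail the two-ligand validation
(\(Q_c < 0.355\) or \(Q_v < 0.25\)) — an objective construction that avoids
hand-picking decoys.

## Evaluation metrics

Site identity is compared by the intersection-over-union ratio of ligand
residue sets (IoUR), with IoUR ≥ 0.5 marking a true positive; matching is
greedy one-to-one by descending IoUR, with ties resolved toward the
earlier actual site. On the dominant-overlap instances the method actually
produces (each prediction perturbs one actual site) greedy matching is
verified against exhaustive optimal assignment; on adversarial overlap
matrices greedy is not guaranteed cardinality-optimal, a known and
documented property. A position-based scheme is also provided: predictions
within 5 Å of an experimental site are true positives, unmatched
experimental sites false negatives, and mutually close (< 5 Å) false
predictions are clustered to count once. Precision, recall, F1 and
accuracy follow the standard formulas, with undefined ratios reported as
`NA` rather than 0.

## What the synthetic generator emulates — and what it does not

`make_site_structure()` builds exact coordination geometry: donors at the
2.1 Å bond length, two-ligand separations as requested (3.6 Å by default,
the empirical mean), tetrahedral directions for 3–4 ligands, imidazoles as
regular pentagons with 1.37 Å edges whose lone-pair rays point at the
zinc, and side-chain CB/CA/N atoms at standard bond lengths with the 109°
Zn–SG–CB angle built in. An optional shell of carbons (radius ≈ 5.9 Å)
around a few polar atoms (≈ 3.3 Å) gives metal-like hydrophobicity
profiles; decoys invert it. Gaussian positional noise and a seed make
noisy replicates reproducible.

Placement-recovery tests build two-ligand fixtures at the tetrahedral
separation (3.43 Å), where the 1.2 Å locus radius is exact; at the 3.6 Å
default the radius alone contributes ~0.12 Å of irreducible placement
error, and real regulatory sites are looser still. The generator does not
emulate rotamer strain, backbone context, crystallographic disorder,
solvent, or the correlated noise of real refinement — so green tests here
demonstrate correctness of the geometry and logic, not real-data accuracy.
The labelled-feature generator (`make_labelled_features()`) draws
class-conditional Gaussians whose positives centre on the empirical
geometry and whose negatives are dispersed; it is separable by
construction and exists to give learner-recovery tests a known answer, not
to mimic the hardness of real discrimination.

## Problem sizes and numerical choices

The test suite runs at desk scale: classifier recovery uses 400 sites per
class; the structure-trained ensemble for end-to-end decoy screening uses
36 fixtures per class; property suites use 1000 randomized geometries and
8–10-residue search fixtures. The circle scan uses 3600 points plus
golden-section refinement to 1e-12 rad; score clamps (`[0, 1]`),
zero-valence and empty-sphere cases, missing-CB fallback (midpoint, with a
note), and the constant-curve correlation convention are all explicit code
paths with tests. Validation of a predicted (metal-free) site assumes
occupancy 1 and the environment B-factor for the absent metal, which makes
\(Q_e\) measure only occupancy/B coherence of the donors.

## Limitations

Backbone N/O donors are not searched, so sites coordinated mainly through
backbone atoms are missed by design; Glu/Asp-first sites are only
annotated post hoc as auxiliary ligands, not predicted; the shipped logic
targets Zn²⁺ (other transition metals would need their own bond-valence
rows, oxidation states and training data); and certainty scores are
calibrated only in the weak sense that 0.5 separates the verification
classes — they are not posterior probabilities of binding.
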