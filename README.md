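# znsite

Zinc-binding site prediction and validation in macromolecular structures.

About a third of proteins need metal cofactors, and zinc — the most common
transition metal in deposited structures — plays structural roles at
4-residue sites, catalytic roles at 3-residue sites, and transient
regulatory roles at 2-residue sites that experiments frequently miss.
`znsite` predicts where zinc ions sit in a protein structure and which
residues coordinate them, from local geometry and physicochemistry alone
(no homologs, no density maps), and validates both predictions and
already-modelled ions with bond-valence scores. It is aimed at structural
biologists annotating new models (including cryo-EM structures at modest
resolution, where metal ions are easily missed) and at method developers
who need the underlying primitives.

## The method in brief

**Search.** Candidate sites are sets of 2–4 Cys/His residues whose
coordinating side-chain atoms (SG; ND1/NE2/CE1/CD2) lie pairwise within
2.4–4.5 Å. SG pairs below 2.400 Å — the upper confidence bound
μ + 2.575σ of the disulfide SG–SG distance peak (μ = 2.058 Å,
σ = 0.133 Å) — are disulfide bonds and are excluded.

**Placement.** The zinc position is deduced per subgroup: two-ligand sites
by scanning a 1.2 Å locus circle perpendicular to the donor–donor segment
and scoring Zn–donor–CB angles against empirical targets (109° SG, 100°
ND1, 155° NE2); two-His sites from the imidazole lone-pair rays
(centroid → ring atom, candidate at the 2.1 Å bond length beyond the
atom); three-His and mixed triples by averaging or majority-voting the
pairwise constructions; four-residue sites as the centroid of the four
donors.

**Verification.** Around each placed zinc, hydrophobicity-contrast and
mean atomic-solvation curves are evaluated at 21 radii (2–7 Å, 0.25 Å
steps). 3/4-residue sites are scored by Pearson correlation against
per-group reference curves; 2-residue sites by a five-learner ensemble
(logistic regression, decision tree, MLP, radial SVM, feed-forward
network) over 61 features with a 3-of-5 majority vote. Certainty > 0.5
verifies a site; verified zincs closer than 2.5 Å are merged so genuine
dinuclear sites (3–4 Å apart) survive.

**Validation.** Any metal site, predicted or deposited, is scored with
bond-valence sums (valence `exp((R0 − d)/b)`, b = 0.37 Å):
valence agreement `Qv = min(S/Vox, Vox/S)`, sphere completeness
`Qc = 1 − |Σ v⃗| / N`, and occupancy/B-factor environment agreement `Qe`.
Sites with ≥ 3 donors must exceed 0.5 on all three; 2-donor sites use the
looser 0.25 / 0.355 / 0.5 thresholds derived from the two-ligand optima
(Qv = 0.5, Qc = 0.71).

## Worked example

The synthetic generator builds a noisy Cys4 structural site with a known
zinc (here with realistic 2.3 Å Zn–S bonds), and the pipeline recovers it:

```r
library(znsite)

fx <- make_site_structure("CH4", bond_length = 2.3, noise_sd = 0.05, seed = 42)
refs <- build_reference_curves(tibble::tibble(
  structure = list(make_site_structure("CH4", bond_length = 2.3,
                                       include_zinc = FALSE)$structure),
  center = list(c(0, 0, 0)), group = "CH4"))
cfg <- prediction_config(reference_curves = refs)

report <- predict_structure(fx$structure, cfg)
report
#> <zn_prediction> synthetic_CH4
#>   verified sites: 1
#>   rejected candidates: 0
#>   modelled metals validated: 1

tidy(report)
#> # A tibble: 1 × 9
#>   site_id group subgroup ligands       zn_x   zn_y    zn_z certainty n_auxiliary
#>     <int> <chr> <chr>    <chr>        <dbl>  <dbl>   <dbl>     <dbl>       <int>
#> 1       1 CH4   CH4      A:C10,A:C2… 0.0433 0.0192 -0.0458     0.832           6
```

One CH4 site is found and verified (certainty 0.83, written into the
occupancy field of the output zinc record by `write_predictions()`); its
placed position sits 0.07 Å from the true zinc at the origin. The
ground-truth zinc carried by the fixture is validated like any deposited
ion:

```r
validate_structure_metals(fx$structure)
#> # A tibble: 1 × 11
#>   chain resseq icode     x     y     z q_valence q_completeness q_environment
#>   <chr>  <dbl> <chr> <dbl> <dbl> <dbl>     <dbl>          <dbl>         <dbl>
#> 1 M        900 ""        0     0     0     0.823          0.956             1
```

`Qv = 0.82`, `Qc = 0.96`, `Qe = 1` — a sound tetrahedral site (all three
exceed the 0.5 thresholds, so `passed` is `TRUE`).

A thin command-line wrapper is installed at `exec/znsite` inside the
package library (`search`, `validate`, `predict`, `eval`, `fixtures`
subcommands emitting TSV).

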