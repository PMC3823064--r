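# specswap

Substrate-specificity evolution in subfamily Iα aminotransferases.

Aminotransferases of subfamily Iα divide into aspartate aminotransferases
(AATases) and aromatic/tyrosine aminotransferases (TATases), yet overall
sequence identity does not predict which is which — near-identical
sequences can prefer different substrates. `specswap` is an analysis
package for researchers studying how that substrate preference is encoded
and how it evolved. It implements the full computational chain:

* **Active-site shells** — per-residue minimum heavy-atom distances to a
  bound cofactor (PLP) and ligand, with closed shell boundaries
  (first shell ≤ 3.40 Å; ~5 Å per shell beyond).
* **Conservation statistics** — ClustalX-style per-column q-scores
  (0–100), the summed score of active-site columns, and a permutation
  test drawing equal-size column sets without replacement from
  reference-ungapped columns, with an add-one p-value.
* **D&V selection** — the distance-and-variability criteria
  (< 15 Å from the cofactor, modal residue in 25–75 % of aligned
  sequences) select scoring positions; a candidate's **D&V score**
  counts positions where it differs from *every* characterized
  reference; asymmetric pairwise scores and mutual `< 9` linkage group
  candidates, one representative per group.
* **Ping-pong bi-bi kinetics** — for substrates A (amino acid) and B
  (2-oxoglutarate),
  `v = [E]·kcat·A·B / (Km_A·B + Km_B·A + A·B)`,
  fitted by Levenberg–Marquardt with Hanes starting values, demoted to
  the first-order model `v = [E]·(kcat/Km)·A` when no saturation is seen
  below 40 mM. Specificity is the ratio
  `(kcat/Km)_Asp : (kcat/Km)_aromatic`, reported at 2 significant
  figures: > 1 AATase, < 1 TATase.
* **Parsimony on the phylogeny** — Sankoff dynamic programming (unit
  costs, free unannotated leaves) for minimum specificity-switch counts
  with optional root constraints, enumeration of co-optimal switch
  branches, and a leave-one-out parsimony predictor.
* **Synthetic-data generators** — seeded generators for alignments with
  planted column conservation, structures with planted distances,
  rate data from the ping-pong law, and trees with planted switches, so
  the whole pipeline is testable offline.

## Worked example

Fit a simulated two-substrate assay and classify an enzyme from its
specificity constants:

```r
library(specswap)

truth  <- rate_law_params(kcat = 90, Km_AA = 2, Km_cosub = 1)
assays <- simulate_kinetics(truth, kinetic_design(), enzyme = "AATlike",
                            substrate = "Asp", noise = 0.01, seed = 42)
fit <- fit_pingpong(assays, "AATlike", "Asp", model = "auto")
fit
#> AATlike / Asp (full): kcat = 89.5 (0.64) s-1, Km_AA = 2 (0.029) mM, Km_cosub = 0.985 (0.015) mM
#>   kcat/Km = 4.47e+04 M-1 s-1 (se 4.2e+02), n = 30

specificity_call(47000, 47)   # constants in M-1 s-1, Asp then aromatic
#> kcat/Km ratio (Asp : aromatic) = 1e+03 -> 1000 : AATase
```

The fitted constants recover the planted truth within their standard
errors, and an enzyme whose aspartate specificity constant is a
thousandfold larger than its aromatic one is called an AATase.

Root-hypothesis parsimony on the bundled 92-leaf consistency preset
(12 AAT + 7 TAT annotations, TAT in three separate clades):

```r
preset <- fig_tree_preset()
min_changes(preset, "AAT")
#> Parsimony: 3 change(s) (root AAT), optimal root state(s): AAT, 1 co-optimal labeling(s)
min_changes(preset, "TAT")
#> Parsimony: 5 change(s) (root TAT), optimal root state(s): TAT, 6 co-optimal labeling(s)
```

An aspartate-preferring root explains the annotations with three
independent specificity switches; forcing an aromatic-preferring root
requires five.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the chain over
a fully synthetic bundle and write tables under `results/`:

```sh
Rscript analysis/01_simulate_inputs.R        # alignment, structure, rates, tree
Rscript analysis/02_active_site_positions.R  # shells + D&V position selection
Rscript analysis/03_conservation_permutation.R
Rscript analysis/04_dv_groups.R              # scores, shortlist, groups
Rscript analysis/05_kinetics_classification.R
Rscript analysis/06_parsimony_switches.R
```

Externally obtained inputs (a curated subfamily alignment, liganded PDB
structures, published rate tables, a rooted subfamily tree) flow through
the same readers; `run_pipeline()` orchestrates all stages from one
config and `write_report()` serialises the result.

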