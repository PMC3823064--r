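---
title: "Methods: substrate-specificity evolution in subfamily Ia aminotransferases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: substrate-specificity evolution in subfamily Ia aminotransferases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specswap)
```

## The scientific problem

Subfamily Ia aminotransferases split into aspartate aminotransferases
(AATases) and aromatic/tyrosine aminotransferases (TATases). The two
classes are not separated by overall sequence identity — closely related
sequences can prefer different substrates — so three questions arise:
which active-site positions carry the specificity signal, how should new
enzymes be chosen for kinetic characterization so that they sample
divergent active sites, and how often did specificity switch during the
subfamily's evolution? `specswap` implements the computational chain
that addresses these questions: active-site shells from a liganded
structure, alignment-column conservation statistics with a permutation
test, distance-and-variability (D&V) candidate scoring and grouping,
ping-pong bi-bi kinetic fitting with kcat/Km ratio classification, and
binary-trait parsimony on a rooted phylogeny.

## Active-site shells

Given a structure with a bound cofactor (PLP) and optionally a ligand,
`residue_min_distances()` computes, for every polymer residue, the
minimum Euclidean distance between any of its heavy atoms and any heavy
atom of the target group(s); hydrogens are excluded because the crystal
structures this analysis assumes do not resolve them. When both a
cofactor and a ligand are selected the distance is the minimum over the
union of their atoms. `assign_shells()` bins residues by closed
(`<=`) cutoffs. Defaults: the first shell ends at 3.40 Å (direct
contact with cofactor or ligand); the third and fourth shells end at
16.3 Å and 22.0 Å, the observed ~5 Å-per-shell spacing of the
aminotransferase active site. The second-shell boundary is not directly
observable and defaults to the interpolated 11.3 Å; all radii are
arguments. The 15 Å radius used for D&V position selection is an open
bound (`< 15`), distinct from the closed shell boundaries, and is taken
from the cofactor alone by default (configurable to include the
ligand).

## Column conservation and the q-score

`column_profiles()` counts the 21 symbols (20 amino acids + gap) per
column. The modal fraction is computed over non-gap residues only, with
the gap fraction reported separately: "the same amino acid in x% of the
sequences" is a statement about residues, and gap filters are applied
separately where needed.

The q-score is a 0–100 column quality score in the style of the
ClustalX column score. The exact historical parameterization of that
score is not recoverable, so the scorer is an interface with two
implementations (argument `scorer`):

* `"clustalx"` (default): each residue r maps to its row vector of a
  substitution matrix (BLOSUM62 by default); the column consensus is the
  mean vector of its non-gap residues; residue i scores
  `1 - d_i / d_max`, where `d_i` is its Euclidean distance to the
  consensus and `d_max` the largest distance any of the 20 amino acids
  could have to that consensus; gaps score 0, and the column value is
  100 times the mean over all rows. A column scores exactly 100 iff it
  contains a single residue type and no gaps; an all-gap column scores 0.
* `"modal"`: `100 * modal_fraction * (1 - gap_fraction)`, a deliberately
  simple fallback.

The permutation test (`permutation_test()`) asks whether the summed
q-score of the k active-site columns exceeds what equally sized random
column sets achieve. Null sets are drawn without replacement from the
columns ungapped in the reference (structure-bearing) sequence. The
p-value uses the add-one estimator `(1 + #{null >= obs}) / (1 + n_perm)`
so it is never zero; with 100,000 draws and no exceedances it reports
1e-05, matching how a vanishing tail is conventionally stated. The test
is bit-reproducible given its seed, and its null p-values are uniform on
the achievable grid (verified by a Kolmogorov–Smirnov calibration test).

`conserved_set()` declares a column conserved in a subset of n
sequences when one amino acid occurs at least `ceiling(level * n)`
times. The ceiling convention is what produces count thresholds 15, 9
and 6 for subsets of 19, 12 and 7 sequences at level 0.75.
`venn_partition()` then splits columns into those conserved across the
union of two specificity groups, those conserved only in one, and flags
the corner case of a column conserved as different residues in the two
groups (such a column is in both group-conserved sets, hence in neither
"only" set).

## D&V selection, scoring and grouping

`select_dv_positions()` keeps alignment columns that are (a) mapped via
the ungapped reference sequence to a residue strictly closer than
`d_max = 15` Å to the cofactor and (b) moderately variable:
`0.25 <= modal fraction < 0.75` (closed–open, per "at least 25% but
fewer than 75%"). `dv_score()` counts, per candidate, the selected
positions at which the candidate differs from *every* member of the
characterized reference panel. Gaps act as a 21st symbol: gap vs
residue is a difference, gap vs gap an identity (the least surprising
rule; configurable behaviour was considered and rejected as untestable
against any stated convention). The score is monotonically
non-increasing in panel size.

The pairwise score `s(i -> j)` counts mismatches between i and j over
the positions that contributed to i's D&V score; it is asymmetric by
construction. `group_candidates()` links two candidates when both
directed scores are `< 9` and takes connected components. The published
grouping rule speaks only of pairs; closure to components is this
package's explicit reading (disjoint groups imply transitive closure)
and is tested as such. Representative choice within a group was
originally driven by gene availability, which is not computable;
`pick_representatives()` therefore exposes policies: lexicographic
(default, deterministic), max-score, and manual. Shortlisting of
diverse candidates uses a strict `score > 10` filter.

## Ping-pong bi-bi kinetics

The two-substrate ping-pong mechanism (first product released before the
second substrate binds) has the rate law

v = [E] kcat A B / (Km_A B + Km_B A + A B)

with A the varied amino acid and B the co-substrate (2-oxoglutarate),
both in mM; there is no ternary-complex (Km_A·Km_B) term. Its
first-order limit, v = [E] (kcat/Km) A, is used when amino-acid
saturation cannot be reached. Specificity constants kcat/Km are
reported in M⁻¹ s⁻¹ (a factor 1000 from s⁻¹/mM).

`fit_pingpong()` fits by Levenberg–Marquardt least squares with
starting values from a Hanes linearization of the rows nearest
saturation in the other substrate; tolerance 1e-10 on the relative
parameter change, at most 500 iterations, parameters bounded positive.
Standard errors come from the local curvature; the kcat/Km standard
error uses the delta method. The reduced model is the closed-form
origin-constrained regression of rate on [E]·[AA].

The no-saturation ("NS") rule: a full fit is demoted to the reduced
model (in `model = "auto"`) when the fitted Km of the varied substrate
exceeds the smaller of the largest tested concentration and `ns_bound`
(40 mM, the highest attainable assay concentration), or when its
standard error is not finite — the practical proxy for an unbounded
upper confidence limit. NS rows carry only kcat/Km, mirroring how such
measurements are reported.

Weighting: unweighted least squares is the default because the original
fits' weighting is unknown. Initial-rate assay error scales with the
signal, so the generator uses multiplicative Gaussian noise; under that
error model the optional relative (1/rate²) weighting is the correct
variance model and is what the calibration tests use. In simulation
(1% noise, 30-point designs, 200 replicates) the weighted fits show
median |bias| below 2% and 3-standard-error coverage of 0.97–1.0;
unweighted fits give the same point estimates to within fractions of a
percent but anticonservative standard errors in weakly identified
corners (Km at the design edge).

Classification: the specificity ratio is (kcat/Km)_Asp over
(kcat/Km)_aromatic, reported at 2 significant figures. Ratios above 1
are AATases, below 1 TATases. "Equal to 1 at reported precision" is
declared symmetric in the ratio and its reciprocal
(`signif(r, 2) == 1` or `signif(1/r, 2) == 1`) so the call is
antisymmetric under swapping the two reactions; no characterized enzyme
falls in that zone.

## Parsimony on the phylogeny

`min_changes()` computes the small-parsimony minimum number of
AAT↔TAT switches by Sankoff dynamic programming with a unit cost
matrix (equivalent to Fitch for two states). Unannotated leaves are
free variables optimized over rather than pruned — this is how one
reasons about a 92-leaf tree with 19 annotations. Root constraints fix
the root symbol, and the constrained minimum is never below the
unconstrained one. Counting of co-optimal labelings is done in the same
pass; `enumerate_switch_edges()` backtracks through all co-optimal
pointer choices to list each optimal labeling's switch branches (every
set has exactly `min_changes` edges), guarded by a cap on the number of
labelings. `parsimony_predict()` reports the set of states a masked
leaf takes across all optimal labelings — computed by constrained
re-evaluation rather than enumeration — and `loo_accuracy()` masks each
annotated leaf in turn; an undecided prediction counts as incorrect by
default (a deliberately conservative choice; 0.5 credit is available).
This simple predictor stands in for full phylogenomic function
prediction, which is out of scope.

`fig_tree_preset()` is a deterministic 92-leaf consistency preset: 12
AAT and 7 TAT annotations with the TAT leaves in three separate clades
alternating with five AAT clades along a two-limb backbone, and 73
unannotated filler leaves grafted where free variables leave all costs
unchanged. On it, constrained parsimony needs 3 switches under an
AAT root and 5 under a TAT root, so an aspartate-preferring ancestor is
the more parsimonious hypothesis. The preset is a topology *consistent
with* the described clade structure of the real subfamily tree, not a
reconstruction of it — the real tree is not machine-readable from its
published figure.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, in the
standard formats (aligned FASTA, PDB coordinate records, CSV, Newick +
TSV), deterministically under a seed:

* `simulate_msa()` plants per-column modal-residue fractions by exact
  count (`round(target × non-gap cells)`), with non-modal residues
  uniform over the remaining 19 amino acids and i.i.d. gaps; the
  reference row is kept ungapped to anchor the column→residue map.
* `simulate_structure()` places one heavy atom per residue on a sphere
  of the planted radius around a single-atom pseudo-cofactor: exact
  distance control beats stereochemical realism for testing.
* `simulate_kinetics()` draws rates from the ping-pong law with
  multiplicative Gaussian noise (CV-style, matching how initial-rate
  error scales); negative draws are resampled.
* `simulate_annotated_tree()` plants k specificity switches on edges
  chosen pairwise non-nested and non-sibling, which guarantees the
  parsimony minimum equals k exactly.

None of this emulates real protein evolution: there are no indels
beyond i.i.d. gaps, no rate heterogeneity, no covariation between
columns, no phylogenetic signal in the alignment, and single-atom
residues. Passing tests therefore demonstrate algorithmic correctness
(against brute-force oracles and planted truths), not that the
biological conclusions would replicate on arbitrary real data. The
quantities that depend on the real 92-sequence alignment and the
liganded crystal structures (the published q-score sum, the 76 selected
positions, the Venn counts, pairwise identities) require those external
inputs; the pipeline accepts them through the same file interfaces.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 20-sequence × 50-column
alignments over 100 seeds for the D&V oracles; 200 random trees with at
most 8 leaves for the parsimony oracle (exhaustive enumeration is exact
there); 200 replicates of 30-point kinetic designs at 1% noise; 10,000
to 100,000 permutation draws; and the fixed 92-leaf preset. These sizes
were chosen so each property is measured with comfortable statistical
resolution while a full run stays interactive. Ties in representative
selection break lexicographically; ties in parsimony are enumerated,
not broken. Degenerate inputs (all-gap columns, empty contributing
sets, zero concentrations) are defined explicitly rather than left to
floating-point accident, and classed error conditions
(`specswap_input_error`, `specswap_config_error`, `specswap_fit_error`)
separate bad data from bad configuration from numerical failure.

## Known limitations

* The q-score is ClustalX-*style*, not bit-identical to any specific
  ClustalX release; published score sums serve as regression anchors
  only when the original alignment is supplied.
* The reduced kinetic model estimates kcat/Km consistently only in the
  true first-order regime; when data approach saturation the full model
  should be used (the auto rule prefers it whenever saturation is
  observed).
* Parsimony counts are lower bounds on the number of historical
  switches and inherit the assumption that the supplied topology is
  correct.
* The leave-one-out predictor is intentionally minimal; leaves at clade
  boundaries are genuinely undecidable under parsimony and score as
  errors.
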