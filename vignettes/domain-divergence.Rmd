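---
title: "Domain-resolved divergence analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-resolved divergence analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coildiverge)
```

## The question the package answers

Functional protein domains usually evolve more slowly than the rest of the
protein: purifying selection holds the residues that do the work. A domain
that instead accumulates substitutions *faster* than its own protein
background, in one lineage only, is a candidate for lineage-specific
adaptive change. `coildiverge` operationalizes this comparison for a set of
orthologues split into species groups (the motivating case is the synaptic
and kinetochore protein SIP30/Zwint in primates, domesticated mammals, and
rodents, with its coiled-coil protein-interaction domain as the focal
region).

The core statistic is geometric. For every unordered species pair we
compute two percent identities from one protein alignment: `x` over the
whole sequence and `y` over the domain columns only. Each pair becomes a
point in the `(x, y)` plane, and two summaries follow:

* **Conservation distance** — the Euclidean distance
  `sqrt((100 - x)^2 + (100 - y)^2)` from the full-conservation corner
  `(100, 100)`. Groups of pairs ("clusters") are ranked by their mean
  distance; cluster dispersion is reported as mean ± SEM (sample SD with
  the n − 1 denominator over √n, left blank for a single pair).
* **Diagonal classification** — position relative to the slope-1 line
  `y = x`. Above the line the domain is better conserved than the protein
  as a whole (`domain_conserved`); below it the domain diverges faster
  (`domain_accelerated`). The line is treated as a strict demarcation: the
  tie tolerance defaults to `1e-9` and exists only to absorb floating-point
  equality, not to create a "near the line" band.

Distances are computed from full-precision identities and rounded only for
display (identities to 1 decimal, distances to 2); rounding before the
arithmetic can move the second decimal.

## Percent identity: the denominator convention

Published pairwise identity values rarely state their denominator. The
package fixes one convention everywhere: **columns where both sequences are
non-gap**; matches are divided by that count. This choice is symmetric in
the two sequences, unchanged by columns where either sequence is gapped,
and stable under region restriction. Every identity matrix carries a
`convention` attribute (`"both-ungapped"`) so an alternative denominator
could be added later without silently changing results.

Pairwise values are read off the supplied multiple alignment by default —
matching the single-alignment presentation such data sets usually come in.
Per-pair Needleman–Wunsch re-alignment (`global_align()`, linear gap
penalty, deterministic diagonal > gap-in-b > gap-in-a tie-breaking) is
available when no trusted alignment exists; both routes are exposed
because the original analyses of this kind do not say which was used.

## The coiled-coil caller is a convenience, not a dependency

Coiled coils are heptad repeats (positions `a`–`g`) with hydrophobic
residues at `a`/`d` and charged residues flanking. `predict_coiled_coil()`
scores 28-residue windows (four heptads) at each of the seven register
phases by summing per-residue positional log-odds, gives every residue the
best score of any window covering it, and reports maximal runs at or above
a threshold, merging runs separated by fewer than 7 residues (one broken
heptad should not split a domain).

The shipped propensity table (`inst/extdata/coil_propensity.tsv`) is
synthetic: hand-constructed from the qualitative architecture of canonical
coiled coils, not trained on any external data set, with the window,
decision threshold (21), and unknown-residue rule stored in the file so
tuning never touches code. Unknown residues (`X`, `*`) score at the table
minimum, which discourages calls through uncertain sequence. Because the
table is a stand-in, **every downstream analysis accepts explicit domain
coordinates** (BED or a `region()`); the caller is a fallback for when no
coordinates are available, and its tested guarantee is deliberately
modest — implanted ideal repeats are recovered with Jaccard ≥ 0.7.

## The synthetic data generator

No accessions are attached to the motivating study, so the package carries
its own data generator, built to be a first-class, tested component rather
than a fixture. `simulate_cds()` evolves a coding sequence along a fixed
tree under HKY85 with discrete-gamma rate variation:

* **Substitution model defaults** are the values estimated for the SIP30
  coding alignment: base frequencies (0.2844, 0.2519, 0.2947, 0.1690),
  Ti/Tv ratio 2.2233 (converted to κ via
  `TiTv = κ(π_A π_G + π_C π_T) / ((π_A + π_G)(π_C + π_T))`, stated
  explicitly because papers print Ti/Tv while simulators need κ), gamma
  shape 0.9665, no invariable sites. Those parameters were estimated for
  tree inference, not simulation; adopting them as generator defaults is
  this package's construction.
* **Rates across sites**: 4 equal-probability discrete gamma categories
  (median-of-category rates, renormalized to mean exactly 1), drawn once
  at the root and shared across the tree.
* **Domain rate scaling**: a codon-space region whose rate is multiplied
  by a per-edge factor; edges are addressed by stable keys (tip label, or
  sorted clade labels joined by `|`), so a configuration is independent of
  internal edge numbering.
* **Open reading frames stay clean**: a codon that mutates into a stop is
  resampled at the node where the stop arises. This conditions the process
  on stop-free paths and therefore shifts the law slightly away from
  textbook HKY: the leaf base composition follows the stop-excluded law
  (≈0.7 percentage points less T/A than the nominal frequencies), and the
  expected p-distance is a fraction of a percent below the unconditioned
  closed form. The test suite checks the simulator against the *exact*
  stop-conditioned codon law (computed by enumeration over the 64 codons
  with an independent matrix exponential), not against the unconditioned
  formula — at desk scale the difference is real and measurable.
* **Reproducibility**: one master seed; the root state and every edge
  consume separate streams derived by hashing the master seed with the
  edge key, so results do not depend on traversal order and are
  bit-identical for a fixed seed.

### The mammal scenario

`mammal_config()` packages the study conditions: 9 taxa (3 primates, 4
domesticated animals, 2 rodents) on `mammal_tree()`, 280 codons (a
SIP30-sized protein), and an 80-codon domain at codons 111–190. Branch
lengths were chosen once so that the identity pattern of a fast-evolving
mammalian protein emerges: within-group identities high (primates > 90%,
rodents near 88%), between-group identities in the 40–70% band, and a
human terminal branch longer than the chimpanzee one.

The `"accelerated"` scenario sets the domain multiplier to 1/3 on every
edge — a functional domain under ordinary purifying selection — and to 3 on
the three primate terminal edges. The baseline 1/3 is a deliberate part of
the emulated biology: in the motivating data, all non-primate comparisons
lie *above* the diagonal, which can only happen if the domain is better
conserved than background by default. With a neutral baseline (multiplier
1 everywhere, the `"null"` scenario) a pair falls above or below the
diagonal by coin flip; the null scenario is therefore reserved for
calibration and symmetry checks, and the headline recovery property — all
three within-primate pairs below the diagonal, all non-primate
within-group pairs above — is tested under the accelerated scenario across
20 seeds with a ≥ 90% success requirement.

What the generator does **not** emulate: insertions and deletions (the
synthetic alignments are gap-free, so gap-handling code paths are
exercised only by hand-built fixtures), codon models and selection proper
(dN/dS), base-composition drift between lineages, and alignment error.
Passing the recovery tests shows the statistic detects a rate shift the
generator planted; it says nothing about alignment quality or domain
annotation on real data.

## Desk-scale phylogenetics

The tree machinery is deliberately small and fully authored here, so every
step can be checked against an oracle:

* **Distances**: p, Jukes–Cantor, and Kimura two-parameter, with pairwise
  deletion of gapped columns. Saturated pairs (log-domain violations)
  become `NA` plus a `saturated` attribute — never infinities.
* **Neighbor joining**: Saitou–Nei with the standard Q criterion. Q ties
  break on the smallest (row, column) pair; negative branch estimates are
  clamped to zero with the deficit moved to the sister edge. On additive
  matrices the input distances are reproduced exactly (tested at 1e-9).
* **Bootstrap**: columns resampled with replacement at constant width;
  replicates whose distance matrix contains a saturated pair are skipped
  and counted; support is the fraction of successful replicates containing
  the bipartition. The conventional full-study setting is 2000 replicates;
  tests use 25–100.
* **Majority-rule consensus**: strictly greater than the cutoff (≥ 0.5),
  which guarantees the retained splits are pairwise compatible without any
  resolution rule; frequencies are annotated as node labels.
* **Fitch parsimony scoring** of a fixed topology, characters unordered,
  gaps treated as missing (equivalent to column-wise leaf exclusion). Tree
  *search* is intentionally out of scope.

Newick output is canonical: children are ordered by smallest descendant
leaf label and unrooted trees are serialized from the internal node next
to the alphabetically first leaf, so topologically identical trees
serialize identically — this is what makes bit-exact tree tests possible.
Branch lengths print with 6 significant digits; supports ride as internal
node labels in `[0, 1]`.

## Numerical and degenerate-input choices

* Transition probabilities come from the symmetrized eigendecomposition of
  the reversible HKY generator (exact for any branch length, including 0
  and effectively infinite).
* An empty sequence aligns against gaps (score = gap × length) rather than
  erroring; a pair with no mutually ungapped columns yields `NA` identity
  with a classed warning rather than a silent number.
* Cluster partitions must cover every observed group pair exactly once;
  merged clusters (e.g. treating D:D and P:D as one moderate-conservation
  cluster) reflect observed overlap and are always supplied explicitly —
  the package never invents a clustering rule.
* Problem sizes in the test suite (n = 2000 codons for calibration and
  topology recovery, 150–300 codons for symmetry and bootstrap checks, 20
  or 50 seeds per property) were chosen as the smallest sizes at which the
  checked effects are comfortably larger than Monte-Carlo noise.

## Known limitations

* The identity denominator and the per-alignment (rather than per-pair)
  computation are conventions; published values computed under other
  conventions can differ by a percentage point or more, which matters when
  comparing to printed tables.
* The coiled-coil caller is a single-residue approximation; it is not a
  substitute for a trained predictor when domain boundaries actually
  matter, which is why explicit coordinates take precedence.
* Saturated distances abort neighbor joining rather than being imputed;
  deeply diverged data sets need a better-corrected distance before the
  tree stage.
* The simulator's stop-codon conditioning means its output is not exactly
  HKY+G at the nucleotide level; tests and calibration account for this,
  but users comparing against analytic HKY expectations should expect
  sub-percent deviations.
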