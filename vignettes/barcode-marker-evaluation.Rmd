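---
title: "Evaluating DNA barcode markers: models, tests and the synthetic family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DNA barcode markers: models, tests and the synthetic family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A DNA barcode identifies a specimen by comparing a short standardized
sequence against a reference library. In plants the workhorse markers are
plastid loci — typically the coding genes *rbcL* and *matK*, supplemented
by the *trnH-psbA* intergenic spacer — and their discriminating power
varies enormously between families: groups that radiated recently carry so
little plastid variation that conspecific and heterospecific sequences
become indistinguishable. `barcodegauge` implements the complete
evaluation workflow for this question: sequence-set curation, pairwise
genetic distances, the 100%-identity best-match identification test,
multi-marker concatenation, neighbor-joining trees with bootstrap support,
species/genus monophyly accounting, and a synthetic barcode-family
generator so that every stage can be exercised, end to end, on data built
in code.

# Distances

All distances operate on per-pair site counts under **pairwise deletion**:
for each pair of aligned sequences, a column is compared only when both
sequences carry an unambiguous base (A/C/G/T). Gaps (`-`), missing data
(`N`, `?`) and all other IUPAC ambiguity codes are excluded for that pair
only. Pairwise (rather than complete) deletion is the appropriate choice
when one marker is a spacer with extensive indels: complete deletion would
discard most of its columns for every pair. Ambiguity codes are treated as
missing rather than partially matched — a simple, defensible rule that
touches few sites.

With $P$ and $Q$ the transition and transversion proportions among
comparable sites and $p = P + Q$:

* p-distance: $p$
* Jukes–Cantor: $d_{JC} = -\tfrac34 \ln(1 - \tfrac43 p)$
* Kimura 2-parameter: $d_{K2P} = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q)$

Distances are held in substitutions/site; percentages in reports are
simply $100d$. When a correction's logarithm argument is non-positive the
pair is *saturated*; `barcodegauge` raises an error naming the offending
pairs rather than silently emitting `NaN`, because a saturated pair in a
barcode data set nearly always indicates a contaminant or misalignment
rather than genuine divergence. The all-pairs matrix is computed by
indicator-matrix products (six BLAS multiplications for any number of
sequences) and is tested for exact agreement with a literal double loop
over `site_counts()` + `model_distance()`.

The "overall distance" of a data set is the arithmetic mean over the
strict upper triangle, and the realized transition/transversion ratio is
the ratio of summed counts over all pairs, matching how distance software
reports both. Distance distributions (`distance_histogram()`) use
half-open bins $[kw, (k+1)w)$ with a default width of 0.005 (0.5%) —
fine enough to separate intraspecific from interspecific mass at plastid
divergences — and expose three scopes (all, interspecific, intraspecific)
so a barcoding gap, or its absence, can be read directly.

# The best-match identification test

The identification criterion is deliberately strict, mirroring practice
with local-search engines at the 100% threshold: a query matches a
reference only if **every column where the query has an unambiguous base
is identical in the reference** (and the query has at least one such
column). Missing data in the *query* is forgiven; missing data in the
*reference* at a query-covered column is a failed match, because the
reference then does not cover the entire query. At a 100%-identity,
full-length threshold this is equivalent to what an alignment engine
reports, without the opaque dependency.

Every library entry is queried against all others (leave-one-out; the
self-match is excluded). With $M(q)$ the set of species owning a perfect
match: a query *succeeds* when $M(q)$ is exactly its own species, *fails*
when $M(q)$ contains another species, and is a *no-match* when $M(q)$ is
empty. Species aggregate conservatively: any failing query makes the
species a failure; otherwise one success suffices; otherwise no-match.
The success rate is $100 \cdot n_{success}/n_{species}$, with no-match
species kept in the denominator — queries that match nothing certainly
were not identified. Both query modes (every sequence, or the first
sequence per species) are provided since reference-designation
conventions differ between studies; per-sequence is the default as the
strictest symmetric reading.

Marker combinations are evaluated on supermatrices built by
`concatenate_markers()`, which enforces the complete-data rule: a
specimen missing any member marker is excluded, which is why the species
denominators differ between marker sets in the comparison table.

# Trees, bootstrap and monophyly

`nj_tree()` is canonical neighbor joining (Saitou–Nei $Q$ criterion,
standard branch-length and reduction formulas) with two determinism
choices: ties in $Q$ are broken by the lowest (row, column) pair in the
current label order, and new nodes are appended at the end of that order,
so a given matrix always yields the same tree. A negative branch length
is set to zero with the difference transferred to its sibling branch so
paths through the joined node are preserved — the standard cosmetic
repair; additive matrices never trigger it, and on any additive matrix
the output reproduces the generating topology and path lengths exactly
(tested to 1e-9 against exhaustive topology enumeration for 4–5 taxa).

Bootstrap support resamples alignment columns with replacement, rebuilds
distance + NJ per pseudoreplicate, and scores each internal edge of the
point tree by the percentage of replicates containing the same
bipartition (tip-set comparison; branch lengths ignored). A replicate
whose resampled columns leave some pair with no comparable sites — or
saturated — is discarded with a warning and removed from the
denominator rather than poisoning the support values. The default of
1000 replicates follows common practice for NJ barcode trees; tests use
far fewer.

Monophyly is evaluated on the outgroup-rooted tree: a group is
monophyletic when the smallest clade containing its tips contains no
others. `monophyly_summary()` scores every species and genus with at
least two tips (singletons carry no grouping signal and are excluded
from both numerator and denominator).

# The synthetic barcode family

The generator emulates the data regime in which plant barcoding is
hardest: a recent radiation with many close species and several
accessions per species.

* **Species tree.** Pure birth (Yule), scaled to unit depth. A Yule
  process places many splits near the present, reproducing the
  short-internal-branch regime of a recent radiation; a coalescent at the
  intraspecific level is deliberately avoided (see limitations). Genera
  are defined by cutting the tree at a configurable time before present
  (default 0.6 of the depth), so genera are clades of the true tree.
* **Divergence dial.** For each marker the species tree is rescaled so
  the accession-weighted mean pairwise path equals the target overall
  divergence (defaults 0.6% / 1.4% / 0.7% for the rbcL-, matK- and
  trnH-psbA-like markers, matching typical plastid values). The rescaling
  is exact given the tree, so "realized vs target" discrepancies in
  sequences reflect substitution noise only.
* **Intraspecific variation.** Conspecific accessions sit on a star
  whose height is half the configured expected conspecific distance
  (`intra_divergence`, default 0.001 substitutions/site — a typical
  plastid intraspecific value), carved out of the species' pendant branch
  so interspecific paths are untouched. This parameter is an *absolute*
  distance, not a fraction of the family's depth: empirically,
  intraspecific plastid variation is roughly constant across families
  while interspecific divergence varies several-fold, and it is exactly
  this decoupling that makes identification success grow with
  family-level divergence (the barcoding gap widens). Tying intraspecific
  variation proportionally to the divergence dial would instead make
  conspecific 100% matches exponentially rarer at higher divergence and
  invert that relationship at barcode lengths. Setting
  `intra_divergence = 0` gives identical conspecific accessions.
* **Substitution model.** Sites evolve independently under the Kimura
  2-parameter rate matrix (simulation by `phangorn::simSeq`, branch
  lengths in expected substitutions/site; root sequence uniform over
  A/C/G/T). The rate-matrix `kappa` is distinct from the *realized*
  transition/transversion count ratio, which decays with divergence as
  transitions saturate; `kappa_for_ts_tv()` inverts the closed-form
  expectation, and the default calibrates `kappa` (≈4.2) so the realized
  ratio is about 2.09 at the mean marker divergence.
* **Indels.** Spacer-like markers receive indel events Poisson in
  (rate × length × total branch length), placed on branches with
  probability proportional to branch length, geometric lengths (default
  mean 11.4 bp), uniform positions. An event gaps the affected columns in
  the clade below its branch, or in the clade's complement for
  insertion-type events, so the output alignment respects the true
  homology. The default spacer rate (0.7 events/site/unit branch length)
  yields on the order of 30 events on a family-scale data set.
* **Missing data.** Each marker drops specimens at a configured rate
  (defaults 0.089 / 0 / 0.02), emulating uneven sequencing success and
  exercising the complete-data concatenation rule.
* **Seeding.** One master seed; every draw flows from a single RNG
  stream that is restored afterwards, so simulations are reproducible and
  never perturb the caller's RNG.

## What the generator does *not* emulate

Passing tests on simulated data show the machinery is correct and that
the divergence–discrimination relationship behaves as expected; they do
not certify performance on real data. Known gaps:

* Intraspecific variation is a star, not a coalescent: no shared
  haplotype structure, no introgression or hybridization — processes that
  depress real-world success rates further.
* Because `intra_divergence` is per-marker and independent, concatenating
  markers *compounds* conspecific mismatches (a pair identical at one
  marker may differ at another), so combined marker sets can score
  *below* the best single marker in simulation. In real plastid data
  conspecific sequences are very often literally identical across all
  markers (the plastid is one linked molecule), and combinations help.
  With `intra_divergence = 0` the simulator reproduces that regime.
* Inserted segments are filled by the same tree-wide substitution
  process rather than evolving only within the inserted clade.
* No base-composition bias, rate heterogeneity across sites, or
  alignment error (alignments are consumed as given; no aligner is run
  or wrapped).

# Numerical and design choices

* "More than 10 Ns" curation is strict: exactly 10 is retained. Unnamed
  species are recognized by an epithet of `sp.` or `sp`.
* Sequences are upper-cased on read; `N` and `?` are both missing; `-`
  is an alignment gap.
* Equal trimming of database-derived sets is a user-supplied 0-based
  half-open column interval (`crop_matrix()`); no default coordinates
  are assumed.
* The default FASTA header convention is `Genus_species|specimenID`
  (separator configurable); species labels are not machine-readable in
  herbarium vouchers, so the package defines its own stable convention.
* All file coordinates (partition maps, crop intervals) are 0-based
  half-open; histograms use half-open bins.
* Reports round to 2 decimals for display but JSON stores full
  precision; pipeline reruns with one seed are byte-identical.

# Problem sizes used in the tests

The suite checks distance formulas against closed forms and a brute-force
pair loop; NJ against exhaustive topology enumeration (4–5 taxa) and
exact additive recovery (4–8 taxa); identification against a literal
restatement of the matching rule on 100 random toy libraries; monophyly
against clade enumeration on 200 random 8-tip trees; and the
divergence–discrimination claim on 46-species, 797-bp simulations at
overall K2P 1.9% vs 4.8% (ten seeds each), where mean realized divergence
is recovered within ±20% and mean success is strictly higher at the
higher divergence. The end-to-end pipeline test runs the full 46-species,
three-marker family with a reduced bootstrap. These sizes were chosen to
keep the whole suite comfortably under a minute of compute per module
while still exercising family-scale data.

# Limitations

The package evaluates markers; it does not align them (use any aligner
upstream), does not fetch sequences from databases, and implements no
likelihood or parsimony tree inference — NJ is the only tree engine, as
the distance-based view is what the evaluation statistics need. Success
rates are reported without between-marker significance tests.
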