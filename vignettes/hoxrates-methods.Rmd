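---
title: "Fossil-calibrated divergence rates of Hox homeoboxes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fossil-calibrated divergence rates of Hox homeoboxes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoxrates)
```

## The model and its assumptions

The analysis converts sequence divergence within named taxonomic groups
into absolute rates of molecular evolution. Three quantities are chained:

1. **p-distance.** For two aligned homeobox fragments, `p_distance()`
   returns the proportion of differing sites among the sites where *both*
   sequences carry a resolved character. Gaps (`-`), missing data (`?`)
   and IUPAC ambiguity codes (`N`, `R`, `Y`, …, and `X` for amino acids)
   are treated as missing: they never count as a match or a mismatch.
   No multiple-hit correction is applied anywhere in the headline path —
   the statistic is deliberately the *uncorrected* proportion, which
   saturates with time and therefore underestimates true divergence. For
   a between-group *rate contrast* this is conservative in the direction
   that matters: the faster group's rate is shrunk more.

2. **Within-group mean.** `within_group_mean()` averages over all
   C(n, 2) unordered pairs of a group and reports the value in percent,
   together with the taxon count and site count. Groups of one have no
   defined mean and are an error, not a zero.

3. **Fossil-calibrated rate.** `divergence_rate()` divides the mean
   p-distance (%) by the group's fossil *minimum* age in million years:
   r = p̄ / t, in % per My. Ages are fixed constants — minimum ages from
   first fossil occurrences (e.g. Insecta 396 My on *Rhyniognatha
   hirsti*, molluscan classes 510–528 My, crown mammals 195 My on
   *Hadrocodium wui*) — and no age uncertainty is propagated, because the
   statistic is a strict quotient. Since fossil ages are minima, rates
   are again overestimated uniformly within a calibration, which cancels
   in within-group comparisons that share an age.

The insect versus non-insect contrast takes **one rate per (gene, group)
row** of the rate table: 8 insect values (one per Hox gene: lab, pb, Dfd,
Scr, Antp, Ubx, abd-A, Abd-B) against the remaining 52 non-insect rows.
This selection rule is what reproduces the published summary values
(insect mean 0.06, SE 0.003; non-insect mean 0.04); it is a parameter of
`group_rate_summary()` only in the sense that the super-label assignment
travels with the input rows, so alternative groupings can be explored by
relabelling.

A note on dispersion: the non-insect sample has SD ≈ 0.017 and SE ≈
0.0024 over its 52 rows. A published-style "0.04 ± 0.02" is consistent
with the SD, not the SE; the package reports both and asserts neither
interpretation.

## The Mann–Whitney U test

`mann_whitney_u()` computes U for the first sample from mid-ranks,
`U = R1 − n1(n1+1)/2`, and offers two paths:

* **Exact.** The permutation null of U under random relabelling of the
  pooled values, ties respected. The probability mass function is
  computed by a rank-sum convolution (a subset-count dynamic program
  over doubled mid-ranks, so all sums are integers) — mathematically
  identical to enumerating all C(n1+n2, n1) labelings, but polynomial
  cost, which keeps the exact path usable at sizes where brute-force
  enumeration is not. The two-sided p is the null mass at deviations
  |U − n1n2/2| at least as large as observed; the null pmf is symmetric
  about n1n2/2 (reversing the value order is a measure-preserving
  bijection of labelings), so this equals the doubled single tail.
* **Normal approximation.** Mean n1n2/2 and tie-corrected variance
  `n1n2/12 · ((N+1) − Σ(t³−t)/(N(N−1)))`. No continuity correction is
  applied by default, so the convention is explicit and results match
  the textbook z; a `continuity = TRUE` switch adds the usual 0.5
  correction. The correction matters for calibration: at n = 15 per
  side the uncorrected normal p can differ from the exact p by up to
  the central pmf (≈ 0.019), while the corrected path agrees within
  ≈ 0.006. The test suite checks exact-versus-normal agreement with the
  corrected path for that reason.

`method = "auto"` uses the exact path when C(n1+n2, n1) ≤ 2×10⁵ and the
normal approximation otherwise. Degenerate inputs are explicit: empty
samples error; all values tied across both samples gives p = 1 with a
warning. Because the exact test is discrete, its attainable size at
α = 0.05 sits slightly below 0.05 (≈ 0.043 at 10 per side); the type-I
calibration check uses a binomial error band around the nominal level.

On the published rate table the normal path gives p = 0.0011 (identical
to `wilcox.test(..., exact = FALSE, correct = FALSE)`) and the exact
path gives p = 0.00051. The package asserts the contrast at p < 0.01 and
reports the recomputed values rather than guaranteeing any printed
bound, since rounding of the input p-distances already moves the third
decimal.

## Neighbor joining and homolog assignment

`neighbor_joining()` implements the standard agglomeration
(Q-criterion, pendant-length formulas, matrix reduction) with two
conventions chosen for determinism and reproducibility:

* Q-ties are broken by the lexicographically smallest pair of minimal
  leaf labels, so the output is invariant to input row order;
* negative pendant lengths are clamped to zero with the deficit moved
  to the sister branch, preserving the joined pair's total length.

On additive matrices the algorithm recovers the generating topology and
branch lengths exactly (checked to 1e-9 against random trees of up to
12 taxa). Trees are returned as `ape::phylo` objects; `to_newick()` adds
single-quoting for labels with spaces, which the underlying writer does
not produce. `is_monophyletic()` tests *unrooted* monophyly — whether
some edge bipartition isolates exactly the query leaf set — which is the
meaningful notion for NJ trees that have no root.

`assign_family()` scores a query fragment against reference panels by
mean p-distance over shared resolved positions and flags the call
ambiguous on a tie (default margin 0). A separate `short_window` flag
marks queries covering fewer than 30 homeodomain positions. The
motivating case is the Scr/Antp problem: those two homeodomains differ
at positions 1, 4, 6, 7 and 60 only, so a fragment spanning positions
20–45 is structurally unassignable — the expected behaviour is an
ambiguous call with candidates {Antp, Scr}, not a forced best hit.
Because the real reference accessions are external data, the test suite
exercises this with *synthetic* panels constructed to differ at exactly
those five positions; `diagnostic_positions()` (positions where the two
panels' residue sets are disjoint) recovers them. Nucleotide queries are
expected to be translated to the amino-acid frame before classification;
the package does not guess reading frames.

## In-silico PCR conventions

* **Degeneracy** is the product of per-position IUPAC cardinalities
  (N = 4; B/D/H/V = 3; two-base codes = 2).
* **Coordinates** are 0-based half-open on the plus strand. A reverse
  primer (written 5'→3' on the minus strand) is matched as its reverse
  complement on the plus strand and reported with strand `"-"`.
* **Product length** is inclusive of both primer footprints
  (`rev_end − fw_start`). Under this convention templates constructed at
  the published spacings yield exactly the published fragment lengths
  (160, 128, 145, 164 bp); whether those published figures include the
  footprints is not stated anywhere, so the inclusive reading is a
  documented assumption, not a derived fact.
* **Mismatches** are counted uniformly along the primer; no 3'-anchor
  weighting. This is the simplest defensible model — annealing chemistry
  is far more 3'-sensitive in reality, so mismatch-tolerant searches
  should be read as permissive.
* **Melting temperatures** use the Wallace rule Tm = 2(A+T) + 4(G+C),
  evaluated at the minimal- and maximal-GC expansions of the degenerate
  positions. This is advisory output; reported annealing optima are
  empirical and are carried as metadata only.

## The synthetic-data generator

`simulate_group()` emulates the structure the rate analysis consumes: a
star phylogeny per group (all lineages radiate independently from one
random ancestral fragment), fixed-length fragments, and a per-site,
per-lineage Poisson number of substitutions with uniform replacement
among the remaining states. The star shape is deliberate: the analysis
uses a *group-mean* p-distance, and independent lineages keep the
expectation algebra exact. Each lineage carries half the pairwise
divergence, mirroring the fact that the fossil age bounds the pairwise
split, so a pair accumulates rate × age.

Two saturation models are exposed:

* `"linear"` (default): the per-lineage Poisson intensity is set by
  inverting the uniform-replacement hit process,
  λ = −(c/2)·ln(1 − p/c) with c = (S−1)/S, so the *expected pairwise
  p-distance equals rate × age / 100 exactly* at any target below the
  plateau c (0.75 for nucleotides). Targets at or beyond c error as
  "saturated".
* `"jukes-cantor"`: the nominal divergence d = rate × age / 100 is
  interpreted as expected substitutions per site of a pair, and the
  observable p-distance saturates as p = 0.75·(1 − e^(−4d/3))
  (nucleotides), i.e. the realized distances fall below the nominal
  target the way real saturating sequences would.

Defaults are the study-shaped conditions: nucleotide alphabet, L = 75
(the modal site count of the published table; per-gene site counts 72–76
are taken from that table in `default_simulation_spec()`), taxon counts
and fossil ages per (gene, group) as published, and true rates 0.06
(insect rows) versus 0.04 (non-insect rows) — the two published
super-group means. All randomness flows from a single integer seed;
`generate_study_fixture()` writes bit-reproducible FASTA/TSV/JSON
bundles with the ground truth in the manifest.

What the generator does *not* emulate — and therefore what passing
recovery tests do not show about real data: within-group tree structure
(real groups are not stars, so pairwise distances covary), among-site
rate heterogeneity, codon structure and selection, indels, and
fragmentary coverage. These are exactly the effects the uncorrected
p-distance analysis itself ignores; the simulator is matched to the
estimator, not to biology.

## Numerical choices and problem sizes

* Rates are computed at full precision; the reporting convention (p% to
  1 decimal, rates to 3 decimals) is applied only by
  `format_rate_table()` at output time.
* Q-matrix tie tolerance in NJ is 1e-12; distance matrices must be
  symmetric to 1e-12; undefined distance cells (no comparable sites) are
  `NA` and are rejected by tree building rather than silently zeroed.
* The exact U-test pmf uses integer doubled mid-ranks, so no floating
  tie arithmetic enters the null distribution.
* Simulation sizes used by the checks: 200 replicates for parameter
  recovery at the insect point estimate (n = 30 taxa, L = 75); 20
  study-shaped end-to-end bundles for the power check; 2000 null
  replicates (10 per side, exact path) for type-I calibration; 100
  random additive matrices (4–12 taxa) for NJ recovery. These sizes give
  Monte-Carlo standard errors comfortably inside the asserted
  tolerances.

## Known limitations

* Rates inherit every bias of uncorrected p-distances on saturating
  sequences; absolute values should be read as lower bounds.
* Fossil minimum ages bias rates upward; the two biases do not cancel.
* The 8-versus-52 sample construction treats (gene, group) rows as
  exchangeable observations, ignoring that rows share genes and
  calibrations; the U-test's independence assumption is therefore an
  approximation of convenience, as in the original analysis design.
* `assign_family()` is a nearest-panel classifier, not a phylogenetic
  placement; it is intended for triage and for making ambiguity
  *visible*, not for settling orthology.
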