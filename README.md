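# hoxrates

Fossil-calibrated divergence rates of Hox homeobox sequences, with the
supporting machinery such an analysis needs: uncorrected p-distances,
neighbor-joining homolog assignment with explicit Scr/Antp ambiguity
handling, a tie-aware Mann–Whitney U test, in-silico validation of
degenerate PCR primers, and a seeded star-phylogeny simulator.

## The scientific problem

Hox genes pattern the anterior–posterior body axis of bilaterian animals,
and their ~180-bp homeobox (encoding the 60-residue homeodomain) is short
enough to align unambiguously across phyla. That makes it a convenient
window onto how fast the most important developmental regulators evolve in
different lineages — in particular whether insects, the most successful
radiation among animals, show accelerated Hox sequence evolution relative
to other arthropods, molluscs and mammals.

The core statistic is deliberately simple. For a group of taxa with a
fossil record, the mean within-group p-distance

    p̄ = (2 / n(n−1)) Σ_{i<j} p_ij,   p_ij = (# differing sites) / (# comparable sites)

is divided by the group's fossil minimum age *t* (in My) to give an
absolute divergence rate

    r = p̄(%) / t    [% per million years].

One rate per (gene, group) cell yields a gene × group rate table; the
insect rows (one per Hox gene) and the non-insect rows form two samples
compared with a two-sided Mann–Whitney U test (mid-ranks, tie-corrected
variance). p-distances are left uncorrected for multiple hits, so rates
are conservative underestimates — which only strengthens a *higher*-rate
finding for the group with larger distances.

## Worked example

The packaged table `hox_divergence_table.tsv` transcribes a published
gene × group analysis (60 rows: mean p%, taxon/site counts, fossil ages).
`run_rate_analysis()` in precomputed-distance mode rebuilds every rate and
the group comparison from those inputs:

```r
library(hoxrates)
tab <- load_hox_divergence_table()
res <- run_rate_analysis(
  precomputed = tab[, c("gene", "group", "super_label",
                        "n_taxa", "n_sites", "mean_p_percent")],
  outdir = "results/published_table")
```

Running `Rscript analysis/01_published_table_rates.R` prints:

```
60 / 60 rate-table rows reproduce the published rate to 3 decimals
insect rates (n = 8):     mean 0.06 +/- 0.003 (SE) % per My
non-insect rates (n = 52): mean 0.04 (SD 0.02) % per My
Mann-Whitney U = 358, two-sided p = 0.00111 (normal path)
full-enumeration p = 0.000506
```

That is: every printed divergence rate is the exact quotient p̄/t; insect
homeoboxes evolved at 0.06 ± 0.003 % per My versus 0.04 % per My in
non-insects, and the difference is significant well below the 1% level
(the full permutation enumeration puts it below 0.001).

The other drivers cover the remaining stages:

* `analysis/02_simulation_recovery.R` — the star-phylogeny simulator
  recovers a true rate of 0.066 %/My to within Monte-Carlo error and the
  full pipeline declares insects faster in 20/20 study-shaped replicates;
* `analysis/03_nj_classification.R` — NJ trees in Newick, and the
  demonstration that a fragment covering homeodomain positions 20–45 is
  unassignable between Scr and Antp (diagnostic residues sit at positions
  1, 4, 6, 7 and 60 only);
* `analysis/04_primer_validation.R` — degeneracy, Wallace-rule Tm ranges
  and predicted amplicon lengths (160/128/145/164 bp) for the four
  degenerate insect-specific primer pairs.

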