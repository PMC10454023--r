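# nucleosurvey

Bacterial pathogens secrete or surface-anchor two related nucleotidases that
act on extracytoplasmic nucleotides and help the bacterium evade host innate
immunity: UshA-like enzymes (5'-nucleotidase / UDP-sugar hydrolase /
CDP-alcohol hydrolase) and CpdB-like enzymes (3'-nucleotidase /
2',3'-cyclic-nucleotide and dinucleotide phosphodiesterase). Whether a given
taxon carries *ushA*-like and/or *cpdB*-like genes varies widely — across
phyla, and down to individual genomes within a single species.

`nucleosurvey` implements, as a tested and reusable R pipeline, a genomic
survey of these two gene families across a taxonomy of complete genomes:

* **Translated homology search** — a desk-scale stand-in for TBlastN: each
  replicon is translated in all six reading frames and protein probes are
  aligned locally (Smith–Waterman, BLOSUM62, affine gaps 11/1, via
  Biostrings). Raw scores are expressed in bits with the Karlin–Altschul
  normalisation `bits = (λS − ln K)/ln 2` (gapped λ = 0.267, K = 0.041), and
  a probe-vs-genome comparison counts as a **hit** when the best bit score
  exceeds 150 and the query coverage exceeds 70% (both strict). Plasmid
  replicons are excluded by default.
* **Probe panel management** — an all-vs-all relatedness matrix over a
  candidate panel of nucleotidases, connected-component relatedness groups,
  and greedy set-cover selection of a minimal covering probe set. The
  packaged panel metadata describes the 21-protein candidate set and its
  seven selected probes (5 UshA-like, 2 CpdB-like).
* **Hierarchical survey engine** — per-taxon presence levels among analyzed
  genomes (absent; ≤50%; >50% but <100%; 100%, per gene kind, unioned over
  the kind's probes), a completeness rule (a taxon whose two kinds are each
  absent-or-100% is *complete*), and a phylum→species descent that prunes
  complete taxa. Searches above genus rank are restricted to type-material
  genomes when at least five are available.
* **Reconciliation** — per-genome joint statuses (U+C+, U+C−, U−C+, U−C−),
  category inference from marginal counts by inclusion–exclusion, the
  four-way partition of complete taxa, per-rank bookkeeping, and correlation
  percentages.
* **Synthetic data generator** — deterministic toy datasets (taxonomy,
  manifest, genomes with planted probe homologs at controlled protein
  identity, decoy ORFs, plasmids, strand choice) with a ground-truth
  manifest, so the full pipeline is testable without any database download.

## Worked example

Generate a small synthetic dataset, run the hierarchical survey, and
tabulate the outcome:

```r
library(nucleosurvey)

ds <- generate_dataset(synthetic_config(
  seed = 7, n_phyla = 2, n_classes = 2, n_orders = 1, n_families = 1,
  n_genera = 1, n_species = 2, n_genomes = 3,
  background_length = 6000, probe_length = 200))

sv <- hierarchical_survey(ds$tree, ds$manifest, ds$genomes, ds$probes)
glance(sv)
#> # A tibble: 3 × 9
#>   rank   n_probed n_without_genomes n_analyzed n_complete n_both n_u_only
#> 1 phylum        2                 0          2          1      1        0
#> 2 class         2                 0          2          2      0        1
#> 3 total         4                 0          4          3      1        1
```

Reading the summary: both phyla were probed and analyzed; one phylum was
*complete* (every analyzed genome carried both gene kinds, category U+C+),
so it was not descended. The other phylum was mixed, so its two classes were
surveyed: one proved complete with only *ushA*-like genes (U+C−), the other
complete double-negative. `tidy(sv)` gives the per-taxon rows with the
presence levels, and `autoplot(sv)` draws them as a presence-level map.

Per-genome reconciliation works the same way on real score tables. The
packaged transcription of the *E. coli* genomes that lack one of the two
genes reconciles, under the strict >150 filter, to

```r
categorize_genomes(status_from_scores(read_score_table("ecoli_exception_genomes")))
#> # A tibble: 1 × 5
#>   n_both n_u_only n_c_only n_neither n_total
#> 1      0        4       14         0      18
```

i.e. 4 genomes carry an *ushA*-like but no *cpdB*-like gene and 14 the
converse. When only marginal counts are known, the joint breakdown follows
by inclusion–exclusion; for a species with 17 genomes, all 17 with
*ushA*-like hits but only 4 with *cpdB*-like hits:

```r
infer_categories_from_counts(17, 17, 4, 4)
#> # A tibble: 1 × 5
#>   n_both n_u_only n_c_only n_neither n_total
#> 1      4       13        0         0      17
```

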