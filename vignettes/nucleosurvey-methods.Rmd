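---
title: "Surveying ushA-like and cpdB-like genes across a taxonomy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying ushA-like and cpdB-like genes across a taxonomy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

UshA-like 5'-nucleotidases and CpdB-like 3'-nucleotidases are periplasmic or
cell wall-bound enzymes that degrade extracytoplasmic nucleotides and are
pro-virulent in several pathogens. Their genes are not ubiquitous: some
bacterial taxa carry both, some one, some neither, and within a species
individual genomes may differ. `nucleosurvey` turns the survey of this
distribution into a reproducible pipeline: translated homology search of
protein probes against complete genomes, three-tier presence classification
per taxon, completeness-based pruning of a phylum-to-species descent, and
cross-probe reconciliation of which genomes carry which gene kind.

## The search model

The search is a desk-scale equivalent of a protein-vs-translated-nucleotide
(TBlastN-style) search, made exact rather than heuristic:

* Each replicon is translated in all six frames (offsets 0, 1, 2 on the
  forward strand and on the reverse complement) under the bacterial/archaeal
  genetic code (transl_table 11). Stop codons are kept as `*` in the
  translation.
* Each probe is aligned to each frame by optimal local alignment
  (Smith–Waterman) under BLOSUM62 with affine gap penalties: a gap of
  length L costs 11 + L. The matrix includes the stop symbol, scored −4
  against every residue and +1 against itself, so an alignment may cross a
  stop codon at a penalty. This is delegated to
  `Biostrings::pairwiseAlignment()`; the test suite checks the scores
  against an independent exhaustive enumeration of all gapped local
  alignments on short peptides.
* Raw scores are reported in bits, `bits = (λS − ln K)/ln 2`, with the
  classic gapped BLOSUM62 11/1 constants λ = 0.267 and K = 0.041. On this
  scale a perfect match of a 200-residue probe scores far above the hit
  threshold, while the best random local alignment of an unrelated probe
  against a 20-kb genome sits around 15–20 bits.

**Hit criterion.** One hit record is produced per (probe, genome): the best
bit score across all replicons and frames, and the query coverage. A hit
*passes* when the bit score exceeds 150 **and** the coverage exceeds 70%,
both strict; the filter is deliberately score-based only (no E-values — the
score threshold is independent of database size).

**Query coverage.** One HSP (the optimal local alignment) is reported per
frame when it reaches a floor of 50 bits; the coverage of a genome is the
fraction of probe residues covered by the union of HSP query ranges on the
best-scoring replicon. The underlying convention ("per best HSP" vs "per
subject union") is genuinely ambiguous in web-BLAST-style reports; we chose
the union because it is the more permissive reading and coincides with the
per-best-HSP value in the common case of a single strong HSP. The floor
only affects coverage aggregation, never the best score.

**Replicon merging.** A gene is not split across replicons in our synthetic
model, so replicon results merge to one hit per genome: best score is the
maximum across replicons; coverage is taken from the best replicon only.
Plasmid-flagged replicons are excluded by default, mirroring a "NOT plasmid"
title filter on the database side.

**Traceback ties.** Between co-optimal alignments we accept Biostrings'
deterministic traceback rather than imposing a bespoke tie-break order; the
choice can move coordinates of co-optimal HSPs but never scores, filters or
survey outcomes.

## The survey engine

For a taxon, the engine takes all genomes mapped to it or any descendant,
applies the eligibility rule, and runs every probe against every eligible
genome:

* **Eligibility.** Above genus rank, when at least five type-material
  genomes exist, only type material is analyzed; otherwise — and always at
  genus and species rank — all genomes are analyzed.
* **Presence levels.** Per gene kind, a genome is positive when *any* probe
  of that kind passes the filter (the per-kind union). With k positive of n
  analyzed genomes: absent (k = 0), low (k/n ≤ 50%), partial
  (50% < k/n < 100%), full (k = n). The 50% boundary is inclusive on the
  low side.
* **Completeness.** A taxon is complete when each kind is absent or full.
  Complete taxa are not descended further; the hierarchical driver surveys
  phyla below the root, then the classes of non-complete analyzed phyla,
  and so on down to species, which are terminal. Taxa without genomes are
  recorded as probed but not analyzed, and not descended. Traversal is
  deterministic (ascending taxid within each rank), and a per-(probe,
  genome) cache guarantees each pair is aligned at most once per run. An
  explicit taxon list can be surveyed instead of the systematic descent,
  for curated species sets.

## Reconciliation

Per-genome joint statuses (has U, has C) feed four-way category counts
(U+C+, U+C−, U−C+, U−C−), which always sum to the number of genomes. When
only marginal counts are known (n genomes, n hit by each kind, n hit by
both), the joint breakdown follows by inclusion–exclusion. Complete taxa
partition into the same four categories keyed by per-kind presence (any
non-absent level) and are aggregated per rank: probed, without genomes,
analyzed, complete, and category counts.

**Percentages.** Category percentages are reported to one decimal by
largest-remainder apportionment: each category receives the floor of its
share in tenths of a percent and the tenths missing from 100.0 go to the
largest fractional remainders. We prefer this to independent rounding
because a four-way split that visibly sums to 100.0 is the convention such
survey tables use, and independent half-up rounding does not generally
achieve it (e.g. shares of 31.36/21.69/7.80/39.15 would print as a 100.1
total).

## The synthetic data generator

Real genome databases change over time, so correctness is validated on
fully synthetic datasets with known ground truth. The generator emits, from
a single seed, a rank-complete toy taxonomy (superkingdom root down to
species), a genome manifest with type-material flags, synthetic probe
proteins, and genome sequences with planted homologs:

* **Backgrounds** are uniform over ACGT — adequate because the validation
  is structural (recovery, exclusion, pruning), not statistical: random
  local alignments against uniform background score far below the 150-bit
  threshold, exactly as the null model predicts.
* **Plants.** Each species follows a presence plan per gene kind (absent /
  low / partial / full) realised as a count of planted genomes (0, ⌊n/2⌋,
  n−1, n). The planted protein is the probe mutated to a target identity
  (substitutions at uniformly chosen positions, realised within one residue
  of the target), back-translated with uniformly chosen synonymous codons
  plus a stop, and written onto the chromosome forward or reverse strand
  (50/50 by default). Decoy ORFs from random proteins are planted alongside.
  Overlapping plants are rejected.
* **Plan assignment** is deterministic from the species' position: the
  first phylum is uniformly double-full (so a complete U+C+ taxon exists at
  the top rank and pruning is exercised immediately), the first class of
  later phyla is double-absent, the first order double... and so on, with
  remaining species cycling through twelve mixed archetypes. This places
  complete taxa of all four categories at several ranks and all presence
  levels at species rank.
* **Default scale**: 2 phyla × 2 classes × 2 orders × 2 families ×
  2 genera × 3 species × 4 genomes = 384 genomes of 20 kb, with two
  UshA-like probes and one CpdB-like probe of 220 residues, planted at
  identity 1.0, a quarter of genomes carrying a 5-kb plasmid, and half of
  each species' genomes flagged as type material. These sizes keep a full
  generate-survey-reconcile run in the low minutes on one CPU while leaving
  every rule (type-material restriction, pruning, per-kind unions across
  multiple probes) observable; identity 1.0 is the intended recovery
  regime, with divergence explored separately (below).

**What the tests show — and do not show.** On these datasets the pipeline's
presence levels must (and do) equal an independent recursive recomputation
from the planted truth, the surveyed taxon set must equal an independent
reference walk, plants on plasmids must vanish exactly when exclusion is
on, and strand choice must not change scores. Detection of a 300-residue
plant is certain down to 70% protein identity and is lost towards 30%,
with the median best score decreasing monotonically. None of this
demonstrates sensitivity on *real* genomes — no repeat structure, gene
models, compositional bias, or fragmented homologs are simulated — so the
synthetic results validate the machinery and the bookkeeping, not the
biological detection limits of the probe set.

## Numerical choices and degenerate inputs

* Strict thresholds: 151 bits / 71% coverage are the smallest passing
  values at the data's resolution; a published borderline case at exactly
  151 bits is therefore classified positive.
* Sequences shorter than one codon translate to empty frames without error;
  genomes whose replicons are all excluded yield an empty, failing hit.
* A mutation target identity is realised as `round((1 − id) · L)`
  substitutions, so tests compare identities with ±1-residue slack.
* Taxonomy loading validates a unique root, no orphan parents and full
  reachability (which doubles as a cycle check); ranks outside the
  seven-level ladder are traversed transparently as "no rank".
* `classify_presence` is undefined for n = 0 by design; the survey layer
  never calls it for unanalyzed taxa.
* The greedy probe-set cover is not guaranteed minimal in general; on the
  synthetic panels used in tests it matches the exhaustive minimal cover,
  and ties break towards the earlier panel member for determinism.
* The Nss ("not significant similitude") threshold of the panel matrix
  defaults to 50 bits: comfortably above the 15–25 bits that unrelated
  random proteins of panel-typical length score, and far below the hundreds
  of bits of genuinely related nucleotidases. It is configurable.

## Known limitations

* The search is exhaustive Smith–Waterman per frame — exact but quadratic;
  it is sized for desk-scale validation, not for scanning millions of
  genomes (the heuristics that make that feasible — seeding, two-hit
  extension, E-values, masking — are deliberately out of scope).
* One HSP per frame means a genome with two same-frame gene copies
  contributes a single query-coverage interval; copy-number questions are
  out of scope.
* The packaged panel carries metadata only (accessions, kinds, lengths);
  sequence-bearing panel operations are exercised on synthetic panels.
* Real per-taxon hit counts against a live genome database are
  database-snapshot dependent and are not reproduced here; the packaged
  transcriptions of published per-genome score tables and count vignettes
  serve as fixed reconciliation inputs instead.
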