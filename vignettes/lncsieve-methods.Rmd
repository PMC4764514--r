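---
title: "Methods: how lncsieve finds, classifies and profiles lncRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how lncsieve finds, classifies and profiles lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncsieve)
```

## The discovery model

Long non-coding RNAs cannot be recognized positively from sequence: they
are poorly conserved and carry no reliable motif. `lncsieve` therefore
implements discovery by elimination, the strategy used throughout the
lncRNA literature. The underlying assumptions are worth stating
explicitly, because every filter encodes one:

* **Length** separates lncRNAs (> 200 nt by definition) from most small
  structural RNAs (tRNA, miRNA, sno/snRNA), which are shorter.
* **ORF size** proxies coding capacity. A transcript whose longest
  complete ATG-to-stop frame exceeds ~100 amino acids is more likely an
  mRNA. The stringent regime tightens this to 83 aa — the mean ORF
  length of the shortest decile of the reference proteome — and adds a
  relative rule (ORF ≤ 35% of transcript length) so short transcripts
  cannot hide proportionally large ORFs.
* **Homology** to a protein database (E ≤ 10⁻⁴, inclusive) marks coding
  remnants and pseudogene transcripts; homology to small-RNA databases
  (same cutoff) marks structural RNAs that escaped the length filter.
* **A coding-potential score** (CPC-style index, consumed here as a
  precomputed table) summarizes ORF quality and database support; kept
  transcripts must score strictly below −0.5 (traditional) or −1.0
  (stringent). A transcript with no score entry is kept and logged — the
  conservative choice, since absence of evidence of coding ability is the
  very property being selected for.
* **Reproducibility across datasets** suppresses assembly noise: a real
  transcript should be co-detected in at least two of the independent
  datasets. Matching is anchored on genomic coordinates because all
  datasets are assembled against one genome; sequence identity over the
  shared region, when sequences are available, acts as confirmation.

Known-lncRNA databases are used only to *annotate* evolutionary
conservation, never to filter — low conservation is expected, so a match
is informative but a non-match is not disqualifying.

## Parameters and their defaults

| parameter | default | units | role |
|---|---|---|---|
| `min_length_nt` | 200 | nt | lncRNA definition; removal strictly below |
| `max_orf_aa` | 100 / 83 | aa | traditional / stringent ORF cap (strict >) |
| `max_orf_fraction` | — / 0.35 | fraction | stringent-only relative ORF cap (strict >) |
| `homology_evalue` | 1e-4 | — | inclusive removal threshold, both databases |
| `coding_score_cutoff` | −0.5 / −1.0 | index | keep strictly below |
| `min_support` | 2 | datasets | consensus support |
| `dedup_overlap` | 100 | nt | shared exonic nt strictly above removes the shorter |
| `strand_identity` | 95 | % | strict > for strand rescue |
| `window` | 15000 | nt | intergenic classification window, inclusive |
| `fold`, `min_specific_rpkm` | 8, 0.5 | —, RPKM | tissue-specific call, both inclusive |
| `min_ubiquitous_rpkm` | 1.0 | RPKM | housekeeping call, inclusive |
| `min_corr`, `retain_fraction` | 0.97, 0.20 | r, fraction | clustering contract and entropy retention |

The strictness of each comparison is part of the contract and is pinned by
boundary tests (199/200 nt, 83/84 and 100/101 aa, fraction 0.35, E = 10⁻⁴,
scores −0.5/−1.0, 100 nt overlap, 500 nt gap, 15 kb window).

## Representation and numerical choices

* Coordinates are 0-based half-open internally; GTF I/O converts to and
  from the format's 1-based inclusive convention, and BED export uses the
  internal convention directly. The gap between half-open intervals is
  `start₂ − end₁`, so abutting features have distance 0 and "within X nt"
  is an inclusive `≤ X`.
* Strand is `+`, `−` or `*` (unknown). Unknown-strand transcripts are
  legal everywhere: they are ORF-scanned in 6 frames instead of 3, they
  match either strand in the consensus graph, they produce the
  `exonic_unknown` / `intergenic_unoriented` classes, and the sense-overlap
  filter keeps them (sense cannot be established) with a logged count.
* The ORF definition counts complete ATG-to-stop frames only; `aa_length`
  excludes the stop codon, while the covered fraction charges the stop's
  3 nt: `3·(aa_length+1)/length`. Ties break to the smaller nucleotide
  start, then to the forward strand. Codons containing N never match a
  start or stop. Incomplete ORFs are not counted — both choices are
  configurable only in the sense that the scan itself is exposed
  (`find_longest_orf`).
* Redundancy removal is a deterministic fixpoint: while any cross-dataset
  pair shares more than 100 exonic nt, the member with the smaller
  *spliced length* is removed (span length is the other defensible
  reading; spliced length matches the sequence-comparison origin of the
  rule), with length ties removed by lexicographically later id. Because
  removal never creates overlap, the conflict list is computed once.
* Category precedence in classification is containing > exonic >
  intronic > intergenic; a transcript satisfying several definitions gets
  the first. "Convergent" and "divergent" mean same-strand and
  opposite-strand relative to the nearest gene — the usage of the
  reference study, which differs from the head-to-head/tail-to-tail
  meaning elsewhere in the literature. A lncRNA overlapping a gene's span
  without touching its exons is classified intronic even if it straddles
  the span boundary, keeping "distance 0 ⇒ genic" exact.
* Mean-scaling normalization multiplies each tissue column by
  (mean of column means)/(column mean), leaving all-zero columns
  unscaled with a warning. Entropy uses log₂ with tissue-share
  normalization and 0·log 0 ≡ 0.
* Clustering is average-linkage agglomerative on 1 − Pearson r. Rather
  than trusting a single tree cut, clusters failing the mean-pairwise-r
  ≥ 0.97 contract are recursively split, so the reported clusters satisfy
  the contract by construction. Zero-variance profiles are excluded
  (correlation undefined) with a logged count; entropy retention keeps
  `ceiling(0.20·size)` members so small clusters keep at least one.

## What the synthetic generator emulates — and what it does not

`synth_generate()` builds a toy genome organized in wide loci ("slots"),
one per coding gene, spaced so that features of different slots are always
more than 15 kb apart; lncRNAs are placed inside their host slot to
realize a requested genomic-context class exactly, and distal lncRNAs and
small RNAs live on a gene-free chromosome. Defaults mirror the reference
study's conditions: 4 datasets (one stranded), 13 tissues, 200 coding
genes (~1.64 kb mRNAs, ~4.8 exons), 100 small RNAs (< 200 nt), 300
lncRNAs (~0.82 kb, predominantly single-exon) spread over all nine
classes, and negative-binomial read counts.

Planted records pass or fail each filter with margin: coding transcripts
carry ORFs of at least 110 aa and ~80% CDS content, protein hits at
E ≤ 10⁻¹⁰ and scores ≥ 0.5; lncRNAs are ≥ 450 nt with scores ≤ −1.3 and,
for a planted decoy subset, only weak hits at E ≥ 10⁻³. The lncRNA ORF
constraint is planted by rejection sampling to ≤ 80 aa and ≤ 33% coverage
— just inside the stringent keep conditions — because a multiplicative
safety margin on ORF length is statistically unreachable for realistic
~800 nt random sequences (a random 800-mer almost always contains an ORF
longer than 41 aa). Expression planting uses 4 RPKM for the emphasized
patterns (the study-wide mean lncRNA abundance is ~3.5 RPKM) against a
0.05 RPKM leaky background, library sizes of 10⁷ and NB size 50; these
levels were chosen from a closed-form noise calculation so that
noise-free recovery is exact and recovery under default noise is
comfortably above 95%.

The generator does **not** emulate: read-level data (counts are drawn
directly), sequencing error, genome duplication and paralogy (a major
feature of salmonid genomes), incomplete or fragmented assemblies,
overlapping gene models, alternative isoforms, or expression correlation
structure beyond the planted co-expression blocks. Passing the planted
tests therefore demonstrates that the *decision logic* is correct under
its stated assumptions, not that those assumptions hold in any particular
real dataset — on real assemblies the filters inherit all the noise of
the upstream aligner, assembler and score calculator.

## Problem sizes

The shipped validation runs the full pipeline on the default fixture
(600 planted transcripts, seed 42), on 20 small random fixtures for
regime-dominance checks, and compares the classifier and ORF finder
against brute-force oracles on over 1,000 random instances each; the
expression recall experiments use 200 transcripts per pattern. These
sizes keep the whole suite in a few minutes while exercising every
decision path; all of them scale with configuration if heavier validation
is wanted.

## Known limitations

* Strand rescue trusts the stranded dataset unconditionally; conflicting
  counterparts leave the strand unknown rather than voting.
* The consensus criterion is coordinate overlap with optional identity
  confirmation; it cannot merge transcripts assembled against different
  genome builds.
* The classifier reports a single nearest gene; equidistant genes resolve
  deterministically (lexicographically smallest id) rather than reporting
  both.
* MeV-style clustering and the CPC score itself are not reimplemented:
  the score is an input table, and the clustering is a documented
  approximation (average linkage + recursive threshold enforcement) of a
  tool whose exact algorithm is unspecified.
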