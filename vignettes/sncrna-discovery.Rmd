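---
title: "Discovering hairpin-borne small noncoding RNAs from small RNA-seq"
author: "sprfinder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering hairpin-borne small noncoding RNAs from small RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprfinder)
```

## The problem

Deep-sequenced small-RNA libraries from transcriptionally inert cells
such as mature spermatozoa are dominated by degradation fragments of
long RNAs (rRNA, tRNA, mRNA) mixed with genuine small RNAs (miRNAs,
piRNAs).  Hidden in that mixture can be novel small noncoding RNAs
(sncRNAs): 20–23 nt species that match no known miRNA or piRNA, map to
a single genomic locus — often inside a piRNA cluster — and whose
proximal genomic context folds into a hairpin with the read forming one
strand of the stem, suggesting biogenesis by cleavage from a
stem-loop-structured precursor rather than from long double-stranded
RNA.  `sprfinder` implements that discovery procedure as a tested,
reusable pipeline, together with the quantification used to
characterize such candidates: reads-per-million (RPM) normalization,
cross-library enrichment ratios, 3′ non-templated variant calling, and
in-silico sizing of poly(A)-tailed RT-PCR products.

## The procedure

1. **Classification.** Every distinct read is matched, by *exact
   substring identity in sense orientation*, against per-class
   reference sets (miRNA mature+star, rRNA, tRNA, snoRNA, snRNA, piRNA,
   mRNA).  Substring rather than end-to-end matching is essential:
   degradation fragments of long RNAs must classify to their parent
   class.  tRNA references carry the post-transcriptionally added 3′
   CCA.  A read matching several sets receives the first class in the
   priority order miRNA > rRNA > tRNA > snoRNA > snRNA > piRNA > mRNA.
   The priority is our convention (configurable): the literature
   describes the databases used but not a tie-break, and this order
   puts the two classes used as discovery exclusions first.  Reads
   matching no reference are aligned exactly to both genome strands and
   become `repeat_associated` (a hit overlaps a repeat annotation),
   `genomic_unannotated`, or `unmapped`.
2. **Candidate selection.** Reads of 20–23 nt that are neither miRNA
   nor rRNA are kept; reads mapping to two or more genomic loci are
   screened out (a locus is a distinct (chrom, start, strand) triple).
3. **Window folding.** For each unique locus the ±140 nt window
   (~300 nt total, matching the window size used for this analysis in
   practice) is extracted in sense orientation and folded.
4. **Stem containment.** The structure is decomposed into hairpins and
   a candidate is kept when the read lies *fully inside one arm* of a
   hairpin stem with at least 60% of its bases paired in that stem.
5. **Reporting.** One row per candidate: sequence (RNA alphabet),
   size, read count, 1-based location, piRNA-cluster membership
   (strand-agnostic overlap, since clusters host divergently oriented
   RNAs), stem-loop flag, and paired fraction.

## Folding by base-pair maximization

The stem criterion needs hairpin *topology*, not free energies, so the
built-in folder maximizes the number of nested base pairs (Nussinov
dynamic programming) over Watson–Crick plus G:U wobble pairs with a
minimum hairpin loop of 3 nt (the steric minimum; both parameters are
configurable and unstated in the original manual procedure).  A
thermodynamic structure computed externally (e.g. by RNAfold) can be
injected through `read_dotbracket()` + `rna_structure()` and fed to the
same decomposition, so the criterion itself is folder-agnostic.

Maximal-pairing structures are massively degenerate.  The traceback is
made deterministic by preferring, on every interval, to pair the 5′
base with its **most distant** admissible partner, and to pair rather
than bifurcate.  Preferring the distant partner keeps long stems intact
when an equal-count local alternative exists; the opposite convention
(nearest partner) shreds designed and biological hairpins into chains
of micro-hairpins and makes the stem criterion useless in practice.
Correctness of the pair *count* is checked against an exhaustive
enumerator (`enumerate_structures_bruteforce()`, no memoization,
n ≤ 16) on hundreds of random sequences.

Hairpin decomposition starts at each hairpin loop and extends the stem
outward through nested pairs, tolerating unpaired interruptions of up
to 6 nt per side (`max_internal_loop`); extension stops at a
bifurcation.  The containment thresholds — full containment in one arm,
`min_paired_frac = 0.6` — quantify the originally manual "one strand of
the stem" judgment; they are declared conventions, not inferred intent,
and are logged with every run.  `longest_helix()` measures the longest
perfectly stacked run, the quantity one inspects to exclude a long
dsRNA precursor (a configurable flag of ≥ 20 stacked pairs is the
suggested operationalization of a "long stretch" of dsRNA).

## What the synthetic data emulate

`sim_config()` defaults define the reference study conditions used by
the acceptance tests:

* a 100 kb single-chromosome genome containing a 40 kb piRNA cluster
  (the span reported for the cluster hosting the two published sperm
  sncRNAs), 30 cluster piRNAs (24–31 nt, 5′ U, mixed orientations), and
  long-RNA genes (2 rRNA, 5 mRNA, 4 tRNA, 5 miRNA hairpins, one
  two-copy repeat) outside it;
* **two planted 20–23 nt sncRNAs** inside the cluster, divergently
  oriented, each embedded in a designed hairpin: 8 nt of 5′ stem
  extension, the read, 4 nt of templated 3′ context (`TTTG`, the
  source of templated 3′ extensions), a 6 nt loop chosen so no legal
  pair can form inside it, and a complementary arm in which three
  read-facing positions are switched to G:U wobble partners.  The
  wobbles keep the designed stem at full pairing strength — so
  base-pair maximization preserves it — while making the arm differ
  from the exact reverse complement, which keeps the read's genomic
  locus unique.  The stem extensions place the read strictly interior
  to the arm, as in a pre-miRNA, so that end-fraying of the outermost
  stem pairs never clips the read interval;
* a **multi-copy decoy** (identical 21-mer at two loci) that must be
  removed by the unique-locus screen, and a **shuffled-context
  control** (same cassette geometry but with the arm shuffled) that
  must not be called a stem-loop.  Chance stem containment of a
  shuffled control is rare but not impossible under pure pair
  maximization (about 2–3% of seeds in our sweeps), which is itself a
  useful calibration of the criterion's false-positive behaviour;
* a degraded long-RNA **background** drawn from the mature long RNAs
  (tRNAs with CCA) as a finite pool of 20,000 distinct fragment
  species with log-uniform abundances and lengths of 13–248 nt
  decaying exponentially (mean excess 60 nt).  Deep small-RNA
  libraries are strongly duplicated, so a finite species pool is the
  realistic regime and also what makes exact-match classification of a
  million-read library tractable;
* Table-2-style **3′ tailing** of the planted sncRNAs: the suffix
  distribution over {"", A, TT, T, AA, TA, G, AAA, C} follows the
  observed A-rich proportions, mixing templated (T, TT) and
  non-templated (A, G, C…) extensions;
* **sperm/testis enrichment**: each planted sncRNA is emitted at
  60 RPM in the non-enriched library and 150× that in the enriched
  one, at 10^6 reads per library.  Sixty RPM puts tens of reads in the
  denominator library at this depth, the regime in which a ratio
  estimator is informative rather than dominated by Poisson noise.

Everything is deterministic given the seed: the genome, the species
universe shared by both libraries, and each library's multinomial draw
use separate derived seeds, so two libraries differ only in their
composition targets and sampling noise.

What the generator does **not** model: sequencing errors, quality
values, adapter contamination, 5′ heterogeneity, RNA modifications, or
a literature-faithful length profile (any smooth 13–248 nt distribution
is acceptable).  Passing the recovery tests therefore demonstrates the
pipeline's logic — classification hierarchy, screening, folding,
containment, normalization — not robustness to platform noise, and
candidate counts on real libraries are not expected to match the
published tallies, which depended on manual structure inspection of
raw archive data.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally (BED convention);
  reports print 1-based inclusive locations.  The internal alphabet is
  DNA (U→T on input); mature-sncRNA report columns print RNA.
* Reads containing N are dropped with a logged count (ambiguous bases
  cannot participate in exact matching); N in the genome never pairs
  and never matches.
* Windows are clipped at chromosome ends; minus-strand windows are
  reverse-complemented so the read is in sense orientation.
* Enrichment ratios are reported at 2 significant figures (this
  reproduces both published example values); a zero denominator is
  flagged `inf`, 0/0 `undefined`.  RPM uses the total read count of
  the library as denominator — the published footnote does not
  distinguish mapped from total reads — and distinct-sequence counts
  (variant families are not collapsed).
* Variant calling requires reads to share the canonical 5′ start;
  reads mismatching the context at position 1 are rejected, and the
  templated prefix is maximal by construction (asserted).
* The empty read set, empty annotation, and zero-pair structures all
  return empty-but-well-typed results rather than errors.

## Problem sizes used by the test suite

Unit tests run on a 20 kb genome with 50,000-read libraries and a
1,500-species background pool.  The acceptance properties use the full
reference conditions above (100 kb, 10^6 reads per library, ten seeds
1–10) and complete in a few minutes on one CPU; the folding oracle
compares the dynamic program against exhaustive enumeration on 200
random sequences of 8–14 nt.

## Known limitations

* Base-pair maximization is a topological proxy; it overpairs relative
  to thermodynamic folding, which is why the containment criterion,
  not the raw structure, carries the decision.  Supplying RNAfold
  structures is supported where fidelity matters.
* Exact matching means a single sequencing error reclassifies a read;
  the published pipeline had the same property (complete matches
  only).
* The unique-locus screen counts exact occurrences; near-duplicates
  (one mismatch apart) are distinct loci.
* Multi-chromosome genomes are supported throughout, but the simulator
  plants all features on a single chromosome.
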