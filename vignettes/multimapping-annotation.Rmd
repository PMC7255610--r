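---
title: "Multi-mapping aware annotation of small RNA classes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-mapping aware annotation of small RNA classes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaAnnot)
```

## The problem

Small RNA-seq libraries mix many RNA classes — miRNAs, snoRNAs, snRNAs,
tRNA fragments, piRNAs, siRNAs — and a routine analysis step is to quantify
how many reads each class received. The obstacle is multi-mapping: small
RNAs are short, and many of them sit in duplicated genes or repeated
regions, so a sizeable fraction of reads aligns equally well at several
genomic loci. The common workarounds are all biased in a known direction:

* **unique** — discard multi-mappers entirely; duplicated classes are
  under-counted (and classes that happen to be single-copy are
  over-represented in the percentages);
* **random** — keep one arbitrary hit per read; individual reads are
  frequently misplaced, and a read whose drawn hit is intergenic is lost;
* **ratio** — give each of the $n$ hits weight $1/n$; the true class is
  under-counted and every co-mapping class over-counted, and weight falling
  on intergenic hits is lost.

The method implemented here takes the opposite view: **compare every hit of
the read with the annotation before deciding anything**. Three outcomes are
possible.

1. All informative hits agree on a single annotation class. The read is
   counted for that class. If the read had several hits (a duplicated miRNA
   family is the typical case) it is flagged **rescued**; hits falling in
   unannotated (intergenic) regions do not veto the rescue, they are simply
   ignored as uninformative.
2. Equally ranked classes disagree, either because two annotations overlap
   at one locus or because different hits fall in different classes. No
   guess is made: a **merged annotation** — the concatenation of the
   matching class labels, e.g. `CDS (+)--miRNA` — is created on the fly and
   counted as a category of its own. Ambiguity is thereby *reported*, and
   the supporting feature pairs can be inspected afterwards.
3. No hit touches any selected annotation: the read is **unannotated**.

Because every read contributes exactly one unit of weight (to a class, a
merged class, or the unannotated bucket), totals are conserved, and the
*number* of annotated reads does not depend on the priority ordering — only
the labels do.

## Annotation classes, priorities and orientation

Which classes are quantified, and how conflicts between them are resolved,
is controlled by a plain-text configuration with three sections:

```
Introns:
gene

Vicinity:
gene

Order:
miRNA .:CDS + 5'UTR 3'UTR +
gene -
intron
upstream
downstream
```

`Order` lists class selectors by decreasing priority, one *tier* per line;
selectors sharing a line share a tier. A selector is `source:feature`
(matching GTF columns 2 and 3, `.` = any source) or a bare feature word. A
trailing `+` restricts the class to collinear reads, `-` to antisense reads
(so `gene -` above quantifies antisense transcription over genes). When a
hit overlaps several candidate classes, only the minimal (highest-priority)
tier survives; a tie within that tier is what makes a hit ambiguous. The
same minimal-tier rule is applied a second time when the hits of one read
are pooled.

The words `intron`, `upstream`, `downstream`, `5'UTR`, `3'UTR` are
reserved: they name features that standard annotation files do not contain
and that are derived in memory (the input file is never modified):

* gene models are reconstructed from `exon` records grouped by `gene_id`
  (merged exons; per-gene, not per-transcript — transcript-level intron
  structure is deliberately out of scope);
* **introns** are the gaps between consecutive merged exons;
* **5'/3' UTRs** are the exonic bases strand-upstream/downstream of the CDS
  extremes, inferred only for genes that have CDS records;
* **upstream/downstream** regions of configurable width abut each selected
  feature, strand-aware, clipped at position 1 and at the chromosome end
  when the alignment header provides sequence lengths.

`Introns` and `Vicinity` list the classes for which these derivations run;
the derived features only enter the quantification when their reserved word
also appears in `Order`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| vicinity size | 3000 nt | width of upstream/downstream regions (± 3 kb, the setting used for proximal regions of coding genes in typical analyses) |
| overlap threshold | `1nt` | minimal hit–annotation overlap; also accepts `"P%"` of the read length. Equality passes; below threshold the candidate is ignored |
| bin width | 16384 nt | interval-index bin size; a compromise between short sRNA hits and multi-kilobase vicinity features |
| strategy | `default` | `default`, `unique`, `random`, `ratio` (the biased strategies are provided for comparison) |
| seed | 0 | base seed; file *i* uses stream `seed + i`, so output is identical for any thread count |

A percentage threshold uses `ceiling(p × read length)` and the comparison
is `>=`: a read exactly at the threshold is kept, because only overlaps
strictly lower than the threshold are rejected.

## Input contracts

Alignments are single-end SAM or BAM. Multi-mapping may be encoded either
as one record per hit (records of one read consecutive, NH tag giving the
hit count) or as a BWA-style `XA` tag
(`chr,(+|-)pos,CIGAR,NM;` repeated) on the primary record, whose sign gives
the alternative hit's strand. Hit spans are computed from POS plus the
reference-consuming CIGAR operations (`M/D/N/=/X`). Unmapped and
supplementary records are skipped; secondary records count as hits. If an
NH tag disagrees with the hits actually present (a mapper that caps its
reporting, for instance), the observed hits are trusted and one summary
warning is emitted — only observable hits can be annotated. Mappers such as
bowtie that write one record per hit but no NH tag are handled by the
companion tool `setNhTags()`, which is idempotent and leaves every other
byte of the file unchanged.

Coordinates are 1-based inclusive throughout (GTF native, SAM POS native),
and all interval arithmetic uses closed intervals; this removes every
conversion at the two input boundaries.

## The interval index

Annotation features are registered into fixed-width bins per chromosome
(`[kw+1, (k+1)w]` in 1-based coordinates, membership by integer division of
the clipped endpoints); a query touches only the bins its interval spans,
so lookup cost follows local bin occupancy, not total feature count. The
index does not filter strand — orientation is a class-level rule applied
during hit annotation, after the overlap threshold. Query results are
deduplicated and returned in feature order, making every downstream step
deterministic. The test suite checks the index against an independent
all-pairs overlap scan (`GenomicRanges::findOverlaps`) on random instances.

## Counting and outputs

Three tab-separated outputs are produced: the class-level count table
(merged labels included; one column per input file, absent labels filled
with 0), the feature-level table keyed by canonical feature-id combinations
(sorted, `;`-joined — `mirD1;mirD2` records a rescue across two copies of a
duplicated miRNA, `g1;mirE` a same-locus ambiguity), and the per-read table
(`read_id`, `status`, `label`, supporting features). Under the `ratio`
strategy weights are printed with six decimals; all other strategies count
integers. Accumulation is associative and order-independent, which is what
permits one thread per input file with byte-identical results.

Two reporting choices are worth stating explicitly. First, the per-read
annotation table always reports the method's full resolution
(`unique`/`rescued`/`ambiguous`/`unannotated`); the strategy choice changes
the count tables only. Second, the per-file annotation rate is computed
over the reads present in the alignment file — reads that never mapped and
were dropped upstream are not visible to this tool, so a figure-level
"fraction of sequenced reads" must divide by the sequencer's read count
instead.

## Degenerate inputs and tie-breaks

* A read hitting the same feature twice (tandem duplication inside one
  feature) is deduplicated on (class, feature id) and counted once.
* A multi-hit read whose pooled matches reduce to one class via tier
  minimization (hit 1 → miRNA on tier 1, hit 2 → intron on tier 3) is
  labeled with that class and counted as rescued: the final class is
  unique even though the mapping was not.
* A single-hit read whose one hit is ambiguous gets a merged label and
  status `ambiguous`, regardless of its hit count.
* Merged labels are canonicalized by sorting (the merged classes always
  share a tier, so the order is lexicographic) and joined with `--`; the
  two-character separator keeps labels machine-parseable even though class
  names themselves may contain single dashes.
* The `random` strategy draws among *all* hits, including intergenic ones
  (an intergenic draw yields `unannotated`), mirroring how that strategy
  loses reads in practice.
* Zero-width intervals can arise transiently when clipping derived features
  (an exon starting exactly at the CDS start, a gene starting at position
  1); they are dropped — closed-interval features have no zero width.

## The synthetic data generator

`simulateDataset()` emulates the one property of real sRNA data this method
is about: reads from verbatim-duplicated loci that multi-map to all copies.
It lays non-overlapping class loci (60–150 nt) along a toy chromosome with
random 300–1000 nt gaps — sequential placement makes locus collisions
impossible by construction — duplicates a configurable fraction of loci
verbatim (each read from such a locus appears at the same offset in every
copy, with a correct NH tag), and draws a configurable fraction of reads
from the inter-locus gaps. Reads map perfectly: mapping errors, mismatches,
quality filtering and expression-profile realism are deliberately not
modeled, because the method consumes alignments and is agnostic to how they
were produced. Consequently, passing tests demonstrate the *resolution
logic* (no true class is ever missed; duplicated-locus reads are rescued,
not discarded; weight is conserved; priority order only relabels), not
performance on noisy real libraries, where annotation quality dominates.

Default study conditions used by the acceptance checks: 10,000 reads, four
classes × 25 base loci, 30% of loci duplicated ×2–×3, read length 21 nt, 5%
intergenic reads, every read collinear with its locus. At this size the
full pipeline runs in well under a minute per strategy; the scoring
criterion counts a read as a true positive when at least one class named by
its (possibly merged) label is the correct one.

## Known limitations

* Single-end alignments only; paired-end input is rejected.
* GFF3 parent/child hierarchies are not resolved; gene models come from
  `exon`/`CDS` records grouped by one attribute (default `gene_id`).
* Introns are per-gene (merged exons), not per-transcript.
* No per-class overlap thresholds, no regular-expression selectors, no
  expression-informed read placement (EM-style reassignment is a different
  trade-off: it guesses, this method reports).
* Chromosome-end clipping of vicinity regions requires sequence lengths
  from an alignment header; with none available, the regions extend past
  the (unknown) end harmlessly — no read can map there.

## Worked example

```{r fig9}
fx <- fig9Fixture()
dir <- tempfile(); dir.create(dir)
writeLines(fx$gtf, file.path(dir, "annot.gtf"))
writeLines(fx$config, file.path(dir, "config.txt"))
writeLines(fx$sam, file.path(dir, "reads.sam"))

q <- annotateReads(file.path(dir, "reads.sam"), file.path(dir, "annot.gtf"),
                   file.path(dir, "config.txt"))
q
classCounts(q)
readAnnotations(q)[[1]]
featureCounts(q)
```

Read `D` (two hits on duplicated miRNA copies) is rescued; reads `E` and
`F` show the two flavours of irreducible ambiguity — overlapping
annotations at one locus, and different hits in different classes — and are
reported as merged annotations with their supporting feature pairs.
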