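---
title: "Simulating truth-annotated RNA-seq data and benchmarking pipelines with simbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating truth-annotated RNA-seq data and benchmarking pipelines with simbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simbench)
```

## The problem

Assessing an RNA-seq analysis pipeline — an aligner, a splice-junction
caller, a variant caller, a fusion detector, or any combination — requires
data whose ground truth is known at base resolution. simbench addresses
this with two coupled components: a *simulator* that injects known
biological events (SNVs, short indels, gene fusions) into a reference
genome, simulates paired-end reads from the modified reference, and lifts
every read's alignment back to the original coordinates; and an
*evaluator* that classifies any pipeline's predictions as true positives,
false positives or false negatives against the recorded truth, reporting
precision, recall and F-score per event type.

The central design idea is that the truth travels with the reads: each
read name encodes its own correct alignments and the positions of its
simulated sequencing errors, following the grammar

```
read_id:(chr,(-)pos,cigar(;)?)+:base64(err_pos?)
```

so a pipeline's output can be scored with no side-channel beyond the
dataset directory itself.

## The mutation model

SNVs and indels are injected either randomly or guided by a VCF of known
biallelic variants, or both.

* **Random SNVs** select each non-N base independently with a per-base
  probability (`snv_rate`, default 0.0014 — a polymorphism density typical
  of a normal human sample; 0.0016 is the matching somatic setting). The
  alternate base is uniform over the three non-reference bases. Counts are
  therefore binomial, not fixed: two runs at the same rate differ by
  sampling noise.
* **Random indels** select insertion anchors and deletion starts at their
  own per-base rates (`ins_rate`, `del_rate`, default 1e-4 each). Lengths
  are uniform on 1..`max_indel_len` (default 15 bases); inserted bases are
  uniform over A/C/G/T. A deletion that would run past the chromosome end,
  or would remove an N base, is rejected and resampled.
* **VCF-guided mutations** come from biallelic records only; multi-allelic
  records are skipped and counted. `vcf_ratio` (default 0.95) is the
  fraction of the final mutation set sampled from the VCF pool, the
  remainder coming from the random generators; if the VCF pool is too
  small the shortfall is filled randomly with a warning.

Overlap between mutations is forbidden. Candidates are scanned in
generation order and a mutation is dropped exactly when its footprint (the
substituted base, the deleted span, or the insertion anchor) touches a
footprint already kept. Keeping the earliest-generated candidate makes the
resolution deterministic; nothing downstream depends on the tie-break.

Applying the resolved set produces the haploid mutated genome and a
piecewise-linear coordinate map. The map is exact: every mutated-genome
position lifts to its original coordinate, positions inside inserted
sequence are flagged and mapped to the insertion anchor, and annotation
coordinates are shifted forward through the same map (an exon boundary
landing inside a deletion snaps to the first surviving base — the paperless
corner of the model, chosen so exon order is always preserved).

### Coordinate conventions

Internally everything is 1-based and inclusive, the R/Bioconductor and
GTF/VCF/SAM convention; BED output converts to 0-based half-open at the
I/O boundary only. Splice junctions are stored as the intron interval
(first to last intronic base).

## Gene fusions

A fusion joins the upstream part of one gene to the downstream part of
another. For each fusion two exons are picked uniformly (from each gene's
representative transcript — the one with the largest summed exon length;
the choice of transcript is otherwise arbitrary and fixed for
reproducibility), resampled until the parent genes differ. The fusion
contig is the contiguous genomic segment of gene A from its transcript 5'
end through the first picked exon, concatenated with the segment of gene B
from the second picked exon through the 3' end, each side
strand-normalised to transcription direction so retained introns survive.
The two picked exons become one merged exon in the fusion transcript,
which forces reads across the junction. Contig coordinates map back to the
original genome through a two-segment registry.

Fusion contigs are built from the *original* (unmutated) genome; the
consequence, reflected in the truth database, is that reads from fusion
contigs attest junctions but never mutations. Whether a fusion is
expressed at all depends on the random expression profile, exactly as for
any other transcript.

Junction classification is purely geometric, never by provenance: a
two-locus junction is non-colinear if its sides are on different
chromosomes, different strands, or in reverse transcriptional order;
colinear junctions whose skipped span exceeds `colinear_threshold`
(default 300 kb) are fusion junctions; the rest are ordinary splices. A
400 kb intron therefore lands in the fusion table even though no fusion
was injected, and a fusion between two neighbouring colinear genes lands
in the splice table — both deliberate.

## The read simulator

The built-in generator draws a transcript expression profile from a mixed
power and exponential rank law: transcripts receive distinct ranks `x =
1..T` uniformly at random and weight

```
w(x) = x^k * exp(-x/x0 - (x/x1)^2)
```

with defaults `k = -0.7`, `x0 = 15000`, `x1 = x0^2` (the normal-condition
setting; `x0 = 25000` matches the somatic one) and molecule counts
multinomial with `n_molecules = 1e6` trials. `k` is dimensionless; `x0`
and `x1` are in rank units and govern the exponential tail.

Fragments sample a source transcript proportionally to molecule count
(uniform per molecule; no length weighting — library preparation is not
modelled in detail, and the module boundary is a plug-in contract so a
more detailed generator can be substituted), a normal length (mean 250 bp,
sd 50 bp) rounded and clamped to `[read_length, transcript length]`
(clamping rather than resampling guarantees progress on short
transcripts), and a uniform start. End 1 is the first `read_length` bases
of the fragment; end 2 the reverse complement of the last. Sequencing
errors are uniform per-base substitutions (default 0.001) with the
erroneous base always differing from the original; indel sequencing
errors, quality-string realism, GC bias and positional error profiles are
out of scope, and the emitted quality string is constant.

## Truth encoding and the truth database

Each read end is projected through its exon chain into genomic blocks and
lifted to original coordinates: insertions under the read become I ops,
spanned deletions D ops, introns N ops; insertion bases at an alignment
edge are soft-clipped (a CIGAR cannot begin with I). Reads crossing a
fusion breakpoint produce one record per contig side with the other
side's bases soft-clipped, mirroring chimeric SAM conventions.

A pair gets a single name: end-1 records then end-2 records, error
offsets merged as 0-based positions over the concatenated pair (end 1
then end 2) and serialised as comma-joined decimals in standard base64
with padding stripped. Per-end attribution of records is *not* encoded;
the alignment evaluator accordingly accepts a predicted alignment that
overlaps any truth record of the pair.

The truth database keeps only read-supported events, with support counts:

* an SNV is supported when a non-chimeric record's M op covers it;
* a deletion when its D op appears; an insertion when its internal I op
  appears (a read merely ending on the anchor base cannot evidence an
  insertion);
* every N op contributes its intron as a splice junction — or as a
  colinear fusion junction when the span exceeds the threshold;
* adjacent record pairs of chimeric ends contribute junctions classified
  geometrically.

## The evaluator

Truth events are indexed in per-chromosome-strand interval trees
(GenomicRanges; entries with undefined strand are matched on both
strands). Each event type has a matching rule, all sharing the same tie
discipline: candidates come from an overlap query, the candidate with the
minimum distance is selected, and only then are event-specific checks
applied to the selected candidate — the distance, not the allele, decides
which truth entry a prediction is compared against.

| event      | candidate query                  | distance                | extra check on selected candidate | default threshold |
|------------|----------------------------------|-------------------------|-----------------------------------|-------------------|
| alignment  | first record per read, NH <= max_hits | overlap >= 1 base  | —                                 | max_hits = 1      |
| splice     | interval overlap, same strand    | \|dstart\| + \|dend\|   | —                                 | 10                |
| SNV        | position within ±threshold       | \|dpos\|                | predicted alt base equals truth   | 5                 |
| indel      | position within ±threshold       | \|dpos\|                | \|length difference\| <= threshold | 5                |
| fusion     | composite interval, same composite strand | \|dstart\| + \|dend\| on the transform | — | 20 |

Fusions are transformed into composite intervals (`chr = chr1.chr2`,
`start = pos1`, `end = length(chr1) + pos2`, `strand =
strand1.strand2`); because no orientation convention exists across
fusion callers, the side pair is first put into a canonical order
(lexicographic chromosome, then position, flipping both strands on a
swap) so either reported orientation matches.

The first prediction matching a truth entry consumes it; later duplicates
are *ignored* — excluded from both TP and FP. The alternative reading
(duplicates and multi-mapped alignments as FP) is available behind
`count_ignored_as_fp`. Unconsumed truth entries are FN, so `TP + FN =
|truth|` holds for every evaluator except alignments, whose recall
denominator is the number of simulated reads. Degenerate metric
denominators yield 0, so empty outputs rank last in the F-score-ordered
report.

VCF predictions are split per alternate allele and left-normalised
(shared anchor prefix trimmed) before comparison, so representation
differences between callers do not masquerade as errors.

## What the tests do and do not show

The test suite validates the machinery against independent oracles:
naive string-edit reconstruction for the coordinate map, base-for-base
read reconstruction from names plus the original genome, all-pairs
brute-force matchers for every evaluator, and a self-match check in which
a dataset's own truth, fed back as predictions, must score precision =
recall = F-score = 1 for all six event types.

The simulated data are synthetic in ways that matter for interpretation:
mutation placement is uniform (no hotspots or context dependence),
expression follows a smooth rank law, errors are uniform substitutions,
and the genome is haploid. Passing tests therefore demonstrate
correctness of the bookkeeping — injection, liftover, encoding, matching
— not realism of the reads; conclusions about a pipeline's behaviour on
real data need real-scale references and calibrated error models, which
this package deliberately treats as exchangeable inputs (the read
generator is a plug-in, and any simulator producing the same per-read
fields can replace it).

Problem sizes in the suite are chosen for thorough coverage at desk
scale: the reference benchmark fixture is two 100 kb chromosomes with 50
genes and 20,000 read pairs (indel rates raised to 5e-4 so that both
indel kinds are represented among expressed, read-supported truth
events), liftover oracles run exhaustively on genomes up to 10 kb, and
evaluator oracles on hundreds of randomized truth/prediction sets of up
to 500 events.

## Known limitations

* Haploid genotypes only; no phasing, no structural variants beyond short
  indels and fusions.
* Fusion contigs carry no injected mutations.
* The expression rank law is a parametric stand-in; no claim of
  equivalence with any specific external profile generator is made.
* Expression-estimate and transcript-reconstruction evaluation are out of
  scope.
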