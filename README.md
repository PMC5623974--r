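# simbench

Truth-aware RNA-seq read simulation and qualitative pipeline benchmarking
in R.

Evaluating an RNA-seq pipeline — aligner, splice-junction caller, variant
caller, fusion detector — requires data whose ground truth is known at
base resolution. `simbench` provides both halves of that workflow for
bioinformaticians and method developers:

* **Simulation**: inject single-nucleotide variants, short indels and
  gene fusions into a reference genome (randomly at configured per-base
  rates, and/or guided by a VCF of known biallelic sites), simulate
  paired-end reads from the mutated reference under a rank-law expression
  profile, and lift every read's alignment back to original reference
  coordinates. The truth travels with the reads: each read name encodes
  its correct alignments and sequencing-error positions,

  ```
  read_id:(chr,(-)pos,cigar(;)?)+:base64(err_pos?)
  ```

  and read-supported mutations, splice junctions and fusion junctions are
  written to separate truth files.

* **Benchmarking**: classify pipeline predictions (SAM alignments, BED
  junctions, VCF variant calls, TSV fusion calls) as TP/FP/FN against the
  truth using per-chromosome-strand interval trees with per-event distance
  rules — alignments match on ≥ 1 base of overlap (first record per read
  with `NH <= max_hits`); splices on `d = |Δstart| + |Δend| <= 10`; SNVs
  and indels within ±5 bases with allele/length verification; fusions on a
  composite-interval transform (`start = pos1`, `end = length(chr1) +
  pos2`) within distance 20 — and report

  ```
  precision = TP/(TP+FP),  recall = TP/(TP+FN),
  Fscore = 2 · recall · precision / (recall + precision)
  ```

  per pipeline × event type, ordered by F-score, with optional
  true-positive lists for intersection analyses.

## Worked example

```r
library(simbench)

# A toy reference: two 100 kb chromosomes, 50 multi-exon genes.
fx <- make_fixture(c(chr1 = 100000L, chr2 = 100000L), n_genes = 50, seed = 1)

ds <- simulate_dataset(fx$genome, fx$annotation,
                       snv_rate = 0.0014, ins_rate = 5e-4, del_rate = 5e-4,
                       n_fusions = 10, n_read_pairs = 20000,
                       seed = 2, outdir = "sim_normal")
ds
#> <sim_dataset> 20000 read pairs, 454 mutations, 10 fusion contig(s)
#> <truth_db> 84 mutation(s), 148 splice junction(s), 10 fusion junction(s)

head(ds$names, 2)
#> [1] "0:chr1,37293,80M1D21M;chr1,-37844,101M:"
#> [2] "1:chr2,-8206,101M;chr2,8054,101M:"
```

454 mutations were injected; 84 are covered by at least one read and
therefore enter the truth database, together with 148 read-supported
splice junctions and all 10 fusion junctions. Read 0's name records that
its first end aligns to chr1:37293 spanning a 1-base deletion
(`80M1D21M`) and its mate on the reverse strand at chr1:37844, with no
sequencing errors (empty third field).

Feeding the dataset's own truth back as a "pipeline" must score
perfectly, which doubles as an end-to-end self-check:

```r
truth <- read_truth_db("sim_normal")
truth_to_sam(truth, "self.sam")
res <- run_benchmark(list(
  truth_dir = "sim_normal",
  pipelines = list(list(name = "perfect", alignment = "self.sam",
                        splice = "sim_normal/splices.bed",
                        snv = "sim_normal/mutations.vcf",
                        fusion = "sim_normal/fusions.tsv"))))
tidy(res)
#> # A tibble: 4 × 9
#>   pipeline event     status    tp    fp    fn precision recall fscore
#>   <chr>    <chr>     <chr>  <int> <int> <int>     <dbl>  <dbl>  <dbl>
#> 1 perfect  alignment ok     20000     0     0         1      1      1
#> 2 perfect  splice    ok       148     0     0         1      1      1
#> 3 perfect  snv       ok        41     0     0         1      1      1
#> 4 perfect  fusion    ok        10     0     0         1      1      1
```

`autoplot(res)` draws the precision/recall plane; `glance(res)` gives a
one-row summary; `cmd_benchmark("config.yaml")` runs the same evaluation
from a YAML file describing several pipelines at once.

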