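# Shared simulated datasets, built once per test run and cached.

.shared <- new.env(parent = emptyenv())

# The reference benchmark fixture: two 100 kb chromosomes, 20k read pairs,
# fusions and both indel kinds represented in the expressed truth.
shared_dataset <- function() {
  if (is.null(.shared$ds)) {
    fx <- make_fixture(c(chr1 = 100000L, chr2 = 100000L), n_genes = 50,
                       seed = 101)
    .shared$fixture <- fx
    .shared$dir <- file.path(tempdir(), "simbench-shared-ds")
    .shared$ds <- simulate_dataset(
      fx$genome, fx$annotation,
      snv_rate = 0.0014, ins_rate = 5e-4, del_rate = 5e-4,
      n_fusions = 10L, read_length = 101L, n_read_pairs = 20000L,
      seed = 202, outdir = .shared$dir
    )
  }
  list(ds = .shared$ds, dir = .shared$dir, fixture = .shared$fixture)
}

# Small error-free dataset used for base-level truth re-derivation.
clean_dataset <- function() {
  if (is.null(.shared$clean)) {
    fx <- make_fixture(c(chrA = 60000L, chrB = 40000L), n_genes = 30,
                       seed = 303)
    .shared$clean_fixture <- fx
    .shared$clean <- simulate_dataset(
      fx$genome, fx$annotation,
      snv_rate = 0.002, ins_rate = 5e-4, del_rate = 5e-4,
      n_fusions = 5L, read_length = 75L, n_read_pairs = 8000L,
      error_rate = 0, seed = 404
    )
  }
  list(ds = .shared$clean, fixture = .shared$clean_fixture)
}

# A toy two-gene reference for hand-checked fusion and projection cases.
toy_two_gene <- function() {
  genome <- c(chrT1 = "ACGTACGTGGTTTTTTTTTTCCCCCCCCCCAAAAAAAAAACGCGCGCGCGTATATATATA",
              chrT2 = "TTTTAAAACCCCGGGGACGTACGTACGTACGTTGCATGCATGCATGCATGCAAATTTGGG")
  annotation <- tibble::tibble(
    gene_id = c("gA", "gA", "gB", "gB"),
    transcript_id = c("gA_t1", "gA_t1", "gB_t1", "gB_t1"),
    chrom = c("chrT1", "chrT1", "chrT2", "chrT2"),
    strand = "+",
    start = c(1L, 21L, 1L, 21L),
    end = c(10L, 30L, 10L, 30L)
  )
  list(genome = genome, annotation = annotation)
}

# n dummy SNV mutations with distinct positions (for mixing/ratio tests).
mutation_tbl <- function(n, source = "random") {
  tibble::tibble(kind = rep("SNV", n), chrom = rep("c1", n),
                 pos = seq_len(n) * 10L, ref = rep("A", n),
                 alt = rep("G", n), source = rep(source, n))
}

# Representative transcript of a gene: largest summed exon length, ties by id.
longest_tx <- function(ex) {
  len <- tapply(ex$end - ex$start + 1, ex$transcript_id, sum)
  names(len)[order(-len, names(len))][1]
}

# Internal CIGAR span helpers (reference / read bases consumed).
cigar_ref_span_ <- function(x) simbench:::cigar_ref_span(x)
cigar_read_span_ <- function(x) simbench:::cigar_read_span(x)
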