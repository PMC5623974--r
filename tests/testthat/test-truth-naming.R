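# Read-name codec, alignment liftover CIGARs and the truth database.

random_encoded_name <- function(read_id) {
  n_rec <- sample(1:3, 1)
  aln <- tibble::tibble(
    chrom = sample(c("chr1", "chr2", "fusion_9"), n_rec, TRUE),
    pos = sample.int(1e8, n_rec),
    strand = sample(c("+", "-"), n_rec, TRUE),
    cigar = replicate(n_rec, paste0(
      paste0(sample.int(200, sample(1:4, 1)),
             sample(c("M", "I", "D", "N", "S"), sample(1:4, 1), TRUE),
             collapse = "")))
  )
  err <- if (stats::runif(1) < 0.5) integer(0) else
    sort(sample.int(202, sample(1:6, 1)) - 1L)
  list(read_id = read_id, alignments = aln, err_pos = err)
}

test_that("read names follow the grammar and decode exactly", {
  aln <- tibble::tibble(chrom = "chr1", pos = 100L, strand = "+",
                        cigar = "101M")
  expect_identical(encode_read_name(7L, aln), "7:chr1,100,101M:")

  rev <- tibble::tibble(chrom = "chr2", pos = 500L, strand = "-",
                        cigar = "50M2D51M")
  nm <- encode_read_name(3L, rev, c(0L, 120L))
  expect_match(nm, "^3:chr2,-500,50M2D51M:[A-Za-z0-9+/]+$")
  dec <- decode_read_name(nm)
  expect_identical(dec$read_id, 3L)
  expect_identical(dec$alignments$strand, "-")
  expect_identical(dec$alignments$pos, 500L)
  expect_identical(dec$err_pos, c(0L, 120L))

  expect_error(decode_read_name("no-colons-here"), "Malformed")
  expect_error(decode_read_name("1:chr1,abc,10M:"), "Malformed")
  expect_error(decode_read_name("x:chr1,5,10M:"), "Malformed")
})

test_that("decode is the exact inverse of encode over randomized names", {
  set.seed(41)
  for (i in 1:500) {
    x <- random_encoded_name(i - 1L)
    nm <- encode_read_name(x$read_id, x$alignments, x$err_pos)
    dec <- decode_read_name(nm)
    expect_identical(dec$read_id, x$read_id)
    expect_identical(as.data.frame(dec$alignments), as.data.frame(x$alignments))
    expect_identical(dec$err_pos, x$err_pos)
  }
})

test_that("lifted CIGARs express deletions, insertions and introns", {
  genome <- c(c1 = random_dna(2000))

  # No mutations under the read: pure match, position unchanged.
  id_map <- apply_mutations(genome, mutation_tbl(0))$map
  pj <- tibble::tibble(read_id = 0L, end = 1L, chrom = "c1", strand = "+",
                       blocks = list(cbind(start = 301L, end = 400L)))
  rec <- lift_alignment(pj, id_map)
  expect_identical(rec$cigar, "100M")
  expect_identical(rec$pos, 301L)

  # A 2-base deletion 40 bases into a 100-base read: 40M2D60M.
  del <- tibble::tibble(kind = "DEL", chrom = "c1", pos = 341L,
                        ref = substring(genome[["c1"]], 341, 342), alt = "",
                        source = "random")
  del_map <- apply_mutations(genome, del)$map
  rec2 <- lift_alignment(pj, del_map)
  expect_identical(rec2$cigar, "40M2D60M")
  expect_identical(rec2$pos, 301L)

  # A 3-base insertion after position 340: 40M3I57M, and downstream blocks
  # shift back by 3 when lifted.
  ins <- tibble::tibble(kind = "INS", chrom = "c1", pos = 340L, ref = "",
                        alt = "TTT", source = "random")
  ins_map <- apply_mutations(genome, ins)$map
  rec3 <- lift_alignment(pj, ins_map)
  expect_identical(rec3$cigar, "40M3I57M")
  expect_identical(rec3$pos, 301L)

  # Two blocks on the mutated genome separated by an intron: N op with the
  # original-coordinate gap.
  pj2 <- tibble::tibble(read_id = 0L, end = 1L, chrom = "c1", strand = "+",
                        blocks = list(cbind(start = c(101L, 501L),
                                            end = c(150L, 550L))))
  rec4 <- lift_alignment(pj2, id_map)
  expect_identical(rec4$cigar, "50M350N50M")
})

test_that("fusion-contig reads split at the breakpoint into clipped records", {
  toy <- toy_two_gene()
  ann <- toy$annotation[c(1, 3), ]  # single-exon genes
  set.seed(42)
  fus <- generate_fusions(toy$genome, ann, 1)
  ev <- fus$events

  # A 12-base read crossing the 10/10 contig at offset 7: 7 bases on side
  # A, 5 on side B.
  pj <- tibble::tibble(read_id = 0L, end = 1L, chrom = ev$contig,
                       strand = "+", blocks = list(cbind(start = 4L, end = 15L)))
  id_map <- apply_mutations(toy$genome, mutation_tbl(0))$map
  recs <- lift_alignment(pj, id_map, fus$registry)
  expect_identical(nrow(recs), 2L)
  expect_identical(recs$cigar, c("7M5S", "7S5M"))
  reg <- fus$registry
  expect_identical(recs$chrom, reg$chrom)
  expect_identical(recs$pos[1], reg$start[1] + 3L)
  expect_identical(recs$pos[2], reg$start[2])

  # Hand-check the spec-scale case: breakpoint at offset 55 of a 101-base
  # read on a larger fusion.
  set.seed(43)
  fx <- make_fixture(c(c1 = 50000L, c2 = 50000L), n_genes = 10, seed = 43)
  fus2 <- generate_fusions(fx$genome, fx$annotation, 1)
  bp <- fus2$registry$contig_end[1]
  pj2 <- tibble::tibble(read_id = 0L, end = 1L, chrom = fus2$events$contig,
                        strand = "+",
                        blocks = list(cbind(start = bp - 54L, end = bp + 46L)))
  map2 <- apply_mutations(fx$genome, mutation_tbl(0))$map
  recs2 <- lift_alignment(pj2, map2, fus2$registry)
  expect_identical(nrow(recs2), 2L)
  span <- cigar_ref_span_(recs2$cigar)
  expect_identical(span, c(55L, 46L))
})

test_that("truth database counts read support and drops uncovered events", {
  mutations <- tibble::tibble(
    kind = c("SNV", "SNV", "DEL", "INS"),
    chrom = c("c1", "c1", "c1", "c1"),
    pos = c(150L, 5000L, 160L, 170L),
    ref = c("A", "C", "GG", ""),
    alt = c("G", "T", "", "TTT"),
    source = "random"
  )
  records <- tibble::tibble(
    read_id = c(0L, 1L, 2L), end = 1L, ord = 1L,
    chrom = "c1", pos = c(101L, 101L, 140L),
    strand = "+",
    cigar = c("100M", "100M", "20M2D9M3I69M"),
    tx_strand = "+"
  )
  db <- build_truth_db(records, mutations)
  expect_setequal(db$mutations$pos, c(150L, 160L, 170L))  # SNV at 5000 uncovered
  expect_identical(db$mutations$support[db$mutations$pos == 150L], 3L)
  expect_identical(db$mutations$support[db$mutations$pos == 160L], 1L)
  expect_identical(db$mutations$support[db$mutations$pos == 170L], 1L)

  # Three reads over the same junction: one entry, support 3.
  jrec <- tibble::tibble(
    read_id = 0:2, end = 1L, ord = 1L, chrom = "c1",
    pos = c(90L, 95L, 100L), strand = "+",
    cigar = c("11M200N89M", "6M200N94M", "1M200N99M"),
    tx_strand = "+"
  )
  db2 <- build_truth_db(jrec, mutations[0, ])
  expect_identical(nrow(db2$splices), 1L)
  expect_identical(db2$splices$support, 3L)
  expect_identical(db2$splices$start, 101L)
  expect_identical(db2$splices$end, 300L)

  # A colinear gap beyond the threshold lands in the fusion table even
  # though it came from an N op (geometry, not provenance).
  long <- tibble::tibble(
    read_id = 0L, end = 1L, ord = 1L, chrom = "c1", pos = 100L,
    strand = "+", cigar = "50M400000N50M", tx_strand = "+"
  )
  db3 <- build_truth_db(long, mutations[0, ])
  expect_identical(nrow(db3$splices), 0L)
  expect_identical(db3$fusions$class, "COLINEAR_FUSION")
  expect_identical(db3$fusions$pos1, 149L)
  expect_identical(db3$fusions$pos2, 400150L)

  # Same geometry on the minus strand: donor/acceptor swap.
  long_m <- long
  long_m$tx_strand <- "-"
  db4 <- build_truth_db(long_m, mutations[0, ])
  expect_identical(db4$fusions$pos1, 400150L)
  expect_identical(db4$fusions$pos2, 149L)
})

test_that("dataset outputs are consistent, parseable and dense in read ids", {
  sh <- shared_dataset()
  ds <- sh$ds
  dir <- sh$dir

  fq1 <- readLines(file.path(dir, "reads_1.fastq"))
  fq2 <- readLines(file.path(dir, "reads_2.fastq"))
  expect_identical(length(fq1), 4L * 20000L)
  expect_identical(length(fq2), 4L * 20000L)
  names1 <- sub("^@", "", fq1[seq(1, length(fq1), 4)])
  names2 <- sub("^@", "", fq2[seq(1, length(fq2), 4)])
  expect_identical(names1, names2)

  decoded <- lapply(names1[1:2000], decode_read_name)
  expect_identical(vapply(decoded, `[[`, integer(1), "read_id"), 0:1999)

  all_ids <- as.integer(sub(":.*$", "", names1))
  expect_identical(sort(all_ids), 0:19999)

  # Truth files parse back to the in-memory truth database.
  back <- read_truth_db(dir)
  expect_equal(as.data.frame(back$mutations), as.data.frame(ds$truth$mutations))
  expect_equal(back$splices$start, ds$truth$splices$start)
  expect_equal(as.data.frame(back$fusions), as.data.frame(ds$truth$fusions))
  expect_identical(back$n_read_pairs, 20000L)

  # Every lifted record consumes exactly read_length read bases (chimeric
  # records carry the other side's bases as soft clips).
  spans <- cigar_read_span_(ds$records$cigar)
  expect_true(all(spans == 101L))
  # For chimeric (multi-record) ends the non-clipped bases of the two
  # records partition the read.
  ops <- simbench:::parse_cigar(ds$records$cigar)
  keep <- ops$op %in% c("M", "I")
  body <- tapply(ops$len[keep], ops$rec[keep], sum)
  rec_ids <- as.integer(names(body))
  end_key <- paste(ds$records$read_id[rec_ids], ds$records$end[rec_ids])
  per_end <- tapply(as.integer(body), end_key, sum)
  n_rec <- tapply(rec_ids, end_key, length)
  expect_gt(sum(n_rec > 1), 0)
  expect_true(all(per_end[n_rec > 1] == 101L))
})

test_that("an empty simulation still writes valid, empty outputs", {
  fx <- make_fixture(c(c1 = 20000L), n_genes = 5, seed = 44)
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(fx$genome, fx$annotation, snv_rate = 0,
                         ins_rate = 0, del_rate = 0, n_read_pairs = 0,
                         seed = 45, outdir = dir)
  expect_identical(nrow(ds$reads), 0L)
  expect_identical(length(readLines(file.path(dir, "reads_1.fastq"))), 0L)
  expect_identical(nrow(read_truth_db(dir)$mutations), 0L)
})
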