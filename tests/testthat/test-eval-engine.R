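# Interval-tree queries, per-event matching rules and metrics.

test_that("interval tree queries agree with a linear scan", {
  empty <- gi_tree(tibble::tibble(chrom = character(), start = integer(),
                                  end = integer(), strand = character()))
  expect_identical(query_gi_tree(empty, "c1", 1, 100)[[1]], integer(0))

  set.seed(51)
  truth <- tibble::tibble(
    chrom = sample(c("c1", "c2"), 1000, TRUE),
    start = sample.int(100000, 1000, TRUE),
    strand = sample(c("+", "-", "*"), 1000, TRUE, prob = c(.45, .45, .1))
  )
  truth$end <- truth$start + sample(0:500, 1000, TRUE)
  tree <- gi_tree(truth)

  # A query identical to a stored interval returns it.
  hit <- query_gi_tree(tree, truth$chrom[1], truth$start[1], truth$end[1],
                       truth$strand[1])[[1]]
  expect_true(1L %in% hit)

  q <- tibble::tibble(
    chrom = sample(c("c1", "c2"), 1000, TRUE),
    start = sample.int(100000, 1000, TRUE),
    strand = sample(c("+", "-", "*"), 1000, TRUE)
  )
  q$end <- q$start + sample(0:500, 1000, TRUE)
  got <- query_gi_tree(tree, q$chrom, q$start, q$end, q$strand)
  for (i in seq_len(200)) {   # spot-check against the O(n) scan
    want <- which(truth$chrom == q$chrom[i] &
                    truth$start <= q$end[i] & truth$end >= q$start[i] &
                    (truth$strand == "*" | q$strand[i] == "*" |
                       truth$strand == q$strand[i]))
    expect_identical(got[[i]], want)
  }
})

test_that("splice matching honours the distance threshold and tie rules", {
  truth <- tibble::tibble(chrom = "c1", start = 1000L, end = 2000L,
                          strand = "+")
  pred_at <- function(d) tibble::tibble(chrom = "c1", start = 1000L + d,
                                        end = 2000L, strand = "+")
  expect_identical(evaluate_splices(pred_at(10L), truth)$tp, 1L)
  r11 <- evaluate_splices(pred_at(11L), truth)
  expect_identical(r11$tp, 0L)
  expect_identical(r11$fp, 1L)
  expect_identical(r11$fn, 1L)

  # Two candidates: the nearer one (d = 4) is consumed.
  truth2 <- tibble::tibble(chrom = "c1", start = c(1004L, 1007L),
                           end = c(2000L, 2000L), strand = "+")
  res <- evaluate_splices(tibble::tibble(chrom = "c1", start = 1000L,
                                         end = 2000L, strand = "+"), truth2)
  expect_identical(res$tp, 1L)
  expect_identical(res$tp_ids, "c1:1004-2000(+)")

  # Duplicate predictions of one candidate: TP counted once, rest ignored.
  dup <- dplyr::bind_rows(pred_at(0L), pred_at(1L), pred_at(2L))
  res2 <- evaluate_splices(dup, truth)
  expect_identical(res2$tp, 1L)
  expect_identical(res2$fp, 0L)
  expect_identical(res2$ignored, 2L)
  res3 <- evaluate_splices(dup, truth, count_ignored_as_fp = TRUE)
  expect_identical(res3$fp, 2L)

  # Strand-aware: an opposite-strand prediction cannot match.
  minus <- pred_at(0L)
  minus$strand <- "-"
  expect_identical(evaluate_splices(minus, truth)$tp, 0L)
  # Undefined strand matches either.
  undef <- pred_at(0L)
  undef$strand <- "."
  expect_identical(evaluate_splices(undef, truth)$tp, 1L)
})

test_that("mutation matching verifies the allele on the nearest candidate", {
  truth <- tibble::tibble(kind = "SNV", chrom = "c1", pos = 500L, ref = "A",
                          alt = "G", source = "random")
  pred <- function(offset, alt) tibble::tibble(chrom = "c1",
                                               pos = 500L + offset,
                                               ref = "A", alt = alt,
                                               kind = "SNV")
  expect_identical(evaluate_mutations(pred(5L, "G"), truth, "SNV")$tp, 1L)
  expect_identical(evaluate_mutations(pred(6L, "G"), truth, "SNV")$tp, 0L)
  wrong <- evaluate_mutations(pred(0L, "T"), truth, "SNV")
  expect_identical(wrong$tp, 0L)
  expect_identical(wrong$fp, 1L)

  # Indels compare lengths within the threshold.
  tins <- tibble::tibble(kind = "INS", chrom = "c1", pos = 800L, ref = "",
                         alt = "ACGTACGTAC", source = "random")   # length 10
  pins <- function(len) tibble::tibble(chrom = "c1", pos = 800L, ref = "",
                                       alt = strrep("A", len), kind = "INS")
  expect_identical(evaluate_mutations(pins(15L), tins, "INS")$tp, 1L)
  expect_identical(evaluate_mutations(pins(16L), tins, "INS")$fp, 1L)
  expect_identical(evaluate_mutations(pins(5L), tins, "INS")$tp, 1L)
  expect_identical(evaluate_mutations(pins(4L), tins, "INS")$fp, 1L)
})

test_that("fusion matching uses the composite interval transform", {
  lens <- c(c1 = 100000L, c2 = 100000L)
  truth <- tibble::tibble(chrom1 = "c1", pos1 = 5000L, strand1 = "+",
                          chrom2 = "c2", pos2 = 7000L, strand2 = "-",
                          class = "NONCOLINEAR_FUSION")
  shift <- function(d1, d2, s1 = "+", s2 = "-") {
    tibble::tibble(chrom1 = "c1", pos1 = 5000L + d1, strand1 = s1,
                   chrom2 = "c2", pos2 = 7000L + d2, strand2 = s2)
  }
  expect_identical(evaluate_fusions(shift(0L, 0L), truth, lens)$tp, 1L)
  expect_identical(evaluate_fusions(shift(12L, 8L), truth, lens)$tp, 1L)
  r <- evaluate_fusions(shift(12L, 9L), truth, lens)
  expect_identical(r$tp, 0L)
  expect_identical(r$fp, 1L)
  # Composite strand must match.
  expect_identical(evaluate_fusions(shift(0L, 0L, "+", "+"), truth, lens)$tp, 0L)
  # The reversed reported orientation is the same junction.
  rev_pred <- tibble::tibble(chrom1 = "c2", pos1 = 7000L, strand1 = "+",
                             chrom2 = "c1", pos2 = 5000L, strand2 = "-")
  expect_identical(evaluate_fusions(rev_pred, truth, lens)$tp, 1L)
  # Unknown chromosome records are skipped with a warning.
  expect_warning(
    bad <- evaluate_fusions(dplyr::bind_rows(shift(0L, 0L),
                                             shift(0L, 0L) |>
                                               dplyr::mutate(chrom1 = "cX")),
                            truth, lens),
    "unknown")
  expect_identical(bad$tp, 1L)
})

test_that("alignment evaluation takes the first eligible record per read", {
  dir <- withr::local_tempdir()
  truth_name <- function(id, chrom, pos, cigar = "100M", strand = "+") {
    encode_read_name(id, tibble::tibble(chrom = chrom, pos = pos,
                                        strand = strand, cigar = cigar))
  }
  nm0 <- truth_name(0L, "c1", 1000L)
  nm1 <- truth_name(1L, "c1", 5000L)
  nm2 <- truth_name(2L, "c2", 3000L)
  sam <- file.path(dir, "a.sam")
  writeLines(c(
    "@HD\tVN:1.6",
    paste0(nm0, "\t0\tc1\t1099\t60\t100M\t*\t0\t0\t*\t*\tNH:i:1"),  # 1-base overlap
    paste0(nm1, "\t0\tc1\t5000\t60\t100M\t*\t0\t0\t*\t*\tNH:i:5"),  # multimapped
    paste0(nm2, "\t0\tc1\t3000\t60\t100M\t*\t0\t0\t*\t*\tNH:i:1")   # wrong chrom
  ), sam)
  res <- evaluate_alignments(sam, n_reads = 3L, max_hits = 1L)
  expect_identical(res$tp, 1L)
  expect_identical(res$fp, 1L)
  expect_identical(res$fn, 1L)   # the multimapped read was never evaluated
  expect_identical(res$ignored, 1L)

  # With a looser max_hits the multimapped record is evaluated and correct.
  res5 <- evaluate_alignments(sam, n_reads = 3L, max_hits = 5L)
  expect_identical(res5$tp, 2L)
  expect_identical(res5$fn, 0L)

  # Only the first record of a read is evaluated; later ones are ignored.
  sam2 <- file.path(dir, "b.sam")
  writeLines(c(
    paste0(nm0, "\t0\tc2\t9000\t60\t100M\t*\t0\t0\t*\t*\tNH:i:1"),
    paste0(nm0, "\t0\tc1\t1000\t60\t100M\t*\t0\t0\t*\t*\tNH:i:1")
  ), sam2)
  res2 <- evaluate_alignments(sam2, n_reads = 1L)
  expect_identical(res2$tp, 0L)
  expect_identical(res2$fp, 1L)
})

test_that("metrics follow the precision/recall/F-score formulas", {
  expect_equal(compute_metrics(list(tp = 0, fp = 0, fn = 0))[
    , c("precision", "recall", "fscore")],
    tibble::tibble(precision = 0, recall = 0, fscore = 0))
  expect_equal(compute_metrics(list(tp = 10, fp = 0, fn = 0))$fscore, 1)
  m <- compute_metrics(list(tp = 90, fp = 10, fn = 110))
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.45)
  expect_equal(m$fscore, 0.6)
})

test_that("evaluators agree with the all-pairs brute-force matcher", {
  set.seed(52)
  for (iter in 1:25) {
    n_t <- sample(20:120, 1)
    n_p <- sample(20:120, 1)

    s <- random_splice_set(n_t, n_p)
    got <- evaluate_splices(s$pred, s$truth, threshold = 10)
    want <- oracle_eval_splices(s$pred, s$truth, threshold = 10)
    expect_identical(got$tp, want$tp)
    expect_identical(got$fp, want$fp)
    expect_identical(got$fn, want$fn)

    kind <- sample(c("SNV", "INS", "DEL"), 1)
    m <- random_mutation_set(n_t, n_p, kind)
    got_m <- evaluate_mutations(m$pred, m$truth, kind, threshold = 5)
    want_m <- oracle_eval_mutations(m$pred, m$truth, kind, threshold = 5)
    expect_identical(got_m$tp, want_m$tp)
    expect_identical(got_m$fn, want_m$fn)

    f <- random_fusion_set(n_t, n_p)
    got_f <- evaluate_fusions(f$pred, f$truth, f$chrom_lengths, threshold = 20)
    want_f <- oracle_eval_fusions(f$pred, f$truth, f$chrom_lengths,
                                  threshold = 20)
    expect_identical(got_f$tp, want_f$tp)
    expect_identical(got_f$fn, want_f$fn)
  }
})

test_that("benchmark runner reports per pipeline and orders by F-score", {
  # Zero pipelines: empty report, success.
  dir <- withr::local_tempdir()
  sh <- shared_dataset()
  cfg0 <- list(truth_dir = sh$dir, pipelines = list())
  expect_identical(nrow(run_benchmark(cfg0)$report), 0L)

  # A rigged prediction set with 90 matching and 10 stray junctions over a
  # 200-junction truth... constructed directly on tibbles via the splice
  # evaluator inside the runner.
  set.seed(53)
  truth <- tibble::tibble(
    chrom = "c1",
    start = seq(1000L, by = 2000L, length.out = 200L),
    strand = "+"
  )
  truth$end <- truth$start + 500L
  tdir <- file.path(dir, "truth")
  dir.create(tdir)
  bed <- sprintf("c1\t%d\t%d\tj\t1\t+", truth$start - 1L, truth$end)
  writeLines(bed, file.path(tdir, "splices.bed"))
  writeLines(c("kind\tchrom\tpos\tref\talt\tsource\tsupport"),
             file.path(tdir, "mutations.tsv"))
  writeLines("chrom1\tpos1\tstrand1\tchrom2\tpos2\tstrand2\tclass\tsupport",
             file.path(tdir, "fusions.tsv"))
  writeLines(character(0), file.path(tdir, "reads_1.fastq"))
  jsonlite::write_json(list(n_read_pairs = 0,
                            chrom_lengths = list(c1 = 1000000)),
                       file.path(tdir, "manifest.json"), auto_unbox = TRUE)

  pred <- truth[1:90, ]
  stray <- tibble::tibble(chrom = "c1",
                          start = seq(900000L, by = 997L, length.out = 10L),
                          strand = "+")
  stray$end <- stray$start + 100L
  pred <- dplyr::bind_rows(pred, stray)
  pbed <- sprintf("%s\t%d\t%d\tp\t1\t%s", pred$chrom, pred$start - 1L,
                  pred$end, pred$strand)
  writeLines(pbed, file.path(dir, "pred.bed"))

  cfg <- list(truth_dir = tdir,
              pipelines = list(
                list(name = "rigged", splice = file.path(dir, "pred.bed")),
                list(name = "broken", splice = file.path(dir, "missing.bed"))
              ))
  suppressMessages(res <- run_benchmark(cfg))
  rig <- res$report[res$report$pipeline == "rigged", ]
  expect_identical(rig$tp, 90L)
  expect_identical(rig$fp, 10L)
  expect_identical(rig$fn, 110L)
  expect_equal(rig$fscore, 0.6)
  expect_identical(res$report$status[res$report$pipeline == "broken"], "failed")

  # tidy/glance/autoplot interfaces.
  expect_identical(tidy(res), res$report)
  g <- glance(res)
  expect_identical(g$n_pipelines, 2L)
  expect_identical(g$n_failed, 1L)
  expect_s3_class(autoplot(res), "ggplot")
  # Report ordered by decreasing F-score (failed rows trail with NA).
  okf <- res$report$fscore[res$report$status == "ok"]
  expect_true(all(diff(okf) <= 0))
})

test_that("threshold monotonicity and truth conservation hold", {
  set.seed(54)
  for (iter in 1:15) {
    s <- random_splice_set(60, 60)
    prev <- -1L
    for (thr in c(0, 5, 10, 20, 40)) {
      res <- evaluate_splices(s$pred, s$truth, threshold = thr)
      expect_gte(res$tp, prev)
      expect_identical(res$tp + res$fn, 60L)
      prev <- res$tp
    }
  }
})

test_that("SAM N ops convert to junctions and VCF alleles left-normalise", {
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "j.sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "r1\t0\tc1\t100\t60\t20M50N30M\t*\t0\t0\t*\t*",
    "r2\t16\tc1\t100\t60\t20M50N30M\t*\t0\t0\t*\t*",   # duplicate junction
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"
  ), sam)
  j <- extract_sam_junctions(sam)
  expect_identical(nrow(j), 1L)
  expect_identical(j$start, 120L)
  expect_identical(j$end, 169L)

  vcf <- file.path(dir, "p.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "c1\t100\t.\tAT\tAG\t.\t.\t.",       # normalises to SNV at 101
    "c1\t200\t.\tA\tG,ATT\t.\t.\t."      # multi-allelic split
  ), vcf)
  p <- read_vcf_predictions(vcf)
  expect_identical(nrow(p), 3L)
  snv1 <- p[p$pos == 101L, ]
  expect_identical(snv1$kind, "SNV")
  expect_identical(snv1$ref, "T")
  expect_identical(snv1$alt, "G")
  expect_setequal(p$kind[p$pos %in% c(200L)], c("SNV", "INS"))
  ins <- p[p$kind == "INS", ]
  expect_identical(ins$alt, "TT")
})
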