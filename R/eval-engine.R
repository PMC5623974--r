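# Qualitative evaluation of pipeline predictions against a truth database:
# per-chromosome-strand interval trees, per-event matching rules, and
# TP/FP/FN accounting.

# --- genomic-interval tree -------------------------------------------------

#' Build an interval tree over genomic intervals
#'
#' Indexes truth intervals per chromosome and strand for fast overlap
#' queries; entries with undefined strand (`.` or `*`) match both strands.
#'
#' @param gis Tibble with columns `chrom`, `start`, `end` and optionally
#'   `strand`.
#' @return Object of class `gi_tree`.
#' @export
gi_tree <- function(gis) {
  strand <- if ("strand" %in% names(gis)) gis$strand else rep("*", nrow(gis))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(gis)) gis$chrom else character(0),
    ranges = IRanges::IRanges(start = gis$start, end = gis$end),
    strand = strand
  )
  structure(list(gr = gr, gis = gis), class = "gi_tree")
}

#' Query an interval tree for overlapping truth intervals
#'
#' @param tree A `gi_tree`.
#' @param chrom,start,end,strand Query interval(s); vectors are recycled.
#'   Undefined strand matches both.
#' @return List (one element per query) of integer indices into the indexed
#'   intervals, exactly those overlapping the query by at least one base on
#'   a compatible chromosome strand.
#' @export
query_gi_tree <- function(tree, chrom, start, end, strand = "*") {
  n <- max(length(chrom), length(start), length(end))
  strand <- rep_len(strand, n)
  strand[!strand %in% c("+", "-")] <- "*"
  q <- GenomicRanges::GRanges(rep_len(chrom, n),
                              IRanges::IRanges(rep_len(start, n), rep_len(end, n)),
                              strand = strand)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, tree$gr))
  out <- rep(list(integer(0)), n)
  by_q <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  out[as.integer(names(by_q))] <- lapply(by_q, sort)
  out
}

# --- confusion counts and metrics ------------------------------------------

new_confusion <- function(tp, fp, fn, ignored = 0L, tp_ids = character(0)) {
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 ignored = as.integer(ignored), tp_ids = tp_ids),
            class = "confusion")
}

#' @exportS3Method base::print
print.confusion <- function(x, ...) {
  cat("<confusion> TP=", x$tp, " FP=", x$fp, " FN=", x$fn,
      " (ignored=", x$ignored, ")\n", sep = "")
  invisible(x)
}

#' Precision, recall and F-score from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)` and
#' `Fscore = 2 * recall * precision / (recall + precision)`; degenerate
#' denominators yield 0, so empty outputs rank last.
#'
#' @param counts A `confusion` object or a list/vector with elements `tp`,
#'   `fp`, `fn`.
#' @return Tibble with columns `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `fscore`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  fscore <- if (precision + recall > 0) {
    2 * recall * precision / (recall + precision)
  } else 0
  tibble::tibble(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, fscore = fscore)
}

# Shared greedy matcher. For each prediction (input order) with a candidate
# list and per-candidate distances, pick the minimum-distance candidate
# within the threshold, then (optionally) verify it — the event-specific
# allele/length check applies to the selected candidate, not to candidate
# choice. The first prediction matching a candidate consumes it (TP), later
# predictions of the same candidate are ignored. Predictions with no
# admissible candidate or a failed verification are FP; unconsumed truth
# entries are FN. cand/dist/admissible/verify: lists indexed by prediction.
greedy_match <- function(n_truth, cand, dist, admissible,
                         count_ignored_as_fp = FALSE, truth_ids = NULL,
                         verify = NULL) {
  consumed <- logical(n_truth)
  tp <- 0L; fp <- 0L; ignored <- 0L
  tp_ids <- character(0)
  for (i in seq_along(cand)) {
    ok <- admissible[[i]]
    if (!any(ok)) { fp <- fp + 1L; next }
    cc <- cand[[i]][ok]
    dd <- dist[[i]][ok]
    pick <- which.min(dd)
    best <- cc[pick]
    if (!is.null(verify) && !verify[[i]][ok][pick]) { fp <- fp + 1L; next }
    if (!consumed[best]) {
      consumed[best] <- TRUE
      tp <- tp + 1L
      if (!is.null(truth_ids)) tp_ids <- c(tp_ids, truth_ids[best])
    } else {
      ignored <- ignored + 1L
      if (count_ignored_as_fp) fp <- fp + 1L
    }
  }
  new_confusion(tp, fp, n_truth - sum(consumed), ignored, tp_ids)
}

# --- splice junctions ------------------------------------------------------

#' Evaluate predicted splice junctions
#'
#' Candidates are the truth junctions overlapping the prediction on a
#' compatible chromosome strand; the candidate minimising
#' `d = |start_p - start_c| + |end_p - end_c|` is matched when `d <=
#' threshold`. The first prediction of a candidate is the TP, later
#' duplicates are ignored (or counted FP with `count_ignored_as_fp`);
#' predictions without an admissible candidate are FP; unmatched truth
#' junctions are FN.
#'
#' @param predictions Tibble of predicted junctions (`chrom`, `start`,
#'   `end`, optional `strand`; 1-based intron coordinates).
#' @param truth Tibble of true junctions (same columns).
#' @param threshold Maximum distance `d` (default 10).
#' @param count_ignored_as_fp Count ignored duplicate predictions as FP.
#' @return A `confusion` object.
#' @export
evaluate_splices <- function(predictions, truth, threshold = 10L,
                             count_ignored_as_fp = FALSE) {
  tree <- gi_tree(truth)
  strand <- if ("strand" %in% names(predictions)) predictions$strand else "*"
  cand <- query_gi_tree(tree, predictions$chrom, predictions$start,
                        predictions$end, strand)
  dist <- lapply(seq_along(cand), function(i) {
    j <- cand[[i]]
    abs(predictions$start[i] - truth$start[j]) +
      abs(predictions$end[i] - truth$end[j])
  })
  admissible <- lapply(dist, function(d) d <= threshold)
  ids <- sprintf("%s:%d-%d(%s)", truth$chrom, truth$start, truth$end,
                 if ("strand" %in% names(truth)) truth$strand else "*")
  greedy_match(nrow(truth), cand, dist, admissible, count_ignored_as_fp, ids)
}

# --- mutations -------------------------------------------------------------

indel_len <- function(kind, ref, alt) {
  ifelse(kind == "INS", nchar(alt), ifelse(kind == "DEL", nchar(ref), 1L))
}

#' Evaluate predicted SNVs or indels
#'
#' A truth mutation of the same kind within `threshold` bases is a
#' candidate (query interval `[pos - threshold, pos + threshold]` against
#' the truth positions); the nearest candidate is checked: SNVs must carry
#' the true alternate base, indels must agree in length within the
#' threshold. Tie and duplicate rules are as for splice junctions.
#'
#' @param predictions Tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `kind` (see [read_vcf_predictions()]).
#' @param truth Mutation tibble (truth database `mutations` table).
#' @param kind One of "SNV", "INS", "DEL": the event type under evaluation.
#' @param threshold Maximum positional offset and indel length difference
#'   (default 5).
#' @param count_ignored_as_fp Count ignored duplicate predictions as FP.
#' @return A `confusion` object.
#' @export
evaluate_mutations <- function(predictions, truth, kind, threshold = 5L,
                               count_ignored_as_fp = FALSE) {
  stopifnot(kind %in% c("SNV", "INS", "DEL"))
  pred <- predictions[predictions$kind == kind, , drop = FALSE]
  tru <- truth[truth$kind == kind, , drop = FALSE]
  tree <- gi_tree(tibble::tibble(chrom = tru$chrom, start = tru$pos,
                                 end = tru$pos, strand = "*"))
  cand <- query_gi_tree(tree, pred$chrom, pred$pos - threshold,
                        pred$pos + threshold, "*")
  dist <- lapply(seq_len(nrow(pred)), function(i) {
    abs(pred$pos[i] - tru$pos[cand[[i]]])
  })
  tru_len <- indel_len(tru$kind, tru$ref, tru$alt)
  pred_len <- indel_len(pred$kind, pred$ref, pred$alt)
  admissible <- lapply(dist, function(d) d <= threshold)
  verify <- lapply(seq_len(nrow(pred)), function(i) {
    j <- cand[[i]]
    if (kind == "SNV") {
      pred$alt[i] == tru$alt[j]
    } else {
      abs(pred_len[i] - tru_len[j]) <= threshold
    }
  })
  ids <- sprintf("%s:%d:%s", tru$chrom, tru$pos, tru$kind)
  greedy_match(nrow(tru), cand, dist, admissible, count_ignored_as_fp, ids,
               verify = verify)
}

# --- fusions ---------------------------------------------------------------

# Orientation-normalised composite representation of fusion junctions:
# the side pair is put in canonical (lexicographic chromosome, then
# position) order, flipping both strands when swapped; the composite
# interval is (start = pos1, end = length(chrom1) + pos2) on the composite
# key chr1|chr2 with composite strand strand1.strand2.
canonical_fusions <- function(df, chrom_lengths) {
  swap <- df$chrom2 < df$chrom1 |
    (df$chrom2 == df$chrom1 & df$pos2 < df$pos1)
  out <- df
  out$chrom1 <- ifelse(swap, df$chrom2, df$chrom1)
  out$pos1 <- ifelse(swap, df$pos2, df$pos1)
  out$strand1 <- ifelse(swap, flip_strand(df$strand2), df$strand1)
  out$chrom2 <- ifelse(swap, df$chrom1, df$chrom2)
  out$pos2 <- ifelse(swap, df$pos1, df$pos2)
  out$strand2 <- ifelse(swap, flip_strand(df$strand1), df$strand2)
  unknown <- !(out$chrom1 %in% names(chrom_lengths)) |
    !(out$chrom2 %in% names(chrom_lengths))
  if (any(unknown)) {
    warning(sum(unknown), " fusion record(s) naming an unknown chromosome skipped")
    out <- out[!unknown, , drop = FALSE]
  }
  out$key <- paste0(out$chrom1, "|", out$chrom2, "|", out$strand1, out$strand2)
  out$start <- out$pos1
  out$end <- chrom_lengths[out$chrom1] + out$pos2
  out
}

#' Evaluate predicted gene fusions
#'
#' Both truth and predictions are transformed into composite genomic
#' intervals (`chr = chr1.chr2`, `start = pos1`,
#' `end = length(chr1) + pos2`, `strand = strand1.strand2`), with the side
#' pair orientation-normalised so that either reported order matches. A
#' candidate must share the composite chromosome key and composite strand
#' and lie within the `threshold`-widened window; the distance
#' `d = |dstart| + |dend|` must not exceed `threshold`. Tie and duplicate
#' rules are as for splice junctions.
#'
#' @param predictions Tibble with columns `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2`.
#' @param truth Tibble with the same columns (truth database `fusions`).
#' @param chrom_lengths Named vector of chromosome lengths (for the
#'   composite end transform).
#' @param threshold Maximum combined breakpoint distance (default 20).
#' @param count_ignored_as_fp Count ignored duplicate predictions as FP.
#' @return A `confusion` object.
#' @export
evaluate_fusions <- function(predictions, truth, chrom_lengths,
                             threshold = 20L, count_ignored_as_fp = FALSE) {
  tru <- canonical_fusions(truth, chrom_lengths)
  pred <- canonical_fusions(predictions, chrom_lengths)
  tree <- gi_tree(tibble::tibble(chrom = tru$key, start = tru$start,
                                 end = tru$end, strand = "*"))
  cand <- query_gi_tree(tree, pred$key, pred$start - threshold,
                        pred$end + threshold, "*")
  dist <- lapply(seq_len(nrow(pred)), function(i) {
    j <- cand[[i]]
    abs(pred$start[i] - tru$start[j]) + abs(pred$end[i] - tru$end[j])
  })
  admissible <- lapply(dist, function(d) d <= threshold)
  ids <- sprintf("%s:%d:%s>%s:%d:%s", tru$chrom1, tru$pos1, tru$strand1,
                 tru$chrom2, tru$pos2, tru$strand2)
  greedy_match(nrow(tru), cand, dist, admissible, count_ignored_as_fp, ids)
}

# --- alignments ------------------------------------------------------------

#' Evaluate predicted alignments from a SAM file
#'
#' For each read, the first mapped record in file order whose NH tag does
#' not exceed `max_hits` is evaluated (records without an NH tag count as
#' NH = 1); it is a TP iff it overlaps any truth alignment of that read —
#' decoded from the read name — by at least one base on the same
#' chromosome, else a FP. Reads never evaluated (unmapped, absent, or all
#' records ignored) are FN; the recall denominator is the number of
#' simulated reads.
#'
#' @param sam Path to a SAM file, or a tibble from [read_sam()].
#' @param n_reads Number of simulated read pairs (truth read ids are
#'   `0..n_reads-1`).
#' @param max_hits Maximum NH value evaluated (default 1).
#' @param count_ignored_as_fp Count reads whose records were all ignored as
#'   FP (in addition to FN) instead of excluding them.
#' @return A `confusion` object; TP identifiers are read ids.
#' @export
evaluate_alignments <- function(sam, n_reads, max_hits = 1L,
                                count_ignored_as_fp = FALSE) {
  if (is.character(sam)) sam <- read_sam(sam)
  mapped <- sam[bitwAnd(sam$flag, 4L) == 0L & sam$rname != "*", , drop = FALSE]
  nh <- mapped$nh
  nh[is.na(nh)] <- 1L
  eligible <- mapped[nh <= max_hits, , drop = FALSE]
  first <- eligible[!duplicated(eligible$qname), , drop = FALSE]
  ignored_reads <- setdiff(unique(mapped$qname), first$qname)

  tp <- 0L; fp <- 0L
  tp_ids <- character(0)
  bad_names <- 0L
  for (i in seq_len(nrow(first))) {
    dec <- tryCatch(decode_read_name(first$qname[i]), error = function(e) NULL)
    if (is.null(dec)) { bad_names <- bad_names + 1L; next }
    spans <- cigar_ref_span(dec$alignments$cigar)
    p_end <- first$pos[i] + cigar_ref_span(first$cigar[i]) - 1L
    hit <- any(dec$alignments$chrom == first$rname[i] &
                 dec$alignments$pos <= p_end &
                 dec$alignments$pos + spans - 1L >= first$pos[i])
    if (hit) {
      tp <- tp + 1L
      tp_ids <- c(tp_ids, as.character(dec$read_id))
    } else {
      fp <- fp + 1L
    }
  }
  if (bad_names > 0) {
    warning(bad_names, " SAM record(s) with undecodable read names skipped")
  }
  evaluated <- nrow(first) - bad_names
  fn <- n_reads - evaluated
  if (count_ignored_as_fp) fp <- fp + length(ignored_reads)
  new_confusion(tp, fp, fn, length(ignored_reads), tp_ids)
}
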