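# Gene fusion generation and junction geometry classification.

#' Classify a two-locus junction
#'
#' A junction is NONCOLINEAR_FUSION when its two sides are on different
#' chromosomes, on different strands, or in reverse transcriptional order on
#' the same chromosome and strand. Colinear junctions whose skipped span
#' exceeds `colinear_threshold` are COLINEAR_FUSION; the rest are ordinary
#' SPLICE junctions. The span is the number of genomic bases strictly between
#' the two breakpoint bases.
#'
#' @param chrom1,pos1,strand1 Donor side: chromosome, last transcribed base
#'   of the upstream segment, strand.
#' @param chrom2,pos2,strand2 Acceptor side: chromosome, first transcribed
#'   base of the downstream segment, strand.
#' @param colinear_threshold Span (bases) above which a colinear junction is
#'   called a fusion; default 300000 (300 kb).
#' @return Character vector over `{"SPLICE", "COLINEAR_FUSION",
#'   "NONCOLINEAR_FUSION"}`; classes are exhaustive and mutually exclusive.
#' @export
classify_junction <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                              colinear_threshold = 300000L) {
  n <- max(length(chrom1), length(chrom2))
  chrom1 <- rep_len(chrom1, n); chrom2 <- rep_len(chrom2, n)
  pos1 <- rep_len(pos1, n); pos2 <- rep_len(pos2, n)
  strand1 <- rep_len(strand1, n); strand2 <- rep_len(strand2, n)

  noncol <- chrom1 != chrom2 | strand1 != strand2 |
    (strand1 == "+" & pos2 <= pos1) | (strand1 == "-" & pos2 >= pos1)
  span <- ifelse(strand1 == "+", pos2 - pos1, pos1 - pos2) - 1L
  out <- ifelse(noncol, "NONCOLINEAR_FUSION",
                ifelse(span > colinear_threshold, "COLINEAR_FUSION", "SPLICE"))
  out
}

# Representative transcript per gene: the one with the largest summed exon
# length (ties broken by transcript_id).
representative_transcripts <- function(annotation) {
  annotation |>
    dplyr::group_by(.data$gene_id, .data$transcript_id) |>
    dplyr::summarise(len = sum(.data$end - .data$start + 1), .groups = "drop") |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$len), .data$transcript_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
}

#' Generate fusion genes by random exon pairing
#'
#' Picks pairs of exons (uniformly over the exons of each gene's
#' representative transcript, resampling until the parent genes differ) and
#' joins the upstream part of the first parent gene — from its transcript 5'
#' end through the picked exon — with the downstream part of the second
#' parent gene — from its picked exon through the transcript 3' end. Each
#' side is the contiguous genomic segment of the retained region
#' (strand-normalised to transcription direction), so retained introns are
#' preserved; the two picked exons become one merged exon forcing the fusion
#' junction.
#'
#' @param genome Named character vector of sequences (original reference).
#' @param annotation Annotation tibble (original coordinates); needs at least
#'   two genes.
#' @param n_fusions Number of fusion genes to create.
#' @return List with elements:
#'   * `events`: tibble of fusion events (contig, parent genes, breakpoint
#'     coordinates/strands on the original genome, junction class),
#'   * `contigs`: named character vector of fusion contig sequences,
#'   * `annotation`: tibble of fusion transcript exons in contig coordinates,
#'   * `registry`: tibble mapping contig segments back to original
#'     coordinates (contig, side, contig_start, contig_end, chrom, start,
#'     end, strand).
#' @export
generate_fusions <- function(genome, annotation, n_fusions) {
  stopifnot(n_fusions >= 0)
  empty <- list(
    events = tibble::tibble(
      contig = character(), gene5 = character(), gene3 = character(),
      chrom5 = character(), bp5 = integer(), strand5 = character(),
      chrom3 = character(), bp3 = integer(), strand3 = character(),
      class = character()),
    contigs = character(0),
    annotation = annotation[0, ],
    registry = tibble::tibble(
      contig = character(), side = integer(), contig_start = integer(),
      contig_end = integer(), chrom = character(), start = integer(),
      end = integer(), strand = character())
  )
  if (n_fusions == 0) return(empty)
  rep_tx <- representative_transcripts(annotation)
  if (nrow(rep_tx) < 2) stop("At least two genes are required to generate fusions")
  exons <- dplyr::inner_join(annotation, rep_tx[, c("gene_id", "transcript_id")],
                             by = c("gene_id", "transcript_id"))
  exons <- exons[order(exons$transcript_id, exons$start), ]

  events <- list(); contigs <- character(0); ann_add <- list(); reg <- list()
  for (k in seq_len(n_fusions)) {
    repeat {
      pick <- sample(nrow(exons), 2)
      if (exons$gene_id[pick[1]] != exons$gene_id[pick[2]]) break
    }
    e5 <- exons[pick[1], ]  # upstream-side picked exon (gene A)
    e3 <- exons[pick[2], ]  # downstream-side picked exon (gene B)
    txA <- exons[exons$transcript_id == e5$transcript_id, ]
    txB <- exons[exons$transcript_id == e3$transcript_id, ]
    contig <- sprintf("fusion_%d", k)

    # Side A: transcript 5' end through picked exon, as one genomic segment.
    if (e5$strand == "+") {
      a_start <- min(txA$start); a_end <- e5$end
      a_keep <- txA[txA$end <= e5$end, ]
    } else {
      a_start <- e5$start; a_end <- max(txA$end)
      a_keep <- txA[txA$start >= e5$start, ]
    }
    # Side B: picked exon through transcript 3' end.
    if (e3$strand == "+") {
      b_start <- e3$start; b_end <- max(txB$end)
      b_keep <- txB[txB$start >= e3$start, ]
    } else {
      b_start <- min(txB$start); b_end <- e3$end
      b_keep <- txB[txB$end <= e3$end, ]
    }
    seq_a <- substring(genome[[e5$chrom]], a_start, a_end)
    if (e5$strand == "-") seq_a <- revcomp(seq_a)
    seq_b <- substring(genome[[e3$chrom]], b_start, b_end)
    if (e3$strand == "-") seq_b <- revcomp(seq_b)
    len_a <- nchar(seq_a); len_b <- nchar(seq_b)
    contigs[[contig]] <- paste0(seq_a, seq_b)

    # Exon coordinates on the contig (transcription direction, strand "+").
    to_contig <- function(ex, side_start, side_end, strand, offset) {
      if (strand == "+") {
        tibble::tibble(start = ex$start - side_start + 1L + offset,
                       end = ex$end - side_start + 1L + offset)
      } else {
        tibble::tibble(start = side_end - ex$end + 1L + offset,
                       end = side_end - ex$start + 1L + offset)
      }
    }
    ca <- to_contig(a_keep, a_start, a_end, e5$strand, 0L)
    cb <- to_contig(b_keep, b_start, b_end, e3$strand, len_a)
    ca <- ca[order(ca$start), ]
    cb <- cb[order(cb$start), ]
    # Merge the two picked exons (last of side A, first of side B) into one.
    merged <- tibble::tibble(start = ca$start[nrow(ca)], end = cb$end[1])
    contig_exons <- dplyr::bind_rows(ca[-nrow(ca), ], merged, cb[-1, ])
    ann_add[[k]] <- tibble::tibble(
      gene_id = contig, transcript_id = paste0(contig, "_t1"),
      chrom = contig, strand = "+",
      start = as.integer(contig_exons$start), end = as.integer(contig_exons$end)
    )

    reg[[k]] <- tibble::tibble(
      contig = contig, side = 1:2,
      contig_start = c(1L, len_a + 1L),
      contig_end = c(len_a, len_a + len_b),
      chrom = c(e5$chrom, e3$chrom),
      start = c(a_start, b_start), end = c(a_end, b_end),
      strand = c(e5$strand, e3$strand)
    )

    bp5 <- if (e5$strand == "+") e5$end else e5$start
    bp3 <- if (e3$strand == "+") e3$start else e3$end
    events[[k]] <- tibble::tibble(
      contig = contig,
      gene5 = e5$gene_id, gene3 = e3$gene_id,
      chrom5 = e5$chrom, bp5 = as.integer(bp5), strand5 = e5$strand,
      chrom3 = e3$chrom, bp3 = as.integer(bp3), strand3 = e3$strand,
      class = classify_junction(e5$chrom, bp5, e5$strand,
                                e3$chrom, bp3, e3$strand)
    )
  }
  list(events = dplyr::bind_rows(events),
       contigs = contigs,
       annotation = dplyr::bind_rows(ann_add),
       registry = dplyr::bind_rows(reg))
}
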