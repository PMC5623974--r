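# Readers for pipeline prediction files (SAM, BED, VCF, fusion TSV) and a
# SAM writer for truth alignments.

#' Read a SAM text file (minimal parser)
#'
#' Extracts the fields the alignment evaluator needs: QNAME, FLAG, RNAME,
#' POS, CIGAR and the NH tag. Header lines are skipped; record order is
#' preserved.
#'
#' @param path Path to a SAM file.
#' @return Tibble with columns `qname`, `flag`, `rname`, `pos`, `cigar`,
#'   `nh` (NA when the tag is absent).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(tibble::tibble(qname = character(), flag = integer(),
                          rname = character(), pos = integer(),
                          cigar = character(), nh = integer()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 11)) stop("Malformed SAM record in ", path)
  nh <- vapply(f, function(x) {
    tags <- x[-(1:11)]
    hit <- grep("^NH:i:", tags, value = TRUE)
    if (length(hit) == 0) NA_integer_ else as.integer(sub("^NH:i:", "", hit[1]))
  }, integer(1))
  tibble::tibble(
    qname = vapply(f, `[[`, character(1), 1),
    flag = as.integer(vapply(f, `[[`, character(1), 2)),
    rname = vapply(f, `[[`, character(1), 3),
    pos = as.integer(vapply(f, `[[`, character(1), 4)),
    cigar = vapply(f, `[[`, character(1), 6),
    nh = nh
  )
}

#' Read predicted splice junctions from BED
#'
#' BED columns are 0-based half-open; the returned intron coordinates are
#' 1-based inclusive. A sixth column, when present, provides the strand.
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `chrom`, `start`, `end`, `strand`.
#' @export
read_junction_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    chrom = vapply(f, `[[`, character(1), 1),
    start = as.integer(vapply(f, `[[`, character(1), 2)) + 1L,
    end = as.integer(vapply(f, `[[`, character(1), 3)),
    strand = vapply(f, function(x) if (length(x) >= 6) x[[6]] else ".",
                    character(1))
  )
}

#' Extract splice junctions from a SAM file's N operations
#'
#' Each N op of each mapped record contributes its intron; junctions are
#' deduplicated. Strand is left undefined (SAM alignment strand does not
#' determine transcription strand).
#'
#' @param path Path to a SAM file.
#' @return Tibble with columns `chrom`, `start`, `end`, `strand` (all ".").
#' @export
extract_sam_junctions <- function(path) {
  sam <- read_sam(path)
  sam <- sam[bitwAnd(sam$flag, 4L) == 0L & sam$cigar != "*", , drop = FALSE]
  if (nrow(sam) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  recs <- tibble::tibble(read_id = seq_len(nrow(sam)), end = 1L, ord = 1L,
                         chrom = sam$rname, pos = sam$pos, strand = "+",
                         cigar = sam$cigar, tx_strand = "+")
  ops <- records_ref_ops(recs)
  n_ops <- ops[ops$op == "N", , drop = FALSE]
  dplyr::distinct(tibble::tibble(chrom = n_ops$chrom, start = n_ops$ref_start,
                                 end = n_ops$ref_end, strand = "."))
}

#' Read predicted mutations from VCF
#'
#' Multi-allelic records are split into one prediction per alternate
#' allele; every allele pair is left-normalised (shared prefix trimmed) and
#' classified into SNV/INS/DEL by the REF/ALT length relation. Alleles that
#' remain complex after trimming are dropped.
#'
#' @param path Path to a VCF file.
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `kind`
#'   (internal mutation representation: INS anchored at `pos` with inserted
#'   bases in `alt`; DEL covering `ref` from `pos`).
#' @export
read_vcf_predictions <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  alts <- strsplit(fix$ALT %||% character(0), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  chrom <- rep(fix$CHROM, n_alt)
  pos <- rep(as.integer(fix$POS), n_alt)
  ref <- toupper(rep(fix$REF, n_alt))
  alt <- toupper(unlist(alts, use.names = FALSE))

  # Left-trim the shared prefix (VCF anchor bases).
  for (pass in seq_len(max(c(nchar(ref), 1)))) {
    trim <- nchar(ref) > 1 & nchar(alt) > 1 &
      substring(ref, 1, 1) == substring(alt, 1, 1)
    if (!any(trim)) break
    pos[trim] <- pos[trim] + 1L
    ref[trim] <- substring(ref[trim], 2)
    alt[trim] <- substring(alt[trim], 2)
  }
  kind <- rep(NA_character_, length(ref))
  kind[nchar(ref) == 1 & nchar(alt) == 1] <- "SNV"
  ins <- nchar(ref) == 1 & nchar(alt) > 1 & substring(alt, 1, 1) == ref
  del <- nchar(alt) == 1 & nchar(ref) > 1 & substring(ref, 1, 1) == alt
  kind[ins] <- "INS"
  kind[del] <- "DEL"
  out <- tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                        kind = kind)
  # Convert anchored indels to the internal representation.
  out$alt[ins] <- substring(alt[ins], 2)
  out$ref[ins] <- ""
  out$pos[del] <- out$pos[del] + 1L
  out$ref[del] <- substring(ref[del], 2)
  out$alt[del] <- ""
  out[!is.na(out$kind), , drop = FALSE]
}

#' Read predicted fusions from TSV
#'
#' Expects at least the six columns `chrom1`, `pos1`, `strand1`, `chrom2`,
#' `pos2`, `strand2` (header required); extra columns are ignored.
#'
#' @param path Path to a TSV file.
#' @return Tibble with the six breakpoint columns.
#' @export
read_fusion_tsv <- function(path) {
  if (!file.exists(path)) stop("Fusion TSV not found: ", path)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  assert_cols(df, c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2"),
              "fusion TSV")
  tibble::tibble(chrom1 = df$chrom1, pos1 = as.integer(df$pos1),
                 strand1 = df$strand1, chrom2 = df$chrom2,
                 pos2 = as.integer(df$pos2), strand2 = df$strand2)
}

#' Write the truth alignments of a dataset as a SAM file
#'
#' Emits one record per read pair at its first truth alignment (NH:i:1),
#' reconstructing a perfect-alignment prediction set; useful for self-match
#' checks and as a template for pipeline comparisons.
#'
#' @param truth A `truth_db` from [read_truth_db()] (needs `names` and
#'   `chrom_lengths`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
truth_to_sam <- function(truth, path) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(truth$chrom_lengths),
                      as.integer(truth$chrom_lengths)))
  recs <- vapply(truth$names, function(nm) {
    dec <- decode_read_name(nm)
    a <- dec$alignments[1, ]
    flag <- if (a$strand == "-") 16L else 0L
    sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*\tNH:i:1",
            nm, flag, a$chrom, a$pos, a$cigar)
  }, character(1), USE.NAMES = FALSE)
  writeLines(c(header, recs), path)
  invisible(path)
}
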