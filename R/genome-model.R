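# Genome and annotation I/O.
#
# A genome is a named character vector of uppercase chromosome sequences.
# An annotation is a tibble with one row per exon and columns
# gene_id, transcript_id, chrom, strand, start, end (1-based inclusive).

#' Read a reference genome from FASTA
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return Named character vector of uppercase sequences, one element per
#'   record, in file order. Names are the first whitespace-delimited token of
#'   each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("Malformed FASTA file ", path, ": ", conditionMessage(e))
  )
  if (length(seqs) == 0) stop("Empty FASTA file: ", path)
  g <- toupper(as.character(seqs))
  names(g) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(g))) stop("Duplicated chromosome names in ", path)
  g
}

#' Write a genome to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path, width = 60)
  invisible(path)
}

#' Read transcript annotations from GTF
#'
#' Only `exon` feature lines are consumed; every exon line must carry a
#' `transcript_id` attribute. Exons are grouped by transcript and sorted by
#' start; strand is taken from column 7.
#'
#' @param path Path to a GTF file.
#' @return Annotation tibble (one row per exon) with columns `gene_id`,
#'   `transcript_id`, `chrom`, `strand`, `start`, `end`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[as.character(gr$type) == "exon"]
  if (length(gr) == 0) stop("No exon features in GTF file: ", path)
  tx <- gr$transcript_id
  if (is.null(tx) || anyNA(tx)) stop("GTF exon line without transcript_id in ", path)
  gene <- gr$gene_id
  if (is.null(gene)) gene <- rep(NA_character_, length(gr))
  gene <- dplyr::coalesce(gene, tx)
  ann <- tibble::tibble(
    gene_id = gene,
    transcript_id = tx,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr)
  )
  dplyr::arrange(ann, .data$gene_id, .data$transcript_id, .data$start)
}

#' Write transcript annotations to GTF
#'
#' Emits one `exon` line per row with `gene_id "X"; transcript_id "Y";`
#' attributes.
#'
#' @param annotation Annotation tibble as returned by [read_gtf()].
#' @param path Output path.
#' @param append Append to an existing file instead of overwriting.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path, append = FALSE) {
  assert_cols(annotation, c("gene_id", "transcript_id", "chrom", "strand", "start", "end"),
              "annotation")
  lines <- sprintf(
    "%s\tsimbench\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    annotation$chrom, annotation$start, annotation$end, annotation$strand,
    annotation$gene_id, annotation$transcript_id
  )
  if (append && file.exists(path)) {
    cat(lines, file = path, sep = "\n", append = TRUE)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

#' Validate an annotation against a genome
#'
#' Checks chromosome membership, exon bounds, ascending order and the
#' one-intronic-base separation between consecutive exons of a transcript.
#'
#' @param annotation Annotation tibble.
#' @param genome Named character vector of sequences.
#' @return `annotation`, invisibly; stops on the first violation.
#' @export
validate_annotation <- function(annotation, genome) {
  unknown <- setdiff(unique(annotation$chrom), names(genome))
  if (length(unknown) > 0) {
    stop("Annotation references unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  lens <- nchar(genome)[annotation$chrom]
  if (any(annotation$start < 1 | annotation$end > lens | annotation$start > annotation$end)) {
    stop("Annotation contains out-of-bounds exons")
  }
  by_tx <- split(seq_len(nrow(annotation)), annotation$transcript_id)
  for (idx in by_tx) {
    s <- annotation$start[idx]
    e <- annotation$end[idx]
    o <- order(s)
    if (length(idx) > 1 && any(s[o][-1] <= e[o][-length(e)] + 1)) {
      stop("Transcript ", annotation$transcript_id[idx[1]],
           " has overlapping or adjacent exons")
    }
  }
  invisible(annotation)
}

#' Spliced sequence of one transcript
#'
#' Concatenates the exon substrings in genomic order and reverse-complements
#' the result for minus-strand transcripts.
#'
#' @param genome Named character vector of sequences.
#' @param annotation Annotation tibble.
#' @param transcript_id Transcript to extract.
#' @return A single string; its length equals the summed exon lengths.
#' @export
transcript_sequence <- function(genome, annotation, transcript_id) {
  ex <- annotation[annotation$transcript_id == transcript_id, ]
  if (nrow(ex) == 0) stop("Unknown transcript: ", transcript_id)
  chrom <- ex$chrom[1]
  if (!chrom %in% names(genome)) stop("Unknown chromosome: ", chrom)
  L <- nchar(genome[[chrom]])
  if (any(ex$start < 1 | ex$end > L)) {
    stop("Out-of-bounds exon for transcript ", transcript_id)
  }
  ex <- ex[order(ex$start), ]
  s <- paste(substring(genome[[chrom]], ex$start, ex$end), collapse = "")
  if (ex$strand[1] == "-") s <- revcomp(s)
  s
}

#' Spliced sequences of all transcripts
#'
#' @param genome Named character vector of sequences.
#' @param annotation Annotation tibble.
#' @return Named character vector, one spliced sequence per transcript.
#' @export
transcript_sequences <- function(genome, annotation) {
  ids <- unique(annotation$transcript_id)
  out <- vapply(ids, function(id) transcript_sequence(genome, annotation, id),
                character(1))
  names(out) <- ids
  out
}
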