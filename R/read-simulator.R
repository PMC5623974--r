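# Built-in paired-end read generator: rank-law expression profile, fragment
# sampling, substitution errors, and projection of reads through exon chains
# onto (mutated-)genome coordinates. Any generator producing the same
# per-read fields (sequences, error offsets, alignment blocks) can be
# substituted for it.

#' Draw a transcript expression profile from the rank law
#'
#' Transcripts are assigned distinct ranks `x = 1..T` uniformly at random;
#' the expression weight of rank `x` is `x^k * exp(-x/x0 - (x/x1)^2)`, a
#' mixed power and exponential decay. Molecule counts are multinomial with
#' `n_molecules` trials over the normalised weights.
#'
#' @param transcript_ids Character vector of transcript identifiers.
#' @param k Exponent of the expression rank (dimensionless); default -0.7.
#' @param x0 First decay parameter, in rank units; default 15000.
#' @param x1 Second decay parameter, in rank units; default `x0^2`.
#' @param n_molecules Total number of expressed molecules; default 1e6.
#' @return Tibble with columns `transcript_id`, `rank`, `weight`, `count`;
#'   `sum(count) == n_molecules`.
#' @export
draw_expression_profile <- function(transcript_ids, k = -0.7, x0 = 15000,
                                    x1 = x0^2, n_molecules = 1e6) {
  stopifnot(length(transcript_ids) >= 1, x0 > 0, x1 > 0, n_molecules >= 1)
  n <- length(transcript_ids)
  rank <- sample.int(n)
  w <- rank^k * exp(-rank / x0 - (rank / x1)^2)
  p <- w / sum(w)
  count <- as.integer(stats::rmultinom(1, size = n_molecules, prob = p)[, 1])
  tibble::tibble(transcript_id = transcript_ids, rank = rank,
                 weight = w, count = count)
}

#' Sample sequencing fragments from an expression profile
#'
#' Each fragment's source transcript is drawn proportionally to its molecule
#' count (uniformly per molecule, with no length weighting); its length is
#' normal with mean `fragment_mean` and sd `fragment_sd`, rounded and clamped
#' to `[read_length, transcript length]`; its start is uniform. Transcripts
#' shorter than `read_length` are excluded from sampling with a warning.
#'
#' @param profile Tibble from [draw_expression_profile()].
#' @param tx_seqs Named character vector of spliced transcript sequences.
#' @param n_fragments Number of fragments to emit.
#' @param read_length Read length in bases.
#' @param fragment_mean,fragment_sd Fragment length distribution (bp);
#'   defaults 250 and 50.
#' @return Tibble with columns `transcript_id`, `start` (1-based within the
#'   transcript), `length`.
#' @export
fragment_and_sample <- function(profile, tx_seqs, n_fragments,
                                read_length = 101L,
                                fragment_mean = 250, fragment_sd = 50) {
  stopifnot(nrow(profile) >= 1, n_fragments >= 0)
  tx_len <- nchar(tx_seqs)[profile$transcript_id]
  ok <- !is.na(tx_len) & tx_len >= read_length
  if (any(!ok & profile$count > 0)) {
    warning(sum(!ok & profile$count > 0),
            " expressed transcript(s) shorter than the read length were excluded")
  }
  pool <- profile[ok, ]
  tx_len <- tx_len[ok]
  if (nrow(pool) == 0 || sum(pool$count) == 0) {
    stop("No expressed transcript is long enough to carry a read")
  }
  idx <- sample.int(nrow(pool), n_fragments, replace = TRUE, prob = pool$count)
  len <- as.integer(round(stats::rnorm(n_fragments, fragment_mean, fragment_sd)))
  len <- pmin(pmax(len, read_length), tx_len[idx])
  start <- 1L + as.integer(floor(stats::runif(n_fragments) * (tx_len[idx] - len + 1)))
  tibble::tibble(transcript_id = pool$transcript_id[idx],
                 start = start, length = len)
}

# Inject substitution errors into read sequences. Returns list(seq, err)
# where err is a list of ascending 0-based offsets per read.
inject_errors <- function(seqs, error_rate) {
  n <- length(seqs)
  err <- vector("list", n)
  if (n == 0 || error_rate <= 0) {
    err[] <- list(integer(0))
    return(list(seq = seqs, err = err))
  }
  lens <- nchar(seqs)
  n_err <- stats::rbinom(n, lens, error_rate)
  err[] <- list(integer(0))
  for (i in which(n_err > 0)) {
    pos <- sort(sample.int(lens[i], n_err[i]))
    raw <- charToRaw(seqs[i])
    orig <- strsplit(rawToChar(raw[pos]), "")[[1]]
    raw[pos] <- charToRaw(paste(draw_alt_bases(orig), collapse = ""))
    seqs[i] <- rawToChar(raw)
    err[[i]] <- pos - 1L
  }
  list(seq = seqs, err = err)
}

#' Build paired-end reads from fragments
#'
#' End 1 is the first `read_length` bases of the fragment; end 2 is the
#' reverse complement of the last `read_length` bases. Substitution errors
#' are injected per base at `error_rate` (the erroneous base always differs
#' from the original) and their 0-based offsets within each end recorded.
#'
#' @param fragments Tibble from [fragment_and_sample()].
#' @param tx_seqs Named character vector of spliced transcript sequences.
#' @param read_length Read length in bases.
#' @param error_rate Per-base substitution probability; default 0.001.
#' @return Tibble with columns `read_id` (0-based, dense), `transcript_id`,
#'   `start`, `length`, `seq1`, `seq2`, and list-columns `err1`, `err2` of
#'   ascending 0-based error offsets.
#' @export
make_read_pairs <- function(fragments, tx_seqs, read_length = 101L,
                            error_rate = 0.001) {
  stopifnot(all(fragments$length >= read_length))
  frag_seq <- unname(substring(tx_seqs[fragments$transcript_id], fragments$start,
                               fragments$start + fragments$length - 1L))
  seq1 <- substring(frag_seq, 1L, read_length)
  seq2 <- revcomp(substring(frag_seq, fragments$length - read_length + 1L,
                            fragments$length))
  e1 <- inject_errors(seq1, error_rate)
  e2 <- inject_errors(seq2, error_rate)
  tibble::tibble(
    read_id = seq_len(nrow(fragments)) - 1L,
    transcript_id = fragments$transcript_id,
    start = fragments$start, length = fragments$length,
    seq1 = e1$seq, seq2 = e2$seq, err1 = e1$err, err2 = e2$err
  )
}

# Per-transcript exon chains in transcription order, with cumulative
# transcript coordinates. Returns a named list of tibbles with columns
# chrom, strand, start, end (genomic), t_start, t_end (transcript coords).
exon_chains <- function(annotation) {
  ann <- annotation[order(annotation$transcript_id, annotation$start), ]
  split_ann <- split(ann, ann$transcript_id)
  lapply(split_ann, function(ex) {
    if (ex$strand[1] == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
    w <- ex$end - ex$start + 1L
    t_end <- cumsum(w)
    ex$t_start <- t_end - w + 1L
    ex$t_end <- t_end
    ex
  })
}

# Map a transcript-coordinate interval [t1, t2] through an exon chain to
# genomic blocks: integer matrix with columns start, end, sorted by start.
interval_to_blocks <- function(chain, t1, t2) {
  hit <- which(chain$t_end >= t1 & chain$t_start <= t2)
  lo <- pmax(t1, chain$t_start[hit])
  hi <- pmin(t2, chain$t_end[hit])
  if (chain$strand[1] == "+") {
    m <- cbind(start = chain$start[hit] + (lo - chain$t_start[hit]),
               end = chain$start[hit] + (hi - chain$t_start[hit]))
  } else {
    m <- cbind(start = chain$end[hit] - (hi - chain$t_start[hit]),
               end = chain$end[hit] - (lo - chain$t_start[hit]))
  }
  storage.mode(m) <- "integer"
  m[order(m[, 1]), , drop = FALSE]
}

#' Project read ends through exon chains onto genomic blocks
#'
#' Maps each end of each pair into one or more genomic alignment blocks on
#' the simulation reference (mutated genome or fusion contig): ends spanning
#' splice junctions yield multiple blocks; minus-strand transcripts are
#' handled by coordinate reflection. End 1 aligns on the transcript strand,
#' end 2 on the opposite strand.
#'
#' @param reads Tibble from [make_read_pairs()] (or [fragment_and_sample()]
#'   plus a `read_id` column).
#' @param annotation Annotation tibble on the simulation reference.
#' @param read_length Read length in bases.
#' @return Tibble with one row per read end: `read_id`, `end` (1 or 2),
#'   `chrom`, `strand`, and list-column `blocks` of integer matrices with
#'   columns `start`, `end` sorted by genomic start; block lengths sum to
#'   `read_length`.
#' @export
project_to_genome <- function(reads, annotation, read_length = 101L) {
  chains <- exon_chains(annotation)
  n <- nrow(reads)
  out_blocks <- vector("list", 2L * n)
  out_strand <- character(2L * n)
  out_chrom <- character(2L * n)
  for (i in seq_len(n)) {
    chain <- chains[[reads$transcript_id[i]]]
    if (is.null(chain)) stop("Unknown transcript: ", reads$transcript_id[i])
    strand <- chain$strand[1]
    t1 <- reads$start[i]
    t2 <- t1 + reads$length[i] - 1L
    b1 <- interval_to_blocks(chain, t1, t1 + read_length - 1L)
    b2 <- interval_to_blocks(chain, t2 - read_length + 1L, t2)
    out_blocks[[2 * i - 1]] <- b1
    out_blocks[[2 * i]] <- b2
    out_strand[2 * i - 1] <- strand
    out_strand[2 * i] <- flip_strand(strand)
    out_chrom[c(2 * i - 1, 2 * i)] <- chain$chrom[1]
  }
  tibble::tibble(
    read_id = rep(reads$read_id, each = 2),
    end = rep(1:2, n),
    chrom = out_chrom,
    strand = out_strand,
    blocks = out_blocks
  )
}
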