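# Liftover of simulated alignments to original-reference coordinates,
# truth-encoded read names, and the truth database of read-supported events.
#
# A read alignment record has columns:
#   read_id, end (1/2), ord (record order within the pair), chrom,
#   pos (1-based leftmost original coordinate), strand (read alignment
#   strand), cigar (ops over M/I/D/N/S), tx_strand (transcription strand of
#   the source locus, used for junction orientation).

# --- lifting ---------------------------------------------------------------

# Ops of one block [s, e] (mutated coords) against the coordinate-map
# segments of its chromosome. Returns a list of rows (op, len, orig_s,
# orig_e, anchor).
block_ops <- function(seg, s, e) {
  i1 <- findInterval(s, seg$mut_start)
  i2 <- findInterval(e, seg$mut_start)
  out <- vector("list", i2 - i1 + 1)
  for (i in i1:i2) {
    ov_s <- max(s, seg$mut_start[i])
    ov_e <- min(e, seg$mut_end[i])
    if (ov_s > ov_e) next
    if (seg$type[i] == "match") {
      os <- seg$orig_start[i] + (ov_s - seg$mut_start[i])
      out[[i - i1 + 1]] <- list(op = "M", len = ov_e - ov_s + 1L,
                                orig_s = os, orig_e = os + (ov_e - ov_s),
                                anchor = NA_integer_)
    } else {
      out[[i - i1 + 1]] <- list(op = "I", len = ov_e - ov_s + 1L,
                                orig_s = NA_integer_, orig_e = NA_integer_,
                                anchor = seg$anchor[i])
    }
  }
  out[!vapply(out, is.null, logical(1))]
}

# Lift one read end on an ordinary chromosome to a single alignment record.
# blocks: tibble(start, end) in mutated coordinates, genomic order; N gaps
# between blocks are introns, D gaps within a block are deletions.
lift_ordinary_end <- function(chrom, blocks, map) {
  seg <- map$segments[[chrom]]
  if (is.null(seg)) stop("Unknown contig in lift: ", chrom)
  ops <- character(0); lens <- integer(0); anchors <- integer(0)
  prev_m_end <- NA_integer_; prev_m_block <- NA_integer_
  pos <- NA_integer_
  for (b in seq_len(nrow(blocks))) {
    for (row in block_ops(seg, blocks[b, 1], blocks[b, 2])) {
      if (row$op == "M") {
        if (!is.na(prev_m_end)) {
          gap <- row$orig_s - prev_m_end - 1L
          if (gap > 0) {
            ops <- c(ops, if (prev_m_block == b) "D" else "N")
            lens <- c(lens, gap)
            anchors <- c(anchors, NA_integer_)
          }
        }
        if (is.na(pos)) pos <- row$orig_s
        prev_m_end <- row$orig_e
        prev_m_block <- b
      }
      ops <- c(ops, row$op)
      lens <- c(lens, row$len)
      anchors <- c(anchors, row$anchor)
    }
  }
  # Insertion bases at the alignment edges have no flanking reference match:
  # represent them as soft clips.
  m_idx <- which(ops == "M")
  if (length(m_idx) == 0) {
    # Degenerate: the whole end lies inside inserted sequence.
    anchor <- anchors[which(ops == "I")[1]]
    return(list(chrom = chrom, pos = anchor, cigar = paste0(sum(lens), "S")))
  }
  before <- seq_len(m_idx[1] - 1)
  after <- if (m_idx[length(m_idx)] < length(ops)) (m_idx[length(m_idx)] + 1):length(ops) else integer(0)
  ops[before][ops[before] == "I"] <- "S"
  ops[after][ops[after] == "I"] <- "S"
  list(chrom = chrom, pos = pos, cigar = ops_to_cigar(ops, lens))
}

# Lift one read end on a fusion contig: split blocks at the registered
# breakpoint into one record per contig side, soft-clipping the bases that
# belong to the other side.
lift_fusion_end <- function(contig, blocks, end_strand, reg) {
  reg <- reg[reg$contig == contig, ]
  reg <- reg[order(reg$side), ]
  side_of <- function(p) if (p <= reg$contig_end[1]) 1L else 2L
  # Split each block at the side boundary.
  pieces <- list()
  for (b in seq_len(nrow(blocks))) {
    s <- blocks[b, 1]; e <- blocks[b, 2]
    if (side_of(s) == side_of(e)) {
      pieces[[length(pieces) + 1]] <- list(side = side_of(s), s = s, e = e, block = b)
    } else {
      cut <- reg$contig_end[1]
      pieces[[length(pieces) + 1]] <- list(side = 1L, s = s, e = cut, block = b)
      pieces[[length(pieces) + 1]] <- list(side = 2L, s = cut + 1L, e = e, block = b)
    }
  }
  sides <- vapply(pieces, function(p) p$side, integer(1))
  n_bases <- vapply(pieces, function(p) p$e - p$s + 1L, integer(1))
  records <- list()
  for (side in unique(sides)) {
    r <- reg[side, ]
    own <- which(sides == side)
    # Contig-order ops for this side: M runs with N gaps between pieces.
    ops <- character(0); lens <- integer(0)
    g_start <- integer(0); g_end <- integer(0)
    prev_e <- NA_integer_
    for (j in own) {
      p <- pieces[[j]]
      if (!is.na(prev_e)) {
        gap <- p$s - prev_e - 1L
        if (gap > 0) { ops <- c(ops, "N"); lens <- c(lens, gap) }
      }
      ops <- c(ops, "M"); lens <- c(lens, p$e - p$s + 1L)
      if (r$strand == "+") {
        g_start <- c(g_start, r$start + (p$s - r$contig_start))
        g_end <- c(g_end, r$start + (p$e - r$contig_start))
      } else {
        g_start <- c(g_start, r$end - (p$e - r$contig_start))
        g_end <- c(g_end, r$end - (p$s - r$contig_start))
      }
      prev_e <- p$e
    }
    before <- sum(n_bases[which(sides != side & seq_along(sides) < own[1])])
    after <- sum(n_bases[which(sides != side & seq_along(sides) > own[length(own)])])
    full_ops <- c(if (before > 0) "S", ops, if (after > 0) "S")
    full_lens <- c(if (before > 0) before, lens, if (after > 0) after)
    if (r$strand == "-") {
      full_ops <- rev(full_ops)
      full_lens <- rev(full_lens)
    }
    rec_strand <- if (xor(end_strand == "-", r$strand == "-")) "-" else "+"
    records[[length(records) + 1]] <- list(
      side = side, chrom = r$chrom, pos = min(g_start),
      strand = rec_strand, tx_strand = r$strand,
      cigar = ops_to_cigar(full_ops, full_lens)
    )
  }
  records
}

#' Lift projected read alignments to original-reference records
#'
#' Blocks on ordinary chromosomes become one record per read end whose CIGAR
#' gains I ops where the read crosses inserted bases, D ops where it spans
#' deletions and N ops for introns; insertion bases at the alignment edges
#' are soft-clipped. Blocks on registered fusion contigs are split at the
#' fusion breakpoint into one record per contig side, with the other side's
#' bases soft-clipped, mirroring chimeric SAM conventions.
#'
#' @param projections Tibble from [project_to_genome()] (simulation-reference
#'   coordinates).
#' @param map A `coord_map` from [apply_mutations()].
#' @param registry Fusion contig registry from [generate_fusions()], or
#'   `NULL` when no fusions were simulated.
#' @return Record tibble with columns `read_id`, `end`, `ord`, `chrom`,
#'   `pos`, `strand`, `cigar`, `tx_strand`, and `chimeric` (TRUE for
#'   records lifted from a fusion contig).
#' @export
lift_alignment <- function(projections, map, registry = NULL) {
  fusion_contigs <- if (is.null(registry)) character(0) else unique(registry$contig)
  n <- nrow(projections)
  cap <- 2L * n + 8L
  o_read <- integer(cap); o_end <- integer(cap); o_ord <- integer(cap)
  o_chrom <- character(cap); o_pos <- integer(cap)
  o_strand <- character(cap); o_cigar <- character(cap)
  o_txs <- character(cap)
  o_chim <- logical(cap)
  k <- 0L
  push <- function(read_id, end, ord, chrom, pos, strand, cigar, tx_strand,
                   chimeric = FALSE) {
    k <<- k + 1L
    o_read[k] <<- read_id; o_end[k] <<- end; o_ord[k] <<- ord
    o_chrom[k] <<- chrom; o_pos[k] <<- pos; o_strand[k] <<- strand
    o_cigar[k] <<- cigar; o_txs[k] <<- tx_strand; o_chim[k] <<- chimeric
  }
  for (i in seq_len(n)) {
    chrom <- projections$chrom[i]
    blocks <- projections$blocks[[i]]
    strand <- projections$strand[i]
    if (chrom %in% fusion_contigs) {
      recs <- lift_fusion_end(chrom, blocks, strand, registry)
      for (j in seq_along(recs)) {
        push(projections$read_id[i], projections$end[i], j, recs[[j]]$chrom,
             recs[[j]]$pos, recs[[j]]$strand, recs[[j]]$cigar,
             recs[[j]]$tx_strand, chimeric = TRUE)
      }
    } else {
      tx_strand <- if (projections$end[i] == 1L) strand else flip_strand(strand)
      seg <- map$segments[[chrom]]
      if (is.null(seg)) stop("Unknown contig in lift: ", chrom)
      if (nrow(blocks) == 1L) {
        # Fast path: single block fully inside one match segment.
        i1 <- findInterval(blocks[1, 1], seg$mut_start)
        if (seg$type[i1] == "match" && blocks[1, 2] <= seg$mut_end[i1]) {
          push(projections$read_id[i], projections$end[i], 1L, chrom,
               seg$orig_start[i1] + (blocks[1, 1] - seg$mut_start[i1]),
               strand, paste0(blocks[1, 2] - blocks[1, 1] + 1L, "M"), tx_strand)
          next
        }
      }
      rec <- lift_ordinary_end(chrom, blocks, map)
      push(projections$read_id[i], projections$end[i], 1L, rec$chrom, rec$pos,
           strand, rec$cigar, tx_strand)
    }
  }
  idx <- seq_len(k)
  tibble::tibble(read_id = o_read[idx], end = o_end[idx], ord = o_ord[idx],
                 chrom = o_chrom[idx], pos = o_pos[idx], strand = o_strand[idx],
                 cigar = o_cigar[idx], tx_strand = o_txs[idx],
                 chimeric = o_chim[idx])
}

# --- read-name codec -------------------------------------------------------

b64_encode_err <- function(err_pos) {
  if (length(err_pos) == 0) return("")
  enc <- jsonlite::base64_enc(charToRaw(paste(err_pos, collapse = ",")))
  gsub("=", "", enc, fixed = TRUE)
}

b64_decode_err <- function(field) {
  if (nchar(field) == 0) return(integer(0))
  pad <- (4 - nchar(field) %% 4) %% 4
  txt <- rawToChar(jsonlite::base64_dec(paste0(field, strrep("=", pad))))
  out <- suppressWarnings(as.integer(strsplit(txt, ",", fixed = TRUE)[[1]]))
  if (anyNA(out)) stop("not a comma-joined decimal list")
  out
}

#' Encode truth into a read name
#'
#' Implements the grammar `read_id:(chr,(-)pos,cigar(;)?)+:base64(err_pos?)`:
#' three colon-separated fields — the read id, the `;`-joined alignment
#' records (`chr,pos,cigar` with pos negated on the reverse strand), and the
#' merged 0-based sequencing-error offsets over the concatenated pair (end 1
#' then end 2), serialised as comma-joined decimals and base64-encoded
#' (standard alphabet, padding stripped; empty when there are no errors).
#'
#' @param read_id Non-negative integer read identifier.
#' @param alignments Tibble with columns `chrom`, `pos`, `strand`, `cigar`
#'   in record order.
#' @param err_pos Ascending integer offsets of sequencing errors.
#' @return A single read-name string.
#' @export
encode_read_name <- function(read_id, alignments, err_pos = integer(0)) {
  stopifnot(read_id >= 0)
  recs <- paste0(alignments$chrom, ",",
                 ifelse(alignments$strand == "-", -alignments$pos, alignments$pos),
                 ",", alignments$cigar)
  paste0(read_id, ":", paste(recs, collapse = ";"), ":", b64_encode_err(err_pos))
}

#' Decode a truth-encoded read name
#'
#' Exact inverse of [encode_read_name()].
#'
#' @param name Read-name string.
#' @return List with elements `read_id` (integer), `alignments` (tibble with
#'   `chrom`, `pos`, `strand`, `cigar`) and `err_pos` (integer vector).
#' @export
decode_read_name <- function(name) {
  first <- regexpr(":", name, fixed = TRUE)
  last <- max(gregexpr(":", name, fixed = TRUE)[[1]])
  if (first == -1 || last == first) {
    stop("Malformed read name (expected three ':'-separated fields): ", name)
  }
  id_field <- substr(name, 1, first - 1)
  aln_field <- substr(name, first + 1, last - 1)
  err_field <- substr(name, last + 1, nchar(name))
  read_id <- suppressWarnings(as.integer(id_field))
  if (is.na(read_id)) stop("Malformed read id in read name: ", id_field)
  parts <- strsplit(aln_field, ";", fixed = TRUE)[[1]]
  fields <- strsplit(parts, ",", fixed = TRUE)
  if (any(lengths(fields) != 3)) {
    stop("Malformed alignment record in read name: ", aln_field)
  }
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
  if (anyNA(pos)) stop("Malformed alignment position in read name: ", aln_field)
  strand <- ifelse(pos < 0, "-", "+")
  aln <- tibble::tibble(
    chrom = vapply(fields, `[[`, character(1), 1),
    pos = abs(pos),
    strand = strand,
    cigar = vapply(fields, `[[`, character(1), 3)
  )
  err <- tryCatch(b64_decode_err(err_field),
                  error = function(e) stop("Malformed error field in read name: ",
                                           err_field))
  list(read_id = read_id, alignments = aln, err_pos = err)
}

# Encode names for a whole dataset: one name per pair, concatenating end-1
# then end-2 records and merging error offsets over the pair.
encode_dataset_names <- function(reads, records, read_length) {
  if (nrow(reads) == 0) return(character(0))
  recs <- records[order(records$read_id, records$end, records$ord), ]
  signed <- ifelse(recs$strand == "-", -recs$pos, recs$pos)
  rec_str <- paste0(recs$chrom, ",", signed, ",", recs$cigar)
  aln_field <- vapply(split(rec_str, recs$read_id)[as.character(reads$read_id)],
                      paste, character(1), collapse = ";")
  err_field <- vapply(seq_len(nrow(reads)), function(i) {
    b64_encode_err(c(reads$err1[[i]], reads$err2[[i]] + read_length))
  }, character(1))
  paste0(reads$read_id, ":", aln_field, ":", err_field)
}

# --- truth database --------------------------------------------------------

# Expand records into per-op reference coordinates.
# Returns tibble: rec, read_id, end, block-free op info: op, len, ref_start,
# ref_end (M/D/N; NA otherwise), anchor (I: base before the insertion).
records_ref_ops <- function(records) {
  ops <- parse_cigar(records$cigar)
  ref_start <- integer(nrow(ops))
  ref_end <- integer(nrow(ops))
  anchor <- rep(NA_integer_, nrow(ops))
  cur <- 0L
  rec_prev <- 0L
  for (i in seq_len(nrow(ops))) {
    if (ops$rec[i] != rec_prev) {
      cur <- records$pos[ops$rec[i]]
      rec_prev <- ops$rec[i]
    }
    if (ops$op[i] %in% c("M", "D", "N")) {
      ref_start[i] <- cur
      ref_end[i] <- cur + ops$len[i] - 1L
      cur <- cur + ops$len[i]
    } else {
      ref_start[i] <- NA_integer_
      ref_end[i] <- NA_integer_
      anchor[i] <- cur - 1L
    }
  }
  tibble::tibble(
    rec = ops$rec,
    read_id = records$read_id[ops$rec],
    end = records$end[ops$rec],
    chrom = records$chrom[ops$rec],
    tx_strand = records$tx_strand[ops$rec],
    op = ops$op, len = ops$len,
    ref_start = ref_start, ref_end = ref_end, anchor = anchor
  )
}

#' Build the truth database of read-supported events
#'
#' A mutation enters iff at least one read's lifted alignment expresses it
#' (an M op covering an SNV, the D op of a deletion, the internal I op of an
#' insertion). Every N op contributes its intron as a splice junction unless
#' its span exceeds `colinear_threshold`, in which case it enters the fusion
#' table as a colinear fusion junction — classification is geometric, never
#' by provenance. Adjacent record pairs of chimeric (fusion-contig) reads
#' contribute junctions classified with [classify_junction()]. All entries
#' are deduplicated with per-event support counts.
#'
#' @param records Record tibble from [lift_alignment()].
#' @param mutations Applied mutation tibble (the simulated truth set).
#' @param colinear_threshold Colinear fusion span threshold in bases.
#' @return List of class `truth_db` with tibbles `mutations` (read-supported
#'   rows plus `support`), `splices` (`chrom`, `start`, `end`, `strand`,
#'   `support`; intron coordinates) and `fusions` (`chrom1`, `pos1`,
#'   `strand1`, `chrom2`, `pos2`, `strand2`, `class`, `support`).
#' @export
build_truth_db <- function(records, mutations, colinear_threshold = 300000L) {
  ops <- records_ref_ops(records)

  # Mutation support.
  mut <- mutations
  support <- integer(nrow(mut))
  chim <- if ("chimeric" %in% names(records)) records$chimeric else
    rep(FALSE, nrow(records))
  # Fusion contigs carry unmutated parent-gene sequence: their records
  # attest junctions but cannot evidence mutations.
  m_ops <- ops[ops$op == "M" & !chim[ops$rec], ]
  if (nrow(mut) > 0 && nrow(m_ops) > 0) {
    cov_gr <- GenomicRanges::GRanges(m_ops$chrom,
                                     IRanges::IRanges(m_ops$ref_start, m_ops$ref_end))
    snv_idx <- which(mut$kind == "SNV")
    if (length(snv_idx) > 0) {
      q <- GenomicRanges::GRanges(mut$chrom[snv_idx],
                                  IRanges::IRanges(mut$pos[snv_idx], mut$pos[snv_idx]))
      support[snv_idx] <- GenomicRanges::countOverlaps(q, cov_gr)
    }
    d_ops <- ops[ops$op == "D", ]
    del_idx <- which(mut$kind == "DEL")
    if (length(del_idx) > 0 && nrow(d_ops) > 0) {
      key <- paste(d_ops$chrom, d_ops$ref_start, d_ops$len)
      mkey <- paste(mut$chrom[del_idx], mut$pos[del_idx], nchar(mut$ref[del_idx]))
      support[del_idx] <- as.integer(table(key)[mkey])
      support[del_idx][is.na(support[del_idx])] <- 0L
    }
    i_ops <- ops[ops$op == "I", ]
    ins_idx <- which(mut$kind == "INS")
    if (length(ins_idx) > 0 && nrow(i_ops) > 0) {
      key <- paste(i_ops$chrom, i_ops$anchor, i_ops$len)
      mkey <- paste(mut$chrom[ins_idx], mut$pos[ins_idx], nchar(mut$alt[ins_idx]))
      support[ins_idx] <- as.integer(table(key)[mkey])
      support[ins_idx][is.na(support[ins_idx])] <- 0L
    }
  }
  mut$support <- support
  mut <- mut[mut$support > 0, ]

  # Splice junctions and long-intron colinear fusions from N ops.
  n_ops <- ops[ops$op == "N", ]
  splice_rows <- tibble::tibble(chrom = character(), start = integer(),
                                end = integer(), strand = character())
  fusion_rows <- tibble::tibble(chrom1 = character(), pos1 = integer(),
                                strand1 = character(), chrom2 = character(),
                                pos2 = integer(), strand2 = character(),
                                class = character())
  if (nrow(n_ops) > 0) {
    long <- n_ops$len > colinear_threshold
    sp <- n_ops[!long, ]
    splice_rows <- dplyr::bind_rows(splice_rows, tibble::tibble(
      chrom = sp$chrom, start = sp$ref_start, end = sp$ref_end,
      strand = sp$tx_strand))
    lg <- n_ops[long, ]
    if (nrow(lg) > 0) {
      donor <- ifelse(lg$tx_strand == "+", lg$ref_start - 1L, lg$ref_end + 1L)
      acceptor <- ifelse(lg$tx_strand == "+", lg$ref_end + 1L, lg$ref_start - 1L)
      fusion_rows <- dplyr::bind_rows(fusion_rows, tibble::tibble(
        chrom1 = lg$chrom, pos1 = donor, strand1 = lg$tx_strand,
        chrom2 = lg$chrom, pos2 = acceptor, strand2 = lg$tx_strand,
        class = "COLINEAR_FUSION"))
    }
  }

  # Junctions between adjacent records of chimeric read ends.
  multi <- records |>
    dplyr::group_by(.data$read_id, .data$end) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::arrange(.data$ord, .by_group = TRUE) |>
    dplyr::ungroup()
  if (nrow(multi) > 0) {
    span <- cigar_ref_span(multi$cigar)
    ref_end <- multi$pos + span - 1L
    grp <- paste(multi$read_id, multi$end)
    for (g in unique(grp)) {
      idx <- which(grp == g)
      for (j in seq_len(length(idx) - 1)) {
        r1 <- idx[j]; r2 <- idx[j + 1]
        donor <- if (multi$tx_strand[r1] == "+") ref_end[r1] else multi$pos[r1]
        acceptor <- if (multi$tx_strand[r2] == "+") multi$pos[r2] else ref_end[r2]
        cls <- classify_junction(multi$chrom[r1], donor, multi$tx_strand[r1],
                                 multi$chrom[r2], acceptor, multi$tx_strand[r2],
                                 colinear_threshold)
        if (cls == "SPLICE") {
          # Genomic intron interval; on the minus strand the acceptor
          # precedes the donor in reference order.
          splice_rows <- dplyr::bind_rows(splice_rows, tibble::tibble(
            chrom = multi$chrom[r1],
            start = min(donor, acceptor) + 1L,
            end = max(donor, acceptor) - 1L,
            strand = multi$tx_strand[r1]))
        } else {
          fusion_rows <- dplyr::bind_rows(fusion_rows, tibble::tibble(
            chrom1 = multi$chrom[r1], pos1 = donor, strand1 = multi$tx_strand[r1],
            chrom2 = multi$chrom[r2], pos2 = acceptor, strand2 = multi$tx_strand[r2],
            class = cls))
        }
      }
    }
  }

  splices <- splice_rows |>
    dplyr::count(.data$chrom, .data$start, .data$end, .data$strand,
                 name = "support") |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
  fusions <- fusion_rows |>
    dplyr::count(.data$chrom1, .data$pos1, .data$strand1,
                 .data$chrom2, .data$pos2, .data$strand2, .data$class,
                 name = "support") |>
    dplyr::arrange(.data$chrom1, .data$pos1)

  structure(list(mutations = mut, splices = splices, fusions = fusions),
            class = "truth_db")
}

#' @exportS3Method base::print
print.truth_db <- function(x, ...) {
  cat("<truth_db> ", nrow(x$mutations), " mutation(s), ", nrow(x$splices),
      " splice junction(s), ", nrow(x$fusions), " fusion junction(s)\n", sep = "")
  invisible(x)
}
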