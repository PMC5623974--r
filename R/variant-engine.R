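# Random and VCF-guided mutation generation, overlap resolution, genome
# editing, and the coordinate map between mutated and original references.
#
# Mutations are rows of a tibble with columns:
#   kind  : "SNV", "INS" or "DEL"
#   chrom : chromosome name (original reference)
#   pos   : 1-based original coordinate; first affected base for SNV/DEL,
#           anchor base for INS (alt inserted immediately after pos)
#   ref   : reference allele ("" for INS)
#   alt   : alternate allele ("" for DEL)
#   source: "random" or "vcf"

mutation_tibble <- function(kind = character(), chrom = character(),
                            pos = integer(), ref = character(),
                            alt = character(), source = character()) {
  tibble::tibble(kind = kind, chrom = chrom, pos = as.integer(pos),
                 ref = ref, alt = alt, source = source)
}

# 1-based positions of non-N bases of a sequence, as an integer vector.
non_n_positions <- function(seq) {
  raw <- charToRaw(seq)
  which(raw != charToRaw("N"))
}

base_at <- function(seq, pos) {
  substring(seq, pos, pos)
}

# Draw, for each reference base, an alternate base uniformly among the other 3.
draw_alt_bases <- function(ref) {
  vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1), character(1),
         USE.NAMES = FALSE)
}

#' Generate random SNVs at a per-base rate
#'
#' Each non-N base of each chromosome is selected independently with
#' probability `rate`; the alternate base is drawn uniformly among the three
#' bases different from the reference base.
#'
#' @param genome Named character vector of sequences.
#' @param rate Per-base substitution probability in \[0, 1\].
#' @return Mutation tibble (`kind == "SNV"`, `source == "random"`), sorted by
#'   chromosome and position.
#' @export
generate_random_snvs <- function(genome, rate) {
  stopifnot(rate >= 0, rate <= 1)
  out <- lapply(names(genome), function(chrom) {
    sites <- non_n_positions(genome[[chrom]])
    n <- stats::rbinom(1, length(sites), rate)
    if (n == 0) return(NULL)
    pos <- sort(sample(sites, n))
    ref <- base_at(genome[[chrom]], pos)
    mutation_tibble("SNV", chrom, pos, ref, draw_alt_bases(ref), "random")
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) mutation_tibble() else res
}

#' Generate random short insertions and deletions
#'
#' Insertion anchors and deletion start sites are selected per non-N base at
#' their respective rates; lengths are uniform on `1..max_indel_len`;
#' inserted bases are uniform over A/C/G/T. Deletions that would run past the
#' chromosome end, or whose span contains an N base, are rejected and
#' resampled.
#'
#' @param genome Named character vector of sequences.
#' @param ins_rate Per-base insertion probability.
#' @param del_rate Per-base deletion probability (defaults to `ins_rate`).
#' @param max_indel_len Maximum indel length in bases (default 15).
#' @return Mutation tibble with kinds "INS"/"DEL", `source == "random"`.
#' @export
generate_random_indels <- function(genome, ins_rate, del_rate = ins_rate,
                                   max_indel_len = 15L) {
  stopifnot(max_indel_len >= 1, ins_rate >= 0, ins_rate <= 1,
            del_rate >= 0, del_rate <= 1)
  out <- lapply(names(genome), function(chrom) {
    seq <- genome[[chrom]]
    sites <- non_n_positions(seq)
    L <- nchar(seq)

    n_ins <- stats::rbinom(1, length(sites), ins_rate)
    ins <- NULL
    if (n_ins > 0) {
      pos <- sample(sites, n_ins)
      lens <- sample.int(max_indel_len, n_ins, replace = TRUE)
      alt <- vapply(lens, random_dna, character(1))
      ins <- mutation_tibble("INS", chrom, pos, "", alt, "random")
    }

    n_del <- stats::rbinom(1, length(sites), del_rate)
    del <- NULL
    if (n_del > 0) {
      lens <- sample.int(max_indel_len, n_del, replace = TRUE)
      pos <- integer(n_del)
      for (i in seq_len(n_del)) {
        repeat {
          p <- sample(sites, 1)
          if (p + lens[i] - 1 <= L &&
              !grepl("N", substring(seq, p, p + lens[i] - 1), fixed = TRUE)) {
            pos[i] <- p
            break
          }
        }
      }
      del <- mutation_tibble("DEL", chrom, pos, substring(seq, pos, pos + lens - 1),
                             "", "random")
    }
    dplyr::bind_rows(ins, del)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) mutation_tibble() else res
}

#' Load mutations from a VCF file
#'
#' Only biallelic records are converted; multi-allelic records (comma in ALT)
#' are skipped and counted in the `skipped` attribute of the result. The
#' REF/ALT length relation classifies records into SNV, INS (ALT extends REF
#' by a suffix inserted after POS) and DEL (REF extends ALT; deleted bases
#' start at POS + 1). Records whose REF does not match `genome` (when
#' provided) are skipped with a warning.
#'
#' @param path Path to a VCF file.
#' @param genome Optional genome for REF validation.
#' @return Mutation tibble with `source == "vcf"` and attribute `skipped`
#'   (count of multi-allelic or unsupported records).
#' @export
load_vcf_mutations <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  chrom <- fix$CHROM
  pos <- as.integer(fix$POS)
  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)

  multi <- grepl(",", alt, fixed = TRUE)
  skipped <- sum(multi)
  keep <- !multi & !is.na(alt) & !is.na(ref)

  kind <- rep(NA_character_, length(ref))
  m_snv <- keep & nchar(ref) == 1 & nchar(alt) == 1
  m_ins <- keep & nchar(ref) == 1 & nchar(alt) > 1 &
    substring(alt, 1, 1) == ref
  m_del <- keep & nchar(alt) == 1 & nchar(ref) > 1 &
    substring(ref, 1, 1) == alt
  kind[m_snv] <- "SNV"
  kind[m_ins] <- "INS"
  kind[m_del] <- "DEL"
  skipped <- skipped + sum(keep & is.na(kind))

  out <- dplyr::bind_rows(
    mutation_tibble("SNV", chrom[m_snv], pos[m_snv], ref[m_snv], alt[m_snv], "vcf"),
    mutation_tibble("INS", chrom[m_ins], pos[m_ins], "",
                    substring(alt[m_ins], 2), "vcf"),
    mutation_tibble("DEL", chrom[m_del], pos[m_del] + 1L,
                    substring(ref[m_del], 2), "", "vcf")
  )

  if (!is.null(genome)) {
    check_ref <- ifelse(out$kind == "INS",
                        base_at(genome[out$chrom], out$pos),
                        substring(genome[out$chrom], out$pos,
                                  out$pos + pmax(nchar(out$ref), 1) - 1))
    expected <- ifelse(out$kind == "INS", check_ref, out$ref)
    ok <- !is.na(check_ref) & check_ref == expected & out$chrom %in% names(genome)
    if (any(!ok)) {
      warning(sum(!ok), " VCF record(s) with REF mismatching the genome were skipped")
      skipped <- skipped + sum(!ok)
      out <- out[ok, ]
    }
  }
  attr(out, "skipped") <- skipped
  out
}

#' Mix VCF-guided and randomly generated mutations
#'
#' The final set contains `round(vcf_ratio * total)` mutations sampled
#' without replacement from the VCF pool and the remainder sampled from the
#' random pool. If the VCF pool is too small the shortfall is filled from the
#' random pool with a warning.
#'
#' @param vcf_mutations Mutation tibble with `source == "vcf"`.
#' @param random_mutations Mutation tibble with `source == "random"`.
#' @param vcf_ratio Fraction of the final set drawn from the VCF in \[0, 1\].
#' @param total Size of the final set (default: size of the random pool).
#' @return Mutation tibble of `total` rows (VCF-sourced rows first).
#' @export
mix_sources <- function(vcf_mutations, random_mutations, vcf_ratio,
                        total = nrow(random_mutations)) {
  stopifnot(vcf_ratio >= 0, vcf_ratio <= 1, total >= 0)
  n_vcf <- round(vcf_ratio * total)
  if (n_vcf > nrow(vcf_mutations)) {
    warning("VCF pool has only ", nrow(vcf_mutations), " records; filling ",
            n_vcf - nrow(vcf_mutations), " from the random pool")
    n_vcf <- nrow(vcf_mutations)
  }
  n_rand <- total - n_vcf
  if (n_rand > nrow(random_mutations)) {
    stop("Random pool too small: need ", n_rand, ", have ", nrow(random_mutations))
  }
  picked_vcf <- vcf_mutations[sample(nrow(vcf_mutations), n_vcf), ]
  picked_rand <- random_mutations[sample(nrow(random_mutations), n_rand), ]
  dplyr::bind_rows(picked_vcf, picked_rand)
}

mutation_footprint <- function(mutations) {
  len <- ifelse(mutations$kind == "DEL", nchar(mutations$ref), 1L)
  tibble::tibble(chrom = mutations$chrom,
                 start = mutations$pos,
                 end = mutations$pos + as.integer(len) - 1L)
}

#' Drop overlapping mutations, keeping the earliest generated
#'
#' Mutations are scanned in input (generation) order; one is dropped iff its
#' footprint (SNV: the substituted base; DEL: the deleted span; INS: the
#' anchor base) intersects the footprint of an already kept mutation.
#'
#' @param mutations Mutation tibble in generation order.
#' @return Mutation tibble with pairwise-disjoint footprints, sorted by
#'   chromosome and position.
#' @export
resolve_overlaps <- function(mutations) {
  if (nrow(mutations) == 0) return(mutations)
  fp <- mutation_footprint(mutations)
  keep <- logical(nrow(mutations))
  occupied <- list()
  for (chrom in unique(fp$chrom)) {
    idx <- which(fp$chrom == chrom)
    max_end <- max(fp$end[idx])
    occ <- logical(max_end)
    for (i in idx) {
      span <- fp$start[i]:fp$end[i]
      if (!any(occ[span])) {
        keep[i] <- TRUE
        occ[span] <- TRUE
      }
    }
  }
  out <- mutations[keep, ]
  out[order(out$chrom, out$pos), ]
}

# ---------------------------------------------------------------------------
# Coordinate map

new_coord_map <- function(segments, orig_len, mut_len) {
  structure(list(segments = segments, orig_len = orig_len, mut_len = mut_len),
            class = "coord_map")
}

#' @exportS3Method base::print
print.coord_map <- function(x, ...) {
  cat("<coord_map> ", length(x$segments), " chromosome(s)\n", sep = "")
  for (chrom in names(x$segments)) {
    cat("  ", chrom, ": ", x$orig_len[[chrom]], " -> ", x$mut_len[[chrom]],
        " bases, ", nrow(x$segments[[chrom]]), " segment(s)\n", sep = "")
  }
  invisible(x)
}

#' Apply a mutation set to a genome
#'
#' Substitutes SNV bases, inserts INS alleles after their anchor and removes
#' DEL spans, producing the haploid mutated genome together with the
#' piecewise coordinate map that inverts the edit script.
#'
#' @param genome Named character vector of sequences.
#' @param mutations Mutation tibble with pairwise-disjoint footprints (see
#'   [resolve_overlaps()]); `ref` alleles must match the genome.
#' @return List with elements `genome` (mutated sequences) and `map`
#'   (a `coord_map`).
#' @export
apply_mutations <- function(genome, mutations) {
  assert_cols(mutations, c("kind", "chrom", "pos", "ref", "alt"), "mutations")
  segments <- list()
  mutated <- genome
  mut_len <- integer(0)
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    L <- nchar(seq)
    m <- mutations[mutations$chrom == chrom, ]
    m <- m[order(m$pos), ]

    # Validate reference alleles.
    chk <- m$kind != "INS"
    if (any(chk)) {
      obs <- substring(seq, m$pos[chk], m$pos[chk] + nchar(m$ref[chk]) - 1)
      bad <- which(obs != m$ref[chk])
      if (length(bad) > 0) {
        i <- which(chk)[bad[1]]
        stop("Reference mismatch at ", chrom, ":", m$pos[i],
             " (expected ", m$ref[i], ", genome has ", obs[bad[1]], ")")
      }
    }
    if (any(m$pos < 1 | m$pos + ifelse(m$kind == "DEL", nchar(m$ref), 1) - 1 > L)) {
      stop("Mutation out of bounds on ", chrom)
    }

    # SNVs first: they do not move coordinates.
    snv <- m[m$kind == "SNV", ]
    if (nrow(snv) > 0) {
      raw <- charToRaw(seq)
      raw[snv$pos] <- charToRaw(paste(snv$alt, collapse = ""))
      seq <- rawToChar(raw)
    }

    indels <- m[m$kind != "SNV", ]
    pieces <- character(0)
    seg_type <- character(0)
    seg_mut_start <- integer(0)
    seg_mut_end <- integer(0)
    seg_orig_start <- integer(0)
    seg_anchor <- integer(0)
    o <- 1L       # next original position to copy
    ms <- 1L      # next mutated position to fill
    for (i in seq_len(nrow(indels))) {
      p <- indels$pos[i]
      if (indels$kind[i] == "INS") {
        k <- nchar(indels$alt[i])
        pieces <- c(pieces, substring(seq, o, p), indels$alt[i])
        seg_type <- c(seg_type, "match", "ins")
        seg_mut_start <- c(seg_mut_start, ms, ms + (p - o) + 1L)
        seg_mut_end <- c(seg_mut_end, ms + (p - o), ms + (p - o) + k)
        seg_orig_start <- c(seg_orig_start, o, NA_integer_)
        seg_anchor <- c(seg_anchor, NA_integer_, p)
        ms <- ms + (p - o + 1L) + k
        o <- p + 1L
      } else { # DEL
        k <- nchar(indels$ref[i])
        if (p > o) {
          pieces <- c(pieces, substring(seq, o, p - 1L))
          seg_type <- c(seg_type, "match")
          seg_mut_start <- c(seg_mut_start, ms)
          seg_mut_end <- c(seg_mut_end, ms + (p - o) - 1L)
          seg_orig_start <- c(seg_orig_start, o)
          seg_anchor <- c(seg_anchor, NA_integer_)
          ms <- ms + (p - o)
        }
        o <- p + k
      }
    }
    if (o <= L) {
      pieces <- c(pieces, substring(seq, o, L))
      seg_type <- c(seg_type, "match")
      seg_mut_start <- c(seg_mut_start, ms)
      seg_mut_end <- c(seg_mut_end, ms + (L - o))
      seg_orig_start <- c(seg_orig_start, o)
      seg_anchor <- c(seg_anchor, NA_integer_)
      ms <- ms + (L - o) + 1L
    }
    mutated[[chrom]] <- paste(pieces, collapse = "")
    if (nrow(indels) == 0) mutated[[chrom]] <- seq
    segments[[chrom]] <- tibble::tibble(
      type = seg_type, mut_start = seg_mut_start, mut_end = seg_mut_end,
      orig_start = seg_orig_start, anchor = seg_anchor
    )
    mut_len[[chrom]] <- ms - 1L
    stopifnot(mut_len[[chrom]] == nchar(mutated[[chrom]]))
  }
  list(genome = mutated,
       map = new_coord_map(segments, vapply(genome, nchar, integer(1)), mut_len))
}

#' Lift mutated-genome positions to the original reference
#'
#' Positions inside inserted bases have no original image: they are flagged
#' and mapped to the insertion anchor base.
#'
#' @param map A `coord_map` from [apply_mutations()].
#' @param chrom Chromosome name.
#' @param pos Integer vector of 1-based mutated-genome positions.
#' @return Tibble with columns `chrom`, `pos` (original coordinate) and
#'   `inside_insertion`.
#' @export
lift_position <- function(map, chrom, pos) {
  seg <- map$segments[[chrom]]
  if (is.null(seg)) stop("Unknown chromosome in coordinate map: ", chrom)
  if (any(pos < 1 | pos > map$mut_len[[chrom]])) {
    stop("Position outside mutated chromosome ", chrom)
  }
  idx <- findInterval(pos, seg$mut_start)
  ins <- seg$type[idx] == "ins"
  orig <- ifelse(ins, seg$anchor[idx], seg$orig_start[idx] + (pos - seg$mut_start[idx]))
  tibble::tibble(chrom = chrom, pos = as.integer(orig), inside_insertion = ins)
}

#' Map original-reference positions forward onto the mutated genome
#'
#' Positions falling inside a deleted span are snapped to the first surviving
#' base after the deletion (or the last mutated base for a deletion at the
#' chromosome end).
#'
#' @param map A `coord_map` from [apply_mutations()].
#' @param chrom Chromosome name.
#' @param pos Integer vector of 1-based original-genome positions.
#' @return Integer vector of mutated-genome positions.
#' @export
shift_position <- function(map, chrom, pos) {
  seg <- map$segments[[chrom]]
  if (is.null(seg)) stop("Unknown chromosome in coordinate map: ", chrom)
  if (any(pos < 1 | pos > map$orig_len[[chrom]])) {
    stop("Position outside original chromosome ", chrom)
  }
  ms <- seg[seg$type == "match", ]
  orig_end <- ms$orig_start + (ms$mut_end - ms$mut_start)
  idx <- findInterval(pos, ms$orig_start)
  out <- integer(length(pos))
  for (i in seq_along(pos)) {
    j <- idx[i]
    if (j == 0) {
      out[i] <- ms$mut_start[1]       # deleted prefix: snap forward
    } else if (pos[i] <= orig_end[j]) {
      out[i] <- ms$mut_start[j] + (pos[i] - ms$orig_start[j])
    } else if (j < nrow(ms)) {
      out[i] <- ms$mut_start[j + 1]   # inside a deletion: snap forward
    } else {
      out[i] <- map$mut_len[[chrom]]  # deletion at chromosome end: snap back
    }
  }
  out
}

#' Shift annotation coordinates onto the mutated genome
#'
#' Every exon boundary is mapped through the forward direction of the map;
#' boundaries landing inside a deletion snap to the nearest surviving base.
#' Exon order and strand are preserved.
#'
#' @param annotation Annotation tibble in original coordinates.
#' @param map A `coord_map` from [apply_mutations()].
#' @return Annotation tibble in mutated-genome coordinates.
#' @export
shift_annotations <- function(annotation, map) {
  out <- annotation
  for (chrom in unique(annotation$chrom)) {
    idx <- which(annotation$chrom == chrom)
    out$start[idx] <- shift_position(map, chrom, annotation$start[idx])
    out$end[idx] <- shift_position(map, chrom, annotation$end[idx])
  }
  out
}

#' Write mutations to a minimal VCF file
#'
#' Emits VCF 4.2 records using the standard anchored representation for
#' indels (insertions: REF is the anchor base, ALT prepends it; deletions:
#' POS moves one base left and REF prepends the anchor base).
#'
#' @param mutations Mutation tibble.
#' @param path Output path.
#' @param genome Genome used to recover anchor bases for indels.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(mutations, path, genome) {
  m <- mutations[order(mutations$chrom, mutations$pos), ]
  pos <- m$pos
  ref <- m$ref
  alt <- m$alt
  is_ins <- m$kind == "INS"
  is_del <- m$kind == "DEL"
  if (any(is_ins)) {
    anchor <- base_at(genome[m$chrom[is_ins]], m$pos[is_ins])
    ref[is_ins] <- anchor
    alt[is_ins] <- paste0(anchor, m$alt[is_ins])
  }
  if (any(is_del)) {
    first <- m$pos[is_del] == 1L
    ap <- ifelse(first, m$pos[is_del] + nchar(m$ref[is_del]), m$pos[is_del] - 1L)
    anchor <- base_at(genome[m$chrom[is_del]], ap)
    pos[is_del] <- ifelse(first, 1L, m$pos[is_del] - 1L)
    ref[is_del] <- ifelse(first, paste0(m$ref[is_del], anchor),
                          paste0(anchor, m$ref[is_del]))
    alt[is_del] <- anchor
  }
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", names(genome), nchar(genome)),
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", m$chrom, pos, ref, alt)
  writeLines(c(header, body), path)
  invisible(path)
}
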