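# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of the same length, reverse-complemented.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a random DNA sequence
#'
#' Draws bases uniformly from A/C/G/T using the session RNG.
#'
#' @param n Sequence length in bases.
#' @return A single string of length `n`.
#' @export
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

flip_strand <- function(s) {
  out <- s
  out[s == "+"] <- "-"
  out[s == "-"] <- "+"
  out
}

# Parse CIGAR strings into a long tibble of ops.
# Returns one row per op: rec (index into `cigar`), op, len.
parse_cigar <- function(cigar) {
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDNS])")
  bad <- vapply(seq_along(cigar), function(i) {
    nchar(paste0(m[[i]][, 1], collapse = "")) != nchar(cigar[[i]])
  }, logical(1))
  if (any(bad)) {
    stop("Malformed CIGAR string: ", cigar[which(bad)[1]])
  }
  n_ops <- vapply(m, nrow, integer(1))
  tibble::tibble(
    rec = rep(seq_along(cigar), n_ops),
    op = unlist(lapply(m, function(x) x[, 3]), use.names = FALSE) %||% character(0),
    len = as.integer(unlist(lapply(m, function(x) x[, 2]), use.names = FALSE))
  )
}

# Reference span consumed by a CIGAR (M/D/N ops), vectorised.
cigar_ref_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  keep <- ops$op %in% c("M", "D", "N")
  out <- rep(0L, length(cigar))
  if (any(keep)) {
    agg <- tapply(ops$len[keep], ops$rec[keep], sum)
    out[as.integer(names(agg))] <- as.integer(agg)
  }
  out
}

# Read bases consumed by a CIGAR (M/I/S ops), vectorised.
cigar_read_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  keep <- ops$op %in% c("M", "I", "S")
  out <- rep(0L, length(cigar))
  if (any(keep)) {
    agg <- tapply(ops$len[keep], ops$rec[keep], sum)
    out[as.integer(names(agg))] <- as.integer(agg)
  }
  out
}

# Collapse adjacent ops of the same type and render as a CIGAR string.
ops_to_cigar <- function(op, len) {
  keep <- len > 0
  op <- op[keep]
  len <- len[keep]
  if (length(op) == 0) return("")
  grp <- cumsum(c(TRUE, op[-1] != op[-length(op)]))
  lens <- as.integer(tapply(len, grp, sum))
  ops <- op[!duplicated(grp)]
  paste0(lens, ops, collapse = "")
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing required column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}
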